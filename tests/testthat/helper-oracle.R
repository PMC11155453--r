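## Independent oracles used to cross-check the package implementation.
## Deliberately written as plain loops sharing no code with the package.

## all simple directed paths from receptors, filtered by the node-count rule
## (3..10, or 2 when the single edge is a receptor regulation); optionally
## restricted to end in `targets`, optionally reduced to tied-shortest paths
## per (start, end) pair. Returns a sorted character vector of path keys
## "g1>g2>...".
oracle_enumerate_paths <- function(db, min_len = 3L, max_len = 10L,
                                   targets = NULL,
                                   mode = c("all", "shortest")) {
  mode <- match.arg(mode)
  edges <- db$edges
  ## expand bidirectional edges into both directions
  src <- c(edges$source, edges$target[edges$bidirectional == 1L])
  tgt <- c(edges$target, edges$source[edges$bidirectional == 1L])
  cat <- c(edges$category, edges$category[edges$bidirectional == 1L])
  keep <- !duplicated(paste(src, tgt))
  src <- src[keep]; tgt <- tgt[keep]; cat <- cat[keep]
  adj <- split(tgt, src)
  catmap <- setNames(cat, paste(src, tgt))
  receptors <- db$roles$receptor
  all_paths <- list()
  dfs <- function(path) {
    if (length(path) > max_len) return(invisible())
    all_paths[[length(all_paths) + 1L]] <<- path
    for (nxt in adj[[path[length(path)]]]) {
      if (!(nxt %in% path)) dfs(c(path, nxt))
    }
  }
  for (r in receptors) dfs(r)
  ok <- vapply(all_paths, function(p) {
    if (!is.null(targets) && !(p[length(p)] %in% targets)) return(FALSE)
    n <- length(p)
    if (n >= min_len && n <= max_len) return(TRUE)
    n == 2L && identical(catmap[[paste(p[1L], p[2L])]],
                         "receptor_regulation")
  }, logical(1L))
  paths <- all_paths[ok]
  if (mode == "shortest") {
    ## keep only tied-shortest paths per (start, end), measured over ALL
    ## enumerated simple paths (true graph distance)
    ends <- vapply(all_paths, function(p) paste(p[1L], p[length(p)]),
                   character(1L))
    best <- tapply(lengths(all_paths), ends, min)
    keep <- vapply(paths, function(p) {
      length(p) == 2L && identical(catmap[[paste(p[1L], p[2L])]],
                                   "receptor_regulation") ||
        length(p) == best[[paste(p[1L], p[length(p)])]]
    }, logical(1L))
    paths <- paths[keep]
  }
  sort(vapply(paths, paste, character(1L), collapse = ">"))
}

path_list_keys <- function(pl) {
  sort(vapply(pl$paths, paste, character(1L), collapse = ">"))
}

## straight-line single-cell forward pass: explicit loops over nodes, heads,
## paths and positions; no batching, no shared helpers
oracle_forward <- function(x, ctx, cfg, params) {
  n <- ctx$n; E <- cfg$h_emb; h <- cfg$h; dk <- cfg$d_k
  u_w <- cfg$u; r <- cfg$r; p <- ctx$p
  lnorm <- function(v, g, b) {
    mu <- mean(v); s <- sqrt(mean((v - mu)^2) + 1e-5)
    ((v - mu) / s) * g + b
  }
  smax <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  H <- matrix(0, n, E)
  for (uu in seq_len(n)) {
    H[uu, ] <- params$gene_emb[uu, ] + x[uu] * params$w_expr +
      params$z_in[ctx$deg_in_bucket[uu], ] +
      params$z_out[ctx$deg_out_bucket[uu], ]
  }
  P_layers <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    lp <- params$layers[[l]]
    Hn <- H
    if (cfg$layer_norm) {
      for (uu in seq_len(n)) Hn[uu, ] <- lnorm(H[uu, ], lp$ln1_g, lp$ln1_b)
    }
    O <- matrix(0, n, E)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dk + 1L):(i * dk)
      Q <- Hn %*% lp$Wq[, cols]; K <- Hn %*% lp$Wk[, cols]
      V <- Hn %*% lp$Wv[, cols]
      for (uu in seq_len(n)) {
        logit <- numeric(n)
        for (vv in seq_len(n)) {
          cidx <- ctx$cat_idx[uu, vv]
          bias <- sum(lp$edge_emb[cidx, ] * lp$w_edge[, i])
          nib <- if (cfg$node_index_mode == "full") lp$nib[uu, vv, i] else
            sum(lp$nib_a[uu, , i] * lp$nib_b[vv, , i])
          logit[vv] <- sum(Q[uu, ] * K[vv, ]) / sqrt(dk) + bias + nib
        }
        a <- smax(logit)
        acc <- numeric(dk)
        for (vv in seq_len(n)) acc <- acc + a[vv] * V[vv, ]
        O[uu, cols] <- acc
      }
    }
    H <- H + O %*% lp$Wo
    Hn2 <- H
    if (cfg$layer_norm) {
      for (uu in seq_len(n)) Hn2[uu, ] <- lnorm(H[uu, ], lp$ln2_g, lp$ln2_b)
    }
    for (uu in seq_len(n)) {
      z <- pmax(as.vector(Hn2[uu, ] %*% lp$W1) + lp$b1, 0)
      H[uu, ] <- H[uu, ] + as.vector(z %*% lp$W2) + lp$b2
    }
    ## path encoder on this layer's output
    P <- matrix(0, p, E)
    for (m in seq_len(p)) {
      genes <- ctx$path_list$paths[[m]]
      cats <- ctx$path_list$edge_categories[[m]]
      lm <- length(genes)
      ub <- matrix(0, lm, u_w); sc <- matrix(0, lm, r)
      for (i in seq_len(lm)) {
        gi <- match(genes[i], ctx$gene_order)
        row <- as.vector(H[gi, ] %*% lp$Wu) + lp$bu + lp$pos_emb[i, ]
        if (i < lm) {
          row <- row + lp$pedge_emb[match(cats[i], EDGE_CATEGORIES), ]
        }
        ub[i, ] <- row
        sc[i, ] <- as.vector(tanh(as.vector(row %*% lp$Ws1) + lp$bs1) %*%
                               lp$Ws2) + lp$bs2
      }
      for (set in seq_len(r)) {
        w <- smax(sc[, set])
        seg <- numeric(u_w)
        for (i in seq_len(lm)) seg <- seg + w[i] * ub[i, ]
        P[m, ((set - 1L) * u_w + 1L):(set * u_w)] <- seg
      }
    }
    P_layers[[l]] <- P
  }
  I <- 1 / (1 + exp(-params$M))
  G <- rep(-Inf, E)
  for (l in seq_len(cfg$L)) {
    g <- as.vector(t(P_layers[[l]]) %*% I)
    G <- pmax(G, g)
  }
  smax(as.vector(G %*% params$Wp))
}
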