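## model: the path-centric graph transformer.
##
## Three stages: a node encoder (transformer layers over the gene graph with
## centrality, direct-edge and node-index attention encodings), a path encoder
## (per-layer path embeddings via a within-path scatter-softmax over learned
## node scores), and a graph encoder (sigmoid path-importance weighting of the
## path embeddings, layer-wise max pooling in the JumpingKnowledge style, and
## a softmax classifier).
##
## The whole network - forward and backward - is implemented directly with
## dense matrix algebra; see model_grad.R for the analytic gradients.

#' Model configuration
#'
#' @param L number of transformer layers
#' @param h_emb hidden width; must be divisible by both `h` and `r`
#' @param h number of attention heads (per-head width d_k = h_emb / h)
#' @param r number of node-score sets in the path encoder (per-set width
#'   u = h_emb / r)
#' @param dropout dropout rate applied to attention weights and FFN outputs
#' @param max_degree_bucket degree values are clipped at this bucket for the
#'   centrality encoding
#' @param node_index_mode "full" learns a dense n x n per-head attention bias;
#'   "low_rank" factors it as a b^T with rank `low_rank_dim`
#' @param low_rank_dim rank of the factored node-index encoding
#' @param layer_norm apply pre-layer normalization around both sublayers
#' @param max_path_len positional-table size for the path encoder
#' @return a `model_config` list
#' @export
model_config <- function(L = 6L, h_emb = 128L, h = 8L, r = 8L,
                         dropout = 0.1, max_degree_bucket = 64L,
                         node_index_mode = c("full", "low_rank"),
                         low_rank_dim = 8L, layer_norm = TRUE,
                         max_path_len = PATH_MAX_LEN) {
  node_index_mode <- match.arg(node_index_mode)
  stopifnot(L >= 1L, h_emb %% h == 0L, h_emb %% r == 0L,
            dropout >= 0, dropout < 1)
  structure(list(
    L = as.integer(L), h_emb = as.integer(h_emb), h = as.integer(h),
    r = as.integer(r), d_k = as.integer(h_emb %/% h),
    u = as.integer(h_emb %/% r), dropout = dropout,
    max_degree_bucket = as.integer(max_degree_bucket),
    node_index_mode = node_index_mode,
    low_rank_dim = as.integer(low_rank_dim),
    layer_norm = isTRUE(layer_norm),
    max_path_len = as.integer(max_path_len)
  ), class = "model_config")
}

N_EDGE_CAT <- 9L  # + 1 implicit "no edge" slot in the attention edge table

#' Build the shared graph context for a run
#'
#' The model's gene set is the union of path genes (not the full expression
#' matrix), which keeps the dense n x n node-index tables feasible. The
#' context is identical for every cell in a run: adjacency categories,
#' degree buckets, and the flattened path scatter index.
#'
#' @param db an `interaction_db`
#' @param path_list a `path_list`
#' @param max_degree_bucket clipping bound for the centrality encoding
#' @return a `graph_context` list
#' @export
graph_context <- function(db, path_list, max_degree_bucket = 64L) {
  stopifnot(inherits(db, "interaction_db"), inherits(path_list, "path_list"),
            path_list$p > 0L)
  gene_order <- sort(unique(path_list$flat$gene))
  stopifnot(all(gene_order %in% db$genes))
  n <- length(gene_order)
  e <- db_directed_edges(db)
  e <- e[source %in% gene_order & target %in% gene_order]
  cat_idx <- matrix(N_EDGE_CAT + 1L, n, n)  # 10 = no edge
  si <- match(e$source, gene_order); ti <- match(e$target, gene_order)
  cat_idx[cbind(si, ti)] <- match(e$category, EDGE_CATEGORIES)
  deg_out <- tabulate(si, nbins = n)
  deg_in  <- tabulate(ti, nbins = n)
  slot_gene <- match(path_list$flat$gene, gene_order)
  slot_pos  <- path_list$flat$pos
  ## category index of the edge leaving each slot (10 = last slot, no edge)
  slot_ecat <- rep(N_EDGE_CAT + 1L, path_list$k)
  at <- 0L
  for (m in seq_len(path_list$p)) {
    lm <- length(path_list$paths[[m]])
    cats <- match(path_list$edge_categories[[m]], EDGE_CATEGORIES)
    if (lm > 1L) slot_ecat[at + seq_len(lm - 1L)] <- cats
    at <- at + lm
  }
  structure(list(
    gene_order = gene_order, n = n, p = path_list$p, k = path_list$k,
    cat_idx = cat_idx, cat_vec = as.integer(cat_idx),
    deg_in_bucket  = pmin(deg_in,  max_degree_bucket) + 1L,
    deg_out_bucket = pmin(deg_out, max_degree_bucket) + 1L,
    slot_gene = as.integer(slot_gene), slot_path = path_list$flat$path_id,
    slot_pos = as.integer(slot_pos), slot_ecat = as.integer(slot_ecat),
    path_list = path_list,
    plan_env = new.env(parent = emptyenv())
  ), class = "graph_context")
}

glorot <- function(fin, fout) {
  matrix(rnorm(fin * fout, sd = sqrt(2 / (fin + fout))), fin, fout)
}

#' Initialize model parameters
#'
#' Weight matrices use Glorot-scaled normal initialization, embedding tables
#' small normals, layer-norm gains 1, biases and the node-index tables 0, and
#' the trainable path score `M` starts at 0 so every path begins with
#' importance 0.5.
#'
#' @param cfg a `model_config`
#' @param ctx a `graph_context`
#' @param seed integer RNG seed
#' @return a nested parameter list (class `pathfinder_params`)
#' @export
init_params <- function(cfg, ctx, seed = 0L) {
  set.seed(seed)
  n <- ctx$n; E <- cfg$h_emb; D <- cfg$max_degree_bucket
  layer_params <- function() {
    lp <- list(
      ln1_g = rep(1, E), ln1_b = rep(0, E),
      ln2_g = rep(1, E), ln2_b = rep(0, E),
      Wq = glorot(E, E), Wk = glorot(E, E), Wv = glorot(E, E),
      Wo = glorot(E, E),
      W1 = glorot(E, E), b1 = rep(0, E),
      W2 = glorot(E, E), b2 = rep(0, E),
      edge_emb = matrix(rnorm((N_EDGE_CAT + 1L) * cfg$d_k, sd = 0.02),
                        N_EDGE_CAT + 1L, cfg$d_k),
      w_edge = matrix(rnorm(cfg$d_k * cfg$h, sd = 0.02), cfg$d_k, cfg$h),
      Wu = glorot(E, cfg$u), bu = rep(0, cfg$u),
      pos_emb = matrix(rnorm(cfg$max_path_len * cfg$u, sd = 0.02),
                       cfg$max_path_len, cfg$u),
      pedge_emb = matrix(rnorm(N_EDGE_CAT * cfg$u, sd = 0.02),
                         N_EDGE_CAT, cfg$u),
      Ws1 = glorot(cfg$u, cfg$r), bs1 = rep(0, cfg$r),
      Ws2 = glorot(cfg$r, cfg$r), bs2 = rep(0, cfg$r)
    )
    if (cfg$node_index_mode == "full") {
      lp$nib <- array(0, dim = c(n, n, cfg$h))
    } else {
      lp$nib_a <- array(rnorm(n * cfg$low_rank_dim * cfg$h, sd = 0.02),
                        dim = c(n, cfg$low_rank_dim, cfg$h))
      lp$nib_b <- array(0, dim = c(n, cfg$low_rank_dim, cfg$h))
    }
    lp
  }
  structure(list(
    gene_emb = matrix(rnorm(n * E, sd = 0.02), n, E),
    w_expr = rnorm(E, sd = 0.02),
    z_in  = matrix(rnorm((D + 1L) * E, sd = 0.02), D + 1L, E),
    z_out = matrix(rnorm((D + 1L) * E, sd = 0.02), D + 1L, E),
    layers = lapply(seq_len(cfg$L), function(l) layer_params()),
    M = rep(0, ctx$p),
    Wp = glorot(E, 2L)
  ), class = "pathfinder_params")
}

## ---- building blocks ------------------------------------------------------

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = add_rv(xhat * rep(g, each = nrow(x)), b), xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

## per-layer, per-head attention bias shared by every cell in the batch:
## node-index encoding plus the direct-edge encoding (category embedding
## dotted with the head's edge vector; category 10 is the learned no-edge row)
attention_bias <- function(lp, cfg, ctx, head) {
  scal <- as.vector(lp$edge_emb %*% lp$w_edge[, head])
  bias <- matrix(scal[ctx$cat_vec], ctx$n, ctx$n)
  if (cfg$node_index_mode == "full") {
    bias + lp$nib[, , head]
  } else {
    bias + tcrossprod(lp$nib_a[, , head], lp$nib_b[, , head])
  }
}

dropout_mask <- function(nr, nc, rate) {
  matrix((runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

## per-batch scatter plan: flat indices replicated across the batch plus
## sparse indicator matrices for the within-path and per-node aggregations;
## depends only on (ctx, B), so it is memoized on the context
batch_plan <- function(ctx, B) {
  key <- as.character(B)
  cached <- ctx$plan_env[[key]]
  if (!is.null(cached)) return(cached)
  n <- ctx$n; k <- ctx$k; p <- ctx$p
  rows_idx <- rep((seq_len(B) - 1L) * n, each = k) + ctx$slot_gene
  group <- rep((seq_len(B) - 1L) * p, each = k) + ctx$slot_path
  plan <- list(
    rows_idx = rows_idx,
    group = group,
    pos_rep = rep(ctx$slot_pos, B),
    ecat_rep = rep(ctx$slot_ecat, B),
    slot_rep = rep(seq_len(k), B),
    cell_of_path = rep(seq_len(B), each = p),
    pathrep = rep(seq_len(p), B),
    ## path-sum operator: (B*p) x (B*k), rows sum slots within a path
    Gp = Matrix::sparseMatrix(i = group, j = seq_len(B * k), x = 1,
                              dims = c(B * p, B * k)),
    ## slot-to-node scatter-add operator: (B*n) x (B*k)
    Gh = Matrix::sparseMatrix(i = rows_idx, j = seq_len(B * k), x = 1,
                              dims = c(B * n, B * k))
  )
  ctx$plan_env[[key]] <- plan
  plan
}

#' Embed expression input
#'
#' `H^0_u = gene_emb_u + expr_u * w_expr + Z_in[bucket(in_deg)] +
#' Z_out[bucket(out_deg)]`: a gene-identity embedding shifted by the cell's
#' expression along a learned direction, plus in/out-degree centrality
#' encodings with clipped buckets.
#'
#' @param X cells x genes matrix of log-normalized expression, columns aligned
#'   to `ctx$gene_order`
#' @param ctx a `graph_context`
#' @param params model parameters
#' @return (B*n) x h_emb matrix, cell-major blocks
#' @export
embed_input <- function(X, ctx, params) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  stopifnot(ncol(X) == ctx$n)
  if (any(!is.finite(X))) {
    bad <- ctx$gene_order[unique(which(!is.finite(X), arr.ind = TRUE)[, 2L])]
    stop("non-finite expression for gene(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  B <- nrow(X)
  base <- params$gene_emb +
    params$z_in[ctx$deg_in_bucket, , drop = FALSE] +
    params$z_out[ctx$deg_out_bucket, , drop = FALSE]
  H0 <- base[rep(seq_len(ctx$n), B), , drop = FALSE]
  H0 + outer(as.vector(t(X)), params$w_expr)
}

## one transformer layer over the batch; returns new H and (optionally) the
## cache needed by the backward pass
node_encoder_layer_batch <- function(H, lp, cfg, ctx, B, biases,
                                     training = FALSE, keep = FALSE) {
  n <- ctx$n; E <- cfg$h_emb; h <- cfg$h; dk <- cfg$d_k
  cache <- list()
  if (cfg$layer_norm) {
    ln1 <- ln_forward(H, lp$ln1_g, lp$ln1_b)
    Hn <- ln1$y
    if (keep) cache$ln1 <- ln1[c("xhat", "inv")]
  } else Hn <- H
  Qa <- Hn %*% lp$Wq; Ka <- Hn %*% lp$Wk; Va <- Hn %*% lp$Wv
  O <- matrix(0, B * n, E)
  A_list <- if (keep) vector("list", B * h)
  mask_list <- if (keep && training && cfg$dropout > 0) vector("list", B * h)
  for (cc in seq_len(B)) {
    rows <- ((cc - 1L) * n + 1L):(cc * n)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dk + 1L):(i * dk)
      logits <- tcrossprod(Qa[rows, cols, drop = FALSE],
                           Ka[rows, cols, drop = FALSE]) / sqrt(dk) +
        biases[[i]]
      if (any(!is.finite(logits))) {
        stop("non-finite attention logits", call. = FALSE)
      }
      A <- softmax_rows(logits)
      Ad <- A
      if (training && cfg$dropout > 0) {
        m <- dropout_mask(n, n, cfg$dropout)
        Ad <- A * m
        if (keep) mask_list[[(cc - 1L) * h + i]] <- m
      }
      if (keep) A_list[[(cc - 1L) * h + i]] <- A
      O[rows, cols] <- Ad %*% Va[rows, cols, drop = FALSE]
    }
  }
  attn <- O %*% lp$Wo
  if (training && cfg$dropout > 0) {
    m2 <- dropout_mask(nrow(attn), E, cfg$dropout)
    attn <- attn * m2
    if (keep) cache$attn_mask <- m2
  }
  H1 <- H + attn
  if (cfg$layer_norm) {
    ln2 <- ln_forward(H1, lp$ln2_g, lp$ln2_b)
    Hn2 <- ln2$y
    if (keep) cache$ln2 <- ln2[c("xhat", "inv")]
  } else Hn2 <- H1
  Z1 <- add_rv(Hn2 %*% lp$W1, lp$b1)
  F1 <- pmax(Z1, 0)
  F2 <- add_rv(F1 %*% lp$W2, lp$b2)
  if (training && cfg$dropout > 0) {
    m3 <- dropout_mask(nrow(F2), E, cfg$dropout)
    F2 <- F2 * m3
    if (keep) cache$ffn_mask <- m3
  }
  H2 <- H1 + F2
  if (keep) {
    cache <- c(cache, list(H_in = H, Hn = Hn, Qa = Qa, Ka = Ka, Va = Va,
                           O = O, A = A_list, A_mask = mask_list,
                           H_mid = H1, Hn2 = Hn2, F1 = F1, Z1pos = Z1 > 0))
  }
  list(H = H2, cache = cache)
}

## path encoder over one layer's node embeddings for the whole batch
path_encoder_layer_batch <- function(H, lp, cfg, ctx, B, plan,
                                     keep = FALSE) {
  k <- ctx$k; u <- cfg$u; r <- cfg$r
  Hs <- H[plan$rows_idx, , drop = FALSE]
  U <- add_rv(Hs %*% lp$Wu, lp$bu)
  ## positional + edge-type encodings depend only on the slot; build once
  ## over k slots, then tile over the batch
  pedge_pad <- rbind(lp$pedge_emb, rep(0, u))  # row 10: last slot, no edge
  enc <- lp$pos_emb[ctx$slot_pos, , drop = FALSE] +
    pedge_pad[ctx$slot_ecat, , drop = FALSE]
  Ubar <- U + enc[plan$slot_rep, , drop = FALSE]
  T1 <- tanh(add_rv(Ubar %*% lp$Ws1, lp$bs1))
  S <- add_rv(T1 %*% lp$Ws2, lp$bs2)
  ## scatter softmax within each (cell, path), per score-set column
  Es <- exp(add_rv(S, -vapply(seq_len(r), function(j) max(S[, j]),
                              numeric(1L))))
  denom <- as.matrix(plan$Gp %*% Es)     # groups 1..B*p, all non-empty
  Sbar <- Es / denom[plan$group, , drop = FALSE]
  P <- matrix(0, nrow(denom), cfg$h_emb)
  for (cc in seq_len(r)) {
    P[, ((cc - 1L) * u + 1L):(cc * u)] <-
      as.matrix(plan$Gp %*% (Sbar[, cc] * Ubar))
  }
  cache <- if (keep) list(Hs = Hs, Ubar = Ubar, T1 = T1, Sbar = Sbar)
  list(P = P, cache = cache)
}

#' Run the model forward
#'
#' Embeds the batch, applies the `L` node-encoder layers, runs the path
#' encoder on every layer's output, and aggregates through the graph encoder:
#' `I = sigmoid(M)`, `g^l = I^T P^l`, elementwise max over layers, then a
#' softmax classifier.
#'
#' @param X cells x genes expression matrix aligned to `ctx$gene_order` (a
#'   single cell may be given as a vector)
#' @param ctx a `graph_context`
#' @param cfg a `model_config`
#' @param params model parameters from [init_params()]
#' @param training apply dropout (requires the RNG state; seed externally for
#'   reproducibility)
#' @param keep_cache retain intermediates for the backward pass
#' @return a `forward_trace` list: `p_hat` (B x 2 class probabilities), `I`
#'   (path importance), `G_emb`, `g_layers`, `P_layers`, and `cache` when
#'   requested
#' @export
forward <- function(X, ctx, cfg, params, training = FALSE,
                    keep_cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  B <- nrow(X)
  n <- ctx$n; p <- ctx$p
  plan <- batch_plan(ctx, B)
  H <- embed_input(X, ctx, params)
  biases_l <- lapply(params$layers, function(lp) {
    lapply(seq_len(cfg$h), function(i) attention_bias(lp, cfg, ctx, i))
  })
  P_layers <- vector("list", cfg$L)
  node_caches <- if (keep_cache) vector("list", cfg$L)
  path_caches <- if (keep_cache) vector("list", cfg$L)
  H_layers <- if (keep_cache) vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    nl <- node_encoder_layer_batch(H, params$layers[[l]], cfg, ctx, B,
                                   biases_l[[l]], training, keep_cache)
    H <- nl$H
    pe <- path_encoder_layer_batch(H, params$layers[[l]], cfg, ctx, B,
                                   plan, keep_cache)
    P_layers[[l]] <- pe$P
    if (keep_cache) {
      node_caches[[l]] <- nl$cache
      path_caches[[l]] <- pe$cache
      H_layers[[l]] <- H
    }
  }
  I <- sigmoid(params$M)
  Irep <- rep(I, B)
  g_layers <- lapply(P_layers, function(P) {
    g <- rowsum(P * Irep, plan$cell_of_path)
    rownames(g) <- NULL
    g
  })
  ## JumpingKnowledge max pooling; ties resolve to the earliest layer
  G_emb <- g_layers[[1L]]
  argmax_layer <- matrix(1L, B, cfg$h_emb)
  if (cfg$L > 1L) {
    for (l in 2L:cfg$L) {
      upd <- g_layers[[l]] > G_emb
      G_emb[upd] <- g_layers[[l]][upd]
      argmax_layer[upd] <- l
    }
  }
  logits <- G_emb %*% params$Wp
  p_hat <- softmax_rows(logits)
  stopifnot(all(is.finite(p_hat)))
  out <- list(p_hat = p_hat, I = I, G_emb = G_emb, g_layers = g_layers,
              P_layers = P_layers, argmax_layer = argmax_layer)
  if (keep_cache) {
    out$cache <- list(X = X, B = B, plan = plan, H_layers = H_layers,
                      node = node_caches, path = path_caches,
                      biases = biases_l)
  }
  class(out) <- "forward_trace"
  out
}

#' Graph encoder aggregation (exposed for inspection)
#'
#' @param P_layers list of p x h_emb path-embedding matrices (single cell)
#' @param M trainable path score vector
#' @param Wp classifier weights
#' @return list with `I`, `g_layers`, `G_emb`, `p_hat`
#' @export
graph_encoder <- function(P_layers, M, Wp) {
  I <- sigmoid(M)
  g_layers <- lapply(P_layers, function(P) as.vector(crossprod(P, I)))
  G_emb <- do.call(pmax, g_layers)
  p_hat <- softmax_rows(matrix(G_emb, nrow = 1L) %*% Wp)
  list(I = I, g_layers = g_layers, G_emb = G_emb, p_hat = as.vector(p_hat))
}
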