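## Analytic gradients for the full model. Mirrors the forward pass in
## model.R layer by layer; validated against central finite differences in
## the test suite. Gradient containers mirror the parameter list structure.

path_encoder_backward <- function(dP, cache, lp, cfg, ctx, B, plan) {
  u <- cfg$u; r <- cfg$r
  group <- plan$group
  Ubar <- cache$Ubar; Sbar <- cache$Sbar; T1 <- cache$T1
  dUbar <- matrix(0, nrow(Ubar), u)
  dS <- matrix(0, nrow(Ubar), r)
  dPrep <- dP[group, , drop = FALSE]
  for (cc in seq_len(r)) {
    cols <- ((cc - 1L) * u + 1L):(cc * u)
    dPc <- dPrep[, cols, drop = FALSE]
    dSbar_c <- rowSums(Ubar * dPc)
    dUbar <- dUbar + Sbar[, cc] * dPc
    dot <- as.vector(plan$Gp %*% (Sbar[, cc] * dSbar_c))[group]
    dS[, cc] <- Sbar[, cc] * (dSbar_c - dot)
  }
  g <- list(
    Ws2 = crossprod(T1, dS), bs2 = colSums(dS)
  )
  dT1 <- tcrossprod(dS, lp$Ws2)
  dZ <- dT1 * (1 - T1 * T1)
  g$Ws1 <- crossprod(Ubar, dZ); g$bs1 <- colSums(dZ)
  dUbar <- dUbar + tcrossprod(dZ, lp$Ws1)
  g$pos_emb <- matrix(0, cfg$max_path_len, u)
  agg <- rowsum(dUbar, plan$pos_rep)
  g$pos_emb[as.integer(rownames(agg)), ] <- agg
  g$pedge_emb <- matrix(0, N_EDGE_CAT, u)
  sel <- plan$ecat_rep <= N_EDGE_CAT
  if (any(sel)) {
    agg <- rowsum(dUbar[sel, , drop = FALSE], plan$ecat_rep[sel])
    g$pedge_emb[as.integer(rownames(agg)), ] <- agg
  }
  g$Wu <- crossprod(cache$Hs, dUbar); g$bu <- colSums(dUbar)
  dHs <- tcrossprod(dUbar, lp$Wu)
  dH_add <- as.matrix(plan$Gh %*% dHs)
  list(g = g, dH_add = dH_add)
}

node_encoder_backward <- function(dH_out, cache, lp, cfg, ctx, B) {
  n <- ctx$n; E <- cfg$h_emb; h <- cfg$h; dk <- cfg$d_k
  g <- list()
  ## feed-forward sublayer (residual: dH_out flows to both branches)
  dF2 <- if (!is.null(cache$ffn_mask)) dH_out * cache$ffn_mask else dH_out
  g$W2 <- crossprod(cache$F1, dF2); g$b2 <- colSums(dF2)
  dZ1 <- tcrossprod(dF2, lp$W2) * cache$Z1pos
  g$W1 <- crossprod(cache$Hn2, dZ1); g$b1 <- colSums(dZ1)
  dHn2 <- tcrossprod(dZ1, lp$W1)
  if (cfg$layer_norm) {
    lb <- ln_backward(dHn2, cache$ln2, lp$ln2_g)
    dH_mid <- dH_out + lb$dx
    g$ln2_g <- lb$dg; g$ln2_b <- lb$db
  } else {
    dH_mid <- dH_out + dHn2
    g$ln2_g <- rep(0, E); g$ln2_b <- rep(0, E)
  }
  ## attention sublayer
  dattn <- if (!is.null(cache$attn_mask)) dH_mid * cache$attn_mask else dH_mid
  g$Wo <- crossprod(cache$O, dattn)
  dO <- tcrossprod(dattn, lp$Wo)
  dQ <- matrix(0, B * n, E); dK <- matrix(0, B * n, E); dV <- matrix(0, B * n, E)
  dbias <- lapply(seq_len(h), function(i) matrix(0, n, n))
  for (cc in seq_len(B)) {
    rows <- ((cc - 1L) * n + 1L):(cc * n)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dk + 1L):(i * dk)
      idx <- (cc - 1L) * h + i
      A <- cache$A[[idx]]
      m <- if (!is.null(cache$A_mask)) cache$A_mask[[idx]]
      Ad <- if (!is.null(m)) A * m else A
      dOb <- dO[rows, cols, drop = FALSE]
      dAd <- tcrossprod(dOb, cache$Va[rows, cols, drop = FALSE])
      dV[rows, cols] <- crossprod(Ad, dOb)
      dA <- if (!is.null(m)) dAd * m else dAd
      dlog <- A * (dA - rowSums(A * dA))
      dQ[rows, cols] <- dlog %*% cache$Ka[rows, cols, drop = FALSE] / sqrt(dk)
      dK[rows, cols] <- crossprod(dlog, cache$Qa[rows, cols, drop = FALSE]) /
        sqrt(dk)
      dbias[[i]] <- dbias[[i]] + dlog
    }
  }
  ## shared attention-bias gradients: node-index and direct-edge encodings
  if (cfg$node_index_mode == "full") {
    g$nib <- array(0, dim = c(n, n, h))
  } else {
    g$nib_a <- array(0, dim = dim(lp$nib_a))
    g$nib_b <- array(0, dim = dim(lp$nib_b))
  }
  g$edge_emb <- matrix(0, N_EDGE_CAT + 1L, dk)
  g$w_edge <- matrix(0, dk, h)
  for (i in seq_len(h)) {
    if (cfg$node_index_mode == "full") {
      g$nib[, , i] <- dbias[[i]]
    } else {
      g$nib_a[, , i] <- dbias[[i]] %*% lp$nib_b[, , i]
      g$nib_b[, , i] <- crossprod(dbias[[i]], lp$nib_a[, , i])
    }
    catsum <- rowsum(as.vector(dbias[[i]]), ctx$cat_vec)
    full <- numeric(N_EDGE_CAT + 1L)
    full[as.integer(rownames(catsum))] <- catsum
    g$edge_emb <- g$edge_emb + outer(full, lp$w_edge[, i])
    g$w_edge[, i] <- as.vector(crossprod(lp$edge_emb, full))
  }
  dHn <- tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) + tcrossprod(dV, lp$Wv)
  g$Wq <- crossprod(cache$Hn, dQ)
  g$Wk <- crossprod(cache$Hn, dK)
  g$Wv <- crossprod(cache$Hn, dV)
  if (cfg$layer_norm) {
    lb <- ln_backward(dHn, cache$ln1, lp$ln1_g)
    dH_in <- dH_mid + lb$dx
    g$ln1_g <- lb$dg; g$ln1_b <- lb$db
  } else {
    dH_in <- dH_mid + dHn
    g$ln1_g <- rep(0, E); g$ln1_b <- rep(0, E)
  }
  list(g = g, dH_in = dH_in)
}

#' Loss and analytic gradients for one batch
#'
#' Computes the mean negative log-likelihood over the batch plus
#' `beta` times the KL path-score regularizer, and backpropagates through the
#' graph, path and node encoders down to every trainable parameter.
#'
#' @param X cells x genes expression batch aligned to `ctx$gene_order`
#' @param y integer class indices (1 = control, 2 = test)
#' @param ctx a `graph_context`
#' @param cfg a `model_config`
#' @param params model parameters
#' @param S_prior per-path prior scores (required when `beta > 0`)
#' @param beta regularization weight
#' @param training apply dropout
#' @param reg_variant KL interpretation, see [regularization_loss()]
#' @return list: `loss`, `loss_class`, `loss_reg`, `p_hat`, `grads`
#' @export
loss_and_grad <- function(X, y, ctx, cfg, params, S_prior = NULL, beta = 0,
                          training = TRUE,
                          reg_variant = c("bernoulli", "distribution")) {
  reg_variant <- match.arg(reg_variant)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  B <- nrow(X); n <- ctx$n; p <- ctx$p; E <- cfg$h_emb
  y <- as.integer(y)
  stopifnot(length(y) == B, all(y %in% c(1L, 2L)))
  fw <- forward(X, ctx, cfg, params, training = training, keep_cache = TRUE)
  p_true <- pmax(fw$p_hat[cbind(seq_len(B), y)], 1e-12)
  loss_class <- mean(-log(p_true))
  loss_reg <- 0; dI_reg <- numeric(p)
  if (beta > 0) {
    stopifnot(!is.null(S_prior), length(S_prior) == p)
    rl <- reg_loss_grad(fw$I, S_prior, reg_variant)
    loss_reg <- rl$loss
    dI_reg <- rl$dI
  }
  ## classifier
  Y <- matrix(0, B, 2L); Y[cbind(seq_len(B), y)] <- 1
  dlogits <- (fw$p_hat - Y) / B
  gWp <- crossprod(fw$G_emb, dlogits)
  dG <- tcrossprod(dlogits, params$Wp)
  I <- fw$I
  plan <- fw$cache$plan
  Irep <- rep(I, B)
  cellrep <- plan$cell_of_path
  pathrep <- plan$pathrep
  dI_class <- numeric(p)
  dH <- matrix(0, B * n, E)
  glayers <- vector("list", cfg$L)
  for (l in rev(seq_len(cfg$L))) {
    dG_l <- dG * (fw$argmax_layer == l)
    dG_l_rep <- dG_l[cellrep, , drop = FALSE]
    dP <- dG_l_rep * Irep
    dI_class <- dI_class +
      rowsum(rowSums(fw$P_layers[[l]] * dG_l_rep), pathrep)[, 1L]
    pb <- path_encoder_backward(dP, fw$cache$path[[l]], params$layers[[l]],
                                cfg, ctx, B, plan)
    nb <- node_encoder_backward(dH + pb$dH_add, fw$cache$node[[l]],
                                params$layers[[l]], cfg, ctx, B)
    glayers[[l]] <- c(nb$g, pb$g)
    dH <- nb$dH_in
  }
  ## input embedding
  g_gene_emb <- matrix(0, n, E)
  agg <- rowsum(dH, rep(seq_len(n), B))
  g_gene_emb[as.integer(rownames(agg)), ] <- agg
  xvec <- as.vector(t(X))
  g_w_expr <- colSums(dH * xvec)
  bucket_grad <- function(buckets, nrow_out) {
    out <- matrix(0, nrow_out, E)
    agg <- rowsum(dH, rep(buckets, B))
    out[as.integer(rownames(agg)), ] <- agg
    out
  }
  nb_rows <- cfg$max_degree_bucket + 1L
  gM <- (dI_class + beta * dI_reg) * I * (1 - I)
  grads <- list(
    gene_emb = g_gene_emb, w_expr = g_w_expr,
    z_in = bucket_grad(ctx$deg_in_bucket, nb_rows),
    z_out = bucket_grad(ctx$deg_out_bucket, nb_rows),
    layers = glayers, M = gM, Wp = gWp
  )
  list(loss = loss_class + beta * loss_reg, loss_class = loss_class,
       loss_reg = loss_reg, p_hat = fw$p_hat, grads = grads)
}
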