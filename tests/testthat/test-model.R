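test_that("model_config enforces divisibility and positivity", {
  expect_error(model_config(h_emb = 30L, h = 8L), "h_emb")
  expect_error(model_config(L = 0L))
  cfg <- model_config(L = 2L, h_emb = 32L, h = 4L, r = 8L)
  expect_equal(cfg$d_k, 8L)
  expect_equal(cfg$u, 4L)
})

test_that("input embedding is additive in its components", {
  s <- tiny_setup()
  n <- s$ctx$n; E <- s$cfg$h_emb
  ## zero every table except the gene embedding: H0 equals the gene embedding
  p0 <- s$params
  p0$w_expr[] <- 0; p0$z_in[] <- 0; p0$z_out[] <- 0
  H0 <- embed_input(rep(0, n), s$ctx, p0)
  expect_equal(H0, p0$gene_emb, ignore_attr = TRUE)
  ## two cells differing only in one gene's expression differ by that gene's
  ## row times the expression projection
  x1 <- rep(1, n); x2 <- x1; x2[3L] <- 2
  H1 <- embed_input(x1, s$ctx, s$params)
  H2 <- embed_input(x2, s$ctx, s$params)
  expect_equal(H2[3L, ] - H1[3L, ], s$params$w_expr, ignore_attr = TRUE)
  expect_equal(H2[-3L, ], H1[-3L, ])
  ## degree buckets clip at the configured bound
  ctx2 <- s$ctx
  expect_true(all(ctx2$deg_in_bucket <= s$cfg$max_degree_bucket + 1L))
  expect_error(embed_input(c(NA, rep(1, n - 1L)), s$ctx, s$params),
               "non-finite")
})

test_that("forward produces valid probabilities, strict path importances and is deterministic", {
  s <- tiny_setup()
  X <- matrix(rnorm(4L * s$ctx$n, 1), 4L, s$ctx$n)
  fw <- forward(X, s$ctx, s$cfg, s$params)
  expect_equal(rowSums(fw$p_hat), rep(1, 4L), tolerance = 1e-6)
  expect_true(all(fw$I > 0 & fw$I < 1))
  expect_true(all(is.finite(fw$G_emb)))
  ## M = 0 gives importance 0.5 everywhere
  expect_equal(fw$I, rep(0.5, s$ctx$p))
  ## deterministic without dropout
  fw2 <- forward(X, s$ctx, s$cfg, s$params)
  expect_identical(fw$p_hat, fw2$p_hat)
  ## a batch of identical cells yields identical rows
  Xr <- X[c(1L, 1L), ]
  fwr <- forward(Xr, s$ctx, s$cfg, s$params)
  expect_equal(fwr$p_hat[1L, ], fwr$p_hat[2L, ], tolerance = 1e-12)
})

test_that("scatter-softmax weights sum to one within each path and score set", {
  s <- tiny_setup()
  X <- matrix(rnorm(3L * s$ctx$n, 1), 3L, s$ctx$n)
  fw <- forward(X, s$ctx, s$cfg, s$params, keep_cache = TRUE)
  for (l in seq_len(s$cfg$L)) {
    Sbar <- fw$cache$path[[l]]$Sbar
    plan <- fw$cache$plan
    sums <- rowsum(Sbar, plan$group)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-6)
  }
})

test_that("the path encoder reproduces the worked scatter example", {
  ## paths [1,3,4] and [2,3,4,5]: slot 3 must carry gene 4's embedding
  genes <- sprintf("g%d", 1:5)
  tabs <- structure(list(
    lr_edges = data.table::data.table(source = c("LX", "LX"),
                                      target = c("g1", "g2")),
    signaling_edges = data.table::data.table(
      source = c("g1", "g2", "g3", "g4"),
      target = c("g3", "g3", "g4", "g5")),
    regulation_edges = data.table::data.table(source = character(),
                                              target = character()),
    tf_list = character()
  ), class = "raw_interaction_tables")
  db <- build_interaction_db(tabs)
  pl <- new_path_list(
    list(c("g1", "g3", "g4"), c("g2", "g3", "g4", "g5")),
    list(rep("signaling_signaling", 2L), rep("signaling_signaling", 3L)))
  cfg <- model_config(L = 1L, h_emb = 8L, h = 2L, r = 2L, dropout = 0,
                      max_degree_bucket = 4L)
  ctx <- graph_context(db, pl, cfg$max_degree_bucket)
  expect_equal(ctx$k, 7L)
  ## flat slot 3 indexes gene g4 at position 3 of path 1
  expect_equal(ctx$gene_order[ctx$slot_gene[3L]], "g4")
  params <- init_params(cfg, ctx, seed = 1L)
  X <- matrix(rnorm(ctx$n), 1L, ctx$n)
  fw <- forward(X, ctx, cfg, params, keep_cache = TRUE)
  H1 <- fw$cache$H_layers[[1L]]
  Hs <- fw$cache$path[[1L]]$Hs
  expect_equal(Hs[3L, ], H1[match("g4", ctx$gene_order), ])
})

test_that("graph encoder matches hand arithmetic on a 2-path toy", {
  P1 <- matrix(c(1, 2, 3, 4), 2L, 2L)  # paths x h_emb
  P2 <- matrix(c(5, -1, 0, 2), 2L, 2L)
  M <- c(0, 0)
  Wp <- diag(2L)
  ge <- graph_encoder(list(P1, P2), M, Wp)
  expect_equal(ge$I, c(0.5, 0.5))
  ## g_l = 0.5 * column sums when M = 0
  expect_equal(ge$g_layers[[1L]], 0.5 * colSums(P1))
  expect_equal(ge$G_emb, pmax(0.5 * colSums(P1), 0.5 * colSums(P2)))
  ## L = 1: max over a single layer is that layer
  ge1 <- graph_encoder(list(P1), M, Wp)
  expect_equal(ge1$G_emb, 0.5 * colSums(P1))
})

test_that("batched forward matches the straight-line single-cell oracle", {
  s <- tiny_setup(L = 2L, h_emb = 8L, h = 2L, r = 2L)
  set.seed(11)
  X <- matrix(rnorm(3L * s$ctx$n, 1, 0.5), 3L, s$ctx$n)
  fw <- forward(X, s$ctx, s$cfg, s$params)
  for (i in 1:3) {
    po <- oracle_forward(X[i, ], s$ctx, s$cfg, s$params)
    expect_lt(max(abs(fw$p_hat[i, ] - po)), 1e-5)
  }
  ## low-rank node-index mode agrees with its own oracle too
  cfg_lr <- model_config(L = 2L, h_emb = 8L, h = 2L, r = 2L, dropout = 0,
                         max_degree_bucket = 4L, node_index_mode = "low_rank",
                         low_rank_dim = 2L)
  params_lr <- init_params(cfg_lr, s$ctx, seed = 3L)
  fw_lr <- forward(X, s$ctx, cfg_lr, params_lr)
  po_lr <- oracle_forward(X[2L, ], s$ctx, cfg_lr, params_lr)
  expect_lt(max(abs(fw_lr$p_hat[2L, ] - po_lr)), 1e-5)
})

test_that("relabeling genes consistently leaves predictions unchanged", {
  s <- tiny_setup()
  set.seed(5)
  X <- matrix(rnorm(2L * s$ctx$n, 1), 2L, s$ctx$n)
  fw <- forward(X, s$ctx, s$cfg, s$params)
  ## permute the gene order together with every gene-indexed table
  perm <- sample(s$ctx$n)
  ctx2 <- s$ctx
  ctx2$gene_order <- s$ctx$gene_order[perm]
  ctx2$cat_idx <- s$ctx$cat_idx[perm, perm]
  ctx2$cat_vec <- as.integer(ctx2$cat_idx)
  ctx2$deg_in_bucket <- s$ctx$deg_in_bucket[perm]
  ctx2$deg_out_bucket <- s$ctx$deg_out_bucket[perm]
  inv <- order(perm)
  ctx2$slot_gene <- inv[s$ctx$slot_gene]
  ctx2$plan_env <- new.env(parent = emptyenv())
  params2 <- s$params
  params2$gene_emb <- s$params$gene_emb[perm, ]
  for (l in seq_along(params2$layers)) {
    params2$layers[[l]]$nib <- s$params$layers[[l]]$nib[perm, perm, ,
                                                        drop = FALSE]
  }
  fw2 <- forward(X[, perm, drop = FALSE], ctx2, s$cfg, params2)
  expect_equal(fw2$p_hat, fw$p_hat, tolerance = 1e-5)
})

test_that("analytic gradients match central finite differences", {
  s <- tiny_setup()
  set.seed(21)
  X <- matrix(rnorm(3L * s$ctx$n, 1, 0.5), 3L, s$ctx$n)
  y <- c(1L, 2L, 2L)
  Sp <- runif(s$ctx$p)
  lg <- loss_and_grad(X, y, s$ctx, s$cfg, s$params, S_prior = Sp,
                      beta = 0.5, training = FALSE)
  eps <- 1e-5
  check <- function(getset) {
    v0 <- getset$get(s$params)
    up <- loss_and_grad(X, y, s$ctx, s$cfg, getset$set(s$params, v0 + eps),
                        S_prior = Sp, beta = 0.5, training = FALSE)$loss
    dn <- loss_and_grad(X, y, s$ctx, s$cfg, getset$set(s$params, v0 - eps),
                        S_prior = Sp, beta = 0.5, training = FALSE)$loss
    num <- (up - dn) / (2 * eps)
    ana <- getset$get(lg$grads)
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
  }
  leaf <- function(nm, i) list(
    get = function(P) P[[nm]][i],
    set = function(P, v) { P[[nm]][i] <- v; P })
  layer_leaf <- function(l, nm, i) list(
    get = function(P) P$layers[[l]][[nm]][i],
    set = function(P, v) { P$layers[[l]][[nm]][i] <- v; P })
  set.seed(31)
  for (nm in c("M", "Wp", "gene_emb", "w_expr")) {
    check(leaf(nm, sample(length(s$params[[nm]]), 1L)))
  }
  for (nm in names(s$params$layers[[1L]])) {
    l <- sample(2L, 1L)
    check(layer_leaf(l, nm, sample(length(s$params$layers[[l]][[nm]]), 1L)))
  }
})

test_that("the path score vector receives nonzero gradient end-to-end", {
  s <- tiny_setup()
  set.seed(9)
  X <- matrix(rnorm(4L * s$ctx$n, 1), 4L, s$ctx$n)
  lg <- loss_and_grad(X, c(1L, 1L, 2L, 2L), s$ctx, s$cfg, s$params,
                      training = FALSE)
  expect_gt(max(abs(lg$grads$M)), 0)
  ## importance is monotone in M componentwise
  p2 <- s$params
  p2$M[1L] <- p2$M[1L] + 1
  expect_gt(forward(X, s$ctx, s$cfg, p2)$I[1L], 0.5)
})

test_that("dropout only perturbs training-mode forward passes", {
  s <- tiny_setup(dropout = 0.3)
  X <- matrix(rnorm(2L * s$ctx$n, 1), 2L, s$ctx$n)
  f1 <- forward(X, s$ctx, s$cfg, s$params)               # eval mode
  f2 <- forward(X, s$ctx, s$cfg, s$params)
  expect_identical(f1$p_hat, f2$p_hat)
  set.seed(1); t1 <- forward(X, s$ctx, s$cfg, s$params, training = TRUE)
  set.seed(1); t2 <- forward(X, s$ctx, s$cfg, s$params, training = TRUE)
  set.seed(2); t3 <- forward(X, s$ctx, s$cfg, s$params, training = TRUE)
  expect_identical(t1$p_hat, t2$p_hat)  # same RNG state, same masks
  expect_false(identical(t1$p_hat, t3$p_hat))
})
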