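test_that("log fold change is the difference of condition means and antisymmetric", {
  expr <- matrix(c(0.5, 0.5, 2.0, 2.0,
                   1.0, 1.0, 1.0, 1.0), 4L, 2L,
                 dimnames = list(NULL, c("gA", "gB")))
  labels <- c("control", "control", "test", "test")
  fc <- compute_log_fold_change(expr, labels)
  expect_equal(fc, c(gA = 1.5, gB = 0))
  ## swapping labels negates fc
  fc_sw <- compute_log_fold_change(expr, rev(labels))
  expect_equal(fc_sw, -fc)
  expect_error(compute_log_fold_change(expr, rep("test", 4L)), "conditions")
})

test_that("prior path scores min-max normalize per mode with degenerate fallback", {
  pl <- new_path_list(
    list(c("a", "b"), c("b", "c"), c("a", "c")),
    rep(list("receptor_regulation"), 3L))
  fc <- c(a = -2, b = 2, c = 0)
  ## mode up: raw means are 0, 1, -1 -> min-max 0.5, 1, 0
  expect_equal(prior_path_scores(pl, fc, "up")$S_prior, c(0.5, 1, 0))
  ## mode down negates
  expect_equal(prior_path_scores(pl, fc, "down")$S_prior, c(0.5, 0, 1))
  ## mode deg uses |fc|: raw 2, 1, 1 -> 1, 0, 0
  expect_equal(prior_path_scores(pl, fc, "deg")$S_prior, c(1, 0, 0))
  ## degenerate case: all raw equal -> all 0.5
  expect_equal(prior_path_scores(pl, c(a = 1, b = 1, c = 1), "up")$S_prior,
               rep(0.5, 3L))
  expect_error(prior_path_scores(pl, c(a = 1, b = 1), "up"), "no fold change")
})

test_that("losses match their closed forms", {
  ## p = 0.5 for one cell: loss ln 2
  expect_equal(classification_loss(matrix(c(0.5, 0.5), 1L), "test"), log(2))
  ## perfect prediction: zero loss
  expect_equal(classification_loss(matrix(c(0, 1), 1L), "test"), 0)
  ## batch of two cells at 0.9 and 0.8 on the true class
  p <- rbind(c(0.1, 0.9), c(0.2, 0.8))
  expect_equal(classification_loss(p, c("test", "test")),
               -log(0.9) - log(0.8))
  expect_equal(classification_loss(p, c("test", "test"), "mean"),
               (-log(0.9) - log(0.8)) / 2)
  ## KL closed form under the distribution reading
  expect_equal(
    regularization_loss(c(0.5, 0.5), c(0.9, 0.1), variant = "distribution"),
    0.5 * log(5 / 9) + 0.5 * log(5), tolerance = 1e-6)
  ## identical (proportional) vectors give zero
  expect_equal(
    regularization_loss(c(0.2, 0.2), c(1, 1), variant = "distribution"), 0,
    tolerance = 1e-6)
  expect_equal(regularization_loss(c(0.3, 0.7), c(0.3, 0.7),
                                   variant = "bernoulli"), 0,
               tolerance = 1e-6)
  ## nonnegativity over random pairs, both variants
  set.seed(1)
  for (i in 1:500) {
    I <- runif(5L, 0.01, 0.99); S <- runif(5L)
    expect_gte(regularization_loss(I, S, variant = "distribution"), 0)
    expect_gte(regularization_loss(I, S, variant = "bernoulli"), -1e-12)
  }
  ## total loss is the weighted sum
  expect_equal(total_loss(1, 2, 0.1), 1.2)
  expect_equal(total_loss(1, 2, 0), 1)
  expect_error(total_loss(1, 2, -1))
})

test_that("metric panel matches hand-computed confusion and rank AUC", {
  ## TP=3 FP=1 FN=1 TN=5 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1, 0.05, 0.45)
  labels <- c("test", "test", "test", "control", "test", "control",
              "control", "control", "control", "control")
  m <- compute_metrics(scores, labels)
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["recall"]], 0.75)
  expect_equal(m[["specificity"]], 5 / 6)
  expect_equal(m[["accuracy"]], 0.8)
  expect_equal(m[["F1"]], 0.75)
  ## constant scores give AUC 0.5 by midrank
  expect_equal(compute_metrics(rep(0.5, 10L), labels)[["AUC"]], 0.5)
  ## perfect separation: all ones
  m2 <- compute_metrics(c(0.9, 0.8, 0.1, 0.2), c("test", "test", "control",
                                                 "control"))
  expect_true(all(m2 == 1))
  expect_error(compute_metrics(scores, rep("test", 10L)), "single class")
})

test_that("rank AUC agrees with pROC on random score vectors", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:20) {
    n <- 30L
    labels <- sample(c("control", "test"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2L) next
    scores <- round(runif(n), 2)  # rounding forces ties
    got <- compute_metrics(scores, labels)[["AUC"]]
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(labels, scores, levels = c("control", "test"),
                          direction = "<"))))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("splits honour the ratios and keep both conditions everywhere", {
  y <- pathcomm:::normalize_labels(rep(c("control", "test"), 50L))
  parts <- pathcomm:::split_cells(y, c(0.7, 0.1, 0.2), seed = 3L)
  expect_equal(length(parts$train), 70L)
  expect_equal(length(parts$val), 10L)
  expect_equal(length(parts$test), 20L)
  expect_length(intersect(parts$train, parts$test), 0L)
  for (p in parts) expect_equal(sort(unique(y[p])), c(1L, 2L))
})

test_that("a linearly separable toy reaches test AUC 1 and training is reproducible", {
  s <- tiny_setup(dropout = 0)
  n <- s$ctx$n
  set.seed(2)
  n_cells <- 60L
  labels <- rep(c("control", "test"), each = n_cells / 2L)
  ## one gene fully separates the classes
  expr <- matrix(rnorm(n_cells * n, 1, 0.1), n_cells, n,
                 dimnames = list(NULL, s$ctx$gene_order))
  expr[labels == "test", 2L] <- expr[labels == "test", 2L] + 4
  prot <- train_protocol(repeats = 1L, epochs = 10L, batch_size = 16L,
                         lr = 0.01, mode = "deg", seed = 5L)
  res <- run_experiment(expr, labels, s$ctx, s$cfg, prot)
  expect_equal(res$metrics_mean[["AUC"]], 1.0)
  expect_length(res$repeats, 1L)
  ## training loss decreases over the first epochs
  el <- res$repeats[[1L]]$epoch_losses
  expect_lt(el[5L], el[1L])
  ## identical seeds reproduce identical metrics and scores
  res2 <- run_experiment(expr, labels, s$ctx, s$cfg, prot)
  expect_identical(res$metrics_mean, res2$metrics_mean)
  expect_identical(res$mean_I, res2$mean_I)
})
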