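## training: fold-change priors, the NLL + KL objective, Adam, the repeated
## train/validation/test protocol, and the classification metric panel.

## labels -> integer 1 (control) / 2 (test); "control"/"test" names honoured,
## otherwise the second sorted unique value is the test condition
normalize_labels <- function(labels) {
  lv <- if (is.factor(labels)) levels(droplevels(labels)) else
    sort(unique(as.character(labels)))
  if (all(lv %in% c("control", "test"))) {
    lv <- c("control", "test")  # canonical names; either may be absent
  } else if (length(lv) != 2L) {
    stop("labels must hold exactly two conditions, got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  }
  y <- match(as.character(labels), lv)
  attr(y, "levels") <- lv
  y
}

#' Per-gene log fold change between conditions
#'
#' Difference of mean log-normalized expression, test minus control. Inputs
#' are assumed already log-normalized, so this is a log fold change.
#'
#' @param expr cells x genes matrix with gene column names
#' @param labels per-cell condition labels (two conditions)
#' @return named numeric vector of per-gene fold changes
#' @export
compute_log_fold_change <- function(expr, labels) {
  y <- normalize_labels(labels)
  stopifnot(nrow(expr) == length(y))
  if (!all(c(1L, 2L) %in% y)) {
    stop("both conditions must be present to compute fold changes",
         call. = FALSE)
  }
  colMeans(expr[y == 2L, , drop = FALSE]) -
    colMeans(expr[y == 1L, , drop = FALSE])
}

#' Prior path scores from gene fold changes
#'
#' The raw score of a path is the mean over its genes of the fold change
#' (mode "up"), its negation ("down"), or its absolute value ("deg"); raw
#' scores are then min-max normalized across all paths. If every path has the
#' same raw score, all priors are set to 0.5.
#'
#' @param path_list a `path_list`
#' @param fc named per-gene log fold change (must cover every path gene)
#' @param mode one of "up", "down", "deg"
#' @return a `prior_scores` list with fields `mode`, `fc`, `S_prior`
#' @export
prior_path_scores <- function(path_list, fc, mode = c("up", "down", "deg")) {
  mode <- match.arg(mode)
  missing <- setdiff(unique(path_list$flat$gene), names(fc))
  if (length(missing) > 0L) {
    stop("no fold change for path gene(s): ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  transform <- switch(mode, up = identity, down = function(x) -x, deg = abs)
  raw <- vapply(path_list$paths,
                function(gs) mean(transform(fc[gs])), numeric(1L))
  rng <- range(raw)
  S <- if (diff(rng) == 0) rep(0.5, length(raw)) else
    (raw - rng[1L]) / diff(rng)
  structure(list(mode = mode, fc = fc, S_prior = S), class = "prior_scores")
}

#' Negative log-likelihood classification loss
#'
#' Sum (or mean) over cells of minus the log probability assigned to the true
#' condition; probabilities are clamped at 1e-12 before the log. The mean
#' variant is the per-batch objective used in optimization; sum and mean
#' differ only by the constant batch size.
#'
#' @param p_hat cells x 2 class-probability matrix (rows sum to 1)
#' @param labels per-cell condition labels
#' @param reduction "sum" or "mean"
#' @return scalar loss
#' @export
classification_loss <- function(p_hat, labels, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (is.null(dim(p_hat))) p_hat <- matrix(p_hat, nrow = 1L)
  y <- normalize_labels(labels)
  p_true <- pmax(p_hat[cbind(seq_along(y), y)], 1e-12)
  if (reduction == "sum") sum(-log(p_true)) else mean(-log(p_true))
}

## KL loss + gradient wrt I (pre-sigmoid chain handled by the caller)
reg_loss_grad <- function(I, S_prior, variant = "distribution",
                          eps = 1e-8) {
  if (variant == "distribution") {
    ## both score vectors renormalized to distributions over paths
    sI <- sum(I); In <- I / sI
    Ss <- S_prior + eps; Sn <- Ss / sum(Ss)
    lr <- log(In / Sn)
    loss <- sum(In * lr)
    dI <- (lr - loss) / sI
  } else {
    ## element-wise Bernoulli KL, each score read as an independent
    ## probability
    S <- pmin(pmax(S_prior, eps), 1 - eps)
    Ic <- pmin(pmax(I, eps), 1 - eps)
    loss <- sum(Ic * log(Ic / S) + (1 - Ic) * log((1 - Ic) / (1 - S)))
    dI <- log(Ic / S) - log((1 - Ic) / (1 - S))
  }
  list(loss = loss, dI = dI)
}

#' KL regularization between learned and prior path scores
#'
#' The stated objective is a KL divergence between two score vectors that
#' are not themselves distributions, so two readings are implemented. The
#' default, `"bernoulli"`, treats each score as an independent probability
#' and sums element-wise Bernoulli KL terms; its per-path gradient is O(1),
#' which is what lets the regularizer drive the path ranking at practical
#' path counts. `"distribution"` renormalizes both vectors to distributions
#' over paths (1e-8 smoothing on the prior) before a standard KL; its
#' gradients shrink as 1/sum(I) and with many paths the regularizer then
#' barely moves the scores.
#'
#' @param I learned path importance, in (0,1)
#' @param S_prior prior path scores from [prior_path_scores()]
#' @param variant "bernoulli" (default) or "distribution"
#' @return nonnegative scalar
#' @export
regularization_loss <- function(I, S_prior,
                                variant = c("bernoulli", "distribution")) {
  variant <- match.arg(variant)
  stopifnot(length(I) == length(S_prior))
  reg_loss_grad(I, S_prior, variant)$loss
}

#' Combined training objective
#' @param l_class classification loss
#' @param l_reg regularization loss
#' @param beta nonnegative regularization weight
#' @return `l_class + beta * l_reg`
#' @export
total_loss <- function(l_class, l_reg, beta) {
  stopifnot(beta >= 0)
  l_class + beta * l_reg
}

#' Binary classification metric panel
#'
#' Accuracy, recall (sensitivity on the test condition), precision,
#' specificity, F1 and AUC. The AUC is the rank statistic (probability a
#' random test cell outscores a random control cell) with midranks for ties.
#'
#' @param scores predicted probability of the test condition
#' @param labels per-cell condition labels (both conditions must be present)
#' @param threshold cutoff for the confusion-matrix metrics
#' @return named numeric vector
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  y <- normalize_labels(labels)
  if (!all(c(1L, 2L) %in% y)) {
    stop("AUC is undefined with a single class", call. = FALSE)
  }
  pos <- y == 2L
  n1 <- sum(pos); n0 <- sum(!pos)
  rk <- rank(scores)  # midranks
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- scores >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  c(accuracy = (tp + tn) / length(y),
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    F1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    AUC = auc)
}

#' Training protocol settings
#'
#' Defaults follow the study design: 0.7/0.1/0.2 train/validation/test split,
#' five repeats with different random splits, 30 epochs, Adam at learning
#' rate 5e-4, regularization weight 0.1, and validation AUC for model
#' selection.
#'
#' @param split train/validation/test fractions summing to 1
#' @param repeats number of repeated runs
#' @param epochs training epochs per run
#' @param lr Adam learning rate
#' @param beta regularization weight
#' @param batch_size minibatch size
#' @param mode prior mode, see [prior_path_scores()]
#' @param reg_variant KL interpretation, see [regularization_loss()]
#' @param seed base seed; repeat `i` derives its own seed from it
#' @return a `train_protocol` list
#' @export
train_protocol <- function(split = c(0.7, 0.1, 0.2), repeats = 5L,
                           epochs = 30L, lr = 5e-4, beta = 0.1,
                           batch_size = 32L, mode = "deg",
                           reg_variant = "bernoulli", seed = 0L) {
  stopifnot(abs(sum(split) - 1) < 1e-8, repeats >= 1L, epochs >= 1L)
  structure(list(split = split, repeats = as.integer(repeats),
                 epochs = as.integer(epochs), lr = lr, beta = beta,
                 batch_size = as.integer(batch_size), mode = mode,
                 reg_variant = reg_variant, seed = as.integer(seed)),
            class = "train_protocol")
}

## ---- Adam -----------------------------------------------------------------

map_params <- function(f, ...) {
  dots <- list(...)
  rec <- function(...) {
    args <- list(...)
    if (is.list(args[[1L]])) {
      keys <- names(args[[1L]]) %||% seq_along(args[[1L]])
      out <- vector("list", length(keys))
      names(out) <- names(args[[1L]])
      for (i in seq_along(keys)) {
        out[[i]] <- do.call(rec, lapply(args, `[[`, keys[[i]]))
      }
      out
    } else {
      do.call(f, args)
    }
  }
  do.call(rec, dots)
}

adam_init <- function(params) {
  zero <- function(x) x * 0
  list(m = map_params(zero, unclass(params)),
       v = map_params(zero, unclass(params)), t = 0L)
}

## Adam for the network weights; the path-score vector M takes plain
## gradient-descent steps instead. Adam's per-coordinate normalization makes
## every consistently-signed coordinate move at ~lr regardless of gradient
## magnitude, which would erase the graded signal of the score prior and
## reduce the learned ranking to a sign pattern; plain SGD keeps score
## differences proportional to accumulated gradient magnitude.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  new <- map_params(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, unclass(params), state$m, state$v)
  new$M <- params$M - lr * grads$M
  class(new) <- class(params)
  list(params = new, state = state)
}

## random split honouring the protocol fractions; both classes required in
## every part, one resplit allowed before failing
split_cells <- function(y, split, seed) {
  n <- length(y)
  attempt <- function(s) {
    set.seed(s)
    idx <- sample.int(n)
    n_tr <- floor(split[1L] * n)
    n_va <- floor(split[2L] * n)
    parts <- list(train = idx[seq_len(n_tr)],
                  val = idx[n_tr + seq_len(n_va)],
                  test = idx[(n_tr + n_va + 1L):n])
    if (all(vapply(parts, function(i) length(unique(y[i])) == 2L,
                   logical(1L)))) parts else NULL
  }
  parts <- attempt(seed) %||% attempt(derive_seed(seed, 7919L))
  if (is.null(parts)) {
    stop("could not produce a split with both conditions in every part",
         call. = FALSE)
  }
  parts
}

## one training run on fixed splits; returns best-validation-AUC state
train_single <- function(expr, y, ctx, cfg, protocol, S_prior, parts, seed) {
  set.seed(seed)
  params <- init_params(cfg, ctx, seed)
  state <- adam_init(params)
  tr <- parts$train
  best <- list(auc = -Inf, params = params)
  losses <- numeric(protocol$epochs)
  for (epoch in seq_len(protocol$epochs)) {
    ord <- sample(tr)
    batch_starts <- seq(1L, length(ord), by = protocol$batch_size)
    epoch_loss <- 0
    for (s in batch_starts) {
      b <- ord[s:min(s + protocol$batch_size - 1L, length(ord))]
      lg <- loss_and_grad(expr[b, , drop = FALSE], y[b], ctx, cfg, params,
                          S_prior = S_prior, beta = protocol$beta,
                          training = TRUE,
                          reg_variant = protocol$reg_variant)
      upd <- adam_step(params, lg$grads, state, protocol$lr)
      params <- upd$params; state <- upd$state
      epoch_loss <- epoch_loss + lg$loss * length(b)
    }
    losses[epoch] <- epoch_loss / length(ord)
    val_scores <- forward(expr[parts$val, , drop = FALSE], ctx, cfg,
                          params)$p_hat[, 2L]
    val_auc <- compute_metrics(val_scores, y[parts$val])[["AUC"]]
    ## ties keep the later (longer-trained) checkpoint
    if (val_auc >= best$auc) best <- list(auc = val_auc, params = params)
  }
  best$epoch_losses <- losses
  best
}

#' Run the repeated training protocol
#'
#' For each repeat: a fresh random train/validation/test split (derived
#' seed), prior path scores computed from the training split's fold changes,
#' fresh parameters, Adam optimization, best-validation-AUC model selection,
#' and test-set metrics. Returns per-repeat learned importance scores and
#' metrics plus their aggregate.
#'
#' @param expr cells x genes log-normalized matrix; columns must cover
#'   `ctx$gene_order`
#' @param labels per-cell condition labels
#' @param ctx a `graph_context`
#' @param cfg a `model_config`
#' @param protocol a [train_protocol()]
#' @return a `train_result` list: `repeats` (per-repeat `I`, metrics, seed,
#'   epoch losses), `metrics_mean`, `metrics_sd`, `mean_I`
#' @export
run_experiment <- function(expr, labels, ctx, cfg,
                           protocol = train_protocol()) {
  y <- normalize_labels(labels)
  stopifnot(nrow(expr) == length(y))
  if (min(table(y)) < 10L) {
    stop("need at least 10 cells per condition", call. = FALSE)
  }
  miss <- setdiff(ctx$gene_order, colnames(expr))
  if (length(miss) > 0L) {
    stop("expression matrix lacks model gene(s): ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  expr <- expr[, ctx$gene_order, drop = FALSE]
  reps <- vector("list", protocol$repeats)
  for (i in seq_len(protocol$repeats)) {
    seed_i <- derive_seed(protocol$seed, i - 1L)
    parts <- split_cells(y, protocol$split, seed_i)
    fc <- compute_log_fold_change(expr[parts$train, , drop = FALSE],
                                  structure(y[parts$train],
                                            levels = attr(y, "levels")))
    prior <- prior_path_scores(ctx$path_list, fc, protocol$mode)
    fit <- train_single(expr, y, ctx, cfg, protocol, prior$S_prior, parts,
                        seed_i)
    test_scores <- forward(expr[parts$test, , drop = FALSE], ctx, cfg,
                           fit$params)$p_hat[, 2L]
    metrics <- compute_metrics(test_scores, y[parts$test])
    reps[[i]] <- list(I = sigmoid(fit$params$M), metrics = metrics,
                      seed = seed_i, val_auc = fit$auc,
                      epoch_losses = fit$epoch_losses,
                      params = fit$params, split = parts)
    pc_log("training", sprintf("repeat %d: test AUC %.3f", i,
                               metrics[["AUC"]]))
  }
  mm <- do.call(rbind, lapply(reps, `[[`, "metrics"))
  structure(list(
    repeats = reps,
    metrics_mean = colMeans(mm),
    metrics_sd = apply(mm, 2L, sd),
    mean_I = rowMeans(do.call(cbind, lapply(reps, `[[`, "I")))
  ), class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("train_result: %d repeat(s)\n", length(x$repeats)))
  print(round(rbind(mean = x$metrics_mean, sd = x$metrics_sd), 4L))
  invisible(x)
}
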