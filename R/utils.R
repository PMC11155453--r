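## Small numerical and logging helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-wise softmax
#' @param x numeric matrix
#' @return matrix of the same shape whose rows sum to 1
#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## add a length-ncol(X) vector to every row of X without transposes
add_rv <- function(X, v) X + rep(v, each = nrow(X))

## stage-tagged logging; WARN always surfaces, INFO only when verbose option set
pc_log <- function(stage, msg, level = "INFO") {
  if (identical(level, "WARN")) {
    warning(sprintf("[%s] %s", stage, msg), call. = FALSE)
  } else if (isTRUE(getOption("pathcomm.verbose", FALSE))) {
    message(sprintf("[%s] %s %s", level, stage, msg))
  }
  invisible(NULL)
}

## Spearman rank correlation (wrapper kept for a single obvious call site)
spearman <- function(x, y) stats::cor(x, y, method = "spearman")

## deterministic seed derivation: keep derived seeds well inside 32-bit range
## (double arithmetic is exact here and avoids integer overflow)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(offset)) %% 2147483629)
}
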