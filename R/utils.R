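#' Round half away from zero
#'
#' Base `round()` rounds half to even; administrative reports round half up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# Derive a reproducible 32-bit stage seed from a global seed and stage name.
#' @keywords internal
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% .Machine$integer.max)
}

# Stratified fold assignment: within each class, cycle fold labels over a
# shuffled ordering so fold sizes differ by at most one per class.
#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
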