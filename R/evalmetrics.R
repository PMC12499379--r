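#' Pearson correlation between two maps
#'
#' Computed over unmasked, finite upper-triangle entries (diagonal
#' excluded from neither input's geometry; pairs with any `NA` dropped).
#'
#' @param a,b [log_fold_matrix()]s or [contact_matrix()]s of the same
#'   shape (or plain matrices).
#' @return Pearson r, or `NA` when either input is constant or fewer than
#'   2 pairs remain.
#' @export
pearson_map <- function(a, b) {
  va <- if (is.matrix(a)) a else a$values
  vb <- if (is.matrix(b)) b else b$values
  if (!all(dim(va) == dim(vb))) stop("maps differ in shape")
  ut <- upper.tri(va, diag = TRUE)
  x <- va[ut]; y <- vb[ut]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Distance-stratified correlation
#'
#' Pearson r between the d-th diagonals of the two maps, per separation d,
#' for evaluating long-range agreement independently of the distance
#' decay.
#'
#' @param a,b Maps as in [pearson_map()].
#' @param min_pairs Minimum complete pairs per diagonal (default 3);
#'   shorter or constant diagonals get `NA`.
#' @return `data.frame` with `separation_bins`, `distance_bp` (`NA` for
#'   plain matrices), `r`.
#' @export
distance_stratified_corr <- function(a, b, min_pairs = 3) {
  va <- if (is.matrix(a)) a else a$values
  vb <- if (is.matrix(b)) b else b$values
  if (!all(dim(va) == dim(vb))) stop("maps differ in shape")
  res <- if (is.matrix(a)) NA_real_ else a$resolution
  n <- nrow(va)
  seps <- 0:(n - 1)
  r <- vapply(seps, function(d) {
    i <- seq_len(n - d)
    x <- va[cbind(i, i + d)]; y <- vb[cbind(i, i + d)]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < min_pairs || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
  data.frame(separation_bins = seps, distance_bp = seps * res, r = r)
}

#' AUROC of a score against a truth labeling
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, ties counting one half (the Mann-Whitney U
#' convention).
#'
#' @param scores Numeric score per candidate (higher = more positive).
#' @param truth Logical truth per candidate.
#' @return AUROC in `[0, 1]`.
#' @export
recovery_auroc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
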