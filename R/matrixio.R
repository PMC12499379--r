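#' Read a contact matrix from text
#'
#' Two plain-text layouts are supported. `triplet`: upper-triangle sparse
#' records `bin1_id<TAB>bin2_id<TAB>count` with 0-based bin ids, mirrored
#' into a full symmetric matrix (absent pairs are zero); requires a bin
#' table. `dense`: whitespace-separated square matrix, which must already be
#' symmetric.
#'
#' @param path File to read.
#' @param format `"triplet"` or `"dense"`.
#' @param bins Bin table `data.frame` (`chrom start end`) or path to a
#'   3-column TSV; required for `triplet`, optional for `dense`.
#' @param resolution Bin size in bp used when `bins` is absent.
#' @param chrom Chromosome name used when `bins` is absent.
#' @return A [contact_matrix()].
#' @export
read_contacts <- function(path, format = c("triplet", "dense"), bins = NULL,
                          resolution = 1, chrom = "chrU") {
  format <- match.arg(format)
  if (is.character(bins)) bins <- read_bins(bins)
  if (format == "triplet") {
    if (is.null(bins)) stop("triplet format requires a bin table")
    n <- nrow(bins)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    v <- matrix(0, n, n)
    for (k in seq_along(lines)) {
      f <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
      rec <- suppressWarnings(as.numeric(f))
      if (length(rec) != 3 || anyNA(rec)) {
        stop(sprintf("malformed triplet record at line %d of %s", k, path))
      }
      i <- rec[1] + 1L; j <- rec[2] + 1L
      if (i < 1 || i > n || j < 1 || j > n) {
        stop(sprintf("bin index out of range at line %d of %s", k, path))
      }
      v[i, j] <- v[i, j] + rec[3]
      if (i != j) v[j, i] <- v[j, i] + rec[3]
    }
    res <- bins$end[1] - bins$start[1]
    contact_matrix(v, resolution = res, bins = bins)
  } else {
    v <- as.matrix(utils::read.table(path))
    dimnames(v) <- NULL
    if (nrow(v) != ncol(v)) stop("dense matrix file is not square")
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8))) {
      stop("dense matrix file is not symmetric")
    }
    if (is.null(bins)) bins <- bin_table(chrom, nrow(v), resolution)
    res <- bins$end[1] - bins$start[1]
    contact_matrix(v, resolution = res, bins = bins)
  }
}

#' Read a bin table (`chrom<TAB>start<TAB>end`)
#' @param path TSV file without header.
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_bins <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(b) < 3) stop("bin table needs 3 columns: chrom start end")
  names(b)[1:3] <- c("chrom", "start", "end")
  b[1:3]
}

#' Write a contact matrix as text
#'
#' @param m A [contact_matrix()].
#' @param path Output file.
#' @param format `"triplet"` (upper triangle, nonzero, 0-based ids) or
#'   `"dense"`.
#' @param bins_path Optional path for a companion bin table.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path, format = c("triplet", "dense"),
                           bins_path = NULL) {
  format <- match.arg(format)
  v <- m$values
  if (format == "triplet") {
    idx <- which(upper.tri(v, diag = TRUE) & v != 0 & !is.na(v),
                 arr.ind = TRUE)
    utils::write.table(
      data.frame(idx[, 1] - 1L, idx[, 2] - 1L, v[idx]),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(v, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(bins_path)) {
    utils::write.table(m$bins, bins_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Balance a contact matrix by iterative correction (ICE)
#'
#' Alternately rescales rows and columns of the valid submatrix until the
#' marginal sums are uniform, removing multiplicative per-bin coverage
#' biases. Convergence is declared when the coefficient of variation (CV)
#' of the valid row sums drops to `tol`.
#'
#' @param m Unbalanced [contact_matrix()].
#' @param max_iter Maximum iterations (default 200).
#' @param tol Row-sum CV tolerance (default 1e-5).
#' @return A balanced `contact_matrix` with the accumulated per-bin `bias`
#'   vector (`NA` for masked bins); `m$values == bias_i * bias_j * out`.
#' @export
ice_balance <- function(m, max_iter = 200, tol = 1e-5) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$balanced) stop("matrix is already balanced")
  valid <- m$mask
  w <- m$values[valid, valid, drop = FALSE]
  if (length(w) == 0 || sum(w, na.rm = TRUE) == 0) {
    stop("degenerate input: no contacts to balance")
  }
  # bins with an empty row cannot be balanced; mask them
  dead <- rowSums(w, na.rm = TRUE) == 0
  if (any(dead)) {
    keep <- which(valid)[!dead]
    valid <- rep(FALSE, n_bins(m)); valid[keep] <- TRUE
    w <- m$values[valid, valid, drop = FALSE]
  }
  bias <- rep(1, nrow(w))
  cv <- Inf
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)
    cv <- stats::sd(s) / mean(s)
    if (is.na(cv)) cv <- 0  # single valid bin
    if (cv <= tol) break
    sbar <- s / mean(s)
    w <- w / outer(sbar, sbar)
    bias <- bias * sbar
  }
  if (cv > tol) {
    stop(sprintf("ICE did not converge in %d iterations (row-sum CV %.3g)",
                 max_iter, cv))
  }
  out <- matrix(NA_real_, n_bins(m), n_bins(m))
  out[valid, valid] <- w
  full_bias <- rep(NA_real_, n_bins(m))
  full_bias[valid] <- bias
  contact_matrix(out, resolution = m$resolution, bins = m$bins, mask = valid,
                 balanced = TRUE, bias = full_bias)
}

#' Mask bins with sparse rows
#'
#' Bins whose row has fewer than `min_nonzero` nonzero entries are masked
#' (matrix shape unchanged); the conventional low-coverage filter applied
#' after balancing.
#'
#' @param m A [contact_matrix()].
#' @param min_nonzero Minimum nonzero entries per row (default 10).
#' @return `m` with the updated mask.
#' @export
filter_low_coverage_bins <- function(m, min_nonzero = 10) {
  stopifnot(inherits(m, "contact_matrix"))
  nz <- rowSums(m$values != 0 & !is.na(m$values))
  mask <- m$mask & (nz >= min_nonzero)
  contact_matrix(ifelse(is.na(m$values), 0, m$values),
                 resolution = m$resolution, bins = m$bins, mask = mask,
                 balanced = m$balanced, bias = m$bias)
}

#' Average-pool a matrix to coarser resolution
#'
#' 2-D average pooling over `factor` x `factor` blocks; the output
#' resolution is `factor` times coarser. A trailing partial block is
#' averaged over its actual members. Masked entries are excluded from block
#' means; a pooled bin with no valid source bin stays masked.
#'
#' @param x A [contact_matrix()] or [log_fold_matrix()].
#' @param factor Integer pooling factor, >= 2.
#' @return Object of the same class at `factor`-fold coarser resolution.
#' @export
pool <- function(x, factor) {
  if (!(is.numeric(factor) && length(factor) == 1 && factor >= 2 &&
        factor == round(factor))) {
    stop("pooling factor must be an integer >= 2")
  }
  v <- x$values
  n <- nrow(v)
  grp <- ceiling(seq_len(n) / factor)
  ng <- max(grp)
  out <- matrix(NA_real_, ng, ng)
  for (a in seq_len(ng)) {
    ia <- which(grp == a)
    for (b in a:ng) {
      blk <- v[ia, which(grp == b), drop = FALSE]
      mu <- mean(blk, na.rm = TRUE)
      out[a, b] <- out[b, a] <- if (is.nan(mu)) NA_real_ else mu
    }
  }
  mask <- vapply(seq_len(ng), function(a) any(x$mask[grp == a]), logical(1))
  res <- x$resolution * factor
  chrom <- x$bins$chrom[1]
  bins <- data.frame(chrom = chrom,
                     start = x$bins$start[match(seq_len(ng), grp)],
                     end = x$bins$end[n - match(seq_len(ng), rev(grp)) + 1L],
                     stringsAsFactors = FALSE)
  out[is.na(out) & outer(mask, mask, "&")] <- 0
  if (inherits(x, "contact_matrix")) {
    contact_matrix(out, resolution = res, bins = bins, mask = mask,
                   balanced = x$balanced)
  } else {
    expd <- x$expected
    if (!is.null(expd)) {
      g <- ceiling(seq_along(expd) / factor)
      expd <- as.numeric(tapply(expd, g, mean, na.rm = TRUE))[seq_len(ng)]
    }
    log_fold_matrix(out, resolution = res, bins = bins, mask = mask,
                    expected = expd)
  }
}

#' Mean contact intensity per genomic separation
#'
#' Entry `d + 1` is the mean of the matrix over valid bin pairs separated by
#' `d` bins (the distance-decay curve). Separations with no valid pair get
#' `NA`, never zero.
#'
#' @param m A [contact_matrix()].
#' @return Numeric vector of length `n_bins` (separations `0..n-1` in bins).
#' @export
expected_by_distance <- function(m) {
  v <- intensity_values(m)
  n <- nrow(v)
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    vals <- v[cbind(i, i + d)]
    mu <- mean(vals, na.rm = TRUE)
    if (is.nan(mu)) NA_real_ else mu
  }, numeric(1))
}

#' Log fold over distance-based expected
#'
#' `out[i, j] = log((m[i, j] + pseudocount) / (expected[|i - j|] +
#' pseudocount))` (natural log). Masked bins propagate as `NA`.
#'
#' @param m A [contact_matrix()].
#' @param expected Per-distance vector as from [expected_by_distance()];
#'   computed from `m` when `NULL`.
#' @param pseudocount Non-negative stabilizer added to numerator and
#'   denominator (default 0, appropriate for balanced intensities).
#' @return A [log_fold_matrix()].
#' @export
log_fold_oe <- function(m, expected = NULL, pseudocount = 0) {
  stopifnot(inherits(m, "contact_matrix"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (is.null(expected)) expected <- expected_by_distance(m)
  v <- m$values
  n <- nrow(v)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- matrix(expected[d + 1L], n, n)
  lf <- log(v + pseudocount) - log(e + pseudocount)
  lf[!is.finite(lf) & !is.na(v)] <- NA_real_
  log_fold_matrix(lf, resolution = m$resolution, bins = m$bins,
                  mask = m$mask, expected = expected)
}
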