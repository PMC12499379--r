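#' Build a bin table for one chromosome
#'
#' Bins tile the chromosome with 0-based half-open coordinates
#' (`[start, end)`), cooler-style. All bins have width `resolution` except
#' possibly the last, which may be truncated at `chrom_length`.
#'
#' @param chrom Chromosome name.
#' @param n_bins Number of bins.
#' @param resolution Bin width in bp.
#' @param chrom_length Optional chromosome length in bp; truncates the last
#'   bin. Defaults to `n_bins * resolution`.
#' @return A `data.frame` with columns `chrom`, `start`, `end` and implicit
#'   bin index `1..n_bins` (bin index in files is 0-based:
#'   `floor(start / resolution)`).
#' @export
bin_table <- function(chrom, n_bins, resolution, chrom_length = NULL) {
  stopifnot(n_bins >= 1, resolution >= 1)
  start <- (seq_len(n_bins) - 1) * resolution
  end <- start + resolution
  if (!is.null(chrom_length)) {
    if (chrom_length <= start[n_bins]) {
      stop("chrom_length must exceed the start of the last bin")
    }
    end[n_bins] <- min(end[n_bins], chrom_length)
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Construct a symmetric per-chromosome contact matrix
#'
#' Masked bins carry `NA` in their rows/columns (never silent zeros) and
#' `FALSE` in `mask`. Values must be symmetric and non-negative.
#'
#' @param values Symmetric numeric matrix of counts or balanced intensities.
#' @param resolution Bin size in bp.
#' @param bins Optional bin table (see [bin_table()]); built from
#'   `resolution` when absent.
#' @param chrom Chromosome name used when `bins` is absent.
#' @param mask Logical per-bin validity vector (`TRUE` = valid).
#' @param balanced Whether `values` are balanced intensities.
#' @param bias Optional per-bin bias vector from balancing.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(values, resolution, bins = NULL, chrom = "chrU",
                           mask = NULL, balanced = FALSE, bias = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("contact matrix must be square")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("contact matrix must be symmetric")
  }
  if (!balanced && any(values < 0, na.rm = TRUE)) {
    stop("unbalanced contact counts must be non-negative")
  }
  if (is.null(bins)) bins <- bin_table(chrom, n, resolution)
  if (nrow(bins) != n) stop("bin table does not match matrix size")
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  values[!mask, ] <- NA_real_
  values[, !mask] <- NA_real_
  structure(list(bins = bins, values = values, resolution = resolution,
                 mask = mask, balanced = balanced, bias = bias),
            class = "contact_matrix")
}

#' Construct a log-fold (observed over expected) matrix
#'
#' Same geometry as its source [contact_matrix()]; `expected` records the
#' per-distance background it was divided by. Usually produced by
#' [log_fold_oe()] or [surrogate_predict()].
#'
#' @param values Symmetric numeric matrix of natural-log fold changes.
#' @param resolution Bin size in bp.
#' @param bins,chrom,mask See [contact_matrix()].
#' @param expected Per-distance expected vector (index `d + 1` holds
#'   separation `d` in bins), or `NULL`.
#' @return An object of class `log_fold_matrix`.
#' @export
log_fold_matrix <- function(values, resolution, bins = NULL, chrom = "chrU",
                            mask = NULL, expected = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("log-fold matrix must be square")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    stop("log-fold matrix must be symmetric")
  }
  if (is.null(bins)) bins <- bin_table(chrom, n, resolution)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(nrow(bins) == n, length(mask) == n)
  values[!mask, ] <- NA_real_
  values[, !mask] <- NA_real_
  structure(list(bins = bins, values = values, resolution = resolution,
                 mask = mask, expected = expected),
            class = "log_fold_matrix")
}

#' Genomic signal track with uniform step
#'
#' A fixed-step signal vector (ATAC-seq -log10 p, CTCF ChIP-seq log2
#' fold-change, CpG density, ...). Value `i` covers
#' `[start + (i-1) * step, start + i * step)`, 0-based half-open.
#'
#' @param chrom Chromosome name.
#' @param start Start coordinate (bp) of the first value.
#' @param step Step width in bp.
#' @param values Numeric signal vector.
#' @return An object of class `track`.
#' @export
track <- function(chrom, start, step, values) {
  stopifnot(step >= 1, start >= 0, is.numeric(values))
  structure(list(chrom = chrom, start = start, step = step,
                 values = as.numeric(values)),
            class = "track")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %g bp (%s, %d masked)\n",
              x$bins$chrom[1], nrow(x$values), x$resolution,
              if (x$balanced) "balanced" else "raw counts",
              sum(!x$mask)))
  invisible(x)
}

#' @export
print.log_fold_matrix <- function(x, ...) {
  cat(sprintf("<log_fold_matrix> %s: %d bins @ %g bp (%d masked)\n",
              x$bins$chrom[1], nrow(x$values), x$resolution, sum(!x$mask)))
  invisible(x)
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track> %s:%g-%g @ %g bp step (%d values)\n", x$chrom,
              x$start, x$start + length(x$values) * x$step, x$step,
              length(x$values)))
  invisible(x)
}

#' @method as.matrix contact_matrix
#' @export
as.matrix.contact_matrix <- function(x, ...) x$values

#' @method as.matrix log_fold_matrix
#' @export
as.matrix.log_fold_matrix <- function(x, ...) x$values

n_bins <- function(m) nrow(m$values)

# matrix values of either container, optionally exponentiated to fold space
intensity_values <- function(x, fold = FALSE) {
  if (inherits(x, "contact_matrix")) {
    x$values
  } else if (inherits(x, "log_fold_matrix")) {
    if (fold) exp(x$values) else x$values
  } else {
    stop("expected a contact_matrix or log_fold_matrix")
  }
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
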