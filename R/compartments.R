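#' Call A/B compartments by spectral clustering with an LDA score
#'
#' The contact map is treated as the adjacency matrix of a weighted graph
#' over bins. The symmetric normalized Laplacian is eigendecomposed; the
#' two-group partition comes from k-means on the Fiedler vector (the
#' standard spectral 2-cut), and a linear discriminant axis fit on the
#' `n_eig` smallest-eigenvalue eigenvectors with those cluster labels
#' yields the signed per-bin score. Positive score = compartment A,
#' negative = B. The sign is oriented so that A has the higher mean of a
#' reference track (accessibility or CpG density); without a reference the
#' orientation is arbitrary and flagged.
#'
#' @param m A [contact_matrix()] (or [log_fold_matrix()], exponentiated to
#'   fold space) for one chromosome.
#' @param n_eig Number of eigenvectors in the LDA embedding (default 50;
#'   clipped to half the valid bin count).
#' @param reference Optional per-bin numeric vector (same length as bins)
#'   used to orient the sign.
#' @param seed Seed for the k-means step (default 1).
#' @return A `compartment_assignment`: list with `bins`, `score` (signed,
#'   `NA` on masked bins), `label` (`"A"`, `"B"`, `"masked"`), and
#'   `orientation` (`"reference"` or `"arbitrary"`).
#' @export
compartment_labels <- function(m, n_eig = 50, reference = NULL, seed = 1L) {
  v <- intensity_values(m, fold = TRUE)
  n <- nrow(v)
  valid <- m$mask & rowSums(!is.na(v)) > 0
  w <- v[valid, valid, drop = FALSE]
  w[is.na(w)] <- 0
  w[w < 0] <- 0
  nv <- nrow(w)
  if (nv < 4) stop("too few valid bins for compartment calling")
  if (stats::sd(w) == 0) {
    stop("degenerate clustering: contact map is constant")
  }
  deg <- rowSums(w)
  if (any(deg == 0)) {
    keep <- which(valid)[deg > 0]
    valid <- rep(FALSE, n); valid[keep] <- TRUE
    w <- v[valid, valid, drop = FALSE]; w[is.na(w)] <- 0; w[w < 0] <- 0
    deg <- rowSums(w)
    nv <- nrow(w)
  }
  dhalf <- 1 / sqrt(deg)
  lsym <- diag(nv) - (dhalf * w) %*% diag(dhalf)
  lsym <- (lsym + t(lsym)) / 2
  eig <- eigen(lsym, symmetric = TRUE)
  k <- max(2L, min(as.integer(n_eig), floor(nv / 2)))
  emb <- eig$vectors[, nv:(nv - k + 1), drop = FALSE]  # smallest first
  fiedler <- emb[, 2]
  cl <- with_seed(seed, stats::kmeans(fiedler, centers = 2, nstart = 10))
  grp <- factor(cl$cluster)
  score <- tryCatch({
    keep_col <- apply(emb, 2, function(col) stats::sd(col) > 1e-10)
    keep_col[1] <- FALSE  # trivial near-constant eigenvector
    ld <- MASS::lda(emb[, keep_col, drop = FALSE], grouping = grp)
    sc <- stats::predict(ld, emb[, keep_col, drop = FALSE])$x[, 1]
    mid <- mean(tapply(sc, grp, mean))
    sc - mid
  }, error = function(e) {
    # a perfectly separating eigenvector is constant within groups, which
    # the discriminant fit rejects; the Fiedler axis centered between the
    # two cluster means is then already the exact discriminant
    fiedler - mean(tapply(fiedler, grp, mean))
  })
  orientation <- "arbitrary"
  if (!is.null(reference)) {
    stopifnot(length(reference) == n)
    ref <- reference[valid]
    a <- score > 0
    if (any(a) && any(!a) &&
        mean(ref[a], na.rm = TRUE) < mean(ref[!a], na.rm = TRUE)) {
      score <- -score
    }
    orientation <- "reference"
  }
  full <- rep(NA_real_, n)
  full[valid] <- score
  label <- ifelse(is.na(full), "masked", ifelse(full > 0, "A", "B"))
  structure(list(bins = m$bins, score = full, label = label,
                 orientation = orientation),
            class = "compartment_assignment")
}

#' Compartmentalization order parameter
#'
#' Quadrant contact means over off-diagonal unmasked pairs: `AA` (both bins
#' labeled A), `BB`, `AB`/`BA` (cross). `COMP = (AA + BB) / (AB + BA)`,
#' rescaled to `(COMP - 1) / (COMP + 1)` in `[-1, 1]`: +1 means contacts
#' only within compartments, -1 only across. Log-fold input is
#' exponentiated to fold space before averaging, so COMP compares mean
#' fold enrichment per label-pair class.
#'
#' @param x A [log_fold_matrix()] (conventional: the 32-Mb-scale map in log
#'   fold over background) or a [contact_matrix()] whose values are used
#'   directly as intensities.
#' @param labels A `compartment_assignment` (or character vector of
#'   `"A"`/`"B"`/`"masked"` per bin).
#' @return A `comp_score`: list with `aa`, `ab`, `ba`, `bb`, `comp`,
#'   `comp_rescaled`.
#' @export
comp_score <- function(x, labels) {
  v <- intensity_values(x, fold = TRUE)
  lab <- if (inherits(labels, "compartment_assignment")) labels$label
         else as.character(labels)
  if (length(lab) != nrow(v)) stop("labels do not cover the matrix bins")
  ok <- lab %in% c("A", "B") & x$mask
  ia <- which(ok & lab == "A")
  ib <- which(ok & lab == "B")
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both compartments must be present with at least 2 bins")
  }
  offdiag_mean <- function(rows, cols) {
    sub <- v[rows, cols, drop = FALSE]
    same <- identical(rows, cols)
    if (same) diag(sub) <- NA_real_
    mean(sub, na.rm = TRUE)
  }
  aa <- offdiag_mean(ia, ia)
  bb <- offdiag_mean(ib, ib)
  ab <- offdiag_mean(ia, ib)
  ba <- offdiag_mean(ib, ia)
  intra <- aa + bb
  inter <- ab + ba
  if (is.nan(intra) || is.nan(inter)) {
    stop("quadrant means undefined (all entries masked)")
  }
  if (inter == 0) {
    if (intra == 0) stop("degenerate map: no contacts in any quadrant")
    comp <- Inf
    rescaled <- 1
  } else {
    comp <- intra / inter
    rescaled <- (comp - 1) / (comp + 1)
  }
  structure(list(aa = aa, ab = ab, ba = ba, bb = bb, comp = comp,
                 comp_rescaled = rescaled),
            class = "comp_score")
}

#' @export
print.comp_score <- function(x, ...) {
  cat(sprintf(
    "<comp_score> AA=%.4g AB=%.4g BA=%.4g BB=%.4g COMP=%.4g rescaled=%.4g\n",
    x$aa, x$ab, x$ba, x$bb, x$comp, x$comp_rescaled))
  invisible(x)
}

#' @export
print.compartment_assignment <- function(x, ...) {
  cat(sprintf("<compartment_assignment> %d bins: %d A, %d B, %d masked (%s sign)\n",
              length(x$label), sum(x$label == "A"), sum(x$label == "B"),
              sum(x$label == "masked"), x$orientation))
  invisible(x)
}
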