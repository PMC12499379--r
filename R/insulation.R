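#' Insulation ratio profile
#'
#' For each bin `i` with a full `window_bins` window on both sides, the
#' score is `INSUL = (L + R + Const) / (M + Const)` where `L` and `R` are
#' the mean intensities of the upstream and downstream `w x w` intra-side
#' squares, `M` is the mean of the `w x w` cross block spanning the bin,
#' and `Const` is the average intensity of the map at this resolution
#' (the mean over unmasked nonzero entries; in a sparse map, zeros encode
#' unobserved pairs rather than intensity, so they are left out of the
#' map-wide average). High values mean strong insulation: a boundary-like
#' bin with depleted cross contacts. On a uniform map INSUL = 1.5
#' everywhere; at a perfect two-block boundary it is 3.
#'
#' @param x A [contact_matrix()] or [log_fold_matrix()]; balanced counts
#'   are the conventional input.
#' @param window_bins Window half-extent in bins (default 50).
#' @return An `insulation_profile`: list with `bins`, `insul` (per-bin,
#'   `NA` where a full window does not fit), `window_bins`, `const`,
#'   `resolution`.
#' @export
insulation_profile <- function(x, window_bins = 50) {
  v <- intensity_values(x)
  n <- nrow(v)
  w <- as.integer(window_bins)
  if (n <= 2 * w) stop("matrix smaller than twice the insulation window")
  nz <- v[!is.na(v) & v != 0]
  if (length(nz) == 0) {
    stop("degenerate input: map has no nonzero intensity")
  }
  const <- mean(nz)
  insul <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    li <- (i - w):(i - 1)
    ri <- (i + 1):(i + w)
    L <- mean(v[li, li], na.rm = TRUE)
    R <- mean(v[ri, ri], na.rm = TRUE)
    M <- mean(v[li, ri], na.rm = TRUE)
    insul[i] <- (L + R + const) / (M + const)
  }
  structure(list(bins = x$bins, insul = insul, window_bins = w,
                 const = const, resolution = x$resolution),
            class = "insulation_profile")
}

#' Sliding-diamond insulation track
#'
#' The classic boundary-calling score: for each bin the mean intensity of
#' the `w x w` diamond crossing it, log2-normalized to the track mean.
#' Minima mark insulating boundaries. Kept separate from
#' [insulation_profile()], which measures boundary strength as a ratio.
#'
#' @param x A [contact_matrix()] or [log_fold_matrix()] (exponentiated to
#'   fold space).
#' @param window_bins Diamond half-extent in bins.
#' @return List with `score` (per-bin log2 relative diamond mean, `NA` at
#'   edges), `raw` (diamond means), `window_bins`.
#' @export
diamond_insulation <- function(x, window_bins = 10) {
  v <- intensity_values(x, fold = TRUE)
  n <- nrow(v)
  w <- as.integer(window_bins)
  if (w < 1) stop("window must span at least one bin")
  if (n <= 2 * w) stop("matrix smaller than twice the diamond window")
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    raw[i] <- mean(v[(i - w):(i - 1), (i + 1):(i + w)], na.rm = TRUE)
  }
  mu <- mean(raw, na.rm = TRUE)
  score <- ifelse(raw > 0 & mu > 0, log2(raw / mu), NA_real_)
  list(score = score, raw = raw, window_bins = w)
}

#' Call TAD boundaries from diamond-insulation minima
#'
#' Computes the sliding-diamond insulation track at the matrix resolution
#' (`window` bp wide), its delta vector from `delta_bins` bins up- and
#' downstream, and calls boundaries where the delta crosses zero downward
#' at a local insulation minimum whose strength — the range of the delta
#' vector across the minimum (max before minus min after, within
#' `delta_bins`) — exceeds `min_strength` (log2 units).
#'
#' @param m A [contact_matrix()] (pool first if the map is not at the
#'   target resolution; the convention is 25-kb maps with a 1-Mb window).
#' @param window Diamond window in bp (default 1e6).
#' @param delta_bins Bins on each side entering the delta vector
#'   (default 3).
#' @param min_strength Minimum boundary depth in log2 units (default 0.1).
#' @return A `boundary_set`: list with `positions` (bin indices, sorted),
#'   `scores` (boundary strength), plus the insulation `score` track used.
#' @export
tad_boundaries <- function(m, window = 1e6, delta_bins = 3,
                           min_strength = 0.1) {
  w <- max(2L, as.integer(round(window / m$resolution)))
  if (round(window / m$resolution) < 2) {
    stop("window must span at least 2 bins at this resolution")
  }
  di <- diamond_insulation(m, w)
  ins <- di$score
  n <- length(ins)
  d <- as.integer(delta_bins)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    up <- (i - d):(i - 1); dn <- (i + 1):(i + d)
    if (i - d < 1 || i + d > n) next
    if (anyNA(ins[up]) || anyNA(ins[dn])) next
    delta[i] <- mean(ins[up]) - mean(ins[dn])
  }
  pos <- integer(0); sco <- numeric(0)
  for (i in seq_len(n - 1)) {
    if (is.na(delta[i]) || is.na(delta[i + 1])) next
    if (delta[i] > 0 && delta[i + 1] <= 0) {
      j <- if (!is.na(ins[i + 1]) && ins[i + 1] < ins[i]) i + 1L else i
      lo <- max(1, j - d); hi <- min(n, j + d)
      strength <- suppressWarnings(
        max(delta[lo:j], na.rm = TRUE) - min(delta[j:hi], na.rm = TRUE))
      if (is.finite(strength) && strength >= min_strength) {
        pos <- c(pos, j); sco <- c(sco, strength)
      }
    }
  }
  keep <- !duplicated(pos)
  structure(list(positions = pos[keep], scores = sco[keep],
                 score_track = ins, window_bins = w,
                 resolution = m$resolution),
            class = "boundary_set")
}

#' Insulation ratio at boundary positions
#'
#' Evaluates [insulation_profile()] at each boundary; boundaries without a
#' full window are skipped with a warning.
#'
#' @param m Matrix as for [insulation_profile()].
#' @param boundaries A `boundary_set` or integer vector of bin positions.
#' @param window_bins Window half-extent in bins.
#' @return Named numeric vector of INSUL values (names = bin positions).
#' @export
boundary_insul <- function(m, boundaries, window_bins = 50) {
  pos <- if (inherits(boundaries, "boundary_set")) boundaries$positions
         else as.integer(boundaries)
  if (length(pos) == 0) return(stats::setNames(numeric(0), character(0)))
  prof <- insulation_profile(m, window_bins)
  vals <- prof$insul[pos]
  if (anyNA(vals)) {
    warning(sprintf("%d boundaries lack a full window and were skipped",
                    sum(is.na(vals))))
  }
  stats::setNames(vals[!is.na(vals)], pos[!is.na(vals)])
}

#' Differential insulation around a perturbed locus
#'
#' `delta = perturbed - original` insulation; the peak is the extremum of
#' `|delta|` inside the analysis window, and the impact width counts the
#' contiguous bins around the peak sharing the peak's sign (peak
#' inclusive, both arms summed). Identical profiles yield a null-peak
#' record (`peak_value` 0, undefined sign, width 0), not an error.
#'
#' @param orig,pert `insulation_profile`s on the same bins (or plain
#'   numeric vectors).
#' @param center Optional bin index at the perturbed locus; peak search is
#'   restricted to `center +/- window_bins` and ties go to the bin nearest
#'   `center`.
#' @param window_bins Analysis half-window in bins (default: whole
#'   profile).
#' @return A `differential_insulation`: list with `delta`, `peak_position`,
#'   `peak_value`, `peak_sign` (+1/-1/`NA`), `impact_width`, `arm_up`,
#'   `arm_down`.
#' @export
differential_insulation <- function(orig, pert, center = NULL,
                                    window_bins = NULL) {
  o <- if (inherits(orig, "insulation_profile")) orig$insul else orig
  p <- if (inherits(pert, "insulation_profile")) pert$insul else pert
  if (length(o) != length(p)) stop("profiles do not share bins")
  delta <- p - o
  idx <- which(!is.na(delta))
  if (!is.null(center) && !is.null(window_bins)) {
    idx <- idx[abs(idx - center) <= window_bins]
  }
  if (length(idx) == 0 || all(delta[idx] == 0)) {
    return(structure(list(delta = delta, peak_position = NA_integer_,
                          peak_value = 0, peak_sign = NA_integer_,
                          impact_width = 0L, arm_up = 0L, arm_down = 0L),
                     class = "differential_insulation"))
  }
  amax <- max(abs(delta[idx]))
  cand <- idx[abs(delta[idx]) == amax]
  peak <- if (!is.null(center)) cand[which.min(abs(cand - center))]
          else cand[1]
  sgn <- sign(delta[peak])
  same <- !is.na(delta) & sign(delta) == sgn
  up <- 0L
  i <- peak - 1L
  while (i >= 1 && same[i]) { up <- up + 1L; i <- i - 1L }
  dn <- 0L
  i <- peak + 1L
  while (i <= length(delta) && same[i]) { dn <- dn + 1L; i <- i + 1L }
  structure(list(delta = delta, peak_position = peak,
                 peak_value = delta[peak], peak_sign = as.integer(sgn),
                 impact_width = up + dn + 1L, arm_up = up, arm_down = dn),
            class = "differential_insulation")
}
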