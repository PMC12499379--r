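# ---- track coordinate helpers -------------------------------------------

# indices of track steps overlapping [from, to) (bp, 0-based half-open)
track_idx <- function(tr, from, to) {
  n <- length(tr$values)
  lo <- floor((from - tr$start) / tr$step) + 1
  hi <- ceiling((to - tr$start) / tr$step)
  if (hi < 1 || lo > n) return(integer(0))
  seq(max(1, lo), min(n, hi))
}

# aggregate track values into bins of `resolution` bp over [from, to)
bin_track <- function(tr, from, to, resolution, fun = mean) {
  n_out <- (to - from) / resolution
  vapply(seq_len(n_out), function(b) {
    idx <- track_idx(tr, from + (b - 1) * resolution, from + b * resolution)
    if (length(idx) == 0) return(0)
    fun(tr$values[idx])
  }, numeric(1))
}

# ---- perturbation operators ---------------------------------------------

#' Silence a track region
#'
#' Sets the signal to zero on every step overlapping `[from, to)`;
#' elsewhere unchanged. The elementary deactivation used in the screen.
#'
#' @param tr A [track()].
#' @param from,to Region in bp (0-based half-open).
#' @return The modified track.
#' @export
silence_region <- function(tr, from, to) {
  tr$values[track_idx(tr, from, to)] <- 0
  tr
}

#' Activate enhancer regions on a track
#'
#' `replace_if_greater`: on each region the output is the pointwise max of
#' the track and a donor track (an original peak is replaced only when the
#' replacement is greater). `fold`: the track is multiplied by `fold` on
#' each region (e.g. the 1.1-fold global enhancer activation).
#'
#' @param tr A [track()].
#' @param regions `data.frame` with `start`, `end` in bp (or `from`/`to`).
#' @param mode `"replace_if_greater"` or `"fold"`.
#' @param donor Donor [track()] on the same coordinates (replace mode).
#' @param fold Positive fold-change factor (fold mode, default 1.1).
#' @return The modified track.
#' @export
activate_enhancers <- function(tr, regions,
                               mode = c("replace_if_greater", "fold"),
                               donor = NULL, fold = 1.1) {
  mode <- match.arg(mode)
  from <- if ("start" %in% names(regions)) regions$start else regions$from
  to <- if ("end" %in% names(regions)) regions$end else regions$to
  if (mode == "replace_if_greater") {
    stopifnot(!is.null(donor), donor$step == tr$step,
              donor$start == tr$start,
              length(donor$values) == length(tr$values))
    for (k in seq_along(from)) {
      i <- track_idx(tr, from[k], to[k])
      tr$values[i] <- pmax(tr$values[i], donor$values[i])
    }
  } else {
    if (fold <= 0) stop("fold must be positive")
    for (k in seq_along(from)) {
      i <- track_idx(tr, from[k], to[k])
      tr$values[i] <- tr$values[i] * fold
    }
  }
  tr
}

#' Add a Gaussian CTCF peak at a motif
#'
#' Inserts a Gaussian profile centered at the motif midpoint with maximum
#' `peak_value` and support equal to the motif extended by `extension` bp
#' on both sides, combined with the original signal by pointwise max (the
#' original is replaced only where the enhanced value is greater).
#'
#' @param tr A [track()] (CTCF ChIP-seq log2 fold-change, typically at
#'   1-bp step).
#' @param motif_start,motif_end Motif interval in bp (0-based half-open).
#' @param peak_value Peak apex (default 1000).
#' @param extension Support extension on each side in bp (default 30).
#' @return The modified track.
#' @export
add_ctcf_peak <- function(tr, motif_start, motif_end, peak_value = 1000,
                          extension = 30) {
  from <- motif_start - extension
  to <- motif_end + extension
  mid <- (motif_start + motif_end) / 2
  width <- to - from
  sigma <- width / 6  # support covers +/- 3 sigma
  idx <- track_idx(tr, from, to)
  if (length(idx) == 0) return(tr)
  x <- tr$start + (idx - 0.5) * tr$step  # step midpoints
  g <- peak_value * exp(-(x - mid)^2 / (2 * sigma^2))
  tr$values[idx] <- pmax(tr$values[idx], g)
  tr
}

#' Permute a sequence region in fixed-size segments
#'
#' The region is split into consecutive `segment`-bp pieces whose order is
#' shuffled with the given seed (a trailing remainder shorter than
#' `segment` stays in place); the rest of the sequence is untouched.
#' Length and base composition are preserved.
#'
#' @param seq Nucleotide string.
#' @param from,to Region in bp (0-based half-open).
#' @param segment Segment size in bp (default 16).
#' @param seed Integer seed; the same seed reproduces the permutation.
#' @return The permuted sequence string.
#' @export
permute_sequence <- function(seq, from, to, segment = 16, seed = 1L) {
  stopifnot(from >= 0, to <= nchar(seq), to - from >= 2 * segment)
  region <- substr(seq, from + 1, to)
  len <- nchar(region)
  nseg <- len %/% segment
  starts <- (seq_len(nseg) - 1) * segment + 1
  segs <- substring(region, starts, starts + segment - 1)
  tail_part <- if (len %% segment > 0) {
    substr(region, nseg * segment + 1, len)
  } else ""
  ord <- with_seed(seed, sample.int(nseg))
  shuffled <- paste0(paste(segs[ord], collapse = ""), tail_part)
  paste0(substr(seq, 1, from), shuffled,
         substr(seq, to + 1, nchar(seq)))
}

#' Scale a whole track by a fold-change factor
#'
#' @param tr A [track()].
#' @param fold Positive factor.
#' @return The scaled track.
#' @export
global_scale <- function(tr, fold) {
  if (fold <= 0) stop("fold must be positive")
  tr$values <- tr$values * fold
  tr
}

# ---- surrogate predictor -------------------------------------------------

#' Parameters of the mechanistic surrogate predictor
#'
#' Defaults are chosen so that maps rendered from realistic tracks show
#' visible loops, TADs and a compartment checkerboard at the analyzed
#' scales.
#'
#' @param kappa_comp Compartment-field coupling (default 0.4).
#' @param kappa_loop Loop bump amplitude in log-fold units (default 1.5).
#' @param kappa_ins Insulation penalty per crossed boundary weight unit
#'   (default 0.3).
#' @param sigma_loop Loop bump width in bins (default 2).
#' @param theta_c CTCF peak threshold for boundaries/anchors (default 2).
#' @param theta_a ATAC peak threshold gating loop anchors (default 4).
#' @param d_max Maximum anchor-pair span in bp (default 1e6).
#' @param min_sep_bins Minimum anchor-pair separation in bins (default
#'   12); closer pairs sit inside the diagonal / bump blur (several
#'   `sigma_loop`) and are not resolvable loops.
#' @param cap Saturation of the crossed-boundary weight sum (default 3).
#' @param w_cap Per-peak boundary weight cap, in units of `theta_c`
#'   (default 3).
#' @param block_w Boundary weight that blocks loop extrusion: no loop
#'   forms across a peak of weight `>= block_w` (default 1).
#' @param d_ins Distance scale of the insulation penalty in bp (default
#'   2e6); boundary effects decay as `exp(-distance / d_ins)`, leaving
#'   long-range structure to the compartment field.
#' @param smooth_halfwidth Running-mean half-width for the compartment
#'   field in bp (default 1e5).
#' @param z_max Bound on the compartment-field z-score (default 1.2),
#'   keeping the compartment term subordinate to loop bumps at anchor
#'   pixels.
#' @return Named list of parameters.
#' @export
surrogate_params <- function(kappa_comp = 0.4, kappa_loop = 1.5,
                             kappa_ins = 0.3, sigma_loop = 2,
                             theta_c = 2, theta_a = 4, d_max = 1e6,
                             min_sep_bins = 12, cap = 3, w_cap = 3,
                             block_w = 1, d_ins = 2e6,
                             smooth_halfwidth = 1e5, z_max = 1.2) {
  list(kappa_comp = kappa_comp, kappa_loop = kappa_loop,
       kappa_ins = kappa_ins, sigma_loop = sigma_loop, theta_c = theta_c,
       theta_a = theta_a, d_max = d_max, min_sep_bins = min_sep_bins,
       cap = cap, w_cap = w_cap, block_w = block_w, d_ins = d_ins,
       smooth_halfwidth = smooth_halfwidth, z_max = z_max)
}

# symmetric running mean with half-width hw bins (truncated at edges)
running_mean <- function(x, hw) {
  if (hw < 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - hw, 1)
  hi <- pmin(seq_len(n) + hw, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Deterministic surrogate contact-map predictor
#'
#' A mechanistic stand-in honoring the predictor contract: a pure function
#' of the input tracks within the requested window that composes the three
#' canonical determinants of the log-fold map. (1) Compartment field:
#' `kappa_comp * s_i * s_j`, `s` the bounded z-score of the smoothed
#' binned ATAC signal. (2) Loops: Gaussian bumps of width `sigma_loop` at
#' each pair of anchor bins separated by at least `min_sep_bins` bins and
#' at most `d_max` bp, with no strong boundary (weight `>= block_w`) in
#' between — extrusion does not cross strong CTCF boundaries. An anchor is a CTCF peak above `theta_c` that
#' also carries an ATAC peak (`>= theta_a` at bin maximum), and the bump
#' amplitude is gated by `min(atac/theta_a, 1)` at each anchor, so
#' silencing an anchor's accessibility removes its loops. (3) Insulation:
#' `-kappa_ins * min(sum of crossed boundary weights, cap) *
#' exp(-distance/d_ins)`; each CTCF peak contributes its strength above
#' threshold, `min(ctcf/theta_c, w_cap) - 1`, and the distance decay
#' confines boundary effects to extrusion scales so that long-range
#' structure stays compartmental. Identical inputs give bit-identical
#' outputs, and signal outside the window never enters.
#'
#' @param tracks List with `atac` and `ctcf` [track()]s covering the
#'   window.
#' @param window `c(from, to)` in bp; `to - from` must be a multiple of
#'   `resolution`.
#' @param resolution Output bin size in bp.
#' @param params [surrogate_params()].
#' @return A [log_fold_matrix()] over the window.
#' @export
surrogate_predict <- function(tracks, window, resolution,
                              params = surrogate_params()) {
  from <- window[1]; to <- window[2]
  n <- (to - from) / resolution
  if (n != round(n) || n < 2) {
    stop("window must be a multiple of the resolution with >= 2 bins")
  }
  n <- as.integer(n)
  p <- params
  a_mean <- bin_track(tracks$atac, from, to, resolution, mean)
  a_max <- bin_track(tracks$atac, from, to, resolution, max)
  c_max <- bin_track(tracks$ctcf, from, to, resolution, max)
  # compartment field
  hw <- round(p$smooth_halfwidth / resolution)
  sm <- running_mean(a_mean, hw)
  sdv <- stats::sd(sm)
  s <- if (is.na(sdv) || sdv == 0) rep(0, n) else (sm - mean(sm)) / sdv
  s <- pmin(pmax(s, -p$z_max), p$z_max)
  m <- p$kappa_comp * outer(s, s)
  # CTCF peaks (strict local maxima above theta_c)
  left <- c(-Inf, c_max[-n]); right <- c(c_max[-1], -Inf)
  peaks <- which(c_max > p$theta_c & c_max >= left & c_max > right)
  if (length(peaks) > 0) {
    wvec <- rep(0, n)
    wvec[peaks] <- pmax(pmin(c_max[peaks] / p$theta_c, p$w_cap) - 1, 0)
    cb <- cumsum(wvec)
    idx <- seq_len(n)
    # boundary weight summed strictly between i and j
    crossed <- outer(idx, idx, function(i, j) {
      pmax(cb[pmax(pmax(i, j) - 1, 1)] - cb[pmin(i, j)], 0)
    })
    dist_bp <- abs(outer(idx, idx, "-")) * resolution
    m <- m - p$kappa_ins * pmin(crossed, p$cap) * exp(-dist_bp / p$d_ins)
    # loop anchors: CTCF peaks with an ATAC peak above theta_a
    strong <- which(wvec >= p$block_w)
    has_atac <- a_max[peaks] >= p$theta_a
    anchors <- peaks[has_atac]
    gate <- pmin(a_max[anchors] / p$theta_a, 1)
    if (length(anchors) >= 2) {
      grid <- seq_len(n)
      for (ai in seq_along(anchors)) {
        for (bi in seq_along(anchors)) {
          if (bi <= ai) next
          pa <- anchors[ai]; pb <- anchors[bi]
          if ((pb - pa) * resolution > p$d_max ||
              pb - pa < p$min_sep_bins) next
          if (any(strong > pa & strong < pb)) next  # extrusion blocked
          amp <- p$kappa_loop * gate[ai] * gate[bi]
          ga <- exp(-(grid - pa)^2 / (2 * p$sigma_loop^2))
          gb <- exp(-(grid - pb)^2 / (2 * p$sigma_loop^2))
          m <- m + amp * (outer(ga, gb) + outer(gb, ga))
        }
      }
    }
  }
  m <- (m + t(m)) / 2
  bins <- data.frame(chrom = tracks$atac$chrom,
                     start = from + (seq_len(n) - 1) * resolution,
                     end = from + seq_len(n) * resolution,
                     stringsAsFactors = FALSE)
  log_fold_matrix(m, resolution = resolution, bins = bins)
}

# ---- impact scoring and screening ---------------------------------------

#' Mean absolute difference between two predicted maps
#'
#' @param orig,pert [log_fold_matrix()]s of identical shape.
#' @param window_bins Optional `c(lo, hi)` bin-index range restricting the
#'   comparison (default: whole matrix).
#' @return Non-negative scalar; 0 for identical maps.
#' @export
impact_score <- function(orig, pert, window_bins = NULL) {
  a <- orig$values; b <- pert$values
  if (!all(dim(a) == dim(b))) stop("matrices differ in shape")
  if (!is.null(window_bins)) {
    i <- window_bins[1]:window_bins[2]
    a <- a[i, i, drop = FALSE]; b <- b[i, i, drop = FALSE]
  }
  d <- abs(b - a)
  mean(d, na.rm = TRUE)
}

#' Screen 1-kb fragments for impact on genome organization
#'
#' Tiles the span into fragments; for every fragment and scale, predicts
#' the map on the scale-sized window centered on the fragment (clipped at
#' the span ends), silences the fragment's ATAC signal, re-predicts, and
#' records the mean absolute difference as the impact score. Per scale,
#' the HIS-subset is the top 10% of fragments by impact (ties broken by
#' impact then coordinate, so membership is deterministic).
#'
#' @param tracks List with `atac` and `ctcf` [track()]s.
#' @param span `c(from, to)` bp covered by the tracks.
#' @param scales Window sizes in bp, sorted ascending (e.g. 256 kb ...
#'   32 Mb).
#' @param resolutions Bin size per scale (same length as `scales`;
#'   default `scales / 64`).
#' @param fragment_size Fragment length in bp (default 1000).
#' @param params [surrogate_params()] passed to the predictor.
#' @param predictor Prediction function with the [surrogate_predict()]
#'   signature; swap in an adapter to use externally computed maps.
#' @param annotations Optional list with `genes` and `enhancers` passed to
#'   [categorize_fragments()] to attach regulatory classes.
#' @return A `screen_result`: list with `fragments` (data.frame `chrom
#'   start end category`), `impact` (fragments x scales matrix),
#'   `his` (logical matrix, same shape), `scales`.
#' @export
screen_fragments <- function(tracks, span, scales,
                             resolutions = pmax(fragment_size,
                                                round(scales / 64)),
                             fragment_size = 1000,
                             params = surrogate_params(),
                             predictor = surrogate_predict,
                             annotations = NULL) {
  from <- span[1]; to <- span[2]
  stopifnot(length(scales) == length(resolutions))
  starts <- seq(from, to - 1, by = fragment_size)
  ends <- pmin(starts + fragment_size, to)
  nf <- length(starts)
  ns <- length(scales)
  impact <- matrix(0, nf, ns,
                   dimnames = list(NULL, paste0("scale_", scales)))
  for (si in seq_len(ns)) {
    sc <- scales[si]; r <- resolutions[si]
    for (fi in seq_len(nf)) {
      midp <- (starts[fi] + ends[fi]) / 2
      w_from <- round((midp - sc / 2) / r) * r
      w_from <- max(from, min(w_from, to - sc))
      w_to <- min(to, w_from + sc)
      w_from <- w_to - floor((w_to - w_from) / r) * r
      base <- predictor(tracks, c(w_from, w_to), r, params)
      ptracks <- tracks
      ptracks$atac <- silence_region(ptracks$atac, starts[fi], ends[fi])
      pert <- predictor(ptracks, c(w_from, w_to), r, params)
      impact[fi, si] <- impact_score(base, pert)
    }
  }
  n_his <- floor(nf / 10)
  his <- matrix(FALSE, nf, ns, dimnames = dimnames(impact))
  for (si in seq_len(ns)) {
    ord <- order(-impact[, si], starts)
    his[ord[seq_len(n_his)], si] <- TRUE
  }
  frag <- data.frame(chrom = tracks$atac$chrom, start = starts, end = ends,
                     category = factor("other",
                                       levels = c("promoter", "enhancer",
                                                  "gene_body", "other")),
                     stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    cats <- categorize_fragments(annotations$genes, annotations$enhancers,
                                 tracks$atac$chrom, from, to, fragment_size)
    frag$category <- cats$category
  }
  structure(list(fragments = frag, impact = impact, his = his,
                 scales = scales),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d fragments x %d scales (%s); %d HIS per scale\n",
              nrow(x$fragments), length(x$scales),
              paste(x$scales, collapse = ", "), sum(x$his[, 1])))
  invisible(x)
}

#' Write a screen result as TSV
#'
#' Columns: `chrom start end category impact@<scale>... his@<scale>...`.
#'
#' @param x A `screen_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_screen <- function(x, path) {
  imp <- x$impact
  colnames(imp) <- paste0("impact@", x$scales)
  hs <- x$his
  colnames(hs) <- paste0("his@", x$scales)
  utils::write.table(cbind(x$fragments, imp, hs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
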