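#' Configuration for the synthetic map generator
#'
#' Describes a planted hierarchical structure: an A/B checkerboard over
#' compartment blocks, TAD blocks delimited by insulating boundaries, and
#' nested loop bumps. Contrasts are in natural-log fold units on the
#' log-fold layer; the distance decay lives in the expected vector of the
#' count sampler, not here.
#'
#' @param n_bins Number of bins (default 200).
#' @param resolution Bin size in bp (default 25000).
#' @param chrom Chromosome name (default "chrS").
#' @param n_compartment_blocks Number of alternating A/B blocks
#'   (default 6).
#' @param n_tads Number of TADs (default 4; `n_tads - 1` interior
#'   boundaries).
#' @param n_main_loops Number of planted main-loops (default 3).
#' @param valency Sub-loops nested per main-loop; scalar or vector of
#'   length `n_main_loops` (default 2).
#' @param contrasts List with `checkerboard`, `tad`, `loop` amplitudes
#'   (defaults 0.4, 0.3, 1.5).
#' @param decay_exponent Power-law exponent of the count-level distance
#'   decay (default 1).
#' @param min_anchor_gap Minimum bin gap between nested anchors
#'   (default 5).
#' @param max_loop_span Largest planted main-loop span in bp (default
#'   9e5, within the reach of extrusion-scale loop formation).
#' @return Named list (class `sim_config`).
#' @export
sim_config <- function(n_bins = 200, resolution = 25000, chrom = "chrS",
                       n_compartment_blocks = 6, n_tads = 4,
                       n_main_loops = 3, valency = 2,
                       contrasts = list(checkerboard = 0.4, tad = 0.3,
                                        loop = 1.5),
                       decay_exponent = 1, min_anchor_gap = 5,
                       max_loop_span = 9e5) {
  structure(list(n_bins = n_bins, resolution = resolution, chrom = chrom,
                 n_compartment_blocks = n_compartment_blocks,
                 n_tads = n_tads, n_main_loops = n_main_loops,
                 valency = valency, contrasts = contrasts,
                 decay_exponent = decay_exponent,
                 min_anchor_gap = min_anchor_gap,
                 max_loop_span = max_loop_span),
            class = "sim_config")
}

#' Draw a reproducible planted ground truth
#'
#' Block edges and anchor positions are jittered under the seed; the same
#' `(config, seed)` pair always returns the identical truth. Planted
#' sub-loops respect the nesting rule by construction (each sub-loop chain
#' shrinks both anchors inward by at least `min_anchor_gap` bins).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `ground_truth`: list with `labels` (per-bin `"A"`/`"B"`),
#'   `boundaries` (interior TAD boundary bin indices), `loops`
#'   (data.frame with `bin_lower`, `bin_upper`, `lower`, `upper`,
#'   `is_main_planted`), `config`, `seed`.
#' @export
make_truth <- function(config, seed) {
  cf <- config
  n <- cf$n_bins
  if (cf$n_tads < 1 || cf$n_tads * 8 > n) {
    stop("infeasible config: too many TADs for the bin count")
  }
  if (cf$n_compartment_blocks < 2 || cf$n_compartment_blocks * 4 > n) {
    stop("infeasible config: too many compartment blocks")
  }
  val <- rep_len(cf$valency, max(cf$n_main_loops, 1))
  with_seed(seed, {
    # alternating compartment blocks with jittered edges
    nb <- cf$n_compartment_blocks
    base <- round(n / nb * seq_len(nb - 1))
    jit <- sample(-floor(n / nb / 5):floor(n / nb / 5), nb - 1,
                  replace = TRUE)
    edges <- sort(pmin(pmax(base + jit, 2), n - 1))
    edges <- edges[!duplicated(edges)]
    block <- findInterval(seq_len(n) - 1, edges) + 1
    labels <- ifelse(block %% 2 == 1, "A", "B")
    # TAD boundaries
    boundaries <- integer(0)
    if (cf$n_tads > 1) {
      base_b <- round(n / cf$n_tads * seq_len(cf$n_tads - 1))
      boundaries <- sort(base_b + sample(-2:2, cf$n_tads - 1,
                                         replace = TRUE))
      boundaries <- pmin(pmax(boundaries, 4), n - 3)
      if (any(diff(boundaries) < 8)) {
        stop("infeasible config: TAD boundaries collide")
      }
    }
    # nested loops planted inside TADs, cycled over segments
    seg_start <- c(1, boundaries + 1)
    seg_end <- c(boundaries, n)
    loops <- NULL
    if (cf$n_main_loops > 0) {
      g <- cf$min_anchor_gap
      tad_of <- rep_len(seq_along(seg_start), cf$n_main_loops)
      rows <- list()
      for (k in seq_len(cf$n_main_loops)) {
        a <- seg_start[tad_of[k]]; b <- seg_end[tad_of[k]]
        # nested chain shares the lower anchor; uppers step inward, so the
        # planted loops are exactly the admissible anchor pairings
        l0 <- a + 2
        u0 <- min(b - 2, l0 + round(cf$max_loop_span / cf$resolution))
        need <- g * val[k] + g + 2
        if (u0 - l0 < need) {
          stop("infeasible config: TAD too small for requested valency")
        }
        for (d in 0:val[k]) {
          rows[[length(rows) + 1]] <- c(l0, u0 - d * g)
        }
      }
      loops <- do.call(rbind, rows)
      loops <- data.frame(bin_lower = loops[, 1], bin_upper = loops[, 2])
      loops$lower <- (loops$bin_lower - 1) * cf$resolution +
        cf$resolution / 2
      loops$upper <- (loops$bin_upper - 1) * cf$resolution +
        cf$resolution / 2
      # first loop of each chain is the main
      loops$is_main_planted <- unlist(lapply(val, function(v) {
        c(TRUE, rep(FALSE, v))
      }))
    } else {
      loops <- data.frame(bin_lower = integer(0), bin_upper = integer(0),
                          lower = numeric(0), upper = numeric(0),
                          is_main_planted = logical(0))
    }
    structure(list(labels = labels, boundaries = boundaries, loops = loops,
                   config = cf, seed = seed),
              class = "ground_truth")
  })
}

#' Render the noiseless log-fold map of a ground truth
#'
#' Deterministic composition on a zero baseline: checkerboard
#' `k_cb * s_i * s_j` (`s = +/-1` from the planted labels), a same-TAD
#' block elevation, and Gaussian bumps (width 1.5 bins) at the planted
#' anchor pairs. With all contrasts zero the map is identically zero.
#'
#' @param truth A `ground_truth` from [make_truth()].
#' @return A [log_fold_matrix()].
#' @export
render_logfold <- function(truth) {
  cf <- truth$config
  n <- cf$n_bins
  s <- ifelse(truth$labels == "A", 1, -1)
  m <- cf$contrasts$checkerboard * outer(s, s)
  tad_id <- findInterval(seq_len(n), truth$boundaries + 0.5) + 1
  m <- m + cf$contrasts$tad * outer(tad_id, tad_id, "==")
  if (nrow(truth$loops) > 0 && cf$contrasts$loop != 0) {
    grid <- seq_len(n)
    sigma <- 1.5
    for (k in seq_len(nrow(truth$loops))) {
      ga <- exp(-(grid - truth$loops$bin_lower[k])^2 / (2 * sigma^2))
      gb <- exp(-(grid - truth$loops$bin_upper[k])^2 / (2 * sigma^2))
      m <- m + cf$contrasts$loop * (outer(ga, gb) + outer(gb, ga))
    }
  }
  m <- (m + t(m)) / 2
  log_fold_matrix(m, resolution = cf$resolution,
                  bins = bin_table(cf$chrom, n, cf$resolution))
}

#' Sample Poisson counts around a log-fold map
#'
#' Counts are drawn independently per pair from
#' `Poisson(depth * d^(-decay_exponent) * exp(lf))` with `d` the
#' separation in bins (`d = 0` treated as `d = 1`), then symmetrized.
#' With `noise = FALSE` the Poisson means themselves are returned — the
#' noiseless count-scale map, the natural input for distance-weighted
#' analyses such as TAD boundary calling.
#'
#' @param lf A [log_fold_matrix()].
#' @param decay_exponent Power-law decay exponent (default 1).
#' @param depth Expected count at separation 1 and fold 1 (default 100).
#' @param seed Integer seed; same seed, same counts.
#' @param noise Draw Poisson counts (default `TRUE`) or return the exact
#'   means.
#' @return An unbalanced [contact_matrix()] of counts.
#' @export
sample_counts <- function(lf, decay_exponent = 1, depth = 100, seed = 1L,
                          noise = TRUE) {
  stopifnot(depth > 0)
  v <- lf$values
  n <- nrow(v)
  d <- pmax(abs(outer(seq_len(n), seq_len(n), "-")), 1)
  mu <- depth * d^(-decay_exponent) * exp(v)
  if (!noise) {
    mu[is.na(v)] <- NA_real_
    return(contact_matrix(mu, resolution = lf$resolution, bins = lf$bins,
                          mask = lf$mask, balanced = FALSE))
  }
  counts <- matrix(0, n, n)
  ut <- which(upper.tri(mu, diag = TRUE) & !is.na(mu))
  counts[ut] <- with_seed(seed, stats::rpois(length(ut), mu[ut]))
  counts <- counts + t(counts) - diag(diag(counts))
  counts[is.na(mu)] <- NA_real_
  contact_matrix(counts, resolution = lf$resolution, bins = lf$bins,
                 mask = lf$mask, balanced = FALSE)
}

#' Build ATAC and CTCF tracks consistent with a planted truth
#'
#' ATAC (-log10 p): an elevated plateau over A-label bins plus a tall
#' single-step peak at the center of every loop-anchor bin. CTCF (log2
#' fold-change): a strong single-step peak at every TAD boundary bin and a
#' weaker one at every anchor bin. Peak steps are single `step`-bp
#' intervals, so a 1-kb silencing removes a whole anchor peak while
#' leaving the bin-mean plateau (the compartment signal) nearly unchanged.
#' Deterministic in the truth.
#'
#' @param truth A `ground_truth`.
#' @param step Track step in bp (default 1000).
#' @param levels Named list of signal levels: `atac_base` (0.5),
#'   `atac_open` (2.5), `atac_peak` (6), `ctcf_boundary` (6),
#'   `ctcf_anchor` (2.5).
#' @return List with `atac` and `ctcf` [track()]s covering the map span.
#' @export
make_tracks <- function(truth, step = 1000,
                        levels = list(atac_base = 0.5, atac_open = 2.5,
                                      atac_peak = 6, ctcf_boundary = 6,
                                      ctcf_anchor = 2.5)) {
  cf <- truth$config
  n_steps <- cf$n_bins * cf$resolution / step
  if (n_steps != round(n_steps)) {
    stop("step must divide the map resolution")
  }
  per_bin <- cf$resolution / step
  atac <- rep(ifelse(truth$labels == "A", levels$atac_open,
                     levels$atac_base), each = per_bin)
  ctcf <- rep(0, n_steps)
  center_step <- function(bin) round((bin - 0.5) * per_bin)
  anchors <- unique(c(truth$loops$bin_lower, truth$loops$bin_upper))
  for (b in anchors) {
    i <- center_step(b)
    atac[i] <- max(atac[i], levels$atac_peak)
    ctcf[i] <- max(ctcf[i], levels$ctcf_anchor)
  }
  for (b in truth$boundaries) {
    i <- center_step(b)
    ctcf[i] <- max(ctcf[i], levels$ctcf_boundary)
  }
  list(atac = track(cf$chrom, 0, step, atac),
       ctcf = track(cf$chrom, 0, step, ctcf))
}

#' Write a synthetic dataset to a directory
#'
#' Renders a truth, samples counts, and writes: triplet matrix + bin
#' table, bedGraph tracks, BEDPE truth loops, BED truth boundaries, and a
#' two-column per-bin label table.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param depth Sequencing depth for [sample_counts()] (default 100).
#' @return The `ground_truth`, invisibly.
#' @export
simulate_dataset <- function(config, seed, dir, depth = 100) {
  truth <- make_truth(config, seed)
  lf <- render_logfold(truth)
  counts <- sample_counts(lf, config$decay_exponent, depth, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contacts(counts, file.path(dir, "contacts.triplet.tsv"),
                 format = "triplet",
                 bins_path = file.path(dir, "bins.tsv"))
  tracks <- make_tracks(truth)
  write_track(tracks$atac, file.path(dir, "atac.bedGraph"))
  write_track(tracks$ctcf, file.path(dir, "ctcf.bedGraph"))
  write_bedpe(loop_table(config$chrom, truth$loops$lower,
                         truth$loops$upper),
              file.path(dir, "loops.bedpe"))
  if (length(truth$boundaries) > 0) {
    write_bed(data.frame(chrom = config$chrom,
                         start = (truth$boundaries - 1) * config$resolution,
                         end = truth$boundaries * config$resolution),
              file.path(dir, "boundaries.bed"))
  }
  utils::write.table(
    data.frame(bin = seq_len(config$n_bins) - 1, label = truth$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(truth)
}
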