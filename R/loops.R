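#' Create a loop table
#'
#' Loops are point-to-point contact enrichments stored as a `data.frame`
#' with anchor coordinates `lower < upper` (bp, 0-based), a caller score
#' (p-value or confidence) and a regulatory category.
#'
#' @param chrom Chromosome name(s).
#' @param lower,upper Lower/upper anchor coordinates in bp.
#' @param score Caller score (default `NA`).
#' @param category One of `"PP"`, `"EP"`, `"EE"`, `"other"`, `"unset"`.
#' @return `data.frame` with columns `chrom`, `lower`, `upper`, `score`,
#'   `category`.
#' @export
loop_table <- function(chrom, lower, upper, score = NA_real_,
                       category = "unset") {
  if (any(lower >= upper)) stop("each loop needs lower < upper")
  data.frame(chrom = chrom, lower = lower, upper = upper,
             score = rep_len(score, length(lower)),
             category = rep_len(category, length(lower)),
             stringsAsFactors = FALSE)
}

#' Is loop `a` a sub-loop of loop `b`?
#'
#' True iff `b$lower <= a$lower < a$upper <= b$upper` with `a != b`
#' (identical coordinates are not nested in each other) and both loops on
#' the same chromosome.
#'
#' @param a,b Single loops: one-row data.frames or lists with `chrom`,
#'   `lower`, `upper`.
#' @return Logical scalar.
#' @export
is_subloop <- function(a, b) {
  if (!identical(as.character(a$chrom)[1], as.character(b$chrom)[1])) {
    return(FALSE)
  }
  al <- a$lower[1]; au <- a$upper[1]; bl <- b$lower[1]; bu <- b$upper[1]
  (bl <= al) && (au <= bu) && !(al == bl && au == bu)
}

#' Build the main-loop / sub-loop hierarchy
#'
#' Main-loops are loops not nested inside any other loop; every other
#' loop's parent is its smallest enclosing loop. The valency of a
#' main-loop counts all loops nested within it at any depth. Duplicate
#' coordinates (which would nest in each other) are deduplicated with a
#' warning.
#'
#' @param loops Loop table (single chromosome) as from [loop_table()].
#' @return A `loop_hierarchy`: list with `loops` (deduplicated table),
#'   `parent` (index of smallest enclosing loop, `NA` for main-loops),
#'   `is_main` (logical), `valency` (integer, `NA` for non-main loops).
#' @export
loop_hierarchy <- function(loops) {
  if (length(unique(loops$chrom)) > 1) {
    stop("loop hierarchy is built per chromosome")
  }
  key <- paste(loops$chrom, loops$lower, loops$upper)
  if (anyDuplicated(key)) {
    warning("duplicate loop coordinates removed before hierarchy construction")
    loops <- loops[!duplicated(key), , drop = FALSE]
    rownames(loops) <- NULL
  }
  n <- nrow(loops)
  if (n == 0) {
    return(structure(list(loops = loops, parent = integer(0),
                          is_main = logical(0), valency = integer(0)),
                     class = "loop_hierarchy"))
  }
  l <- loops$lower; u <- loops$upper
  # nested[a, b]: a is a sub-loop of b
  nested <- outer(l, l, ">=") & outer(u, u, "<=")
  diag(nested) <- FALSE
  is_main <- !apply(nested, 1, any)
  size <- u - l
  parent <- rep(NA_integer_, n)
  for (a in which(!is_main)) {
    enc <- which(nested[a, ])
    parent[a] <- enc[which.min(size[enc])]
  }
  valency <- rep(NA_integer_, n)
  valency[is_main] <- colSums(nested)[is_main]
  structure(list(loops = loops, parent = parent, is_main = is_main,
                 valency = valency),
            class = "loop_hierarchy")
}

#' @export
print.loop_hierarchy <- function(x, ...) {
  cat(sprintf("<loop_hierarchy> %d loops, %d main-loops, valencies: %s\n",
              nrow(x$loops), sum(x$is_main),
              paste(x$valency[x$is_main], collapse = ",")))
  invisible(x)
}

#' Categorize loops by the regulatory elements at their anchors
#'
#' Each anchor (a `+/- anchor_pad` window around `lower` and `upper`) is
#' labeled `promoter` if it overlaps any promoter interval, else
#' `enhancer` if it overlaps any enhancer, else `other` (promoter wins
#' when both overlap). The loop category follows from the anchor pair:
#' `PP`, `EP`, `EE`, or `other`.
#'
#' @param loops Loop table.
#' @param promoters,enhancers `GRanges` or `data.frame` (`chrom start
#'   end`) annotation intervals.
#' @param anchor_pad Half-width of the anchor window in bp (default 10 kb,
#'   matching 10-kb-resolution loop calls).
#' @return The loop table with `category` filled in.
#' @export
classify_loops <- function(loops, promoters, enhancers, anchor_pad = 10000) {
  pr <- as_granges(promoters)
  en <- as_granges(enhancers)
  anchor_label <- function(pos) {
    gr <- GenomicRanges::GRanges(
      loops$chrom,
      IRanges::IRanges(start = pmax(pos - anchor_pad, 0) + 1,
                       end = pos + anchor_pad))
    hit_p <- GenomicRanges::countOverlaps(gr, pr) > 0
    hit_e <- GenomicRanges::countOverlaps(gr, en) > 0
    ifelse(hit_p, "P", ifelse(hit_e, "E", "O"))
  }
  a1 <- anchor_label(loops$lower)
  a2 <- anchor_label(loops$upper)
  pair <- paste0(pmin(a1, a2), pmax(a1, a2))
  loops$category <- c(PP = "PP", EP = "EP", EE = "EE")[pair]
  loops$category[is.na(loops$category)] <- "other"
  loops
}

#' Summary statistics of a loop hierarchy
#'
#' @param h A [loop_hierarchy()].
#' @param region_length Length of the analyzed region in bp.
#' @return List with `count_per_mb` (all loops per Mb), `n_main`,
#'   `mean_main_size` (bp), `mean_valency` (over main-loops, zeros
#'   included), and `mean_size_per_valency` (ratio of means;
#'   `NA` when no main-loops or mean valency is zero).
#' @export
loop_stats <- function(h, region_length) {
  stopifnot(region_length > 0)
  n_loops <- nrow(h$loops)
  count_per_mb <- n_loops / (region_length / 1e6)
  mains <- which(h$is_main)
  if (length(mains) == 0) {
    return(list(count_per_mb = count_per_mb, n_main = 0L,
                mean_main_size = NA_real_, mean_valency = NA_real_,
                mean_size_per_valency = NA_real_))
  }
  sizes <- h$loops$upper[mains] - h$loops$lower[mains]
  mean_size <- mean(sizes)
  mean_val <- mean(h$valency[mains])
  list(count_per_mb = count_per_mb, n_main = length(mains),
       mean_main_size = mean_size, mean_valency = mean_val,
       mean_size_per_valency = if (mean_val > 0) mean_size / mean_val
                               else NA_real_)
}

#' Naive enrichment loop caller
#'
#' A deliberately simple caller for synthetic and surrogate maps: strict
#' local maxima of the log-fold map are scored against a surrounding ring
#' background with a one-sided Poisson-tail test at a nominal sequencing
#' depth, and calls with `p <= p_threshold` are returned. It stands in for
#' the heavyweight learned callers used on experimental data.
#'
#' @param lf A [log_fold_matrix()].
#' @param p_threshold Maximum p-value for a call (default 0.01).
#' @param min_separation Minimum anchor separation in bins (default 2).
#' @param neighborhood Half-width of the local-maximum square in bins
#'   (default 2).
#' @param ring_width Width of the background ring beyond the neighborhood
#'   in bins (default 2).
#' @param depth Nominal counts at background fold 1 for the Poisson test
#'   (default 100).
#' @param min_lf Minimum log-fold enrichment over the distance background
#'   at a candidate pixel (default 0.5); rejects pixels that look locally
#'   enriched only because their ring straddles a depleted boundary.
#' @param cluster_anchors Collapse called anchor coordinates differing by
#'   at most one bin onto the coordinate of the best-scoring call using
#'   them (default `TRUE`); apexes of bumps sharing an anchor can shift
#'   by a pixel on a sloped background, and collapsing restores the
#'   shared anchor.
#' @return Loop table (anchors at bin midpoints, `score` = p-value),
#'   sorted by score.
#' @export
naive_loop_caller <- function(lf, p_threshold = 0.01, min_separation = 2,
                              neighborhood = 2, ring_width = 2,
                              depth = 100, min_lf = 0.5,
                              cluster_anchors = TRUE) {
  stopifnot(inherits(lf, "log_fold_matrix"))
  v <- lf$values
  n <- nrow(v)
  nb <- as.integer(neighborhood)
  rw <- as.integer(ring_width)
  chrom <- lf$bins$chrom[1]
  res <- lf$resolution
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < min_separation) next
      x0 <- v[i, j]
      if (is.na(x0) || x0 < min_lf) next
      ri <- max(1, i - nb - rw):min(n, i + nb + rw)
      rj <- max(1, j - nb - rw):min(n, j + nb + rw)
      local <- v[ri, rj, drop = FALSE]
      cheb <- outer(abs(ri - i), abs(rj - j), pmax)
      nbr <- local[cheb <= nb & cheb > 0]
      if (any(nbr >= x0, na.rm = TRUE)) next  # not a strict local max
      ring <- local[cheb > nb]
      bg <- mean(exp(ring), na.rm = TRUE)
      if (is.nan(bg)) next
      lambda <- depth * bg
      x <- depth * exp(x0)
      if (x <= lambda) next
      p <- stats::pgamma(lambda, shape = x)  # P(Pois(lambda) >= x)
      if (p <= p_threshold) {
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom,
          lower = lf$bins$start[i] + res / 2,
          upper = lf$bins$start[j] + res / 2,
          score = p, category = "unset",
          bin_lower = i, bin_upper = j,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(cbind(loop_table(character(0), numeric(0), numeric(0)),
                 bin_lower = integer(0), bin_upper = integer(0)))
  }
  res_df <- do.call(rbind, out)
  res_df <- res_df[order(res_df$score), , drop = FALSE]
  rownames(res_df) <- NULL
  if (cluster_anchors && nrow(res_df) > 1) {
    bins2bp <- function(b) lf$bins$start[b] + res / 2
    for (col in c("bin_lower", "bin_upper")) {
      coords <- sort(unique(c(res_df$bin_lower, res_df$bin_upper)))
      grpid <- cumsum(c(1, diff(coords) > 1))
      for (g in unique(grpid)) {
        members <- coords[grpid == g]
        if (length(members) < 2) next
        use <- res_df[[col]] %in% members
        if (!any(use)) next
        rep_bin <- res_df[[col]][use][1]  # rows sorted by score
        res_df[[col]][use] <- rep_bin
      }
    }
    res_df$lower <- bins2bp(res_df$bin_lower)
    res_df$upper <- bins2bp(res_df$bin_upper)
    key <- paste(res_df$bin_lower, res_df$bin_upper)
    res_df <- res_df[!duplicated(key), , drop = FALSE]
    rownames(res_df) <- NULL
  }
  res_df
}

#' Read loops from a BEDPE file
#'
#' Columns `chrom1 start1 end1 chrom2 start2 end2 [name score]`; each
#' anchor interval's midpoint becomes the loop coordinate.
#'
#' @param path BEDPE file.
#' @return Loop table.
#' @export
read_bedpe <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(b) < 6) stop("BEDPE needs at least 6 columns")
  if (!all(b[[1]] == b[[4]])) stop("trans-chromosomal records unsupported")
  loop_table(chrom = b[[1]],
             lower = (b[[2]] + b[[3]]) / 2,
             upper = (b[[5]] + b[[6]]) / 2,
             score = if (ncol(b) >= 8) b[[8]] else NA_real_)
}

#' Write loops as BEDPE
#'
#' @param loops Loop table.
#' @param path Output file.
#' @param anchor_halfwidth Half-width of the written anchor intervals in
#'   bp (default 5000).
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path, anchor_halfwidth = 5000) {
  b <- data.frame(loops$chrom,
                  pmax(0, loops$lower - anchor_halfwidth),
                  loops$lower + anchor_halfwidth,
                  loops$chrom,
                  pmax(0, loops$upper - anchor_halfwidth),
                  loops$upper + anchor_halfwidth,
                  name = paste0("loop", seq_len(nrow(loops))),
                  score = ifelse(is.na(loops$score), ".", loops$score))
  utils::write.table(b, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# coerce a chrom/start/end data.frame (0-based half-open) to GRanges
as_granges <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x))
  nm <- names(x)
  chrom <- x[[if ("chrom" %in% nm) "chrom" else 1]]
  start <- x[[if ("start" %in% nm) "start" else 2]]
  end <- x[[if ("end" %in% nm) "end" else 3]]
  strand <- if ("strand" %in% nm) x$strand else "*"
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1,
                                                 end = end),
                         strand = strand)
}
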