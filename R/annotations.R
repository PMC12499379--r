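#' Categorize genome fragments into regulatory classes
#'
#' Tiles `[span_start, span_end)` into `fragment_size` fragments and labels
#' each one `promoter`, `enhancer`, `gene_body` or `other` by interval
#' overlap, with that fixed precedence. Promoter intervals are built
#' strand-aware around each gene's TSS: 5 kb upstream and 500 bp
#' downstream. Gene records without a strand are skipped with a warning.
#'
#' @param genes `GRanges` or `data.frame` (`chrom start end strand`,
#'   0-based half-open) of gene bodies; the TSS is the strand-dependent
#'   5' end.
#' @param enhancers `GRanges` or `data.frame` of enhancer intervals.
#' @param chrom Chromosome of the fragment span.
#' @param span_start,span_end Fragment span in bp (0-based half-open).
#' @param fragment_size Fragment length in bp (default 1000).
#' @return `data.frame` with `chrom`, `start`, `end`, `category` (factor
#'   with levels promoter, enhancer, gene_body, other); every fragment
#'   gets exactly one category.
#' @export
categorize_fragments <- function(genes, enhancers, chrom, span_start,
                                 span_end, fragment_size = 1000) {
  ggr <- as_granges(genes)
  no_strand <- as.character(GenomicRanges::strand(ggr)) == "*"
  if (any(no_strand)) {
    warning(sprintf("%d gene records without strand skipped",
                    sum(no_strand)))
    ggr <- ggr[!no_strand]
  }
  prom <- GenomicRanges::promoters(ggr, upstream = 5000, downstream = 500)
  prom <- GenomicRanges::trim(prom)
  egr <- as_granges(enhancers)
  starts <- seq(span_start, span_end - 1, by = fragment_size)
  ends <- pmin(starts + fragment_size, span_end)
  frag <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = starts + 1,
                                                  end = ends))
  hit_p <- GenomicRanges::countOverlaps(frag, prom) > 0
  hit_e <- GenomicRanges::countOverlaps(frag, egr) > 0
  hit_g <- GenomicRanges::countOverlaps(frag, ggr) > 0
  category <- ifelse(hit_p, "promoter",
                     ifelse(hit_e, "enhancer",
                            ifelse(hit_g, "gene_body", "other")))
  data.frame(chrom = chrom, start = starts, end = ends,
             category = factor(category, levels = c("promoter", "enhancer",
                                                    "gene_body", "other")),
             stringsAsFactors = FALSE)
}

#' Relative enrichment of a selection within annotation classes
#'
#' For each class `c` of the partition (e.g. CGI forest/prairie, or
#' low/moderate/high CpG content — supplied as input annotation, not
#' computed), returns `|selected in c| / |universe in c|`.
#'
#' @param selected Character vector of selected element ids (a subset of
#'   `universe`).
#' @param universe Character vector of all element ids.
#' @param partition Named character/factor vector mapping element id to
#'   class.
#' @return Named numeric vector of per-class ratios in `[0, 1]`; `NA` for
#'   a class with an empty universe.
#' @export
relative_enrichment <- function(selected, universe, partition) {
  if (!all(selected %in% universe)) {
    stop("selected elements must be a subset of the universe")
  }
  cls <- partition[universe]
  classes <- if (is.factor(partition)) levels(partition)
             else sort(unique(as.character(partition)))
  out <- vapply(classes, function(cc) {
    tot <- sum(cls == cc, na.rm = TRUE)
    if (tot == 0) return(NA_real_)
    sum(cls == cc & universe %in% selected, na.rm = TRUE) / tot
  }, numeric(1))
  stats::setNames(out, classes)
}
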