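#' Write a track as bedGraph
#'
#' @param tr A [track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_track <- function(tr, path) {
  n <- length(tr$values)
  gr <- GenomicRanges::GRanges(
    tr$chrom,
    IRanges::IRanges(start = tr$start + (seq_len(n) - 1) * tr$step + 1,
                     width = tr$step),
    score = tr$values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a uniform-step track from bedGraph
#'
#' The file must cover one chromosome with equal-width, contiguous
#' intervals (as written by [write_track()]).
#'
#' @param path bedGraph file.
#' @return A [track()].
#' @export
read_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) != 1) {
    stop("track files must cover a single chromosome")
  }
  gr <- sort(gr)
  w <- GenomicRanges::width(gr)
  if (length(unique(w)) != 1) stop("track intervals must share one step")
  track(as.character(GenomicRanges::seqnames(gr))[1],
        start = GenomicRanges::start(gr)[1] - 1,
        step = w[1],
        values = S4Vectors::mcols(gr)$score)
}

#' Read BED intervals as a 0-based data.frame
#'
#' @param path BED file (3+ columns; strand read when present).
#' @return `data.frame` with `chrom`, `start`, `end` and, when present,
#'   `name` and `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) out$name <- mc$name
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write intervals as BED
#'
#' @param x `data.frame` with `chrom`, `start`, `end` (0-based half-open)
#'   and optional `name`, `score`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  gr <- as_granges(x)
  if (!is.null(x$name)) gr$name <- x$name
  if (!is.null(x$score)) gr$score <- x$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read the first sequence of a FASTA file as a character string
#' @param path FASTA file.
#' @return Character scalar (the sequence), named by its FASTA header.
#' @export
read_fasta_seq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss[[1]]), names(ss)[1])
}

#' Write a sequence as FASTA
#' @param seq Character scalar.
#' @param path Output file.
#' @param name Sequence header (default "seq").
#' @return `path`, invisibly.
#' @export
write_fasta_seq <- function(seq, path, name = "seq") {
  ss <- Biostrings::DNAStringSet(seq)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
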