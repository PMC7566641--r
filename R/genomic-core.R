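#' Build a genomic interval from browser-style coordinates
#'
#' Printed coordinate spans for large target regions (e.g.
#' `chr11:1,850,000-3,200,000`) follow the BED convention: a 0-based,
#' half-open span whose length is `end - start`. This helper converts such
#' a span to the 1-based, closed `GRanges` representation used internally,
#' so that the round trip through [asBedCoords()] is lossless.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open span.
#' @return A `GRanges` of width `end - start`.
#' @examples
#' r <- regionInterval("chr11", 1850000, 3200000)
#' BiocGenerics::width(r)  # 1.35 Mbp
#' @export
regionInterval <- function(chrom, start, end) {
  if (end <= start) stop("'end' must exceed 'start'")
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1, end = end))
}

#' Convert a GRanges back to 0-based half-open coordinates
#'
#' @param gr A `GRanges`.
#' @return A `data.frame` with `chrom`, `start` (0-based), `end`
#'   (exclusive).
#' @export
asBedCoords <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr))
}

#' Map CpG dinucleotides in a nucleotide sequence
#'
#' Scans the plus strand of `seq` for `CG` occurrences and returns one
#' width-2 site per occurrence, offset into genome coordinates. Because CG
#' is its own reverse complement as a dinucleotide class, the plus-strand
#' census equals the strand-collapsed census; methylation calls are
#' assumed strand-collapsed upstream.
#'
#' @param seq A `DNAString` or character scalar (IUPAC alphabet; a
#'   non-IUPAC character is an error naming its position).
#' @param offset A `GRanges` (or [regionInterval()]) locating base 1 of
#'   `seq` on the genome.
#' @return A `GRanges` of CpG sites with a `site_id` metadata column.
#' @examples
#' cpgMapFromSequence("ACGCGT", regionInterval("chr1", 0, 6))
#' @export
cpgMapFromSequence <- function(seq, offset) {
  if (is.character(seq)) {
    seq <- toupper(seq)
    bad <- regmatches(seq, regexpr("[^ACGTURYSWKMBDHVN]", seq))
    if (length(bad) && nzchar(bad))
      stop(sprintf("non-IUPAC character '%s' at position %d", bad,
                   regexpr("[^ACGTURYSWKMBDHVN]", seq)))
    seq <- Biostrings::DNAString(seq)
  }
  hits <- Biostrings::matchPattern("CG", seq)
  starts <- BiocGenerics::start(hits)
  chrom <- as.character(GenomicRanges::seqnames(offset))[1]
  gstart <- BiocGenerics::start(offset)[1] - 1L  # 0-based offset
  gr <- GenomicRanges::GRanges(
    rep(chrom, length(starts)),
    IRanges::IRanges(start = gstart + starts, width = 2L))
  S4Vectors::mcols(gr)$site_id <- seq_along(gr)
  gr
}

#' Pairwise interval intersection with overlap lengths
#'
#' Records every overlapping pair between two interval collections,
#' together with the overlap length (`min(end) - max(start)` in half-open
#' coordinates). Symmetric in its arguments up to record orientation.
#'
#' @param a,b `GRanges` collections.
#' @return A `data.frame` with `a_idx`, `b_idx` and `overlap` (bp).
#' @export
intersectIntervals <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- BiocGenerics::width(IRanges::pintersect(
    GenomicRanges::ranges(a)[qi], GenomicRanges::ranges(b)[si]))
  data.frame(a_idx = qi, b_idx = si, overlap = ov)
}
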