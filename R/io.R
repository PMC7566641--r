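#' Read per-CpG methylation call tables
#'
#' Reads a TSV of per-CpG bisulfite calls into a
#' [MethylationExperiment-class]. The file must have columns `chrom`,
#' `pos` (1-based position of the C of each plus-strand CpG) and, per
#' sample, either `<id>.meth` + `<id>.total` (read counts) or
#' `<id>.pct` + `<id>.total` (percent-methylation format, as distributed
#' by common methylation callers; counts are reconstructed as
#' `round(pct/100 * total)`).
#'
#' Rows with malformed counts (negative, non-integer, or non-numeric) are
#' rejected and reported by row index. A methylated count exceeding the
#' total is a hard error naming the offending cell, since it indicates a
#' corrupted file rather than noise. Cells with zero total reads are kept
#' but their beta value is missing, not zero.
#'
#' @param path Path to the TSV file.
#' @param sampleSheet `data.frame` mapping `sample` to `cohort` (and
#'   optionally `group`). Every sample in the sheet must have columns in
#'   the file.
#' @return A [MethylationExperiment-class].
#' @export
readMethCalls <- function(path, sampleSheet) {
  stopifnot(is.data.frame(sampleSheet), all(c("sample", "cohort") %in%
                                            colnames(sampleSheet)))
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% colnames(tab)))
    stop("methylation call table must have 'chrom' and 'pos' columns")
  ids <- sampleSheet$sample
  pctMode <- paste0(ids, ".pct") %in% colnames(tab)
  countCol <- ifelse(pctMode, paste0(ids, ".pct"), paste0(ids, ".meth"))
  totalCol <- paste0(ids, ".total")
  missing <- ids[!(countCol %in% colnames(tab)) |
                 !(totalCol %in% colnames(tab))]
  if (length(missing))
    stop("sample(s) in sheet without columns in file: ",
         paste(missing, collapse = ", "))
  cnt <- as.matrix(tab[, countCol, drop = FALSE])
  tot <- as.matrix(tab[, totalCol, drop = FALSE])
  suppressWarnings(storage.mode(tot) <- "double")
  suppressWarnings(storage.mode(cnt) <- "double")
  meth <- cnt
  if (any(pctMode))
    meth[, pctMode] <- round(cnt[, pctMode] / 100 * tot[, pctMode])
  badRow <- which(rowSums(
    (!is.na(meth) & (meth < 0 | meth != floor(meth) & !pctMode[col(meth)])) |
    (!is.na(tot) & (tot < 0 | tot != floor(tot)))) > 0 |
    is.na(tab$pos) | !is.finite(tab$pos))
  if (length(badRow)) {
    warning(sprintf("rejected %d malformed row(s): %s", length(badRow),
                    paste(utils::head(badRow, 10), collapse = ", ")))
    keep <- setdiff(seq_len(nrow(tab)), badRow)
    tab <- tab[keep, , drop = FALSE]
    meth <- meth[keep, , drop = FALSE]
    tot <- tot[keep, , drop = FALSE]
  }
  over <- which(!is.na(meth) & !is.na(tot) & meth > tot, arr.ind = TRUE)
  if (nrow(over))
    stop(sprintf("meth > total at row %d, sample '%s'",
                 over[1, 1], ids[over[1, 2]]))
  ## both NA together: a count without a total (or vice versa) is missing
  na <- is.na(meth) | is.na(tot)
  meth[na] <- NA
  tot[na] <- NA
  ord <- order(tab$chrom, tab$pos)
  sites <- GenomicRanges::GRanges(
    tab$chrom[ord], IRanges::IRanges(start = tab$pos[ord], width = 2L))
  MethylationExperiment(meth[ord, , drop = FALSE], tot[ord, , drop = FALSE],
                        sites, as.data.frame(sampleSheet))
}

#' Write a methylation call table
#'
#' Inverse of [readMethCalls()]: emits `chrom`, `pos` (1-based) and per
#' sample `<id>.meth`, `<id>.total` columns; positions round-trip
#' losslessly.
#'
#' @param x A [MethylationExperiment-class].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeMethCalls <- function(x, path) {
  rr <- cpgSites(x)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = BiocGenerics::start(rr),
                    check.names = FALSE)
  m <- methReads(x)
  n <- totalReads(x)
  for (i in seq_len(ncol(x))) {
    out[[paste0(colnames(x)[i], ".meth")]] <- m[, i]
    out[[paste0(colnames(x)[i], ".total")]] <- n[, i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read labeled annotation intervals from BED
#'
#' Accepts BED4/BED6, optionally with a seventh `key=value;key=value`
#' attribute column (used for TR names, enhancer source, signature class,
#' or per-sample ATAC scores). Intervals outside `region`, when given, are
#' dropped with a message reporting the count.
#'
#' @param path BED file path.
#' @param kind Free-text label stored in the `kind` metadata column.
#' @param region Optional `GRanges` analysis region.
#' @return A `GRanges` with `name`, `score` (if present), `kind`, and any
#'   parsed attributes as metadata columns.
#' @export
readAnnotationBed <- function(path, kind = NA_character_, region = NULL) {
  first <- readLines(path, n = 1L)
  nf <- length(strsplit(first, "\t")[[1]])
  gr <- if (nf >= 7)
    rtracklayer::import(path, format = "bed",
                        extraCols = c(attrs = "character"))
  else rtracklayer::import(path, format = "bed")
  S4Vectors::mcols(gr)$kind <- kind
  if (!is.null(S4Vectors::mcols(gr)$attrs)) {
    kv <- strsplit(as.character(S4Vectors::mcols(gr)$attrs), ";", fixed = TRUE)
    keys <- unique(unlist(lapply(kv, function(p) sub("=.*", "", p))))
    for (k in keys) {
      S4Vectors::mcols(gr)[[k]] <- vapply(kv, function(p) {
        hit <- grep(paste0("^", k, "="), p, value = TRUE)
        if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
      }, character(1))
    }
    S4Vectors::mcols(gr)$attrs <- NULL
  }
  if (!is.null(region)) {
    keep <- IRanges::overlapsAny(gr, region, type = "within")
    if (any(!keep))
      message(sprintf("dropped %d interval(s) outside the analysis region",
                      sum(!keep)))
    gr <- gr[keep]
  }
  gr
}

#' Write labeled annotation intervals as BED
#'
#' Emits BED6 plus a `key=value` attribute column for any extra metadata
#' columns, matching what [readAnnotationBed()] parses.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param attrCols Metadata columns to serialize as attributes.
#' @return Invisibly, the path.
#' @export
writeAnnotationBed <- function(gr, path, attrCols = NULL) {
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- rep(".", length(gr))
  sc <- S4Vectors::mcols(gr)$score
  if (is.null(sc)) sc <- rep(0, length(gr))
  st <- as.character(BiocGenerics::strand(gr))
  st[st == "*"] <- "."
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    name = nm, score = sc, strand = st)
  if (!is.null(attrCols)) {
    attrs <- vapply(seq_along(gr), function(i)
      paste(sprintf("%s=%s", attrCols,
                    vapply(attrCols, function(k)
                      as.character(S4Vectors::mcols(gr)[[k]][i]),
                      character(1))),
            collapse = ";"), character(1))
    out$attrs <- attrs
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export per-window or per-position scores as bedGraph
#'
#' Writes a UCSC bedGraph track (0-based, half-open, deterministic
#' position order). Non-finite scores are skipped, with a warning giving
#' the count, rather than emitted as invalid lines.
#'
#' @param gr A `GRanges` whose `score` metadata column holds the values.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return Invisibly, the number of data lines written.
#' @export
writeBedGraph <- function(gr, path, name = "track") {
  sc <- S4Vectors::mcols(gr)$score
  if (is.null(sc)) stop("'gr' must carry a 'score' metadata column")
  bad <- !is.finite(sc)
  if (any(bad))
    warning(sprintf("skipped %d non-finite score(s)", sum(bad)))
  gr <- gr[!bad]
  gr <- BiocGenerics::sort(gr)
  lines <- c(sprintf("track type=bedGraph name=%s", name),
             sprintf("%s\t%d\t%d\t%s",
                     as.character(GenomicRanges::seqnames(gr)),
                     BiocGenerics::start(gr) - 1L,
                     BiocGenerics::end(gr),
                     format(S4Vectors::mcols(gr)$score, trim = TRUE,
                            digits = 10, scientific = FALSE)))
  writeLines(lines, path)
  invisible(length(gr))
}
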