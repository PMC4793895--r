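## Genomic-range annotations: BED files and pasted range strings become
## per-variant boolean fields (RANGE.<name>) usable in filter chains.
## Coordinate conventions, fixed and tested: BED is 0-based half-open,
## pasted ranges are 1-based inclusive, VCF POS is 1-based.  Internally
## everything is stored 1-based inclusive in a GRanges, so a variant is
## inside a BED interval (start, end] iff start < POS <= end.

#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges overlapsAny
NULL

.mkRangeAnnotation <- function(name, chrom, start1, end1) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start1, end = end1))
  new("RangeAnnotation", name = name, ranges = gr)
}

#' Load a BED file as a named range annotation
#'
#' Reads the first three BED columns (chrom, chromStart, chromEnd;
#' 0-based half-open); extra columns are ignored and \code{track}/
#' \code{browser}/comment lines are skipped.
#'
#' @param path BED file path.
#' @param name annotation label; the derived field will be
#'   \code{RANGE.<name>}.  Each loaded annotation needs a distinct name
#'   (enforced when registered in a session or applied to a dataset).
#' @return a \linkS4class{RangeAnnotation}.
#' @export
loadBed <- function(path, name) {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path)
  chrom <- character(0); s <- integer(0); e <- integer(0)
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "track") ||
        startsWith(line, "browser") || startsWith(line, "#")) next
    cols <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(cols) < 3)
      stop(sprintf("%s line %d: BED needs at least 3 columns", path, i))
    st <- suppressWarnings(as.integer(cols[2]))
    en <- suppressWarnings(as.integer(cols[3]))
    if (is.na(st) || is.na(en))
      stop(sprintf("%s line %d: non-numeric BED coordinates", path, i))
    if (st >= en)
      stop(sprintf("%s line %d: chromStart %d >= chromEnd %d",
                   path, i, st, en))
    chrom <- c(chrom, cols[1]); s <- c(s, st); e <- c(e, en)
  }
  ## BED (start, end] half-open 0-based == 1-based inclusive [start+1, end]
  .mkRangeAnnotation(name, chrom, s + 1L, e)
}

#' Parse pasted genomic ranges as a named annotation
#'
#' Accepts whitespace- or comma-separated tokens of the form
#' \code{chrom:start-end}, 1-based with inclusive endpoints (so
#' \code{"chr1:5-5"} matches exactly POS 5).
#'
#' @param text the pasted ranges.
#' @param name annotation label.
#' @return a \linkS4class{RangeAnnotation}.
#' @export
parseAdhocRanges <- function(text, name) {
  tokens <- unlist(strsplit(text, "[,;[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0)
    stop("no ranges found in text")
  m <- regmatches(tokens, regexec("^([^:]+):([0-9]+)-([0-9]+)$", tokens))
  chrom <- character(0); s <- integer(0); e <- integer(0)
  for (i in seq_along(tokens)) {
    if (length(m[[i]]) != 4)
      stop(sprintf("malformed range token '%s' (expected chrom:start-end)",
                   tokens[i]))
    st <- as.integer(m[[i]][3]); en <- as.integer(m[[i]][4])
    if (st > en)
      stop(sprintf("reversed range '%s': start %d > end %d",
                   tokens[i], st, en))
    if (st < 1)
      stop(sprintf("range '%s': positions are 1-based", tokens[i]))
    chrom <- c(chrom, m[[i]][2]); s <- c(s, st); e <- c(e, en)
  }
  .mkRangeAnnotation(name, chrom, s, e)
}

#' Label every variant by membership in a range annotation
#'
#' Adds the boolean derived field \code{RANGE.<name>} to every document:
#' \code{TRUE} iff the variant's POS lies inside some interval of the
#' annotation on its chromosome (point semantics — the REF span is not
#' considered), \code{FALSE} otherwise, including for chromosomes absent
#' from the annotation.  Re-annotating under the same name recomputes the
#' labels (idempotent).
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @param ra a \linkS4class{RangeAnnotation}.
#' @param normalizeChr logical; when \code{TRUE}, chromosome names are
#'   compared after stripping a \code{"chr"} prefix on both sides
#'   (default \code{FALSE}: exact string equality).
#' @return the dataset with the labels attached (existing indexes are
#'   kept; the new field is unindexed until \code{\link{buildIndex}}).
#' @export
annotateRanges <- function(ds, ra, normalizeChr = FALSE) {
  key <- paste0("RANGE.", ra@name)
  norm <- function(x) if (normalizeChr) sub("^chr", "", x) else x
  n <- length(ds@docs)
  if (n == 0) return(ds)
  vChrom <- norm(vapply(ds@docs, function(d) d$chrom, character(1)))
  vPos <- vapply(ds@docs, function(d) d$pos, integer(1))
  subjChrom <- norm(as.character(GenomicRanges::seqnames(ra@ranges)))
  subjStart <- GenomicRanges::start(ra@ranges)
  subjEnd <- GenomicRanges::end(ra@ranges)
  inside <- logical(n)
  for (ch in unique(vChrom)) {
    onCh <- which(subjChrom == ch)
    if (!length(onCh)) next
    idx <- which(vChrom == ch)
    inside[idx] <- IRanges::overlapsAny(
      IRanges::IRanges(start = vPos[idx], width = 1L),
      IRanges::IRanges(start = subjStart[onCh], end = subjEnd[onCh]))
  }
  for (i in seq_len(n))
    ds@docs[[i]]$derived[[key]] <- inside[i]
  ds
}
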