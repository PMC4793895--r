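## Genotype-level logic: zygosity from GT, ref/alt depths from AD, and
## per-variant min/max summaries of numeric FORMAT fields.

.ZYGOSITIES <- c("NO_CALL", "REFERENCE", "HETEROZYGOUS", "HOMOZYGOUS")

#' Classify a genotype string by alternate-allele count
#'
#' Splits a GT string on \code{/} and \code{|} (phasing-blind) and counts
#' the tokens that are neither \code{.} nor \code{0}: that count is the
#' number of alternate alleles the sample carries.  One alternate allele
#' is heterozygous, more than one homozygous, none with at least one
#' called token is reference, and all-missing tokens are a no-call.  The
#' rule is ploidy-agnostic: \code{"0/1"} and \code{"0/0/1"} are both
#' heterozygous.  Tokenizing (rather than deleting characters) keeps
#' multi-digit allele indices such as \code{"10"} intact.
#'
#' Note that \code{"1/2"} carries two alternate alleles and is therefore
#' classified homozygous under this count rule, even though the site is
#' biologically a heterozygous-alt genotype.  Half-calls like \code{"./1"}
#' count the called alternate: heterozygous.
#'
#' @param gt genotype string: allele indices joined by \code{/} or
#'   \code{|}, or \code{"."} tokens for missing alleles.
#' @return list with elements \code{zygosity} (one of \code{"NO_CALL"},
#'   \code{"REFERENCE"}, \code{"HETEROZYGOUS"}, \code{"HOMOZYGOUS"}) and
#'   \code{altAlleleCount} (non-negative integer).
#' @examples
#' classifyGenotype("0/1")    # heterozygous, 1
#' classifyGenotype("0/0/1")  # heterozygous, 1 (triploid call)
#' classifyGenotype("1|1")    # homozygous, 2
#' classifyGenotype("./.")    # no-call, 0
#' @export
classifyGenotype <- function(gt) {
  if (!is.character(gt) || length(gt) != 1 || is.na(gt) || !nzchar(gt))
    stop("GT must be a single non-empty string")
  tokens <- strsplit(gt, "[/|]")[[1]]
  if (length(tokens) == 0)
    stop(sprintf("empty genotype '%s'", gt))
  bad <- !(tokens == "." | grepl("^[0-9]+$", tokens))
  if (any(bad))
    stop(sprintf("invalid allele token '%s' in genotype '%s'",
                 tokens[bad][1], gt))
  nAlt <- sum(tokens != "." & tokens != "0")
  zyg <- if (nAlt == 1) "HETEROZYGOUS"
    else if (nAlt > 1) "HOMOZYGOUS"
    else if (all(tokens == ".")) "NO_CALL"
    else "REFERENCE"
  list(zygosity = zyg, altAlleleCount = as.integer(nAlt))
}

#' Parse an AD (allelic depth) field into reference and alternate depths
#'
#' The AD field is assumed to hold the number of reads supporting the
#' reference allele followed by the number supporting the alternate,
#' comma-separated.  \code{"."} means both depths are absent.  More than
#' two elements (an unnormalized multi-allelic record) is tolerated with a
#' warning, using the second element; records should be normalized to one
#' allele per row first.
#'
#' @param ad AD field string, e.g. \code{"12,5"}.
#' @return list with integer elements \code{refDepth} and \code{altDepth},
#'   each \code{NA} when absent.
#' @examples
#' parseAlleleDepth("12,5")
#' parseAlleleDepth(".")
#' @export
parseAlleleDepth <- function(ad) {
  if (!is.character(ad) || length(ad) != 1 || is.na(ad))
    stop("AD must be a single string")
  if (ad == "." || ad == "")
    return(list(refDepth = NA_integer_, altDepth = NA_integer_))
  parts <- strsplit(ad, ",", fixed = TRUE)[[1]]
  if (length(parts) < 2)
    stop(sprintf("AD '%s' must have at least two comma-separated values",
                 ad))
  if (length(parts) > 2)
    warning(sprintf(
      "AD '%s' has %d elements; using the first two (normalize the record first)",
      ad, length(parts)))
  vals <- suppressWarnings(as.integer(parts[1:2]))
  ## per-element "." is a legal missing depth
  missing <- parts[1:2] == "."
  if (any(is.na(vals) & !missing) || any(vals < 0, na.rm = TRUE))
    stop(sprintf("AD '%s' must contain non-negative integers", ad))
  list(refDepth = vals[1], altDepth = vals[2])
}

#' Minimum and maximum of a numeric FORMAT field across samples
#'
#' Summarizes one declared-numeric FORMAT field over all samples with a
#' present value at this variant.  The results are what the derived
#' \code{FORMAT.<field>.min} / \code{FORMAT.<field>.max} filterable
#' fields expose: they let a chain drop, say, structural variants with too
#' few supporting reads in any sample.
#'
#' @param doc a variant document (element of \code{docs(dataset)}).
#' @param field FORMAT field id (e.g. \code{"DP"}).
#' @param header the dataset's \linkS4class{VcfHeader} (used to check the
#'   declared type).
#' @return numeric \code{c(min, max)}, or \code{NULL} if no sample has a
#'   value.
#' @export
summarizeNumericFormat <- function(doc, field, header) {
  fmt <- header@format
  row <- match(field, fmt$id)
  if (is.na(row))
    stop(sprintf("FORMAT field '%s' is not declared in the header", field))
  if (!fmt$type[row] %in% c("Integer", "Float"))
    stop(sprintf("FORMAT field '%s' is declared %s, not numeric",
                 field, fmt$type[row]))
  vals <- unlist(lapply(doc$calls, function(call) {
    if (field == "AD") c(call$refDepth, call$altDepth)
    else call$other[[field]]
  }), use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NULL)
  c(min(vals), max(vals))
}

## Build a SampleCall (plain list) from the positional FORMAT values of
## one sample column.  `keys` is the FORMAT column split on ':'.
## `nAlt` is the record's alternate count: an AD of nAlt+1 elements on a
## multi-allelic record matches its declared arity, so no warning.
.makeSampleCall <- function(keys, values, nAlt = 1L) {
  call <- list(gt = NA_character_, zygosity = "NO_CALL",
               altAlleleCount = 0L,
               refDepth = NA_integer_, altDepth = NA_integer_,
               other = list())
  ## VCF permits trailing fields to be dropped from a sample column
  n <- min(length(keys), length(values))
  for (i in seq_len(n)) {
    key <- keys[i]; val <- values[i]
    if (key == "GT") {
      call$gt <- val
      if (!is.na(val) && val != "." && nzchar(val)) {
        cls <- classifyGenotype(val)
        call$zygosity <- cls$zygosity
        call$altAlleleCount <- cls$altAlleleCount
      }
    } else if (key == "AD") {
      ad <- if (nAlt > 1L &&
                length(strsplit(val, ",", fixed = TRUE)[[1]]) ==
                  nAlt + 1L)
        suppressWarnings(parseAlleleDepth(val))
      else parseAlleleDepth(val)
      call$refDepth <- ad$refDepth
      call$altDepth <- ad$altDepth
      call$other[["AD"]] <- val
    } else if (val != "." && nzchar(val)) {
      call$other[[key]] <- val
    }
  }
  call
}
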