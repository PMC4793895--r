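## In-memory indexed document store.  Field paths are dot-separated to
## disambiguate namespaces:
##   CORE.CHROM ... CORE.FILTER      the eight fixed VCF columns
##   INFO.<key>                      typed INFO annotations
##   FORMAT.<key>.min / .max         per-variant sample minima / maxima
##   DERIVED.sample_count / sample_list   carrier summaries
##   RANGE.<name>                    boolean range-annotation labels

#' Resolve a field path on one variant document
#'
#' @param doc a variant document.
#' @param field dot-separated field path (see \code{\link{catalogFields}}
#'   for the namespaces).
#' @return the typed value, or \code{NULL} when the document lacks the
#'   field.
#' @export
fieldValue <- function(doc, field) {
  if (startsWith(field, "CORE.")) {
    out <- switch(substring(field, 6),
      CHROM = doc$chrom, POS = doc$pos, ID = doc$id, REF = doc$ref,
      ALT = paste(doc$alt, collapse = ","), QUAL = doc$qual,
      FILTER = doc$filter,
      stop(sprintf("unknown core field '%s'", field)))
    if (length(out) == 1 && is.na(out)) NULL else out
  } else if (startsWith(field, "INFO.")) {
    doc$info[[substring(field, 6)]]
  } else if (startsWith(field, "FORMAT.") || startsWith(field, "RANGE.")) {
    doc$derived[[field]]
  } else if (startsWith(field, "DERIVED.")) {
    doc$derived[[substring(field, 9)]]
  } else {
    stop(sprintf("unknown field namespace in '%s'", field))
  }
}

#' Catalog every filterable field of a dataset
#'
#' Types each observed field as numeric, flag or string from the header
#' metadata and, for string fields, collects the observed distinct values
#' and their cardinality (a GUI uses such a cardinality to switch between
#' a checkbox list and a type-ahead box; the threshold is metadata here,
#' not enforced).
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @return data.frame with columns \code{field}, \code{kind},
#'   \code{cardinality} (NA for non-string fields) and \code{values}
#'   (list column of observed distinct string values).
#' @export
catalogFields <- function(ds) {
  fields <- .catalogSkeleton(ds)
  fields$cardinality <- NA_integer_
  fields$values <- vector("list", nrow(fields))
  for (i in which(fields$kind == "string")) {
    vals <- sort(unique(as.character(unlist(lapply(ds@docs, fieldValue,
      field = fields$field[i])))))
    fields$values[[i]] <- vals
    fields$cardinality[i] <- length(vals)
  }
  fields
}

## field -> kind table without the (expensive) observed-value scan
.catalogSkeleton <- function(ds) {
  hdr <- ds@header
  fields <- data.frame(field = c("CORE.CHROM", "CORE.POS", "CORE.ID",
                                 "CORE.REF", "CORE.ALT", "CORE.QUAL",
                                 "CORE.FILTER"),
                       kind = c("string", "numeric", "string", "string",
                                "string", "numeric", "string"),
                       stringsAsFactors = FALSE)
  if (nrow(hdr@info))
    fields <- rbind(fields, data.frame(
      field = paste0("INFO.", hdr@info$id),
      kind = ifelse(hdr@info$type == "Flag", "flag",
             ifelse(hdr@info$type %in% c("Integer", "Float"),
                    "numeric", "string")),
      stringsAsFactors = FALSE))
  numFmt <- setdiff(hdr@format$id[hdr@format$type %in%
                                    c("Integer", "Float")], "GT")
  if (length(numFmt))
    fields <- rbind(fields, data.frame(
      field = c(paste0("FORMAT.", numFmt, ".min"),
                paste0("FORMAT.", numFmt, ".max")),
      kind = "numeric", stringsAsFactors = FALSE))
  fields <- rbind(fields, data.frame(
    field = c("DERIVED.sample_count", "DERIVED.sample_list"),
    kind = c("numeric", "string"), stringsAsFactors = FALSE))
  rangeFields <- sort(unique(unlist(lapply(ds@docs, function(d)
    grep("^RANGE\\.", names(d$derived), value = TRUE)))))
  if (length(rangeFields))
    fields <- rbind(fields, data.frame(field = rangeFields,
                                       kind = "flag",
                                       stringsAsFactors = FALSE))
  fields
}

.knownFields <- function(ds) .catalogSkeleton(ds)$field

.checkField <- function(ds, field) {
  known <- .knownFields(ds)
  if (!field %in% known)
    stop(sprintf("unknown field '%s'", field))
  invisible(field)
}

#' Build an index on a field
#'
#' Precomputes the field's value column over all documents so queries on
#' that field take a vectorized path.  Indexing never changes results:
#' queries with and without an index return identical id sets.
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @param field field path present in the catalog.
#' @return the dataset with the index attached.
#' @export
buildIndex <- function(ds, field) {
  .checkField(ds, field)
  vals <- lapply(ds@docs, fieldValue, field = field)
  present <- !vapply(vals, is.null, logical(1))
  ## scalar column for single-valued docs; multi-valued entries fall
  ## back to a list (kept exact, still vectorized over presence)
  scalar <- vapply(vals, function(v) length(v) == 1, logical(1))
  ds@indexes[[field]] <- list(
    present = present,
    scalar = present & scalar,
    column = vals
  )
  ds
}

#' Drop the index on a field (results are unaffected)
#' @param ds a \linkS4class{VariantDataset}.
#' @param field indexed field path.
#' @return the dataset without that index.
#' @export
dropIndex <- function(ds, field) {
  ds@indexes[[field]] <- NULL
  ds
}
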