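## Tab-delimited export of surviving variants with a chosen column set.

.DEFAULT_COLUMNS <- c("CORE.CHROM", "CORE.POS", "CORE.ID", "CORE.REF",
                      "CORE.ALT", "CORE.QUAL", "CORE.FILTER",
                      "DERIVED.sample_count", "DERIVED.sample_list")

.renderValue <- function(v) {
  if (is.null(v) || length(v) == 0) return(".")
  if (is.logical(v)) return(paste(ifelse(v, "TRUE", "FALSE"),
                                  collapse = ","))
  v <- ifelse(is.na(v), ".", as.character(v))
  paste(v, collapse = ",")
}

#' Export surviving variants as a tab-delimited table
#'
#' Writes a UTF-8, LF-terminated TSV with a header row of field paths
#' and one row per surviving document in original file order.  Absent
#' values are rendered \code{"."}; array-valued INFO fields are
#' comma-joined (matching VCF syntax — tabs and newlines inside values
#' are rejected at ingest, so the table is unambiguous).  Derived
#' columns (\code{DERIVED.sample_count}, \code{FORMAT.DP.min},
#' \code{RANGE.*}, ...) export like any field.
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @param survivors integer ids to export (e.g. \code{survivors(chain)});
#'   defaults to all documents.
#' @param columns ordered field paths; \code{NULL} for the default set
#'   (the seven core columns plus carrier count and list; INFO is
#'   expanded per-field, so it is not a default column).
#' @param path output file path.
#' @return number of data rows written (excluding the header),
#'   invisibly.
#' @export
exportTable <- function(ds, survivors = variantIds(ds), columns = NULL,
                        path) {
  if (is.null(columns)) columns <- .DEFAULT_COLUMNS
  if (length(columns) == 0) stop("columns must be non-empty")
  known <- .knownFields(ds)
  bad <- setdiff(columns, known)
  if (length(bad))
    stop(sprintf("unknown column '%s'", bad[1]))
  pos <- match(sort(survivors), ds@ids)
  if (anyNA(pos)) stop("survivors contains unknown document ids")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(columns, collapse = "\t"), "\n")),
           con)
  for (p in pos) {
    row <- vapply(columns, function(col)
      .renderValue(fieldValue(ds@docs[[p]], col)), character(1))
    writeBin(charToRaw(paste0(paste(row, collapse = "\t"), "\n")), con)
  }
  invisible(length(pos))
}

#' Choose the visible column set
#'
#' Computes the ordered list of visible columns from show/hide requests
#' against the dataset's catalog order.  Hiding a field only affects
#' display and export defaults: hidden fields stay in the catalog and
#' remain filterable.
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @param show character vector of field paths to display;
#'   \code{character(0)} means the default set.
#' @param hide field paths to remove from the visible set.
#' @return ordered character vector of visible field paths.
#' @export
selectColumns <- function(ds, show = character(0),
                          hide = character(0)) {
  known <- .knownFields(ds)
  bad <- setdiff(c(show, hide), known)
  if (length(bad))
    stop(sprintf("unknown field '%s'", bad[1]))
  base <- if (length(show)) show else .DEFAULT_COLUMNS
  base[!base %in% hide]
}
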