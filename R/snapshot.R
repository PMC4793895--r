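## Single-file dataset snapshots.  The format is internal but versioned:
## JSON carrying the header tables, the raw per-sample strings and the
## typed INFO values.  On load, values are re-coerced from the header
## metadata and sample calls are rebuilt through the genotype logic, so
## a reloaded dataset behaves identically to a freshly parsed one.

.SNAPSHOT_VERSION <- "1.0"

#' Save a dataset snapshot
#' @param ds a \linkS4class{VariantDataset}.
#' @param path output file (JSON; gzip-compressed when the path ends in
#'   \code{.gz}).
#' @return \code{path}, invisibly.
#' @export
snapshotDataset <- function(ds, path) {
  docs <- lapply(ds@docs, function(doc) {
    list(
      chrom = doc$chrom, pos = doc$pos, id = doc$id, ref = doc$ref,
      alt = as.list(doc$alt), qual = doc$qual, filter = doc$filter,
      info = doc$info,
      calls = lapply(doc$calls, function(call)
        list(gt = call$gt,
             ad = call$other[["AD"]],
             other = call$other[setdiff(names(call$other), "AD")])),
      ranges = doc$derived[grep("^RANGE\\.", names(doc$derived))]
    )
  })
  payload <- list(
    format = "variantsieve-snapshot",
    version = .SNAPSHOT_VERSION,
    header = list(
      info = ds@header@info, format = ds@header@format,
      filters = as.list(ds@header@filters),
      samples = as.list(ds@header@samples)),
    ids = ds@ids,
    docs = docs
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else
    file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE,
                              null = "null", na = "null", digits = NA),
             con)
  invisible(path)
}

#' Load a dataset snapshot
#' @param path snapshot file written by \code{\link{snapshotDataset}}.
#' @return a \linkS4class{VariantDataset} (indexes are not persisted;
#'   rebuild with \code{\link{buildIndex}} as needed).
#' @export
loadSnapshot <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "variantsieve-snapshot"))
    stop(sprintf("'%s' is not a dataset snapshot", path))
  if (!identical(x$version, .SNAPSHOT_VERSION))
    stop(sprintf("snapshot version '%s' not supported (expected %s)",
                 x$version, .SNAPSHOT_VERSION))
  fieldFrame <- function(rows) {
    if (length(rows) == 0) return(.emptyFieldFrame())
    do.call(rbind, lapply(rows, function(r) data.frame(
      id = r$id, number = r$number, type = r$type,
      description = if (is.null(r$description)) NA_character_ else
        r$description,
      stringsAsFactors = FALSE)))
  }
  header <- new("VcfHeader",
    info = fieldFrame(x$header$info),
    format = fieldFrame(x$header$format),
    filters = as.character(unlist(x$header$filters)),
    samples = as.character(unlist(x$header$samples)))
  infoType <- stats::setNames(header@info$type, header@info$id)
  fmtType <- stats::setNames(header@format$type, header@format$id)
  coerce <- function(v, type) {
    v <- unlist(v)
    switch(type,
      Integer = as.integer(v), Float = as.numeric(v),
      Flag = as.logical(v), as.character(v))
  }
  docs <- lapply(x$docs, function(d) {
    nAlt <- length(d$alt)
    info <- list()
    for (key in names(d$info)) {
      type <- infoType[[key]]
      if (is.null(type)) type <- "String"
      info[[key]] <- coerce(d$info[[key]], type)
    }
    calls <- list()
    for (sid in names(d$calls)) {
      c0 <- d$calls[[sid]]
      gt <- if (is.null(c0$gt)) NA_character_ else c0$gt
      keys <- c("GT", if (!is.null(c0$ad)) "AD")
      vals <- c(gt, if (!is.null(c0$ad)) c0$ad)
      call <- .makeSampleCall(keys, vals, nAlt = nAlt)
      for (key in names(c0$other)) {
        type <- fmtType[[key]]
        if (is.null(type)) type <- "String"
        call$other[[key]] <- coerce(c0$other[[key]], type)
      }
      calls[[sid]] <- call
    }
    doc <- list(
      chrom = d$chrom, pos = as.integer(d$pos),
      id = if (is.null(d$id)) NA_character_ else d$id,
      ref = d$ref, alt = as.character(unlist(d$alt)),
      qual = if (is.null(d$qual)) NA_real_ else as.numeric(d$qual),
      filter = d$filter, info = info, calls = calls, derived = list())
    doc <- .finalizeDoc(doc, header)
    for (key in names(d$ranges))
      doc$derived[[key]] <- isTRUE(d$ranges[[key]])
    doc
  })
  new("VariantDataset", header = header, docs = docs,
      ids = as.integer(unlist(x$ids)), indexes = list())
}
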