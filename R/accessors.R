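## Accessor generics: slots are implementation detail, these are the API.

#' @rdname VcfHeader-class
#' @param x a \linkS4class{VcfHeader} or \linkS4class{VariantDataset}.
#' @export
setGeneric("infoFields", function(x) standardGeneric("infoFields"))
#' @rdname VcfHeader-class
#' @export
setGeneric("formatFields", function(x) standardGeneric("formatFields"))
#' @rdname VcfHeader-class
#' @export
setGeneric("filterIds", function(x) standardGeneric("filterIds"))
#' @rdname VcfHeader-class
#' @export
setGeneric("vcfSamples", function(x) standardGeneric("vcfSamples"))

setMethod("infoFields", "VcfHeader", function(x) x@info)
setMethod("formatFields", "VcfHeader", function(x) x@format)
setMethod("filterIds", "VcfHeader", function(x) x@filters)
setMethod("vcfSamples", "VcfHeader", function(x) x@samples)
setMethod("infoFields", "VariantDataset", function(x) x@header@info)
setMethod("formatFields", "VariantDataset",
          function(x) x@header@format)
setMethod("filterIds", "VariantDataset", function(x) x@header@filters)
setMethod("vcfSamples", "VariantDataset", function(x) x@header@samples)

#' @rdname VariantDataset-class
#' @param x a \linkS4class{VariantDataset}.
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
setMethod("variantIds", "VariantDataset", function(x) x@ids)

#' @rdname VariantDataset-class
#' @export
setGeneric("docs", function(x) standardGeneric("docs"))
setMethod("docs", "VariantDataset", function(x) x@docs)

#' @rdname VariantDataset-class
#' @export
setGeneric("vcfHeader", function(x) standardGeneric("vcfHeader"))
setMethod("vcfHeader", "VariantDataset", function(x) x@header)

#' Retrieve one document by its stable id
#' @param ds a \linkS4class{VariantDataset}.
#' @param id integer document id.
#' @return the variant document (a named list).
#' @export
getDoc <- function(ds, id) {
  p <- match(id, ds@ids)
  if (is.na(p)) stop(sprintf("no document with id %d", id))
  ds@docs[[p]]
}

#' @rdname FilterChain-class
#' @param x a \linkS4class{FilterChain}.
#' @export
setGeneric("stepCounts", function(x) standardGeneric("stepCounts"))
setMethod("stepCounts", "FilterChain", function(x) x@counts)

#' @rdname FilterChain-class
#' @export
setGeneric("survivors", function(x) standardGeneric("survivors"))
setMethod("survivors", "FilterChain", function(x) x@survivors)
setMethod("survivors", "MinerSession", function(x) x@chain@survivors)

#' @rdname FilterChain-class
#' @export
setGeneric("initialCount", function(x) standardGeneric("initialCount"))
setMethod("initialCount", "FilterChain", function(x) x@initialCount)

#' @rdname ValidationReport-class
#' @param x a \linkS4class{ValidationReport}.
#' @export
setGeneric("validationOk", function(x) standardGeneric("validationOk"))
setMethod("validationOk", "ValidationReport", function(x) x@ok)

#' @rdname ValidationReport-class
#' @export
setGeneric("issues", function(x) standardGeneric("issues"))
setMethod("issues", "ValidationReport", function(x) x@issues)

#' Render a validation report as machine-readable lines
#' @param report a \linkS4class{ValidationReport}.
#' @return character vector, one \code{line TAB severity TAB message}
#'   per issue.
#' @export
formatIssues <- function(report) {
  df <- report@issues
  sprintf("%d\t%s\t%s", df$line, df$severity, df$message)
}

## --- show methods ----------------------------------------------------

setMethod("show", "VcfHeader", function(object) {
  cat(sprintf(
    "VcfHeader: %d INFO, %d FORMAT, %d FILTER declarations; %d sample(s)\n",
    nrow(object@info), nrow(object@format), length(object@filters),
    length(object@samples)))
  if (length(object@samples))
    cat("  samples:", paste(utils::head(object@samples, 8),
                            collapse = ", "),
        if (length(object@samples) > 8) "..." else "", "\n")
})

setMethod("show", "VariantDataset", function(object) {
  cat(sprintf("VariantDataset: %d variant(s), %d sample(s)\n",
              length(object@docs), length(object@header@samples)))
  nMulti <- sum(vapply(object@docs,
    function(d) isTRUE(d$derived$multiallelic), logical(1)))
  if (nMulti)
    cat(sprintf("  %d multi-allelic record(s) flagged (run normalizeMultiallelic)\n",
                nMulti))
  if (length(object@indexes))
    cat("  indexed:", paste(names(object@indexes), collapse = ", "),
        "\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %s (%d issue(s))\n",
              if (object@ok) "OK" else "FAILED",
              nrow(object@issues)))
  for (i in seq_len(min(nrow(object@issues), 10)))
    cat(sprintf("  line %d [%s] %s\n", object@issues$line[i],
                object@issues$severity[i], object@issues$message[i]))
  if (nrow(object@issues) > 10)
    cat(sprintf("  ... and %d more\n", nrow(object@issues) - 10))
})

.describeSpec <- function(spec) {
  if (spec@kind == "group") {
    gf <- spec@group
    q <- switch(gf@quantifier, any = "in any of",
                all = "in all of",
                fraction = sprintf("in >= %d%% of",
                                   round(100 * gf@fraction)))
    sprintf("%s %s %s group '%s' (%d samples)%s",
            if (gf@mode == "require") "require" else "exclude",
            gf@zygosityReq, q, gf@group@name,
            length(gf@group@members),
            if (is.na(gf@minAltDepth)) "" else
              sprintf(", alt depth >= %d", gf@minAltDepth))
  } else if (spec@kind %in% c("flag", "range")) {
    sprintf("%s %s", spec@field, spec@operator)
  } else if (spec@kind == "string") {
    sprintf("%s %s {%s}", spec@field, spec@operator,
            paste(spec@value, collapse = ", "))
  } else {
    sprintf("%s %s %s", spec@field, spec@operator,
            format(spec@value))
  }
}

setMethod("show", "FilterSpec", function(object) {
  cat("FilterSpec:", .describeSpec(object), "\n")
})

setMethod("show", "FilterChain", function(object) {
  cat(sprintf("FilterChain: %d step(s)", length(object@steps)))
  if (!is.na(object@initialCount))
    cat(sprintf(", %d variants before filtering", object@initialCount))
  cat("\n")
  for (i in seq_along(object@steps)) {
    cat(sprintf("  %d. %s", i, .describeSpec(object@steps[[i]])))
    if (length(object@counts) >= i)
      cat(sprintf("  -> %d remaining", object@counts[i]))
    cat("\n")
  }
})

setMethod("show", "SampleGroup", function(object) {
  cat(sprintf("SampleGroup '%s': %s\n", object@name,
              paste(object@members, collapse = ", ")))
})

setMethod("show", "RangeAnnotation", function(object) {
  cat(sprintf("RangeAnnotation '%s': %d interval(s) on %d chromosome(s)\n",
              object@name, length(object@ranges),
              length(unique(as.character(
                GenomicRanges::seqnames(object@ranges))))))
})

setMethod("show", "MinerSession", function(object) {
  cat(sprintf(
    "MinerSession: %d/%d variants surviving, %d filter(s), %d group(s), %d range annotation(s), %d saved analysis(es)\n",
    length(object@chain@survivors), length(object@dataset@docs),
    length(object@chain@steps), length(object@groups),
    length(object@rangeNames), length(object@saved)))
})

setMethod("show", "TrioSpec", function(object) {
  aff <- function(id) if (isTRUE(object@affected[[id]]))
    "affected" else "unaffected"
  cat(sprintf("TrioSpec: mother=%s (%s), father=%s (%s), child=%s (%s, %s); genes from %s\n",
              object@motherId, aff(object@motherId),
              object@fatherId, aff(object@fatherId),
              object@childId, aff(object@childId), object@childSex,
              object@geneField))
})
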