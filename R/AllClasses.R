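#' @import methods
#' @importFrom stats setNames
NULL

## Central S4 classes. Variant documents themselves are plain named lists
## (heterogeneous, sparse), held inside a VariantDataset; everything that
## carries invariants worth enforcing gets a class with a validity method.

#' VCF header metadata
#'
#' Declared \code{INFO}, \code{FORMAT} and \code{FILTER} fields of a VCF
#' header, plus the ordered sample identifiers.  All record parsing is
#' driven by this object: the declared \code{Type} decides how a value is
#' coerced, the declared \code{Number} decides how multi-allelic records
#' are sliced.
#'
#' @slot info data.frame with columns \code{id}, \code{number}, \code{type},
#'   \code{description} for every \code{##INFO} declaration.
#' @slot format same layout for \code{##FORMAT} declarations.
#' @slot filters character vector of declared \code{##FILTER} codes.
#' @slot samples ordered character vector of sample identifiers from the
#'   \code{#CHROM} line.
#' @exportClass VcfHeader
setClass("VcfHeader",
  representation(
    info = "data.frame",
    format = "data.frame",
    filters = "character",
    samples = "character"
  )
)

setValidity("VcfHeader", function(object) {
  need <- c("id", "number", "type", "description")
  if (!all(need %in% names(object@info)))
    return("info must have columns id, number, type, description")
  if (!all(need %in% names(object@format)))
    return("format must have columns id, number, type, description")
  if (anyDuplicated(object@info$id))
    return("duplicate INFO field id")
  if (anyDuplicated(object@format$id))
    return("duplicate FORMAT field id")
  if (anyDuplicated(object@samples))
    return("duplicate sample id")
  TRUE
})

#' Validation report for a VCF source
#'
#' @slot ok logical; \code{TRUE} iff no issue of severity \code{"error"}.
#' @slot issues data.frame with columns \code{line}, \code{severity},
#'   \code{message}, \code{text} (the offending line, truncated).
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(ok = "logical", issues = "data.frame")
)

setValidity("ValidationReport", function(object) {
  if (!all(c("line", "severity", "message", "text") %in%
           names(object@issues)))
    return("issues must have columns line, severity, message, text")
  hasErr <- any(object@issues$severity == "error")
  if (object@ok == hasErr)
    return("ok must be TRUE exactly when no error-severity issue exists")
  TRUE
})

#' Indexed in-memory variant document collection
#'
#' Holds one parsed variant document per single-allele record (plain named
#' list) under a stable integer id, plus optional per-field indexes and the
#' field catalog used for filter typing.  Stands in for a document
#' database: queries with and without an index are guaranteed to return
#' identical id sets.
#'
#' @slot header a \linkS4class{VcfHeader}.
#' @slot docs list of variant documents, parallel to \code{ids}.
#' @slot ids stable integer document ids (assigned at load, never reused).
#' @slot indexes named list, field path -> index structure.
#' @exportClass VariantDataset
setClass("VariantDataset",
  representation(
    header = "VcfHeader",
    docs = "list",
    ids = "integer",
    indexes = "list"
  )
)

setValidity("VariantDataset", function(object) {
  if (length(object@docs) != length(object@ids))
    return("docs and ids must be parallel")
  if (anyDuplicated(object@ids))
    return("document ids must be unique")
  TRUE
})

#' One typed filter predicate
#'
#' @slot field field path (e.g. \code{"INFO.DP"}, \code{"CORE.QUAL"},
#'   \code{"FORMAT.DP.min"}, \code{"RANGE.exome"}).
#' @slot kind one of \code{"numeric"}, \code{"flag"}, \code{"string"},
#'   \code{"group"}, \code{"range"}.
#' @slot operator numeric: \code{< <= = >= > !=}; flag/range:
#'   \code{is_true}/\code{is_false}; string: \code{in_set}/\code{not_in_set};
#'   group: \code{"matches"}.
#' @slot value numeric scalar, logical, or character set, per kind.
#' @slot missingPolicy \code{"exclude_missing"} (default) or
#'   \code{"include_missing"}: whether documents lacking the field survive.
#' @slot group a \linkS4class{GroupFilter} when \code{kind == "group"},
#'   else \code{NULL}.
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(
    field = "character",
    kind = "character",
    operator = "character",
    value = "ANY",
    missingPolicy = "character",
    group = "ANY"
  )
)

.OP_FAMILY <- list(
  numeric = c("<", "<=", "=", ">=", ">", "!="),
  flag = c("is_true", "is_false"),
  range = c("is_true", "is_false"),
  string = c("in_set", "not_in_set"),
  group = "matches"
)

setValidity("FilterSpec", function(object) {
  if (!object@kind %in% names(.OP_FAMILY))
    return(sprintf("unknown filter kind '%s'", object@kind))
  if (!object@operator %in% .OP_FAMILY[[object@kind]])
    return(sprintf("operator '%s' does not belong to the %s family",
                   object@operator, object@kind))
  if (!object@missingPolicy %in% c("exclude_missing", "include_missing"))
    return("missingPolicy must be exclude_missing or include_missing")
  if (object@kind == "numeric" &&
      (!is.numeric(object@value) || length(object@value) != 1))
    return("numeric filter needs a single numeric value")
  if (object@kind == "string" &&
      (!is.character(object@value) || length(object@value) == 0))
    return("string filter needs a non-empty value set")
  if (object@kind == "group" && !is(object@group, "GroupFilter"))
    return("group filter needs a GroupFilter in slot 'group'")
  TRUE
})

#' An ordered chain of filters with per-step survivor counts
#'
#' Filters are applied consecutively: step i sees only the survivors of
#' step i-1.  After \code{\link{applyChain}} the \code{counts} slot holds
#' the number of surviving variants after each step (the running tabulation
#' a GUI would display next to each filter) and \code{survivors} the final
#' id set.
#'
#' @slot steps list of \linkS4class{FilterSpec}.
#' @slot counts integer, survivor count after each step (empty before
#'   evaluation).
#' @slot initialCount integer, variants before any filtering.
#' @slot survivors integer ids surviving the whole chain.
#' @exportClass FilterChain
setClass("FilterChain",
  representation(
    steps = "list",
    counts = "integer",
    initialCount = "integer",
    survivors = "integer"
  ),
  prototype(counts = integer(0), initialCount = NA_integer_,
            survivors = integer(0))
)

setValidity("FilterChain", function(object) {
  if (!all(vapply(object@steps, is, logical(1), class2 = "FilterSpec")))
    return("all steps must be FilterSpec objects")
  if (length(object@counts)) {
    if (length(object@counts) != length(object@steps))
      return("counts, when populated, must have one entry per step")
    if (is.unsorted(rev(object@counts)))
      return("survivor counts must be monotone non-increasing")
    if (!is.na(object@initialCount) &&
        length(object@counts) && object@counts[1] > object@initialCount)
      return("counts cannot exceed initialCount")
  }
  TRUE
})

#' A named group of samples
#'
#' @slot name unique label within a session.
#' @slot members non-empty character vector of sample ids.
#' @exportClass SampleGroup
setClass("SampleGroup",
  representation(name = "character", members = "character")
)

setValidity("SampleGroup", function(object) {
  if (length(object@name) != 1 || !nzchar(object@name))
    return("group name must be a single non-empty string")
  if (length(object@members) == 0)
    return("group must have at least one member")
  if (anyDuplicated(object@members))
    return("duplicate sample in group")
  TRUE
})

#' A quantified genotype condition over a sample group
#'
#' Encodes the group-filter semantics of case/control mining: a variant
#' passes a \code{require} filter when at least \code{any} / exactly
#' \code{all} / at least \code{ceiling(p * |group|)} group members carry a
#' matching genotype; an \code{exclude} filter is the document-wise
#' negation.  A minimum alternate-read depth (from the AD field) may be
#' required on top of zygosity; a sample without AD fails any depth
#' requirement.
#'
#' @slot group a \linkS4class{SampleGroup}.
#' @slot zygosityReq \code{"either"}, \code{"heterozygous"} or
#'   \code{"homozygous"}.
#' @slot quantifier \code{"any"}, \code{"all"} or \code{"fraction"}.
#' @slot fraction p in (0, 1] when quantifier is \code{"fraction"}.
#' @slot mode \code{"require"} or \code{"exclude"}.
#' @slot minAltDepth non-negative integer, or \code{NA} for no requirement.
#' @exportClass GroupFilter
setClass("GroupFilter",
  representation(
    group = "SampleGroup",
    zygosityReq = "character",
    quantifier = "character",
    fraction = "numeric",
    mode = "character",
    minAltDepth = "integer"
  )
)

setValidity("GroupFilter", function(object) {
  if (!object@zygosityReq %in% c("either", "heterozygous", "homozygous"))
    return("zygosityReq must be either, heterozygous or homozygous")
  if (!object@quantifier %in% c("any", "all", "fraction"))
    return("quantifier must be any, all or fraction")
  if (object@quantifier == "fraction" &&
      (is.na(object@fraction) || object@fraction <= 0 ||
       object@fraction > 1))
    return("fraction must lie in (0, 1]")
  if (!object@mode %in% c("require", "exclude"))
    return("mode must be require or exclude")
  if (!is.na(object@minAltDepth) && object@minAltDepth < 0)
    return("minAltDepth must be non-negative")
  TRUE
})

#' A named set of genomic intervals used as a boolean annotation
#'
#' Intervals are stored 1-based inclusive (as a \code{GRanges}); a variant
#' is labeled \code{TRUE} iff its POS falls inside some interval on its
#' chromosome.  BED input (0-based half-open) and pasted ranges (1-based
#' inclusive) are both converted to this internal convention.
#'
#' @slot name unique annotation label; the derived field is
#'   \code{RANGE.<name>}.
#' @slot ranges a \code{GRanges} of the intervals.
#' @exportClass RangeAnnotation
setClass("RangeAnnotation",
  representation(name = "character", ranges = "ANY")
)

setValidity("RangeAnnotation", function(object) {
  if (length(object@name) != 1 || !nzchar(object@name))
    return("annotation name must be a single non-empty string")
  if (!is(object@ranges, "GRanges"))
    return("ranges must be a GRanges")
  TRUE
})

#' Specification of a sequenced trio
#'
#' @slot motherId,fatherId,childId distinct sample ids.
#' @slot affected named logical, affected status per sample id.
#' @slot childSex \code{"male"}, \code{"female"} or \code{"unknown"}.
#' @slot geneField field path used to group variants by gene for
#'   compound-heterozygote calling (e.g. \code{"INFO.Gene"}).
#' @exportClass TrioSpec
setClass("TrioSpec",
  representation(
    motherId = "character",
    fatherId = "character",
    childId = "character",
    affected = "logical",
    childSex = "character",
    geneField = "character"
  )
)

setValidity("TrioSpec", function(object) {
  ids <- c(object@motherId, object@fatherId, object@childId)
  if (anyDuplicated(ids))
    return("mother, father and child ids must be distinct")
  if (!object@childSex %in% c("male", "female", "unknown"))
    return("childSex must be male, female or unknown")
  if (is.null(names(object@affected)) ||
      !all(ids %in% names(object@affected)))
    return("affected must be a named logical covering all three samples")
  TRUE
})

#' An interactive mining session
#'
#' Bundles a dataset with the current filter chain and survivor set, the
#' defined sample groups, the loaded range annotations and any saved
#' analyses, mirroring an interactive dashboard session as a value object:
#' mutators return the updated session.
#'
#' @slot dataset a \linkS4class{VariantDataset}.
#' @slot chain current \linkS4class{FilterChain} (evaluated).
#' @slot groups named list of \linkS4class{SampleGroup}.
#' @slot rangeNames names of range annotations applied to the dataset.
#' @slot saved named list of saved analyses (each a FilterChain with
#'   counts and survivors).
#' @exportClass MinerSession
setClass("MinerSession",
  representation(
    dataset = "VariantDataset",
    chain = "FilterChain",
    groups = "list",
    rangeNames = "character",
    saved = "list"
  )
)
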