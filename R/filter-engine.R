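## Typed filters applied consecutively, each step reporting its survivor
## count; strategies (chain + groups + range names) persist as versioned
## JSON so an analysis can be replayed on another dataset.

.STRATEGY_VERSION <- "1.0"

## Relative tolerance for numeric equality: values arrive via text
## parsing, so exact float comparison would be brittle.
.NUM_EQ_TOL <- 1e-9

#' Construct a typed filter
#'
#' The filter kind is implied by the operator: relational operators make
#' a numeric filter, \code{is_true}/\code{is_false} a flag filter (used
#' both for INFO flags and \code{RANGE.*} annotations), and
#' \code{in_set}/\code{not_in_set} a string filter.  Use
#' \code{\link{groupFilterSpec}} to wrap a quantified group condition.
#'
#' @param field field path (see \code{\link{catalogFields}}).
#' @param operator one of \code{< <= = >= > !=}, \code{is_true},
#'   \code{is_false}, \code{in_set}, \code{not_in_set}.
#' @param value numeric scalar for relational operators, character set
#'   for the set operators, ignored for flag operators.
#' @param missingPolicy \code{"exclude_missing"} (default): documents
#'   lacking the field are dropped; \code{"include_missing"}: they
#'   survive.  Flags are never missing — an absent flag is \code{FALSE}.
#' @return a \linkS4class{FilterSpec}.
#' @examples
#' filterSpec("INFO.DP", ">=", 10)
#' filterSpec("INFO.IMPACT", "in_set", "HIGH")
#' filterSpec("INFO.SOMATIC", "is_true")
#' @export
filterSpec <- function(field, operator, value = NULL,
                       missingPolicy = c("exclude_missing",
                                         "include_missing")) {
  missingPolicy <- match.arg(missingPolicy)
  kind <- if (operator %in% .OP_FAMILY$numeric) "numeric"
    else if (operator %in% .OP_FAMILY$flag)
      (if (startsWith(field, "RANGE.")) "range" else "flag")
    else if (operator %in% .OP_FAMILY$string) "string"
    else stop(sprintf("unknown operator '%s'", operator))
  if (kind == "numeric") value <- as.numeric(value)
  if (kind == "string") value <- as.character(value)
  if (kind %in% c("flag", "range")) value <- (operator == "is_true")
  new("FilterSpec", field = field, kind = kind, operator = operator,
      value = value, missingPolicy = missingPolicy, group = NULL)
}

.numMatches <- function(v, op, target) {
  hit <- switch(op,
    "<" = v < target,
    "<=" = v <= target,
    ">=" = v >= target,
    ">" = v > target,
    "=" = abs(v - target) <= .NUM_EQ_TOL * pmax(1, abs(target)),
    "!=" = abs(v - target) > .NUM_EQ_TOL * pmax(1, abs(target)))
  any(hit, na.rm = TRUE)
}

## Evaluate one non-group filter on one document.
.docMatches <- function(doc, spec) {
  if (spec@kind == "group")
    return(evaluateGroupFilter(doc, spec@group))
  v <- fieldValue(doc, spec@field)
  if (spec@kind %in% c("flag", "range")) {
    set <- isTRUE(v) || (is.logical(v) && length(v) == 1 && !is.na(v) && v)
    return(if (spec@operator == "is_true") set else !set)
  }
  if (is.null(v) || all(is.na(v)))
    return(spec@missingPolicy == "include_missing")
  if (spec@kind == "numeric") {
    if (!is.numeric(v)) stop(sprintf(
      "field '%s' holds non-numeric values; numeric operator '%s' does not apply",
      spec@field, spec@operator))
    return(.numMatches(v, spec@operator, spec@value))
  }
  v <- as.character(v)
  inSet <- any(v %in% spec@value)
  if (spec@operator == "in_set") inSet else !inSet
}

.kindCompatible <- function(specKind, catalogKind) {
  specKind == catalogKind ||
    (specKind == "range" && catalogKind == "flag") ||
    (specKind == "flag" && catalogKind == "range")
}

#' Apply one filter and return the surviving document ids
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @param spec a \linkS4class{FilterSpec}.
#' @param within integer ids to evaluate (defaults to all documents);
#'   only these can survive.
#' @return sorted integer vector of surviving ids.
#' @export
applyFilter <- function(ds, spec, within = variantIds(ds)) {
  validObject(spec)
  if (spec@kind != "group") {
    cat <- .catalogSkeleton(ds)
    row <- match(spec@field, cat$field)
    if (is.na(row))
      stop(sprintf("unknown field '%s'", spec@field))
    if (!.kindCompatible(spec@kind, cat$kind[row]))
      stop(sprintf("field '%s' is %s; a %s filter does not apply",
                   spec@field, cat$kind[row], spec@kind))
  } else {
    missing <- setdiff(spec@group@group@members, ds@header@samples)
    if (length(missing))
      stop(sprintf("group '%s' references sample '%s' absent from the dataset",
                   spec@group@group@name, missing[1]))
  }
  idx <- if (spec@kind != "group") ds@indexes[[spec@field]] else NULL
  pos <- match(within, ds@ids)
  if (anyNA(pos)) stop("'within' contains unknown document ids")
  if (is.null(idx)) {
    keep <- vapply(ds@docs[pos], .docMatches, logical(1), spec = spec)
  } else {
    ## indexed path: evaluate against the precomputed value column
    keep <- vapply(pos, function(p) {
      if (!idx$present[p]) {
        if (spec@kind %in% c("flag", "range"))
          return(spec@operator == "is_false")
        return(spec@missingPolicy == "include_missing")
      }
      v <- idx$column[[p]]
      if (spec@kind %in% c("flag", "range")) {
        set <- isTRUE(v)
        return(if (spec@operator == "is_true") set else !set)
      }
      if (all(is.na(v)))
        return(spec@missingPolicy == "include_missing")
      if (spec@kind == "numeric")
        return(.numMatches(v, spec@operator, spec@value))
      inSet <- any(as.character(v) %in% spec@value)
      if (spec@operator == "in_set") inSet else !inSet
    }, logical(1))
  }
  sort(within[keep])
}

#' Build a filter chain
#' @param ... \linkS4class{FilterSpec} objects (or a single list of them).
#' @return an unevaluated \linkS4class{FilterChain}.
#' @export
filterChain <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.list(steps[[1]]) &&
      !is(steps[[1]], "FilterSpec"))
    steps <- steps[[1]]
  new("FilterChain", steps = steps)
}

#' Apply a filter chain consecutively, recording per-step survivor counts
#'
#' Step i is evaluated only on the survivors of step i-1, and the number
#' of remaining variants is recorded after each step — the running
#' tabulation displayed next to each filter in an interactive session.
#' Because filters compose conjunctively, the final set is
#' order-invariant even though the intermediate counts are not.
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @param chain a \linkS4class{FilterChain}.
#' @param within starting id set (defaults to all documents).
#' @return the chain with \code{stepCounts()} and \code{survivors()}
#'   populated.
#' @export
applyChain <- function(ds, chain, within = variantIds(ds)) {
  current <- sort(within)
  counts <- integer(length(chain@steps))
  for (i in seq_along(chain@steps)) {
    current <- applyFilter(ds, chain@steps[[i]], within = current)
    counts[i] <- length(current)
  }
  initialize(chain, counts = counts,
             initialCount = length(within), survivors = current)
}

## --- strategy persistence -------------------------------------------

.specToList <- function(spec) {
  out <- list(field = spec@field, kind = spec@kind,
              operator = spec@operator,
              missingPolicy = spec@missingPolicy)
  if (spec@kind == "group") {
    gf <- spec@group
    out$group <- list(
      name = gf@group@name, members = as.list(gf@group@members),
      zygosityReq = gf@zygosityReq, quantifier = gf@quantifier,
      fraction = if (gf@quantifier == "fraction") gf@fraction else NULL,
      mode = gf@mode,
      minAltDepth = if (is.na(gf@minAltDepth)) NULL else
        gf@minAltDepth)
  } else {
    out$value <- spec@value
  }
  out
}

.specFromList <- function(x) {
  if (x$kind == "group") {
    g <- x$group
    gf <- groupFilter(
      sampleGroup(g$name, unlist(g$members)),
      zygosity = g$zygosityReq,
      quantifier = g$quantifier,
      fraction = if (is.null(g$fraction)) NA_real_ else g$fraction,
      mode = g$mode,
      minAltDepth = if (is.null(g$minAltDepth)) NA_integer_ else
        as.integer(g$minAltDepth))
    return(groupFilterSpec(gf))
  }
  value <- switch(x$kind,
    numeric = as.numeric(x$value),
    string = as.character(unlist(x$value)),
    as.logical(x$value))
  new("FilterSpec", field = x$field, kind = x$kind,
      operator = x$operator, value = value,
      missingPolicy = x$missingPolicy, group = NULL)
}

#' Save a filtering strategy as versioned JSON
#'
#' A strategy is the reusable part of an analysis: the filter chain, the
#' sample-group definitions it references and the names of the range
#' annotations it expects.  Counts and survivors are deliberately not
#' saved — a strategy is re-evaluated on whatever dataset it is applied
#' to.
#'
#' @param chain a \linkS4class{FilterChain}.
#' @param groups named list of \linkS4class{SampleGroup} (those the
#'   chain's group filters reference are added automatically).
#' @param rangeNames names of range annotations the chain relies on.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveStrategy <- function(chain, groups = list(),
                         rangeNames = character(0), path) {
  for (spec in chain@steps)
    if (spec@kind == "group") {
      g <- spec@group@group
      if (is.null(groups[[g@name]])) groups[[g@name]] <- g
    }
  payload <- list(
    format = "variantsieve-strategy",
    version = .STRATEGY_VERSION,
    steps = lapply(chain@steps, .specToList),
    groups = lapply(unname(groups), function(g)
      list(name = g@name, members = as.list(g@members))),
    rangeNames = as.list(rangeNames)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Load a filtering strategy, optionally resolving it against a dataset
#'
#' When \code{dataset} is given, every field the chain references must
#' exist in its catalog, every group member among its samples and every
#' range-annotation name among its applied annotations; a violation is a
#' named error, never a silent drop — strategies are portable but not
#' lossy.
#'
#' @param path strategy JSON path.
#' @param dataset optional \linkS4class{VariantDataset} to validate
#'   against.
#' @return list with elements \code{chain} (\linkS4class{FilterChain}),
#'   \code{groups} (named list of \linkS4class{SampleGroup}) and
#'   \code{rangeNames}.
#' @export
loadStrategy <- function(path, dataset = NULL) {
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "variantsieve-strategy"))
    stop(sprintf("'%s' is not a strategy file", path))
  if (!identical(x$version, .STRATEGY_VERSION))
    stop(sprintf("strategy version '%s' not supported (expected %s)",
                 x$version, .STRATEGY_VERSION))
  steps <- lapply(x$steps, .specFromList)
  groups <- list()
  for (g in x$groups)
    groups[[g$name]] <- sampleGroup(g$name, unlist(g$members))
  rangeNames <- as.character(unlist(x$rangeNames))
  out <- list(chain = filterChain(steps), groups = groups,
              rangeNames = rangeNames)
  if (!is.null(dataset)) {
    known <- .knownFields(dataset)
    for (spec in steps) {
      if (spec@kind == "group") {
        absent <- setdiff(spec@group@group@members,
                          dataset@header@samples)
        if (length(absent))
          stop(sprintf(
            "strategy group '%s' references sample '%s' absent from the dataset",
            spec@group@group@name, absent[1]))
      } else if (!spec@field %in% known) {
        stop(sprintf("strategy references field '%s' absent from the dataset",
                     spec@field))
      }
    }
    for (g in groups) {
      absent <- setdiff(g@members, dataset@header@samples)
      if (length(absent))
        stop(sprintf("strategy group '%s' references sample '%s' absent from the dataset",
                     g@name, absent[1]))
    }
    for (rn in rangeNames)
      if (!paste0("RANGE.", rn) %in% known)
        stop(sprintf("strategy expects range annotation '%s' which is not applied",
                     rn))
  }
  out
}
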