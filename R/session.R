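## A mining session: dataset + current chain + groups + range
## annotations + saved analyses, as an immutable value object.  This is
## the batch equivalent of an interactive dashboard: add filters one at
## a time and watch the survivor count drop, save the analysis, clear,
## and start a new line of inquiry without losing the old one.

#' Start a mining session on a dataset
#' @param ds a \linkS4class{VariantDataset}.
#' @return a \linkS4class{MinerSession} with an empty chain and the full
#'   survivor set.
#' @export
minerSession <- function(ds) {
  new("MinerSession", dataset = ds,
      chain = applyChain(ds, filterChain()),
      groups = list(), rangeNames = character(0), saved = list())
}

#' Register a sample group in a session
#' @param session a \linkS4class{MinerSession}.
#' @param group a \linkS4class{SampleGroup}; its name must be unused and
#'   its members must exist in the dataset.
#' @return the updated session.
#' @export
addGroup <- function(session, group) {
  if (group@name %in% names(session@groups))
    stop(sprintf("a group named '%s' already exists", group@name))
  absent <- setdiff(group@members, session@dataset@header@samples)
  if (length(absent))
    stop(sprintf("group '%s' references sample '%s' absent from the dataset",
                 group@name, absent[1]))
  session@groups[[group@name]] <- group
  session
}

#' Apply a range annotation within a session
#'
#' Annotation names must be distinct across the session: loading two
#' different interval sets under one name is an error (re-annotating is
#' only possible through a fresh session).
#'
#' @param session a \linkS4class{MinerSession}.
#' @param ra a \linkS4class{RangeAnnotation}.
#' @param normalizeChr see \code{\link{annotateRanges}}.
#' @return the updated session; the field \code{RANGE.<name>} becomes
#'   filterable.
#' @export
addRangeAnnotation <- function(session, ra, normalizeChr = FALSE) {
  if (ra@name %in% session@rangeNames)
    stop(sprintf("a range annotation named '%s' is already loaded; give each a distinct name",
                 ra@name))
  session@dataset <- annotateRanges(session@dataset, ra, normalizeChr)
  session@rangeNames <- c(session@rangeNames, ra@name)
  ## the current chain's survivors are unaffected by adding a field
  session
}

#' Append a filter to the session's chain and re-evaluate incrementally
#' @param session a \linkS4class{MinerSession}.
#' @param spec a \linkS4class{FilterSpec}.
#' @return the updated session; \code{stepCounts(session@chain)} gains
#'   one entry.
#' @export
addFilter <- function(session, spec) {
  surv <- applyFilter(session@dataset, spec,
                      within = survivors(session@chain))
  session@chain <- initialize(session@chain,
    steps = c(session@chain@steps, spec),
    counts = c(session@chain@counts, length(surv)),
    survivors = surv)
  session
}

#' Clear all filters, restoring the full survivor set
#'
#' Saved analyses are unaffected: clear-and-refilter is how one explores
#' an alternative hypothesis without losing the current one.
#'
#' @param session a \linkS4class{MinerSession}.
#' @return the session with an empty chain.
#' @export
clearFilters <- function(session) {
  session@chain <- applyChain(session@dataset, filterChain())
  session
}

#' Save the current analysis (chain, counts, survivors) under a name
#' @param session a \linkS4class{MinerSession}.
#' @param name analysis label.
#' @return the updated session.
#' @export
saveAnalysis <- function(session, name) {
  session@saved[[name]] <- session@chain
  session
}

#' Retrieve a saved analysis
#' @param session a \linkS4class{MinerSession}.
#' @param name analysis label.
#' @return the saved (evaluated) \linkS4class{FilterChain}.
#' @export
getAnalysis <- function(session, name) {
  if (is.null(session@saved[[name]]))
    stop(sprintf("no saved analysis named '%s'", name))
  session@saved[[name]]
}
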