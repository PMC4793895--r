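## Sample groups and quantified genotype filters over them: the engine
## behind case/control contrasts ("present in cases, absent from
## controls") and family designs ("heterozygous in both parents,
## homozygous in the child").

#' Define a named sample group
#' @param name unique label.
#' @param members character vector of sample ids (non-empty).
#' @return a \linkS4class{SampleGroup}.  Groups may overlap: a sample can
#'   belong to any number of groups.
#' @export
sampleGroup <- function(name, members) {
  new("SampleGroup", name = name, members = as.character(members))
}

#' Define a quantified genotype condition over a group
#'
#' @param group a \linkS4class{SampleGroup}.
#' @param zygosity \code{"either"} (any alternate-carrying genotype),
#'   \code{"heterozygous"} or \code{"homozygous"}.
#' @param quantifier \code{"any"} (at least one member matches),
#'   \code{"all"}, or \code{"fraction"} with \code{fraction} = p: at
#'   least \code{ceiling(p * group size)} members match.  Uncalled
#'   samples count in the denominator and never match.
#' @param fraction p in (0, 1]; only with \code{quantifier="fraction"}.
#' @param mode \code{"require"} keeps variants satisfying the condition;
#'   \code{"exclude"} keeps exactly the others (document-wise negation).
#' @param minAltDepth minimum alternate-read depth (AD field) each
#'   matching sample must additionally show; samples without AD fail any
#'   depth requirement.  \code{NA} (default) for no requirement.
#' @return a \linkS4class{GroupFilter}.
#' @examples
#' cases <- sampleGroup("cases", c("S1", "S2", "S3"))
#' groupFilter(cases, zygosity = "homozygous", quantifier = "all")
#' @export
groupFilter <- function(group,
                        zygosity = c("either", "heterozygous",
                                     "homozygous"),
                        quantifier = c("any", "all", "fraction"),
                        fraction = NA_real_,
                        mode = c("require", "exclude"),
                        minAltDepth = NA_integer_) {
  new("GroupFilter", group = group,
      zygosityReq = match.arg(zygosity),
      quantifier = match.arg(quantifier),
      fraction = as.numeric(fraction),
      mode = match.arg(mode),
      minAltDepth = as.integer(minAltDepth))
}

#' Does one sample's call match a zygosity and depth requirement?
#'
#' @param call a sample call (element of a document's \code{calls}).
#' @param zygosity \code{"either"}, \code{"heterozygous"} or
#'   \code{"homozygous"}.
#' @param minAltDepth minimum alternate-read depth, or \code{NA}.
#' @return \code{TRUE} iff the call carries a matching genotype and
#'   satisfies the depth requirement.  No-call and reference calls never
#'   match; a call without AD fails any depth requirement.
#' @export
sampleMatches <- function(call, zygosity = "either",
                          minAltDepth = NA_integer_) {
  if (is.null(call)) return(FALSE)
  zygOk <- switch(zygosity,
    either = call$altAlleleCount >= 1L,
    heterozygous = identical(call$zygosity, "HETEROZYGOUS"),
    homozygous = identical(call$zygosity, "HOMOZYGOUS"),
    stop(sprintf("unknown zygosity requirement '%s'", zygosity)))
  if (!zygOk) return(FALSE)
  if (is.na(minAltDepth)) return(TRUE)
  !is.na(call$altDepth) && call$altDepth >= minAltDepth
}

#' Evaluate a group filter on one variant document
#'
#' Counts the group members whose call matches
#' (\code{\link{sampleMatches}}) and applies the quantifier: \code{any}
#' needs m >= 1, \code{all} needs m = group size, \code{fraction} p
#' needs m >= \code{ceiling(p * group size)}.  \code{mode = "exclude"}
#' returns the negation.
#'
#' @param doc a variant document.
#' @param gf a \linkS4class{GroupFilter}.
#' @return logical.
#' @export
evaluateGroupFilter <- function(doc, gf) {
  members <- gf@group@members
  m <- sum(vapply(members, function(sid) {
    if (!sid %in% names(doc$calls) && length(doc$calls))
      stop(sprintf("group '%s' member '%s' has no call in this dataset",
                   gf@group@name, sid))
    sampleMatches(doc$calls[[sid]], gf@zygosityReq, gf@minAltDepth)
  }, logical(1)))
  need <- switch(gf@quantifier,
    any = 1L,
    all = length(members),
    fraction = as.integer(ceiling(gf@fraction * length(members))))
  hit <- m >= need
  if (gf@mode == "require") hit else !hit
}

#' Wrap a group filter as a FilterSpec for use in chains
#' @param gf a \linkS4class{GroupFilter}.
#' @return a \linkS4class{FilterSpec} of kind \code{"group"};
#'   \code{\link{applyFilter}} and \code{\link{applyChain}} treat it like
#'   any other filter.
#' @export
groupFilterSpec <- function(gf) {
  new("FilterSpec", field = paste0("GROUP.", gf@group@name),
      kind = "group", operator = "matches", value = NULL,
      missingPolicy = "exclude_missing", group = gf)
}
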