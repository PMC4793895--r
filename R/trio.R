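## Trio annotations: an InheritancePattern label set and a CompoundHet
## flag are computed from the three genotypes and injected as declared
## INFO fields, so the filter engine (and export) can consume them
## exactly like annotations that arrived in the file.
##
## The label rules are a documented reconstruction of the standard
## definitions and can be overridden per label via the `rules` argument:
##   AR           autosome; child homozygous, both parents heterozygous.
##   deNovo       child carries >= 1 alternate, both parents are called
##                reference.
##   NonMendelian all three called and the child's alternate-allele
##                count is impossible given what each parent could
##                transmit (reference -> 0, heterozygous -> 0 or 1,
##                homozygous -> 1); the deNovo pattern is carved out.
##   XLD          X chromosome; affected child carries the variant and
##                exactly one parent carries it, that parent affected.
## Y and MT variants receive no label.  On X, a hemizygous male call
## ("1") counts as carrying; XLD uses carrier status, not zygosity.

#' Specify a sequenced trio
#'
#' @param motherId,fatherId,childId distinct sample ids present in the
#'   dataset the spec is used with.
#' @param affected named logical vector of affected status; defaults to
#'   an affected child with unaffected parents.
#' @param childSex \code{"male"}, \code{"female"} or \code{"unknown"}.
#' @param geneField field path used to group variants into genes for
#'   compound-heterozygote calling.
#' @return a \linkS4class{TrioSpec}.
#' @export
trioSpec <- function(motherId, fatherId, childId,
                     affected = NULL,
                     childSex = c("unknown", "male", "female"),
                     geneField = "INFO.Gene") {
  childSex <- match.arg(childSex)
  if (is.null(affected))
    affected <- stats::setNames(c(FALSE, FALSE, TRUE),
                                c(motherId, fatherId, childId))
  new("TrioSpec", motherId = motherId, fatherId = fatherId,
      childId = childId, affected = affected, childSex = childSex,
      geneField = geneField)
}

## Classify a chromosome name as autosome / X / Y / MT / other.
.chromClass <- function(chrom) {
  c <- toupper(sub("^CHR", "", toupper(chrom)))
  if (c %in% as.character(1:22)) "autosome"
  else if (c == "X") "X"
  else if (c %in% c("Y")) "Y"
  else if (c %in% c("MT", "M")) "MT"
  else "other"
}

.checkTrio <- function(ds, trio) {
  ids <- c(trio@motherId, trio@fatherId, trio@childId)
  absent <- setdiff(ids, ds@header@samples)
  if (length(absent))
    stop(sprintf("trio sample '%s' is absent from the dataset",
                 absent[1]))
  invisible(ids)
}

## Alternate-allele counts a diploid parent call can transmit.
.transmissible <- function(call) {
  switch(call$zygosity,
    REFERENCE = 0L,
    HETEROZYGOUS = c(0L, 1L),
    HOMOZYGOUS = 1L,
    integer(0))   # NO_CALL: nothing known
}

.defaultInheritanceRules <- function() {
  list(
    AR = function(chromClass, mo, fa, ch, affected, trio) {
      chromClass == "autosome" &&
        identical(ch$zygosity, "HOMOZYGOUS") &&
        identical(mo$zygosity, "HETEROZYGOUS") &&
        identical(fa$zygosity, "HETEROZYGOUS")
    },
    deNovo = function(chromClass, mo, fa, ch, affected, trio) {
      chromClass %in% c("autosome", "X") &&
        ch$altAlleleCount >= 1L &&
        identical(mo$zygosity, "REFERENCE") &&
        identical(fa$zygosity, "REFERENCE")
    },
    NonMendelian = function(chromClass, mo, fa, ch, affected, trio) {
      if (chromClass != "autosome") return(FALSE)
      if (any(c(mo$zygosity, fa$zygosity, ch$zygosity) == "NO_CALL"))
        return(FALSE)
      ## the de novo pattern gets its own label
      if (ch$altAlleleCount >= 1L &&
          identical(mo$zygosity, "REFERENCE") &&
          identical(fa$zygosity, "REFERENCE")) return(FALSE)
      ## diploid transmission check only
      gtTokens <- strsplit(ch$gt, "[/|]")[[1]]
      if (length(gtTokens) != 2) return(FALSE)
      possible <- unique(outer(.transmissible(mo), .transmissible(fa),
                               "+"))
      length(possible) > 0 && !(ch$altAlleleCount %in% possible)
    },
    XLD = function(chromClass, mo, fa, ch, affected, trio) {
      if (chromClass != "X") return(FALSE)
      if (!isTRUE(affected[[trio@childId]])) return(FALSE)
      if (ch$altAlleleCount < 1L) return(FALSE)
      moCarries <- mo$altAlleleCount >= 1L
      faCarries <- fa$altAlleleCount >= 1L
      if (moCarries == faCarries) return(FALSE)
      carrier <- if (moCarries) trio@motherId else trio@fatherId
      isTRUE(affected[[carrier]])
    }
  )
}

.declareInfoField <- function(header, id, number, type, description) {
  if (!id %in% header@info$id)
    header@info <- rbind(header@info, data.frame(
      id = id, number = number, type = type,
      description = description, stringsAsFactors = FALSE))
  header
}

#' Annotate a dataset with trio inheritance-pattern labels
#'
#' Adds the string INFO field \code{InheritancePattern} carrying zero or
#' more of the labels \code{AR}, \code{deNovo}, \code{NonMendelian} and
#' \code{XLD} (see the rule table in the package vignette; the field is
#' absent when no label applies, so a single string filter
#' \code{InheritancePattern in_set \{AR, deNovo, NonMendelian, XLD\}}
#' keeps exactly the variants matching some interesting inheritance
#' mode).
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @param trio a \linkS4class{TrioSpec}.
#' @param rules optional named list overriding individual label rules;
#'   each rule is \code{function(chromClass, mo, fa, ch, affected,
#'   trio)} returning logical.
#' @return the annotated dataset (the field is declared in the header
#'   and filterable like any INFO field).
#' @export
annotateInheritance <- function(ds, trio, rules = list()) {
  .checkTrio(ds, trio)
  ruleTable <- utils::modifyList(.defaultInheritanceRules(), rules)
  for (i in seq_along(ds@docs)) {
    doc <- ds@docs[[i]]
    mo <- doc$calls[[trio@motherId]]
    fa <- doc$calls[[trio@fatherId]]
    ch <- doc$calls[[trio@childId]]
    cc <- .chromClass(doc$chrom)
    labels <- names(ruleTable)[vapply(ruleTable, function(rule)
      isTRUE(rule(cc, mo, fa, ch, trio@affected, trio)), logical(1))]
    if (length(labels))
      ds@docs[[i]]$info[["InheritancePattern"]] <- labels
    else
      ds@docs[[i]]$info[["InheritancePattern"]] <- NULL
  }
  ds@header <- .declareInfoField(ds@header, "InheritancePattern", ".",
    "String", "Trio inheritance-pattern labels (AR, deNovo, NonMendelian, XLD)")
  ds@indexes[["INFO.InheritancePattern"]] <- NULL
  ds
}

## Which single parent transmitted a child-heterozygous variant?
## "mother" / "father" when exactly that parent carries the alternate
## and the other is a called non-carrier; NA otherwise.
.transmittingParent <- function(doc, trio) {
  mo <- doc$calls[[trio@motherId]]
  fa <- doc$calls[[trio@fatherId]]
  if (is.null(mo) || is.null(fa)) return(NA_character_)
  moC <- mo$altAlleleCount >= 1L
  faC <- fa$altAlleleCount >= 1L
  if (moC && !faC && fa$zygosity != "NO_CALL") "mother"
  else if (faC && !moC && mo$zygosity != "NO_CALL") "father"
  else NA_character_
}

## Haplotype index (1 or 2) carrying the alternate allele of a phased
## diploid child genotype like "0|1"; NA when unphased or ambiguous.
.altHaplotype <- function(gt) {
  if (is.na(gt) || grepl("/", gt, fixed = TRUE) ||
      !grepl("|", gt, fixed = TRUE)) return(NA_integer_)
  tokens <- strsplit(gt, "|", fixed = TRUE)[[1]]
  alt <- which(tokens != "0" & tokens != ".")
  if (length(alt) == 1) alt else NA_integer_
}

#' Annotate compound-heterozygote candidates in a trio
#'
#' Flags (INFO flag \code{CompoundHet}) every child-heterozygous variant
#' V in gene G that is transmitted from exactly one parent while some
#' other child-heterozygous variant W in G is transmitted from exactly
#' the other parent — the classic one-from-each-parent pattern.
#' "Transmitted from parent P" requires P to carry the alternate and the
#' other parent to be a called non-carrier.  When the child genotypes of
#' both variants are phased, the two alternates must additionally lie on
#' opposite haplotypes (phase confirms, rather than assumes, biparental
#' origin).  Documents lacking the gene field are skipped.
#'
#' @param ds a \linkS4class{VariantDataset}.
#' @param trio a \linkS4class{TrioSpec} (its \code{geneField} defines the
#'   gene grouping).
#' @return the annotated dataset.
#' @export
annotateCompoundHet <- function(ds, trio) {
  .checkTrio(ds, trio)
  n <- length(ds@docs)
  gene <- character(n); origin <- character(n); hap <- integer(n)
  childHet <- logical(n)
  for (i in seq_len(n)) {
    doc <- ds@docs[[i]]
    g <- fieldValue(doc, trio@geneField)
    gene[i] <- if (is.null(g)) NA_character_ else as.character(g[1])
    ch <- doc$calls[[trio@childId]]
    childHet[i] <- !is.null(ch) &&
      identical(ch$zygosity, "HETEROZYGOUS")
    origin[i] <- if (childHet[i]) .transmittingParent(doc, trio) else
      NA_character_
    hap[i] <- if (childHet[i]) .altHaplotype(ch$gt) else NA_integer_
  }
  flag <- logical(n)
  cand <- which(childHet & !is.na(gene) & !is.na(origin))
  for (g in unique(gene[cand])) {
    members <- cand[gene[cand] == g]
    for (v in members) {
      partners <- members[origin[members] != origin[v]]
      if (!length(partners)) next
      ## phase check only when both child genotypes are phased
      ok <- vapply(partners, function(w) {
        if (!is.na(hap[v]) && !is.na(hap[w])) hap[v] != hap[w] else TRUE
      }, logical(1))
      flag[v] <- any(ok)
    }
  }
  for (i in which(flag))
    ds@docs[[i]]$info[["CompoundHet"]] <- TRUE
  for (i in which(!flag))
    ds@docs[[i]]$info[["CompoundHet"]] <- NULL
  ds@header <- .declareInfoField(ds@header, "CompoundHet", "0", "Flag",
    "Child-heterozygous variant with a compound-heterozygous partner in the same gene")
  ds@indexes[["INFO.CompoundHet"]] <- NULL
  ds
}
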