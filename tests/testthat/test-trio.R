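trioHeaderLines <- function() minimalHeader(c("MOTHER", "FATHER",
                                              "CHILD"),
  '##INFO=<ID=Gene,Number=1,Type=String,Description="Gene">')

trioRecord <- function(chrom, pos, mo, fa, ch, gene = "G1") {
  paste(chrom, pos, ".", "A", "T", 50, "PASS",
        sprintf("DP=40;Gene=%s", gene), "GT:AD:DP",
        sprintf("%s:10,10:20", mo), sprintf("%s:10,10:20", fa),
        sprintf("%s:10,10:20", ch), sep = "\t")
}

trioDs <- function(records) loadVcfLines(c(trioHeaderLines(), records))

defaultTrio <- trioSpec("MOTHER", "FATHER", "CHILD",
  affected = c(MOTHER = TRUE, FATHER = FALSE, CHILD = TRUE))

patternOf <- function(ds, i = 1) {
  v <- docs(ds)[[i]]$info$InheritancePattern
  if (is.null(v)) "" else paste(sort(v), collapse = ",")
}

test_that("autosomal labels match the exhaustive diploid truth table", {
  gts <- c(REF = "0/0", HET = "0/1", HOM = "1/1")
  ## hand-derived: what each parent can transmit is REF->{0},
  ## HET->{0,1}, HOM->{1}; deNovo is carved out of NonMendelian
  expected <- function(mo, fa, ch) {
    if (ch == "REF")
      return(if (mo == "HOM" || fa == "HOM") "NonMendelian" else "")
    if (ch == "HET") {
      if (mo == "REF" && fa == "REF") return("deNovo")
      if (mo == "HOM" && fa == "HOM") return("NonMendelian")
      return("")
    }
    ## ch HOM
    if (mo == "HET" && fa == "HET") return("AR")
    if (mo == "REF" && fa == "REF") return("deNovo")
    if (mo == "REF" || fa == "REF") return("NonMendelian")
    ""
  }
  grid <- expand.grid(mo = names(gts), fa = names(gts),
                      ch = names(gts), stringsAsFactors = FALSE)
  records <- vapply(seq_len(nrow(grid)), function(r)
    trioRecord("chr1", r * 100, gts[[grid$mo[r]]], gts[[grid$fa[r]]],
               gts[[grid$ch[r]]], gene = sprintf("G%d", r)),
    character(1))
  ds <- annotateInheritance(trioDs(records), defaultTrio)
  for (r in seq_len(nrow(grid)))
    expect_identical(patternOf(ds, r),
                     expected(grid$mo[r], grid$fa[r], grid$ch[r]),
                     info = paste(grid[r, ], collapse = "/"))
  ## mutual exclusions over the whole table
  for (d in docs(ds)) {
    lab <- d$info$InheritancePattern
    expect_false(all(c("AR", "deNovo") %in% lab))
    expect_false("NonMendelian" %in% lab &&
                   any(c("AR", "deNovo") %in% lab))
  }
})

test_that("the worked inheritance examples annotate as expected", {
  ds <- annotateInheritance(trioDs(c(
    trioRecord("chr2", 100, "0/1", "0/1", "1/1"),
    trioRecord("chr2", 200, "0/0", "0/0", "0/1"),
    trioRecord("chr2", 300, "0/0", "0/1", "1/1"),
    trioRecord("chr2", 400, "0/1", "0/0", "./."),  # child uncalled
    trioRecord("chrM", 500, "0/0", "0/0", "0/1"))),  # MT: no label
    defaultTrio)
  expect_identical(patternOf(ds, 1), "AR")
  expect_identical(patternOf(ds, 2), "deNovo")
  expect_identical(patternOf(ds, 3), "NonMendelian")
  expect_identical(patternOf(ds, 4), "")
  expect_identical(patternOf(ds, 5), "")
  ## the field is declared, so it is filterable downstream
  surv <- applyFilter(ds, filterSpec("INFO.InheritancePattern",
    "in_set", c("AR", "deNovo", "NonMendelian", "XLD")))
  expect_identical(surv, c(1L, 2L, 3L))
})

test_that("X-linked dominant needs carrier status matching affection", {
  recs <- c(
    trioRecord("chrX", 100, "0/1", "0/0", "0/1"),  # affected mother carries
    trioRecord("chrX", 200, "0/0", "0/1", "0/1"),  # unaffected father carries
    trioRecord("chrX", 300, "0/1", "0/1", "0/1"),  # both carry
    trioRecord("chrX", 400, "0/1", "0/0", "0/0"))  # child not a carrier
  ds <- annotateInheritance(trioDs(recs), defaultTrio)
  expect_identical(patternOf(ds, 1), "XLD")
  expect_identical(patternOf(ds, 2), "")
  expect_identical(patternOf(ds, 3), "")
  expect_identical(patternOf(ds, 4), "")

  ## hemizygous male child: single-allele GT counts as carrying
  dsM <- annotateInheritance(trioDs(
    trioRecord("chrX", 100, "0/1", "0", "1")), defaultTrio)
  expect_identical(patternOf(dsM, 1), "XLD")
})

test_that("label rules can be overridden through the rule table", {
  ds <- trioDs(trioRecord("chr1", 100, "0/1", "0/1", "1/1"))
  strictAR <- list(AR = function(chromClass, mo, fa, ch, affected,
                                 trio) FALSE)
  dsOver <- annotateInheritance(ds, defaultTrio, rules = strictAR)
  expect_identical(patternOf(dsOver, 1), "")
  expect_error(annotateInheritance(ds,
    trioSpec("NOPE", "FATHER", "CHILD")), "NOPE")
})

test_that("compound heterozygotes need one variant from each parent", {
  v1 <- trioRecord("chr3", 100, "0/1", "0/0", "0/1", gene = "GENEA")
  v2 <- trioRecord("chr3", 200, "0/0", "0/1", "0/1", gene = "GENEA")
  ds <- annotateCompoundHet(trioDs(c(v1, v2)), defaultTrio)
  expect_true(docs(ds)[[1]]$info$CompoundHet)
  expect_true(docs(ds)[[2]]$info$CompoundHet)

  ## a lone qualifying variant is not flagged
  dsLone <- annotateCompoundHet(trioDs(v1), defaultTrio)
  expect_null(docs(dsLone)[[1]]$info$CompoundHet)

  ## same parent twice: no biparental pair
  v2m <- trioRecord("chr3", 200, "0/1", "0/0", "0/1", gene = "GENEA")
  dsSame <- annotateCompoundHet(trioDs(c(v1, v2m)), defaultTrio)
  expect_null(docs(dsSame)[[1]]$info$CompoundHet)

  ## different genes never pair
  v2g <- trioRecord("chr3", 200, "0/0", "0/1", "0/1", gene = "GENEB")
  dsDiff <- annotateCompoundHet(trioDs(c(v1, v2g)), defaultTrio)
  expect_null(docs(dsDiff)[[1]]$info$CompoundHet)

  ## child homozygous does not qualify
  vHom <- trioRecord("chr3", 300, "0/1", "0/1", "1/1", gene = "GENEA")
  dsHom <- annotateCompoundHet(trioDs(c(v1, vHom)), defaultTrio)
  expect_null(docs(dsHom)[[2]]$info$CompoundHet)
})

test_that("phase information vetoes same-haplotype pairs", {
  mk <- function(gt1, gt2) trioDs(c(
    paste("chr3", 100, ".", "A", "T", 50, "PASS", "DP=4;Gene=GENEA",
          "GT", "0/1", "0/0", gt1, sep = "\t"),
    paste("chr3", 200, ".", "A", "T", 50, "PASS", "DP=4;Gene=GENEA",
          "GT", "0/0", "0/1", gt2, sep = "\t")))
  ## both phased on the same haplotype: not compound het
  same <- annotateCompoundHet(mk("0|1", "0|1"), defaultTrio)
  expect_null(docs(same)[[1]]$info$CompoundHet)
  ## opposite haplotypes: confirmed
  opp <- annotateCompoundHet(mk("0|1", "1|0"), defaultTrio)
  expect_true(docs(opp)[[1]]$info$CompoundHet)
  expect_true(docs(opp)[[2]]$info$CompoundHet)
  ## one unphased: phase cannot veto
  mixed <- annotateCompoundHet(mk("0|1", "0/1"), defaultTrio)
  expect_true(docs(mixed)[[1]]$info$CompoundHet)
})

test_that("planted trio patterns are recovered exactly", {
  res <- generateTrio(c(AR = 8, deNovo = 6, NonMendelian = 5, XLD = 4,
                        CompoundHet = 3, none = 10), seed = 99)
  ds <- loadVcfLines(res$vcf)
  ds <- annotateInheritance(ds, res$trio)
  ds <- annotateCompoundHet(ds, res$trio)
  got <- vapply(docs(ds), function(d) {
    v <- d$info$InheritancePattern
    if (is.null(v)) "none" else paste(v, collapse = ",")
  }, character(1))
  expect_identical(got, res$truth$pattern)
  gotCH <- vapply(docs(ds), function(d) isTRUE(d$info$CompoundHet),
                  logical(1))
  expect_identical(gotCH, res$truth$compoundHet)

  ## CompoundHet flagging is invariant under document order
  ds2 <- loadVcfLines(res$vcf)
  ord <- rev(seq_along(docs(ds2)))
  ds2@docs <- ds2@docs[ord]
  ds2@ids <- ds2@ids[ord]
  ds2 <- annotateCompoundHet(ds2, res$trio)
  expect_identical(vapply(docs(ds2), function(d)
    isTRUE(d$info$CompoundHet), logical(1)), rev(gotCH))
})

test_that("two pairs planted in one gene flag all four variants", {
  res <- generateTrio(c(CompoundHet = 2, none = 1), seed = 7,
                      compoundHetGenes = 1)
  ds <- annotateCompoundHet(loadVcfLines(res$vcf), res$trio)
  expect_equal(sum(vapply(docs(ds), function(d)
    isTRUE(d$info$CompoundHet), logical(1))), 4)
  expect_equal(sum(res$truth$compoundHet), 4)
})
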