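## Deterministic synthetic VCF/BED/trio fixtures.  A single integer
## seed controls all randomness and generation order is fixed, so the
## same call yields byte-identical output on any platform; every
## generated file passes strict validation.

## Evaluate expr under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.BASES <- c("A", "C", "G", "T")

.fixtureHeader <- function(samples, contigs) {
  c("##fileformat=VCFv4.2",
    "##source=VariantSieve-fixtures",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">',
    '##INFO=<ID=IMPACT,Number=1,Type=String,Description="Predicted impact">',
    '##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description="Somatic event">',
    '##INFO=<ID=Gene,Number=1,Type=String,Description="Gene symbol">',
    '##FILTER=<ID=q20,Description="Quality below 20">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT",
           if (length(samples))
             paste0("\t", paste(samples, collapse = "\t")) else "")
  )
}

## One sample column (GT:AD:DP) for a given zygosity category.
.sampleField <- function(category, ploidy, nAlt) {
  altIdx <- if (nAlt > 1) sample(nAlt, 1) else 1L
  tokens <- switch(category,
    nocall = rep(".", ploidy),
    ref = rep("0", ploidy),
    het = sample(c(as.character(altIdx), rep("0", ploidy - 1))),
    hom = {
      t <- rep(as.character(altIdx), ploidy)
      if (ploidy > 2) t[sample(ploidy, 1)] <- "0"
      t
    })
  gt <- paste(tokens, collapse = "/")
  if (category == "nocall")
    return(paste0(gt, ":", paste(rep(".", nAlt + 1), collapse = ","),
                  ":."))
  nAltCopies <- sum(tokens != "0" & tokens != ".")
  refReads <- if (category == "hom") sample(0:3, 1) else
    sample(8:40, 1)
  altReads <- integer(nAlt)
  if (nAltCopies > 0)
    altReads[as.integer(tokens[tokens != "0" & tokens != "."])] <-
      sample(5:45, 1)
  dp <- refReads + sum(altReads)
  paste0(gt, ":", paste(c(refReads, altReads), collapse = ","), ":",
         dp)
}

#' Generate a deterministic synthetic multi-sample VCF
#'
#' Emits a complete VCF (header declaring every generated field, body
#' consistent with it) whose genotype composition, missing-call rate and
#' multi-allelic fraction are controlled parameters.  The per-call
#' zygosity category is a single multinomial draw, so the observed
#' het/hom fractions converge to \code{pHet}/\code{pHom} as the file
#' grows.  The same seed always yields byte-identical text.
#'
#' @param nVariants number of records (>= 0).
#' @param nSamples number of samples (>= 0).
#' @param ploidy tokens per genotype (default 2).
#' @param pHet,pHom expected fraction of heterozygous / homozygous
#'   calls.
#' @param missingRate expected fraction of no-call genotypes.
#' @param multiallelicFrac fraction of records with two ALT alleles.
#' @param sparsity fraction of records where the optional IMPACT
#'   annotation is absent (sparse INFO data is the norm and is what the
#'   missing-value filter policies are for).
#' @param seed integer seed; same seed, same bytes.
#' @return character vector of VCF lines.
#' @examples
#' vcf <- generateVcf(5, 2, seed = 1)
#' ds <- loadVcf(textConnection(vcf))
#' @export
generateVcf <- function(nVariants, nSamples, ploidy = 2, pHet = 0.3,
                        pHom = 0.1, missingRate = 0.05,
                        multiallelicFrac = 0, sparsity = 0.2,
                        seed = 1L) {
  if (nVariants < 0 || nSamples < 0 || ploidy < 1)
    stop("nVariants, nSamples >= 0 and ploidy >= 1 required")
  probs <- c(hom = pHom, het = pHet, nocall = missingRate)
  if (sum(probs) > 1)
    stop("pHom + pHet + missingRate must not exceed 1")
  probs <- c(probs, ref = 1 - sum(probs))
  samples <- if (nSamples > 0) sprintf("S%d", seq_len(nSamples)) else
    character(0)
  .withSeed(seed, {
    chroms <- c("chr1", "chr2", "chr3")
    chromOf <- sort(sample(chroms, nVariants, replace = TRUE))
    body <- character(nVariants)
    pos <- stats::setNames(rep(0L, length(chroms)), chroms)
    for (i in seq_len(nVariants)) {
      ch <- chromOf[i]
      pos[ch] <- pos[ch] + sample(50:5000, 1)
      ref <- sample(.BASES, 1)
      nAlt <- if (stats::runif(1) < multiallelicFrac) 2L else 1L
      alt <- sample(setdiff(.BASES, ref), nAlt)
      qual <- if (stats::runif(1) < 0.05) "." else
        sprintf("%.1f", stats::runif(1, 10, 1000))
      filt <- if (stats::runif(1) < 0.1) "q20" else "PASS"
      info <- sprintf("DP=%d;AF=%s", sample(10:500, 1),
        paste(sprintf("%.3f", stats::runif(nAlt)), collapse = ","))
      if (stats::runif(1) >= sparsity)
        info <- paste0(info, ";IMPACT=",
          sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), 1))
      if (stats::runif(1) < 0.1) info <- paste0(info, ";SOMATIC")
      info <- paste0(info, ";Gene=GENE", sample(1:20, 1))
      cols <- c(ch, pos[ch], ".", ref, paste(alt, collapse = ","),
                qual, filt, info)
      if (nSamples > 0) {
        cats <- sample(names(probs), nSamples, replace = TRUE,
                       prob = probs)
        cols <- c(cols, "GT:AD:DP",
                  vapply(cats, .sampleField, character(1),
                         ploidy = ploidy, nAlt = nAlt))
      }
      body[i] <- paste(cols, collapse = "\t")
    }
    c(.fixtureHeader(samples), body)
  })
}

## genotype triplets (mother, father, child) planted per pattern
.TRIO_GT <- list(
  AR = c("0/1", "0/1", "1/1"),
  deNovo = c("0/0", "0/0", "0/1"),
  NonMendelian = c("0/0", "0/1", "1/1"),
  XLD = c("0/1", "0/0", "0/1"),
  chMother = c("0/1", "0/0", "0/1"),
  chFather = c("0/0", "0/1", "0/1"),
  none = c("0/1", "0/0", "0/0")
)

.trioSampleField <- function(gt) {
  nAltCopies <- sum(strsplit(gt, "/")[[1]] != "0")
  refReads <- if (nAltCopies >= 2) sample(0:3, 1) else sample(10:40, 1)
  altReads <- if (nAltCopies >= 1) sample(8:45, 1) else 0L
  sprintf("%s:%d,%d:%d", gt, refReads, altReads, refReads + altReads)
}

#' Generate a trio VCF with planted inheritance-pattern ground truth
#'
#' Plants a requested number of variants per pattern (\code{AR},
#' \code{deNovo}, \code{NonMendelian}, \code{XLD},
#' \code{CompoundHet} — counted in pairs — and \code{none}) with the
#' canonical genotype triplets, and returns the VCF together with the
#' per-variant truth table, so annotator recovery can be checked
#' exactly.  Compound-het pairs are placed in dedicated genes
#' (\code{compoundHetGenes} genes shared round-robin; every other
#' variant gets a private gene); XLD variants go on chrX, everything
#' else on autosomes.  The mother is generated affected (so the planted
#' X-linked-dominant variants satisfy the matching-affected-status
#' rule); the matching \linkS4class{TrioSpec} is returned.
#'
#' @param planted named integer vector with entries among \code{AR},
#'   \code{deNovo}, \code{NonMendelian}, \code{XLD}, \code{CompoundHet}
#'   (pairs), \code{none}.
#' @param seed integer seed.
#' @param nVariants optional consistency check: must equal the total
#'   number of rows implied by \code{planted}.
#' @param compoundHetGenes number of genes the compound-het pairs share
#'   (default: one gene per pair).
#' @param pImpactHigh fraction of variants annotated
#'   \code{IMPACT=HIGH}.
#' @return list with \code{vcf} (character lines), \code{truth}
#'   (data.frame: \code{chrom}, \code{pos}, \code{gene},
#'   \code{pattern}, \code{compoundHet}, \code{impact}, in body order)
#'   and \code{trio} (a \linkS4class{TrioSpec}).
#' @export
generateTrio <- function(planted, seed = 1L, nVariants = NULL,
                         compoundHetGenes = NULL,
                         pImpactHigh = 0.2) {
  known <- c("AR", "deNovo", "NonMendelian", "XLD", "CompoundHet",
             "none")
  bad <- setdiff(names(planted), known)
  if (length(bad))
    stop(sprintf("unknown planted pattern '%s'", bad[1]))
  get0 <- function(p) if (p %in% names(planted))
    as.integer(planted[[p]]) else 0L
  counts <- stats::setNames(vapply(known, get0, integer(1)), known)
  if (any(counts < 0)) stop("planted counts must be non-negative")
  nCH <- counts[["CompoundHet"]]
  total <- sum(counts[known != "CompoundHet"]) + 2L * nCH
  if (!is.null(nVariants) && nVariants != total)
    stop(sprintf("planted counts imply %d variants, not %d (infeasible)",
                 total, nVariants))
  if (is.null(compoundHetGenes))
    compoundHetGenes <- max(nCH, 1L)
  .withSeed(seed, {
    rows <- list()
    addRow <- function(pattern, gtKey, gene, chrom, ch = FALSE)
      rows[[length(rows) + 1L]] <<- list(pattern = pattern,
        gts = .TRIO_GT[[gtKey]], gene = gene, chrom = chrom,
        compoundHet = ch)
    geneNo <- 0L
    nextGene <- function() {
      geneNo <<- geneNo + 1L
      sprintf("G%03d", geneNo)
    }
    autosomes <- c("chr1", "chr2", "chr3")
    for (p in c("AR", "deNovo", "NonMendelian", "none"))
      for (j in seq_len(counts[[p]]))
        addRow(p, p, nextGene(), autosomes[1 + (j %% 3)])
    for (j in seq_len(counts[["XLD"]]))
      addRow("XLD", "XLD", nextGene(), "chrX")
    if (nCH > 0) {
      chGenes <- sprintf("CHG%02d", seq_len(compoundHetGenes))
      chChrom <- autosomes[1 + (seq_len(compoundHetGenes) %%
                                  length(autosomes))]
      for (j in seq_len(nCH)) {
        g <- 1 + (j - 1) %% compoundHetGenes
        addRow("none", "chMother", chGenes[g], chChrom[g], ch = TRUE)
        addRow("none", "chFather", chGenes[g], chChrom[g], ch = TRUE)
      }
    }
    rows <- rows[sample(length(rows))]
    ## sort into a valid VCF: chromosome blocks, increasing positions
    chromOf <- vapply(rows, function(r) r$chrom, character(1))
    ord <- order(match(chromOf, c(autosomes, "chrX")))
    rows <- rows[ord]
    pos <- stats::setNames(rep(0L, 4), c(autosomes, "chrX"))
    body <- character(length(rows))
    truth <- data.frame(chrom = character(length(rows)),
                        pos = integer(length(rows)),
                        gene = character(length(rows)),
                        pattern = character(length(rows)),
                        compoundHet = logical(length(rows)),
                        impact = character(length(rows)),
                        stringsAsFactors = FALSE)
    for (i in seq_along(rows)) {
      r <- rows[[i]]
      pos[r$chrom] <- pos[r$chrom] + sample(100:5000, 1)
      ref <- sample(.BASES, 1)
      alt <- sample(setdiff(.BASES, ref), 1)
      impact <- if (stats::runif(1) < pImpactHigh) "HIGH" else
        sample(c("MODERATE", "LOW"), 1)
      info <- sprintf("DP=%d;AF=%.3f;IMPACT=%s;Gene=%s",
                      sample(20:200, 1), stats::runif(1), impact,
                      r$gene)
      fields <- vapply(r$gts, .trioSampleField, character(1))
      body[i] <- paste(c(r$chrom, pos[r$chrom], ".", ref, alt,
                         sprintf("%.1f", stats::runif(1, 30, 900)),
                         "PASS", info, "GT:AD:DP", fields),
                       collapse = "\t")
      truth$chrom[i] <- r$chrom
      truth$pos[i] <- pos[r$chrom]
      truth$gene[i] <- r$gene
      truth$pattern[i] <- r$pattern
      truth$compoundHet[i] <- r$compoundHet
      truth$impact[i] <- impact
    }
    trio <- trioSpec("MOTHER", "FATHER", "CHILD",
      affected = c(MOTHER = TRUE, FATHER = FALSE, CHILD = TRUE))
    list(vcf = c(.fixtureHeader(c("MOTHER", "FATHER", "CHILD"),
                                c(autosomes, "chrX")), body),
         truth = truth, trio = trio)
  })
}
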