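## Shared fixtures and independent oracles.  Oracles deliberately avoid
## the package's evaluation code paths: they recompute expectations from
## the raw document values with plain R.

minimalHeader <- function(samples = c("S1", "S2"), extraInfo = character(0)) {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele freq">',
    '##INFO=<ID=IMPACT,Number=1,Type=String,Description="Impact">',
    '##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description="Somatic">',
    extraInfo,
    '##FILTER=<ID=q20,Description="low qual">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
            if (length(samples)) c("FORMAT", samples)),
          collapse = "\t"))
}

writeTempVcf <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".vcf.gz" else ".vcf")
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  path
}

loadVcfLines <- function(lines, ...) {
  path <- writeTempVcf(lines)
  on.exit(unlink(path))
  suppressWarnings(loadVcf(path, ...))
}

## Build a variant document directly from zygosity categories, one
## sample per category.
callFor <- function(z) switch(z,
  REF = list(gt = "0/0", zygosity = "REFERENCE", altAlleleCount = 0L,
             refDepth = 20L, altDepth = 0L, other = list()),
  HET = list(gt = "0/1", zygosity = "HETEROZYGOUS", altAlleleCount = 1L,
             refDepth = 12L, altDepth = 9L, other = list()),
  HOM = list(gt = "1/1", zygosity = "HOMOZYGOUS", altAlleleCount = 2L,
             refDepth = 1L, altDepth = 25L, other = list()),
  NOCALL = list(gt = "./.", zygosity = "NO_CALL", altAlleleCount = 0L,
                refDepth = NA_integer_, altDepth = NA_integer_,
                other = list()))

docFor <- function(zygs, ids = paste0("S", seq_along(zygs))) {
  list(chrom = "chr1", pos = 1L, id = NA, ref = "A", alt = "T",
       qual = 50, filter = "PASS",
       info = list(), calls = setNames(lapply(zygs, callFor), ids),
       derived = list())
}

## ---- linear-scan filter oracle --------------------------------------

## Re-derive the value of a field path from a document with plain list
## access (no shared code with fieldValue beyond the path convention).
oracleFieldValue <- function(doc, field) {
  parts <- strsplit(field, ".", fixed = TRUE)[[1]]
  ns <- parts[1]
  if (ns == "CORE") {
    v <- switch(parts[2], CHROM = doc$chrom, POS = doc$pos,
                ID = doc$id, REF = doc$ref,
                ALT = paste(doc$alt, collapse = ","),
                QUAL = doc$qual, FILTER = doc$filter)
    if (length(v) == 1 && is.na(v)) NULL else v
  } else if (ns == "INFO") {
    doc$info[[paste(parts[-1], collapse = ".")]]
  } else if (ns %in% c("FORMAT", "RANGE")) {
    doc$derived[[field]]
  } else if (ns == "DERIVED") {
    doc$derived[[parts[2]]]
  } else NULL
}

## TRUE iff `doc` passes `spec`, evaluated by brute force.
oracleMatches <- function(doc, spec) {
  if (spec@kind == "group") {
    gf <- spec@group
    m <- 0L
    for (sid in gf@group@members) {
      call <- doc$calls[[sid]]
      ok <- !is.null(call) && switch(gf@zygosityReq,
        either = call$altAlleleCount >= 1,
        heterozygous = call$zygosity == "HETEROZYGOUS",
        homozygous = call$zygosity == "HOMOZYGOUS")
      if (ok && !is.na(gf@minAltDepth))
        ok <- !is.na(call$altDepth) && call$altDepth >= gf@minAltDepth
      if (ok) m <- m + 1L
    }
    need <- switch(gf@quantifier, any = 1L,
                   all = length(gf@group@members),
                   fraction = ceiling(gf@fraction *
                                        length(gf@group@members)))
    hit <- m >= need
    return(if (gf@mode == "require") hit else !hit)
  }
  v <- oracleFieldValue(doc, spec@field)
  if (spec@kind %in% c("flag", "range")) {
    present <- isTRUE(v)
    return(if (spec@operator == "is_true") present else !present)
  }
  if (is.null(v) || all(is.na(v)))
    return(spec@missingPolicy == "include_missing")
  if (spec@kind == "numeric") {
    hits <- switch(spec@operator,
      "<" = v < spec@value, "<=" = v <= spec@value,
      ">" = v > spec@value, ">=" = v >= spec@value,
      "=" = abs(v - spec@value) <= 1e-9 * pmax(1, abs(spec@value)),
      "!=" = abs(v - spec@value) > 1e-9 * pmax(1, abs(spec@value)))
    return(any(hits, na.rm = TRUE))
  }
  inSet <- any(as.character(v) %in% spec@value)
  if (spec@operator == "in_set") inSet else !inSet
}

## Replay a chain per document; returns list(counts, survivors).
oracleChain <- function(ds, specs, within = variantIds(ds)) {
  current <- sort(within)
  counts <- integer(length(specs))
  allDocs <- docs(ds)
  idPos <- match(current, variantIds(ds))
  for (i in seq_along(specs)) {
    keepPos <- idPos[vapply(allDocs[idPos], oracleMatches, logical(1),
                            spec = specs[[i]])]
    idPos <- keepPos
    counts[i] <- length(idPos)
  }
  list(counts = counts, survivors = sort(variantIds(ds)[idPos]))
}

## Random FilterSpec over the standard fixture fields.
randomSpec <- function(ds) {
  kind <- sample(c("numeric", "string", "flag"), 1)
  if (kind == "numeric") {
    field <- sample(c("INFO.DP", "CORE.QUAL", "FORMAT.DP.min",
                      "FORMAT.DP.max", "DERIVED.sample_count",
                      "CORE.POS", "INFO.AF"), 1)
    op <- sample(c("<", "<=", "=", ">=", ">", "!="), 1)
    value <- switch(field,
      INFO.DP = sample(10:500, 1), CORE.QUAL = runif(1, 10, 1000),
      FORMAT.DP.min = sample(0:80, 1), FORMAT.DP.max = sample(0:90, 1),
      DERIVED.sample_count = sample(0:6, 1),
      CORE.POS = sample(1:200000, 1), INFO.AF = runif(1))
    filterSpec(field, op, value,
               missingPolicy = sample(c("exclude_missing",
                                        "include_missing"), 1))
  } else if (kind == "string") {
    field <- sample(c("INFO.IMPACT", "CORE.CHROM", "CORE.FILTER",
                      "INFO.Gene", "CORE.REF"), 1)
    pool <- switch(field,
      INFO.IMPACT = c("HIGH", "MODERATE", "LOW", "MODIFIER"),
      CORE.CHROM = c("chr1", "chr2", "chr3"),
      CORE.FILTER = c("PASS", "q20"),
      INFO.Gene = sprintf("GENE%d", 1:20),
      CORE.REF = c("A", "C", "G", "T"))
    filterSpec(field, sample(c("in_set", "not_in_set"), 1),
               sample(pool, sample(seq_along(pool), 1)),
               missingPolicy = sample(c("exclude_missing",
                                        "include_missing"), 1))
  } else {
    filterSpec("INFO.SOMATIC", sample(c("is_true", "is_false"), 1))
  }
}

## The standard randomized dataset for oracle/property tests.
standardDataset <- function(n = 1000, samples = 6, seed = 42,
                            multiallelicFrac = 0) {
  loadVcfLines(generateVcf(n, samples, seed = seed,
                           multiallelicFrac = multiallelicFrac))
}
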