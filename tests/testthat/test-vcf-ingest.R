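test_that("header declarations are captured with their types", {
  hdr <- parseVcfHeader(minimalHeader(c("S1", "S2")))
  info <- infoFields(hdr)
  expect_equal(info$type[info$id == "AF"], "Float")
  expect_equal(info$number[info$id == "AF"], "A")
  expect_equal(info$type[info$id == "SOMATIC"], "Flag")
  fmt <- formatFields(hdr)
  expect_equal(fmt$type[fmt$id == "AD"], "Integer")
  expect_equal(filterIds(hdr), "q20")
  expect_equal(vcfSamples(hdr), c("S1", "S2"))

  ## no INFO declarations at all, one sample
  bare <- parseVcfHeader(c("##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tonly"))
  expect_equal(nrow(infoFields(bare)), 0)
  expect_equal(vcfSamples(bare), "only")

  expect_error(parseVcfHeader(c("##INFO=<Number=1,Type=Integer>",
                                "#CHROM\tPOS")), "line 1")
  expect_error(parseVcfHeader("##fileformat=VCFv4.2"), "#CHROM")
})

test_that("INFO values are typed, arrays split, flags and '.' handled", {
  hdr <- parseVcfHeader(minimalHeader(character(0)))
  doc <- parseVcfRecord(
    "chr1\t100\trs1\tA\tT\t30.5\tPASS\tDP=10;SOMATIC", hdr)
  expect_identical(doc$info$DP, 10L)
  expect_true(doc$info$SOMATIC)
  expect_equal(doc$pos, 100L)
  expect_equal(doc$qual, 30.5)
  expect_equal(doc$id, "rs1")

  doc2 <- parseVcfRecord("chr1\t100\t.\tA\tT,G\t.\tPASS\tAF=0.5,0.2",
                         hdr)
  expect_equal(doc2$info$AF, c(0.5, 0.2))
  expect_true(is.na(doc2$qual))

  doc3 <- parseVcfRecord("chr1\t100\t.\tA\tT\t1\tPASS\tDP=.", hdr)
  expect_null(doc3$info$DP)   # '.' is absent, not zero
})

test_that("sample columns bind FORMAT values positionally", {
  hdr <- parseVcfHeader(minimalHeader(c("S1", "S2")))
  doc <- parseVcfRecord(paste(
    "chr1", "100", ".", "A", "T", "50", "PASS", "DP=9",
    "GT:DP", "./.:.", "0/1:13", sep = "\t"), hdr)
  expect_equal(doc$calls$S1$zygosity, "NO_CALL")
  expect_true(is.null(doc$calls$S1$other$DP))
  expect_equal(doc$calls$S2$other$DP, 13L)
  expect_equal(fieldValue(doc, "DERIVED.sample_count"), 1L)
  expect_equal(fieldValue(doc, "DERIVED.sample_list"), "S2")

  expect_error(parseVcfRecord("chr1\t100\t.\tA", hdr), "at least 8")
  expect_error(parseVcfRecord("chr1\t0\t.\tA\tT\t1\tPASS\tDP=1", hdr),
               "positive integer")
})

test_that("strict mode rejects what tolerant mode retains", {
  hdr <- parseVcfHeader(minimalHeader(character(0)))
  line <- "chr1\t5\t.\tA\tT\t1\tPASS\tFOO=3"
  expect_error(parseVcfRecord(line, hdr, mode = "strict"), "FOO")
  expect_warning(doc <- parseVcfRecord(line, hdr, mode = "tolerant"),
                 "FOO")
  expect_equal(doc$info$FOO, "3")   # retained as string

  bad <- "chr1\t5\t.\tA\tT\t1\tPASS\tDP=abc"
  expect_error(parseVcfRecord(bad, hdr, mode = "strict"), "Integer")
  expect_warning(doc2 <- parseVcfRecord(bad, hdr, mode = "tolerant"),
                 "Integer")
  expect_equal(unclass(doc2$info$DP)[1], "abc")
})

test_that("gzip and plain encodings yield identical datasets", {
  lines <- generateVcf(30, 2, seed = 11)
  plain <- writeTempVcf(lines)
  gz <- writeTempVcf(lines, gz = TRUE)
  misnamed <- sub("\\.gz$", "", tempfile(fileext = ".vcf"))
  file.copy(gz, misnamed)   # gz content under a plain name
  on.exit(unlink(c(plain, gz, misnamed)))
  dsP <- loadVcf(plain)
  dsG <- loadVcf(gz)
  dsM <- loadVcf(misnamed)  # magic bytes, not extension
  key <- function(ds) vapply(docs(ds), function(d)
    paste(d$chrom, d$pos, d$ref, paste(d$alt, collapse = ","),
          fieldValue(d, "DERIVED.sample_list")), character(1))
  expect_identical(key(dsP), key(dsG))
  expect_identical(key(dsP), key(dsM))
})

test_that("parsing agrees with an independent VCF reader", {
  lines <- generateVcf(40, 3, seed = 71)
  path <- writeTempVcf(lines)
  on.exit(unlink(path))
  ds <- loadVcf(path)
  ref <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(ref)
  expect_equal(length(docs(ds)), length(rr))
  expect_equal(vapply(docs(ds), function(d) d$chrom, character(1)),
               as.character(GenomicRanges::seqnames(rr)))
  expect_equal(vapply(docs(ds), function(d) d$pos, integer(1)),
               GenomicRanges::start(rr))
  expect_equal(vapply(docs(ds), function(d) d$ref, character(1)),
               as.character(rr$REF))
  expect_equal(unlist(lapply(docs(ds), function(d) d$info$DP)),
               unlist(VariantAnnotation::info(ref)$DP),
               ignore_attr = TRUE)
  gt <- VariantAnnotation::geno(ref)$GT
  for (s in colnames(gt))
    expect_equal(vapply(docs(ds), function(d) d$calls[[s]]$gt,
                        character(1)),
                 unname(gt[, s]))
})

test_that("a large generated file streams through with every record", {
  lines <- generateVcf(10000, 2, seed = 5)
  ds <- loadVcfLines(lines)
  expect_equal(length(docs(ds)), 10000)
  expect_equal(variantIds(ds), seq_len(10000))
})

test_that("validation names undeclared keys with their line numbers", {
  lines <- c(minimalHeader(character(0)),
    "chr1\t100\t.\tA\tT\t10\tPASS\tDP=5",
    "chr1\t200\t.\tA\tT\t10\tPASS\tFOO=1")
  rep <- validateVcf(writeTempVcf(lines))
  expect_false(validationOk(rep))
  df <- issues(rep)
  err <- df[df$severity == "error", ]
  expect_equal(nrow(err), 1)
  expect_match(err$message, "FOO")
  expect_equal(err$line, length(minimalHeader(character(0))) + 2L)
  expect_match(formatIssues(rep), "\terror\t", all = FALSE)
})

test_that("clean files validate with zero issues and defects are localized", {
  good <- writeTempVcf(c(minimalHeader(c("S1")),
    "chr1\t100\t.\tA\tT\t10\tPASS\tDP=5\tGT:DP\t0/1:9"))
  rep <- validateVcf(good)
  expect_true(validationOk(rep))
  expect_equal(nrow(issues(rep)), 0)

  ## 5-line body with one malformed record
  hdr <- minimalHeader(character(0))
  body <- sprintf("chr1\t%d\t.\tA\tT\t10\tPASS\tDP=5", (1:5) * 100)
  body[3] <- "chr1\tnotanumber\t.\tA\tT\t10\tPASS\tDP=5"
  rep2 <- validateVcf(writeTempVcf(c(hdr, body)))
  err <- issues(rep2)[issues(rep2)$severity == "error", ]
  expect_equal(nrow(err), 1)
  expect_equal(err$line, length(hdr) + 3L)

  ## unsorted positions are a warning, not an error
  body2 <- c("chr1\t500\t.\tA\tT\t10\tPASS\tDP=5",
             "chr1\t100\t.\tA\tT\t10\tPASS\tDP=5")
  rep3 <- validateVcf(writeTempVcf(c(hdr, body2)))
  expect_true(validationOk(rep3))
  expect_equal(issues(rep3)$severity, "warning")
})

test_that("multi-allelic records split with per-alternate slicing", {
  hdr <- parseVcfHeader(minimalHeader(c("S1", "S2")))

  ## identity on single-ALT records
  one <- parseVcfRecord("chr1\t9\t.\tA\tT\t5\tPASS\tDP=4", hdr)
  expect_identical(splitMultiallelic(one, hdr), list(one))

  doc <- parseVcfRecord(paste(
    "chr1", "100", ".", "G", "A,T", "50", "PASS", "AF=0.1,0.9;DP=70",
    "GT:AD", "1/2:4,6,8", "0/1:10,5,0", sep = "\t"), hdr)
  parts <- splitMultiallelic(doc, hdr)
  expect_length(parts, 2)
  expect_equal(parts[[1]]$alt, "A")
  expect_equal(parts[[1]]$info$AF, 0.1)     # Number=A sliced
  expect_equal(parts[[2]]$info$AF, 0.9)
  expect_equal(parts[[1]]$info$DP, 70L)     # shared field copied
  ## AD: ref depth + that allele's depth
  expect_equal(parts[[1]]$calls$S1$refDepth, 4L)
  expect_equal(parts[[1]]$calls$S1$altDepth, 6L)
  expect_equal(parts[[2]]$calls$S1$altDepth, 8L)
  ## 1/2 sample stays a carrier in both outputs
  expect_gte(parts[[1]]$calls$S1$altAlleleCount, 1L)
  expect_gte(parts[[2]]$calls$S1$altAlleleCount, 1L)
  ## S2 carried allele 1 only
  expect_equal(parts[[1]]$calls$S2$zygosity, "HETEROZYGOUS")
  expect_equal(parts[[2]]$calls$S2$altDepth, 0L)

  ## wrong-arity per-alternate field is a named error
  bad <- parseVcfRecord("chr1\t5\t.\tG\tA,T\t5\tPASS\tAF=0.5", hdr)
  expect_error(splitMultiallelic(bad, hdr), "AF")
})

test_that("normalization conserves the (chrom,pos,ref,alt) multiset", {
  ds <- standardDataset(n = 150, samples = 3, seed = 21,
                        multiallelicFrac = 0.3)
  expected <- sort(unlist(lapply(docs(ds), function(d)
    paste(d$chrom, d$pos, d$ref, d$alt))))
  dsn <- normalizeMultiallelic(ds)
  got <- sort(vapply(docs(dsn), function(d)
    paste(d$chrom, d$pos, d$ref, d$alt), character(1)))
  expect_identical(got, expected)
  expect_true(all(vapply(docs(dsn), function(d) length(d$alt) == 1,
                         logical(1))))
})

test_that("reordering sample columns permutes calls only", {
  hdr <- minimalHeader(c("S1", "S2"))
  hdrSwap <- sub("S1\tS2", "S2\tS1", hdr[length(hdr)])
  rec <- function(s1, s2) paste("chr1", 100, ".", "A", "T", 50, "PASS",
                                "DP=5", "GT:DP", s1, s2, sep = "\t")
  a <- loadVcfLines(c(hdr, rec("0/1:10", "1/1:20")))
  b <- loadVcfLines(c(hdr[-length(hdr)], hdrSwap,
                      rec("1/1:20", "0/1:10")))
  da <- docs(a)[[1]]; db <- docs(b)[[1]]
  expect_identical(da$calls[["S1"]], db$calls[["S1"]])
  expect_identical(da$calls[["S2"]], db$calls[["S2"]])
  expect_identical(da$derived, db$derived)
})
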