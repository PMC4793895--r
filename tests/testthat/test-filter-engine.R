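test_that("missing-value policy decides who survives a typed filter", {
  lines <- c(minimalHeader(character(0)),
    "chr1\t100\t.\tA\tT\t10\tPASS\tIMPACT=HIGH;DP=5",
    "chr1\t200\t.\tA\tT\t10\tPASS\tIMPACT=LOW;DP=5",
    "chr1\t300\t.\tA\tT\t10\tPASS\tDP=5")          # IMPACT missing
  ds <- loadVcfLines(lines)
  excl <- applyFilter(ds, filterSpec("INFO.IMPACT", "in_set", "HIGH"))
  expect_identical(excl, 1L)
  incl <- applyFilter(ds, filterSpec("INFO.IMPACT", "in_set", "HIGH",
                                     missingPolicy = "include_missing"))
  expect_identical(incl, c(1L, 3L))

  ## X < +Inf with include_missing is the identity filter
  all <- applyFilter(ds, filterSpec("CORE.QUAL", "<", Inf,
                                    missingPolicy = "include_missing"))
  expect_identical(all, variantIds(ds))

  ## an absent flag is FALSE, not missing
  noFlag <- applyFilter(ds, filterSpec("INFO.SOMATIC", "is_false"))
  expect_identical(noFlag, variantIds(ds))
  expect_identical(applyFilter(ds, filterSpec("INFO.SOMATIC",
                                              "is_true")), integer(0))

  expect_error(applyFilter(ds, filterSpec("INFO.ABSENT", ">", 1)),
               "INFO.ABSENT")
  expect_error(applyFilter(ds, filterSpec("INFO.IMPACT", ">", 1)),
               "numeric")
})

test_that("operator families are enforced at construction", {
  expect_error(new("FilterSpec", field = "INFO.DP", kind = "numeric",
                   operator = "in_set", value = 1,
                   missingPolicy = "exclude_missing", group = NULL),
               "family")
  expect_error(filterSpec("INFO.IMPACT", "in_set", character(0)),
               "non-empty")
})

test_that("chains apply consecutively with monotone survivor counts", {
  ds <- standardDataset(n = 300, samples = 4, seed = 31)
  empty <- applyChain(ds, filterChain())
  expect_identical(survivors(empty), variantIds(ds))
  expect_length(stepCounts(empty), 0)
  expect_equal(initialCount(empty), 300)

  a <- filterSpec("INFO.DP", ">=", 200)
  b <- filterSpec("INFO.IMPACT", "in_set", c("HIGH", "MODERATE"))
  ab <- applyChain(ds, filterChain(a, b))
  ba <- applyChain(ds, filterChain(b, a))
  expect_identical(survivors(ab), survivors(ba))   # conjunctive
  expect_false(identical(stepCounts(ab)[1], stepCounts(ba)[1]))
  expect_true(all(diff(stepCounts(ab)) <= 0))
  expect_lte(stepCounts(ab)[1], initialCount(ab))
  ## final set equals the intersection of standalone survivor sets
  expect_identical(survivors(ab),
                   sort(intersect(applyFilter(ds, a),
                                  applyFilter(ds, b))))
  ## idempotence
  aa <- applyChain(ds, filterChain(a, a))
  expect_identical(survivors(aa), applyFilter(ds, a))
  expect_identical(stepCounts(aa)[1], stepCounts(aa)[2])
})

test_that("randomized chains agree with the linear-scan oracle", {
  ds <- standardDataset(n = 500, samples = 4, seed = 77)
  set.seed(101)
  for (i in 1:15) {
    specs <- lapply(seq_len(sample(1:4, 1)), function(j)
      randomSpec(ds))
    got <- applyChain(ds, filterChain(specs))
    want <- oracleChain(ds, specs)
    expect_identical(stepCounts(got), want$counts)
    expect_identical(survivors(got), want$survivors)
  }
})

test_that("strategies round-trip and stay portable across datasets", {
  g <- sampleGroup("cases", c("S1", "S2"))
  chain <- filterChain(
    filterSpec("INFO.AF", "<=", 0.4),
    filterSpec("INFO.IMPACT", "in_set", c("HIGH", "MODERATE"),
               missingPolicy = "include_missing"),
    groupFilterSpec(groupFilter(g, zygosity = "heterozygous",
                                quantifier = "fraction",
                                fraction = 0.5, mode = "require",
                                minAltDepth = 5L)))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  saveStrategy(chain, path = path)
  back <- loadStrategy(path)
  expect_length(back$chain@steps, 3)
  for (i in 1:3)
    expect_equal(back$chain@steps[[i]], chain@steps[[i]])
  expect_named(back$groups, "cases")
  expect_equal(back$groups$cases, g)

  ## applying the loaded strategy reproduces a fresh evaluation
  ds <- standardDataset(n = 250, samples = 4, seed = 55)
  fresh <- applyChain(ds, chain)
  replay <- applyChain(ds, loadStrategy(path, dataset = ds)$chain)
  expect_identical(stepCounts(replay), stepCounts(fresh))
  expect_identical(survivors(replay), survivors(fresh))

  ## unresolved references error by name instead of silently dropping
  g9 <- sampleGroup("g9", "S9")
  bad <- filterChain(groupFilterSpec(groupFilter(g9)))
  path9 <- tempfile(fileext = ".json")
  on.exit(unlink(path9), add = TRUE)
  saveStrategy(bad, path = path9)
  expect_error(loadStrategy(path9, dataset = ds), "S9")
  chainF <- filterChain(filterSpec("INFO.NOPE", ">", 1))
  pathF <- tempfile(fileext = ".json")
  on.exit(unlink(pathF), add = TRUE)
  saveStrategy(chainF, path = pathF)
  expect_error(loadStrategy(pathF, dataset = ds), "INFO.NOPE")
})

test_that("sessions support add/clear/save like an interactive panel", {
  ds <- standardDataset(n = 200, samples = 3, seed = 61)
  s <- minerSession(ds)
  expect_identical(survivors(s), variantIds(ds))

  s <- addFilter(s, filterSpec("INFO.DP", ">=", 150))
  n1 <- stepCounts(s@chain)[1]
  s <- addFilter(s, filterSpec("INFO.IMPACT", "in_set", "HIGH"))
  expect_length(stepCounts(s@chain), 2)
  expect_lte(stepCounts(s@chain)[2], n1)
  ## incremental evaluation equals evaluating the chain at once
  atOnce <- applyChain(ds, filterChain(s@chain@steps))
  expect_identical(stepCounts(s@chain), stepCounts(atOnce))

  s <- saveAnalysis(s, "deep")
  s <- clearFilters(s)
  expect_identical(survivors(s), variantIds(ds))
  expect_length(stepCounts(s@chain), 0)
  s <- addFilter(s, filterSpec("INFO.SOMATIC", "is_true"))
  ## both analyses remain retrievable
  expect_identical(survivors(getAnalysis(s, "deep")),
                   survivors(atOnce))
  expect_error(getAnalysis(s, "nope"), "no saved analysis")

  s0 <- clearFilters(minerSession(ds))   # clear on fresh session: no-op
  expect_identical(survivors(s0), variantIds(ds))
})
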