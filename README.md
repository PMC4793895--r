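# VariantSieve

Variant mining for annotated VCF files, as a scriptable R library and
command-line tool.

After alignment, variant calling and annotation, an exome or genome
yields tens of thousands of called variants in one VCF, and the job
becomes *mining*: trimming that list, step by step, down to the handful
of variants worth an investigator's attention — using whatever
annotations the file already carries, including private or
literature-derived ones, rather than a fixed annotation set imposed by
the analysis tool. VariantSieve implements that workflow for
bioinformaticians and analysts who want it reproducible in batch:
every interactive gesture (add a filter, group samples, paste in
ranges, save an analysis, clear, export) is a function call or a shell
command.

## The engine

**Metadata-driven ingestion.** The VCF header's `##INFO`, `##FORMAT`
and `##FILTER` declarations drive all parsing: values are coerced to
their declared `Type`, comma-separated entries become arrays, bare
INFO keys become flags, and `.` means *absent* (distinct from zero).
Files are validated up front — every undeclared key, malformed record
or type violation is reported with its line number and offending line.
Gzip compression is detected from the file content, and multi-allelic
records can be normalized to one alternate allele per row
(`Number=A`/`Number=R` fields sliced, AD rebuilt, GT indices
remapped).

**Genotype logic.** A sample's GT string is split on `/` and `|` and
the tokens that are neither `.` nor `0` are counted as alternate
alleles *n*:

- *n* = 0 → reference (or no-call if every token is `.`),
- *n* = 1 → heterozygous,
- *n* > 1 → homozygous.

The rule is ploidy-agnostic — `0/1` and `0/0/1` are both heterozygous —
so non-diploid organisms and mixed-ploidy calls work unchanged.
Alongside GT, the AD field is parsed as reference-then-alternate read
depths, and every numeric FORMAT field is summarized as a per-variant
minimum/maximum across samples (`FORMAT.DP.min`, `FORMAT.DP.max`),
all filterable.

**Sequential typed filters.** Fields are typed (numeric / flag /
string) from the header metadata, and each type has its operator
family (`< <= = >= > !=`, `is_true`/`is_false`,
`in_set`/`not_in_set`). Filters apply *consecutively*: step *i* sees
only the survivors of step *i−1*, and the survivor count after each
step is recorded — the running tabulation of an interactive left
panel. Because filters compose conjunctively, the final set is
order-invariant; the intermediate counts are not. Chains, group
definitions and range-annotation names save to versioned JSON
strategies that replay on other datasets (unresolvable references are
named errors, never silent drops).

**Group genotype queries.** A named sample group plus a quantified
condition — zygosity requirement (either / heterozygous / homozygous),
quantifier (any / all / at-least-fraction *p*, threshold
⌈*p*·|group|⌉), mode (require / exclude), optional minimum
alternate-read depth — expresses case/control and family designs:
"heterozygous in all nine samples", "homozygous in 50% of group 2,
and not in group 3", "exclude anything homozygous in any control".

**Ranges, trios, export.** BED files (0-based half-open) and pasted
ranges (`chr2:100-200`, 1-based inclusive) become boolean per-variant
fields `RANGE.<name>`. For a sequenced trio, `annotateInheritance()`
writes an `InheritancePattern` INFO field with labels AR / deNovo /
NonMendelian / XLD from an overridable rule table, and
`annotateCompoundHet()` flags child-heterozygous variants with a
partner in the same gene transmitted from the other parent (phase,
when present, must confirm opposite haplotypes). Survivors export as
tab-delimited tables with any column set.

## Worked example: mining a trio

```r
library(VariantSieve)

## deterministic synthetic trio with known planted patterns
res <- generateTrio(c(AR = 40, deNovo = 30, NonMendelian = 25,
                      XLD = 20, CompoundHet = 20, none = 300),
                    seed = 555)
path <- tempfile(fileext = ".vcf"); writeLines(res$vcf, path)

ds <- loadVcf(path)
ds <- annotateInheritance(ds, res$trio)
ds <- annotateCompoundHet(ds, res$trio)

s <- minerSession(ds)
s <- addFilter(s, filterSpec("INFO.InheritancePattern", "in_set",
                             c("AR", "deNovo", "NonMendelian", "XLD")))
s <- addFilter(s, filterSpec("INFO.IMPACT", "in_set", "HIGH"))
s@chain
#> FilterChain: 2 step(s), 455 variants before filtering
#>   1. INFO.InheritancePattern in_set {AR, deNovo, NonMendelian, XLD}  -> 115 remaining
#>   2. INFO.IMPACT in_set {HIGH}  -> 20 remaining

## pivot to the compound-het hypothesis without losing this analysis
s <- saveAnalysis(s, "inheritance")
s <- clearFilters(s)
s <- addFilter(s, filterSpec("INFO.CompoundHet", "is_true"))
s@chain
#> FilterChain: 1 step(s), 455 variants before filtering
#>   1. INFO.CompoundHet is_true  -> 40 remaining
```

455 variants drop to 115 matching an interesting inheritance mode,
then to 20 predicted loss-of-function candidates; clearing and
selecting compound heterozygotes instead keeps the 40 planted
pair-members. Both analyses stay retrievable
(`getAnalysis(s, "inheritance")`), and `exportTable()` writes the
survivors with any columns.

## Command line

```sh
inst/cli/variantsieve validate cohort.vcf.gz
inst/cli/variantsieve filter cohort.vcf.gz \
    --where "INFO.AF <= 0.01" \
    --where "INFO.IMPACT in HIGH" \
    --group "cases=S1,S2,S3" \
    --group-filter "cases:heterozygous:all:require:5" \
    --strategy-out strategy.json --out hits.tsv
```

Filter expressions are `FIELD OP VALUE` with `OP` one of `< <= = !=
>= > in not-in is-true is-false`; `in`/`not-in` take comma-separated
lists; append `@keep-missing` to let documents lacking the field
survive. Exit codes: 0 success, 1 validation/processing failure, 2
usage error.

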