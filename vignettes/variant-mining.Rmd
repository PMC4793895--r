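---
title: "Mining annotated variants with VariantSieve"
author: "VariantSieve authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining annotated variants with VariantSieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantSieve)
```

# The problem

A variant-calling pipeline ends with a VCF holding every called
variant together with whatever annotations were layered onto it —
caller metrics, population frequencies, impact predictions, private
institutional flags. Interpretation is then a *mining* exercise:
successively trimming non-relevant variants using those annotations
until a reviewable candidate list remains. VariantSieve is an engine
for doing this reproducibly: typed filters applied in sequence with a
survivor count at every step, quantified genotype conditions over
named sample groups, genomic-range labels, and trio inheritance
annotations, all scriptable and all exportable.

This vignette is the package's own account of its model: the parsing
and genotype rules, the filter and group semantics, the coordinate
conventions, the trio rule table, what the synthetic generator does
and does not emulate, and the numerical and design choices made where
the design was genuinely open.

# Metadata-driven parsing

Everything the parser does is driven by the header declarations.
An `##INFO=<ID=AF,Number=A,Type=Float,...>` line makes every `AF=`
value a float array with one entry per alternate allele; a field
declared `Flag` is `TRUE` when its bare key is present; `.` always
means the annotation is *absent* — deliberately distinct from zero or
the empty string, because sparse annotations are the norm and filters
need a well-defined missing-value semantics (below).

Two parse modes exist because real-world VCF dialects drift from
their headers. In **strict** mode an undeclared key or a value that
does not parse as its declared type is an error carrying the line
number — this is the mode `validateVcf()` uses, and the generated
validation report cites every offending line so a file can be fixed
before analysis. In **tolerant** mode (the `loadVcf()` default) the
value is retained as a string and a warning is logged, so a mostly
conformant file remains usable. Unsorted positions within a
chromosome are reported as warnings, not errors: they harm no
computation here.

Per-record memory is a contract: ingestion streams the file in
chunks, so file size is bounded by the document collection, not the
parse buffer. Gzip is sniffed from the content (via R's
content-sensing file connections), never the file name.

## Multi-allelic normalization

The engine accepts multi-allelic records but flags them, and
`normalizeMultiallelic()` splits each into one document per
alternate, because per-alternate annotations are only unambiguous at
one allele per row. The slicing rules: `Number=A` fields take the
matching element (arity mismatches are named errors), `Number=R`
fields keep the reference element plus the matching one, everything
else is copied. AD is rebuilt as reference depth plus the retained
allele's depth. GT indices are remapped so the retained alternate is
1; *other* alternates map to index 2 — the index value is arbitrary
by design, but it must stay non-reference so that a `1/2` sample
remains a carrier (and homozygous by the counting rule) in both
output rows.

# Genotype logic

Zygosity is defined by counting alternate alleles: split the GT
string on `/` and `|`, count tokens that are neither `.` nor `0`.
One alternate is heterozygous, more than one homozygous, zero is
reference (no-call when every token is missing). The definition is
ploidy-agnostic, which is the point: `0/0/1` from a triploid or
mosaic call is simply heterozygous.

Three consequences worth knowing:

* `1/2` — two *different* alternates — counts two alternate alleles
  and is classified homozygous. Biologically this is a
  heterozygous-alt site; the package follows the counting rule and
  documents the discrepancy rather than silently special-casing it.
* Half-calls like `./1` count the called alternate: heterozygous.
* We tokenize rather than literally deleting the characters
  `.`, `/`, `|`, `0` from the string, so multi-digit allele indices
  (`10`, `12`, ...) are not corrupted. For single-digit indices the
  two procedures agree on every GT string — the test suite proves
  this by exhaustive enumeration over ploidies 1–3 and allele
  indices 0–4.

AD is read as reference-supporting reads, then alternate-supporting
reads. More than two elements means an unnormalized record; the
second element is used, with a warning, unless the arity matches the
record's own alternate count (then it is expected, and silent).

# The filter chain

Each filter is typed — numeric, flag or string, with the matching
operator family — and validated against the dataset's field catalog
before evaluation. Chains apply consecutively: step $i$ is evaluated
only on the survivors of step $i-1$, and its survivor count is
recorded. Since every filter is a predicate AND-ed into the chain,
the final set is invariant under step order; the counts, which are
the exploratory signal ("which filter did the damage?"), are not.

Numerical choices:

* **Missing values.** Each filter carries an explicit
  `missingPolicy`, default `exclude_missing`. Sparse INFO fields
  make the alternative ("a missing PolyPhen score passes a PolyPhen
  filter") too surprising to be a silent default, but
  `include_missing` is one argument away. Flags are never missing:
  an absent flag is `FALSE`.
* **Numeric equality** uses a relative tolerance of `1e-9`
  (`|x − v| ≤ 1e-9·max(1, |v|)`), because every number in a VCF
  arrived through text parsing.
* **Array-valued fields** match when *any* element satisfies the
  operator; after normalization per-alternate arrays are scalars, so
  this matters mainly for unnormalized input.
* Operators `≥`, `>`, `≠`, `not_in_set` complete the operator
  families beyond the canonical `<`, `≤`, `=` examples.

Strategies — the chain, the group definitions it references, the
range-annotation names it expects — serialize to versioned JSON.
Loading validates against the target dataset when one is supplied:
a referenced field, sample or annotation missing from the new
dataset is an error naming the missing item. Counts are never saved;
a strategy is re-evaluated wherever it is applied.

# Group filters

A `GroupFilter` asks: do enough members of this group carry a
matching genotype? "Matching" combines a zygosity requirement
(either / heterozygous / homozygous — *either* means any
alternate-carrying call) with an optional minimum alternate-read
depth from AD; a sample without AD fails any depth requirement
rather than passing it. "Enough" is the quantifier: `any` (≥ 1),
`all` (= group size), or at-least-fraction $p$ with threshold
$\lceil p \cdot |\text{group}|\rceil$.

The ceiling-over-group-size choice was open ("in 50% of the group"
does not say how to round, nor whether uncalled samples count). We
fix: the denominator is the full group, uncalled samples never
match, and the threshold rounds *up* — a missing genotype must not
satisfy a requirement by arithmetic accident. `exclude` mode is the
document-wise negation of the corresponding `require` filter, which
is exactly what both control scenarios need ("exclude variants seen
in any control" = NOT(any control carries)). Duality, monotonicity
in $p$, `fraction(1.0) ≡ all`, and `all ⊆ any` are property-tested;
groups of ≤ 3 samples are checked against an exhaustive truth table
over all $4^3$ zygosity combinations.

# Coordinate conventions

Three conventions coexist and are fixed once: VCF POS is 1-based;
BED is 0-based half-open; pasted ranges `chrom:start-end` are
1-based inclusive. Internally everything becomes 1-based inclusive
intervals (held in a `GRanges`), so a BED interval `(99, 200]`
labels POS 100 and POS 200 `TRUE` and POS 99 `FALSE` — this exact
arithmetic is asserted in the tests, alongside a brute-force
membership oracle on randomized interval sets.

Membership is *point* semantics on POS: the REF span of an
insertion/deletion is not considered, because the source semantics
label "the variant", not its footprint. Span semantics would be a
straightforward extension. Chromosome names match by exact string
equality; an optional `normalizeChr` switch strips a `chr` prefix
on both sides for mixed-convention inputs (off by default — silent
renaming hides real mismatches).

# Trio annotations

The inheritance labels are a documented reconstruction (the source
workflow computed them with unpublished custom scripts), implemented
as a rule table the caller can override per label:

| Label | Rule (defaults) |
|---|---|
| `AR` | autosome; child homozygous, both parents heterozygous |
| `deNovo` | child carries ≥ 1 alternate; both parents called reference |
| `NonMendelian` | all three called, child's alternate count impossible given parental transmissible counts (reference → {0}, het → {0,1}, hom → {1}); the deNovo pattern is carved out and labeled deNovo instead |
| `XLD` | X chromosome; affected child carries; exactly one parent carries, and that parent is affected |

Y and MT variants receive no label. On X, a hemizygous male call
(`1`) counts as carrying — XLD works on carrier status, not
zygosity. The transmission check is restricted to diploid child
calls; polyploid genotypes simply go unlabeled rather than guessed
at. The 27 diploid genotype combinations on an autosome are checked
against a hand-written truth table in the tests.

`CompoundHet` flags a child-heterozygous variant V in gene G when V
is transmitted from exactly one parent and some other
child-heterozygous variant in G is transmitted from exactly the
other parent. "Transmitted from P" is strict: P carries the
alternate *and* the other parent is a called non-carrier — a variant
both parents carry has ambiguous origin and never anchors a pair
(configurable in principle; strictness is the default because the
whole point of the annotation is biparental origin). When both child
genotypes are phased, the two alternates must sit on opposite
haplotypes: phase *confirms* biparental origin instead of assuming
it, and a same-haplotype pair is vetoed even if the parental pattern
fits. The flag is symmetric in the pair and invariant under document
order.

# The document store

Documents live in an in-memory collection with stable integer ids —
a deliberately database-free stand-in chosen for desk-scale
reproducibility and zero deployment burden. Field paths are
dot-separated namespaces (`CORE.QUAL`, `INFO.DP`, `FORMAT.DP.min`,
`DERIVED.sample_count`, `RANGE.exome`). An index on a field is a
precomputed value column enabling a vectorized query path; indexing
is purely an execution detail and the tests assert bit-identical id
sets with and without one. No field is indexed by default. Datasets
snapshot to versioned JSON; on reload, values are re-coerced from
the header metadata and sample calls are rebuilt through the
genotype logic, so a reloaded dataset is behaviorally identical to a
freshly parsed one.

# The synthetic generator

All tests run on generated data; nothing is downloaded. The
generator emits a complete, strictly valid VCF whose composition is
parametric: per-call zygosity category is one multinomial draw with
defaults 30% heterozygous, 10% homozygous, 5% no-call — ordinary
values for a germline multi-sample call set — over three autosomes,
with read depths in the 5–45 range, a 20% sparse IMPACT annotation
(exercising the missing-value policies), an optional multi-allelic
fraction, and a single integer seed making output byte-identical
across platforms. The trio generator plants requested counts of each
inheritance pattern using the canonical genotype triplets (e.g.
`0/1 × 0/1 → 1/1` for AR), puts XLD variants on chrX with an
affected mother so the planted rows satisfy the affected-status
rule, gives compound-het pairs dedicated genes, shuffles, and
returns the per-variant ground truth with the matching `TrioSpec`.

What this emulates is *structure*, not population genetics: there is
no linkage disequilibrium, no realistic allele-frequency spectrum,
no error model correlating depth with genotype quality. Passing
tests therefore demonstrate that the engine's logic is exact on
well-formed input of realistic shape — they do not validate
biological discovery power on real cohorts, and real files will
additionally stress the tolerant-mode paths in ways clean synthetic
data cannot.

# Problem sizes and verification

The test suite checks the engine at the scale the properties need:
50 randomized filter chains against an independent per-document
linear-scan oracle on a seeded 1000-variant, 6-sample dataset;
exhaustive enumerations for the genotype rule (258 GT strings) and
group semantics (1152 truth-table cases); 50 indexed-vs-unindexed
query pairs; randomized range membership against brute force; planted
trio truth over 1000+ variants recovered with zero mismatches; and
export/strategy/compression round trips. `scripts/acceptance.R`
re-runs these measurements against the installed package from a
caller-supplied seed and writes the observed quantities as JSON.

# Known limitations

* Filter composition is conjunctive only; no OR trees.
* gVCF symbolic alternates (`<NON_REF>`) load as ordinary string
  alternates; reference blocks are not expanded.
* No VCF output: the export surface is tab-delimited tables,
  strategies and snapshots. Merging VCFs and annotation frameworks
  are out of scope.
* Allele-specific zygosity (which alternate a carrier carries) is
  not modeled beyond the multi-allelic split, and genotype
  likelihoods (PL/GL) are carried as opaque FORMAT values, not
  interpreted.
* The store is single-process and in-memory; a document-database
  backend could sit behind the same interface but none is shipped.
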