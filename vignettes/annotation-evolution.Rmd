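---
title: "Tracking annotation evolution and the expression of newly annotated isoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking annotation evolution and the expression of newly annotated isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotrack)
```

## The problem

Reference annotations for the human genome are revised several times a
year. Between successive releases, gene bodies and RNA isoforms are added,
dropped, and occasionally re-classified: a gene annotated protein-coding in
one release may carry a pseudogene biotype in the next and revert in the
one after. Because transcript-level quantification (particularly of
long-read RNA-seq) assigns reads against a specific release, the choice of
release determines which isoforms can be observed at all, and a
meaningful fraction of a gene's measured expression can come from isoforms
that simply did not exist in an older annotation. `annotrack` makes this
measurable with three kinds of computation: per-release censuses, set
algebra over feature identifiers across releases, and expression summaries
for the isoform set that is new between an old and a new release.

## Data model and identity across releases

A release is parsed from an Ensembl-dialect GTF into a validated
gene → transcript → exon hierarchy (`parse_gtf()`), with three modelling
commitments:

* **Coordinates.** GTF coordinates are 1-based and fully closed; an exon
  of `start..end` contributes `end − start + 1` bases. A transcript's
  length is the sum of its exon lengths (`transcript_length()`), never its
  genomic span. Strand is carried but unused by any statistic.
* **Identity.** Features are identified by their *unversioned* stable
  identifier (the trailing `.N` is stripped at parse time), because
  version suffixes differ across releases for unchanged features. The
  corollary is that an identifier *rename* upstream is indistinguishable
  from a drop plus an addition; no identifier-history resolution is
  attempted, and drop counts should be read with that in mind.
* **Contigs.** Older releases carry many alternative (haplotype/patch)
  contigs. The default allowlist keeps chromosomes 1–22, X, Y, MT and
  drops everything else *before* any counting, so censuses are comparable
  across releases; `contig_allowlist = "all"` disables this.

Biotypes are read from the `gene_biotype`/`transcript_biotype` attributes.
Some old dialects lack `transcript_biotype`; the parser then falls back to
the GTF source column and records the fallback in the release's
`provenance`, so downstream summaries can disclose it.

## Census statistics

`census()` counts features in total and per biotype; "protein-coding"
always means the biotype string equals `protein_coding` exactly, while
every other statistic uses all gene bodies regardless of biotype.
`isoforms_per_gene()` counts transcripts per gene (a gene feature with no
transcript rows counts as zero) and reports percentiles using linear
interpolation between order statistics (`stats::quantile` type 7, the R
default). The estimator matters on such heavily discrete distributions:
other types can shift a reported percentile by one isoform, which is why
the choice is fixed and documented. Thresholded counts use at-or-above
(≥), and the most isoform-rich gene is reported with ties broken
lexicographically by identifier so results are deterministic.

## Release comparison and biotype flips

`three_way_compare()` partitions the union of two or three releases'
identifier sets into disjoint Venn regions with exact membership. Under a
`biotype_filter`, an identifier belongs to a release's set only if it is
present *and* carries that biotype there. This convention is what makes
transient re-classifications visible: a gene present in all three releases
but re-biotyped in the middle one lands in the (first ∩ last) − middle
region of the filtered comparison. `find_biotype_flips()` intersects that
region with structural presence in the middle release, which separates
true flips from genuine drop/re-add cycles. The unfiltered (structural)
comparison is always available by leaving the filter unset, and with no
filter a flip cannot occur by definition.

Correctness of the set algebra is established against an independent
oracle: `venn_enumerate()` classifies every identifier by its membership
pattern one at a time, and randomized scripted series must agree exactly
(see the test suite's oracle-equivalence checks).

## Length metrics

`length_summary()` reports the 25th/50th/75th percentiles, N50 and total
bases of exon-sum lengths per harmonized biotype category. Two
conventions are fixed:

* **N50.** Sort descending; return the length at which the cumulative sum
  first reaches ≥ 50% of total bases — the dominant assembly-statistics
  convention. On ties the longer member's length is returned (it is
  reached first in the descending scan). N50 is always the length of some
  cohort member; it is *not* guaranteed to be ≥ the median.
* **Median.** Even-sized cohorts use the mean of the two central order
  statistics, which can produce a half-integer median on integer lengths.

The `lincRNA` biotype is merged into `lncRNA` (`harmonize_biotype()`)
because the label changed around 2020 while denoting a subset of the same
class; the merge applies at summary time only and never rewrites stored
biotypes. These annotation-derived lengths describe what read lengths
would be needed to span annotated isoforms end to end; they are not claims
about the in-vivo RNA length distribution, which depends on what is
actually expressed.

## Expression of newly annotated isoforms

`new_isoforms(old, new)` is a plain set difference of unversioned
transcript identifiers. Expression filtering follows the two-rule design
common in tissue-level long-read studies: per tissue, a transcript is
expressed when its **median unique counts > 1** and **median CPM ≥ 1**
across that tissue's samples. Both comparators are configurable
(`count_strict`, `cpm_strict`) because the strict/inclusive choice at the
boundary is a genuine convention; the default uses the strict count rule
and inclusive CPM rule. CPM uses per-sample library sizes (column sums of
unique counts), never tissue-pooled sizes; the normalization identity —
every CPM column sums to exactly 10⁶ — is enforced by test.

Relative abundance of the new-isoform subset is computed per sample as
`subset counts / all-of-the-gene's counts` and aggregated per tissue as
the median across samples, excluding samples where the gene has zero total
counts (a gene silent in a whole tissue yields no record rather than 0/0).
The per-sample-then-median route was chosen over pooling counts across the
tissue because it matches the median-based filtering style and resists
outlier samples; the pooled ratio remains available via
`method = "pooled"`. The denominator includes *all* of the gene's
transcripts present in the matrix, not only those passing the expression
filter, so the quantity reads as "share of total gene expression".
Because the complement subset's per-sample share is `1 − share` and the
sample median satisfies `median(1 − x) = 1 − median(x)`, new and old
summed abundances add to exactly 1 wherever the gene is expressed — an
invariant the tests exploit.

`abundance_threshold_summary()` counts genes whose subset abundance
exceeds a cutoff in *all* tissues (requiring a record in every tissue) and
in *at least one* tissue, with fractions over the genes considered.

## What the synthetic generator emulates — and what it does not

`generate_release_series()` emulates the *structure* of a decade-long
release series: a base release with a geometric isoforms-per-gene
distribution (long right tail), followed by scripted additions, drops,
transcript edits and reverting biotype flips, plus a few decoy genes on an
alternative contig to exercise the allowlist. The truth tables (Venn
memberships by per-identifier enumeration, scripted flips) are computed
independently of the set-algebra implementation they test.

`generate_counts()` emulates a nine-tissue, 58-sample long-read cohort
(samples per tissue 7/7/6/6/6/7/6/6/7). Unique counts are drawn from a
negative binomial with dispersion `size = 2` — strongly overdispersed, as
transcript-level long-read counts are — and library sizes are dominated by
20 background transcripts of mean 10⁵ counts, putting libraries near
2 × 10⁶ reads so that a CPM of 1 corresponds to about 2 counts and the CPM
rule is not vacuous next to the count rule. Planted structures make every
downstream answer known by construction: expressed transcripts are clamped
after sampling to at least 2 counts and ≥ 1 CPM in every sample of their
tissue, silent ones are capped at 1 count, boundary transcripts sit at
exactly 1 count (always failing the strict count rule, always passing the
inclusive one), and abundance genes carry fixed new:old count ratios
(0.75, 0.5, 1.0, 0.25 by default — interior and boundary shares). The
clamping is iterated with the recomputed library sizes until a fixed
point, so recovery tests are exact with zero tolerance; `clamp = FALSE`
gives raw negative-binomial draws for statistical rather than exact tests.

Two seeds govern the generator: `design_seed` fixes the planted design
(which isoforms are new, where they are expressed) and `seed` the count
draws. They are separate so that changing the sampling seed changes the
counts but never the truth tables — the invariant that makes seed-robust
exact-recovery testing possible.

Passing these tests shows the pipeline's algebra and filters are correct
on data whose truth is known. It does not show robustness to what real
data adds: quantifier-specific count artefacts, between-sample library
composition effects, annotation dialects outside the Ensembl GTF family, or
identifier renames — the last of these is a documented blind spot of any
identifier-based comparison.

## Numerical and degenerate-input choices

* Percentiles: `stats::quantile` type 7 everywhere, for consistency.
* Empty cohorts (after a biotype filter, or a gene silent in a tissue)
  return explicit empty summaries or omit records; they never throw.
* `n50()` on an empty or non-positive cohort is an error, as is a sample
  with zero library size (named in the message).
* Ties: biotype rankings and the max-isoform gene break ties
  lexicographically; N50 ties resolve to the longer member.
* Problem sizes in the test and acceptance runs (200 randomized release
  triples, 1,000 N50 cohorts up to n = 10,000, the 58-sample default
  cohort) were chosen as the smallest sizes that exercise every code path
  and tie-break while keeping the whole suite fast enough to run on every
  change.

## Known limitations

* Identifier renames appear as drop + add; coordinate-based fuzzy matching
  of renamed genes is future work.
* Only the Ensembl GTF dialect with explicit gene/transcript rows is
  supported; GFF3 and sequence-level (FASTA/CDS) analyses are out of
  scope.
* "Unique counts" semantics are inherited from the upstream quantifier and
  taken at face value; no re-quantification or differential testing is
  provided.
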