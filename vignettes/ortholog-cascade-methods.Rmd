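---
title: "Methods: ortholog cascades, conservation statistics and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog cascades, conservation statistics and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthocascade)
```

This vignette documents the models and procedures orthocascade implements,
the assumptions behind them, the parameter choices that were genuinely open,
and what the synthetic benchmark does and does not demonstrate about real
data.

## Orthology model

The package identifies orthologs by **reciprocal best hits** (RBH, the
"blast-back" criterion): a focal transcript *f* and a reference gene *r*
are called orthologous iff *f*'s single best alignment subject among the
reference set is *r*, and *r*'s single best subject among the focal set is
*f*. RBH is deliberately conservative: it yields a one-to-one relation by
construction and makes no attempt to resolve many-to-many families, recent
duplicates or lineage-specific expansions (tree- or graph-based orthogroup
inference is out of scope). Its main failure modes are paralog
interference (a recent duplicate outscoring the true ortholog) and
fragmentary queries losing reciprocity — both of which the synthetic
benchmark plants on purpose.

"Best" is defined by bit score, with a deterministic tie-break chain:
lower e-value, then higher percent identity, then lexicographically
smaller subject identifier. Alignment tools report multiple HSPs per
query–subject pair; the pair is represented by its single best HSP (not a
score sum) before queries are compared. Both choices are pragmatic — the
tie-break chain exists to make runs bit-for-bit reproducible rather than
to encode biology, and representing a pair by its best HSP is the simplest
defensible reading of multi-HSP output feeding best-hit logic.

Hits are first filtered at an e-value cutoff, default `1e-5`, a
conventional transcript-orthology threshold; it is exposed in every entry
point because no single value suits all database sizes.

**The priority cascade.** With several reference species, a focal
transcript may have RBH pairs in more than one. `cascade_assign()` makes
the set non-redundant by assigning each transcript to the *first* species
in a configured priority order for which a pair exists (default: human,
mouse, dog, ferret — most useful annotation first). The output size
therefore equals the union of the per-species focal-id sets, and adding
pairs to a lower-priority species can never reassign a transcript already
matched above it (monotonicity; asserted in the tests).
`shared_orthologs()` is the complementary intersection: transcripts with a
pair in *every* species, the natural frame for cross-species identity
comparisons.

## Identity statistics

Percent identity attached to a pair is taken from the focal→reference
direction's best HSP. `mean_identity()` averages per-pair percent identity
**unweighted** — each ortholog is one observation, regardless of alignment
length — which matches using gene counts as the sample sizes in the
z-test below.

`two_proportion_ztest()` implements the classical pooled two-proportion
z-score without continuity correction. Treating a *mean percent identity*
as a proportion with n = number of genes is statistically loose: identity
is a per-gene continuous quantity, not n Bernoulli trials, so the implied
variance model is not the estimator's true sampling variance. The package
implements the procedure because it is what the comparative analysis it
reproduces used (an online two-population-proportion calculator); the
function is documented as such and nothing downstream depends on its
optimality. The one-tailed direction is `p1 > p2`; callers order the
arguments. Two-tailed values are computed as `2·pnorm(-|z|)`, the
tail-stable form of `2·min(p_one, 1 − p_one)`.

`partition_by_conservation()` splits an identity-ranked gene list into k
contiguous subsets with the remainder placed in the *first* (most
conserved) partition: N = 6,952 and k = 10 gives 697 + 9×695.
Concatenating the partitions restores the input exactly. Ties in the
ranking are broken by gene identifier so partitions are reproducible.

`length_summary()` reports exact integer min/max/total, the mean, and the
sample (n−1) standard deviation by default (a flag switches to the
population form); histogram bins are left-closed right-open, width 500 bp,
starting at 0.

## Enrichment engine

`enrich()` tests each term of an `annotation_table()` for
over-representation in a gene set with the one-sided Fisher exact test:
with a = set genes carrying the term, b = set genes without it, c =
background-minus-set genes with it, d = the rest, the p-value is
P(X ≥ a) for X ~ Hypergeometric(N = a+b+c+d, K = a+c, n = a+b).

The implementation (`fisher_exact_greater()`) is vectorised and works in
log space: tables are grouped by their margins, each group's log-pmf is
evaluated once via `lchoose`, rescaled at its maximum, and tail-summed with
an exact reverse cumulative sum. This keeps p-values accurate far into the
tail (the tests compare it against `phyper` on every table with N ≤ 200,
agreeing to < 1e−12) while remaining fast enough to sweep tens of millions
of tables.

Design points that were genuinely open:

* **Background.** "Rest of the genome" is always an explicit background
  set carried by the annotation table; no implicit genome is assumed, and
  genes outside the background are dropped (with a reported count) before
  testing. Partition enrichment runs every partition against the *full*
  annotation background, not merely the partitioned genes.
* **EASE.** The DAVID-style conservative variant (one success removed:
  the table becomes (a−1, b+1, c, d)) is available behind `ease = TRUE`;
  plain Fisher is the default.
* **min_count.** Terms overlapping the set in fewer than 2 genes are not
  tested (DAVID's default behaviour), and the multiple-testing universe m
  is the number of terms passing that filter in the run. Consequently m
  can differ between gene sets annotated by the same table; the partition
  tests in the suite use terms broad enough to pass the filter everywhere
  when asserting a shared universe.
* **Adjustments.** "Bonferroni" is min(1, m·p); "Benjamini" is the
  Benjamini–Hochberg step-up FDR. Both delegate to `stats::p.adjust`; the
  tests pin them to the hand-evaluated closed forms.

## The synthetic benchmark

The generator emulates the situation the pipeline is built for: a focal
de novo transcriptome anchored to four reference gene sets.

* **Sequences.** Each ancestral gene is a random CDS (ATG, random sense
  codons, stop) of length 492 ± 150 codons (truncated at 67), flanked by
  75 bp untranslated ends. After fragmentation the mean focal transcript
  is ≈ 1.5 kb, matching the scale of a typical mammalian de novo
  assembly; the length *spread* of real assemblies (sd > 1 kb, extremes
  up to ~15 kb) is intentionally not reproduced.
* **Divergence.** A star phylogeny: the focal copy equals the ancestor and
  each reference species mutates it independently, so the configured
  per-species rate is the total pairwise divergence. Substitution is
  per-site without indels: n ~ Binomial(L, d) *distinct* sites change,
  each to a different base, so expected nucleotide identity is exactly
  100·(1−d) — a transparent oracle for the tests. Defaults: human 0.114,
  mouse 0.14063, dog 0.120, ferret 0.113, i.e. expected nucleotide
  identities ≈ 88.6 / 85.94 / 88.0 / 88.7%, the observed ordering for a
  shrew-like focal species (mouse most diverged; the dog value, not
  separately observable, is set between mouse and the carnivores).
* **Synonymous bias.** A fraction `synonymous_bias` of CDS substitutions
  is redirected to degenerate sites and made synonymous, emulating
  purifying selection; the rest are amino-acid-changing where possible and
  never create an internal stop. Protein identity exceeds nucleotide
  identity only when this fraction is above 2/3 — per codon, amino-acid
  identity ≈ (1−(1−b)d)³ versus nucleotide identity 1−d. The default
  b = 0.72 was calibrated once so the most-diverged species' amino-acid
  identity lands near 90% while its nucleotide identity is ≈ 86%, giving
  the realistic protein > nucleotide pattern (≈ 92% amino-acid identity
  for the human-like rate).
* **Confounders.** Per-species per-gene ortholog dropout (default 0.15),
  reference-side paralog duplicates mutated a further 0.08 beyond the
  species rate (so the true ortholog outranks its paralog in score),
  focal fragmentation to uniform windows of ≥ 201 bp (default rate 0.15,
  mirroring the short incomplete assemblies real data contains), and
  spurious low-identity hits (60–75% over 50–150 columns) at a Poisson
  rate per query.
* **Hit tables.** Because evolution is indel-free, homologous sequences
  share coordinates and the emitted percent identity is an *exact*
  positionwise Hamming identity over the aligned window (protein-level
  tables use the in-frame codon overlap of the fragment with the CDS).
  The bit score surrogate is max(0, 2·matches − 3·mismatches) and the
  e-value surrogate 1e9·2^(−bitscore) — deterministic, monotone, and
  explicitly *not* calibrated to BLAST statistics; only their ordering
  matters downstream.
* **Annotations.** Background terms are Bernoulli(base_rate) gene sets; a
  planted term is over-represented in a chosen target subset at a stated
  fold (membership probability min(1, fold·base_rate)); fold = 1 is
  indistinguishable from background by construction.

What passing tests therefore show: the pipeline's set logic, scoring and
statistics are correct against planted truth, and recovery is exact when
the data contain no confounders. What they do not show: robustness to
indels, alternative isoforms, assembly chimeras, real alignment score
statistics, or annotation structure (GO graphs, term correlation) — none
of which the generator attempts.

## Numerical and testing choices

* All randomness flows from a single integer seed; stage-level generators
  derive fixed offsets from it, so identical configurations are
  byte-identical on disk (asserted via checksums).
* The exact-test calibration check compares null p-values to the uniform
  distribution with a Kolmogorov–Smirnov test. A discrete exact test is
  conservative and lattice-valued, so this comparison is only meaningful
  when the hypergeometric support is fine: the check uses a 250-gene
  target at 50% membership (support sd ≈ 8, max atom ≈ 0.05). At sparse
  margins KS would reject for discreteness alone, which is a property of
  exact tests, not a calibration failure.
* Problem sizes in the suite were chosen to exercise the asymptotics while
  staying desk-sized: recovery fixtures use 500 genes across 4 reference
  species (20 seeds for the dropout experiment), the enrichment power and
  calibration checks use 100 and 200 replicates, and the Fisher engine is
  swept exhaustively over all ~7×10⁷ contingency tables with N ≤ 200.
* Degenerate inputs fail loudly and early: empty transcript sets, empty
  pair sets, pooled proportions of exactly 0 or 1, fewer genes than
  partitions, termless annotations, and gene sets disjoint from the
  background are all hard errors rather than silent NAs.

## Known limitations

RBH-based orthology inherits all the caveats above; the z-test reproduces
a procedure rather than a recommended analysis (a Welch t-test on per-gene
identities would be the statistically natural choice); identity from a
single best HSP under-represents genes whose homology is split across
HSPs; and the simulator's indel-free, star-topology evolution makes
alignment trivial by design — it validates bookkeeping and statistics, not
aligner behaviour.
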