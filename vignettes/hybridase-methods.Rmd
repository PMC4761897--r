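---
title: "Models and methods behind hybridase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridase)
```

hybridase analyses allele-resolved RNA-seq from F1 hybrids of sequenced
parental strains. This vignette is the package's account of the models it
fits, the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic-data validation does and does not
demonstrate.

## Why hybrids

In an F1 hybrid both parental alleles share one nucleus, so the trans
environment is identical for the two alleles of every gene. A reproducible
expression difference between the alleles (ASE) therefore reflects
cis-acting variation. The complementary contrast — the same parental allele
followed across hybrids with different partner strains — isolates trans
effects: if a partner strain carries a hyperactive transcription factor,
that allele's expression rises specifically in that partner's context. The
package's stages mirror these two contrasts.

## Allele-specific read classification

Reads are classified against pairs of orthologous, equal-length ORF
sequences (`pair_alleles`). The package deliberately replaces short-read
alignment with exhaustive exact-coordinate placement: each read (and its
reverse complement) is slid over every offset of both alleles and the
mismatch count computed at each placement (C-level via Biostrings). This is
exact and auditable under the substitution-only divergence model the
generator produces; it is not a general aligner (no indels, no splicing, no
multi-gene ambiguity). Coordinates are 0-based half-open; promoter windows
use signed offsets relative to the ATG with −1 the base immediately
upstream, defaulting to (−250, −50).

Classification rule: among placements achieving the minimal mismatch count
(over both strands and both alleles), a placement that covers at least one
discriminating position and separates the alleles wins, forward strand
first, then leftmost; the read goes to the allele with strictly fewer
mismatches there. Reads with no such placement, or whose best placement
exceeds `max_mismatch`, are uninformative. The "prefer a discriminating
placement" tie-break matters only for repetitive sequence, where a read can
match both alleles perfectly at different offsets; it is pinned by a
brute-force enumeration test.

Genes are never silently dropped: pairs carry flags (`has_N`,
`missing_in_strain`, `length_mismatch`) and downstream tables carry reason
codes.

## ASE: normalization, filtering, testing

**TMM.** Library composition is normalized with trimmed means of M-values
(reference column by the upper-quartile rule; two-sided trims of 0.3 on M
and 0.05 on A; inverse-variance weights; factors rescaled to geometric mean
1). The implementation is pinned both to a plain-loop re-implementation and
to edgeR's `calcNormFactors` on shared fixtures.

**Filters.** Two detectability rules are kept side by side because they
answer different questions: `hybrid_detectable` (≥ 10 reads per allele in
at least one replicate of that hybrid) gates per-hybrid testing, while the
stricter UDA rule (≥ 10 reads per allele in *every* replicate of *every*
hybrid) defines the gene set comparable across crosses. Both readings
appear in the field's usage; implementing both flags avoids guessing a
single intent.

**Dispersion and test.** The two alleles of a gene are treated as the same
gene in two conditions with replicate negative-binomial counts and a single
table-wide dispersion φ (variance μ + φμ²), estimated by conditional
maximum likelihood on counts scaled to equalized effective library sizes.
Per gene, counts are scaled to a common size, group sums rounded, and a
two-sided exact p-value computed by conditioning on the total: all splits
whose conditional probability does not exceed the observed one contribute.
At φ = 0 this collapses to the conditional binomial. Tagwise or trended
dispersion is deliberately out of scope: a common dispersion keeps the test
fully specified and oracle-testable, and the simulated data are generated
with a common dispersion. Log ratios use a 0.5 pseudocount so M is finite
at zero counts.

**Multiple testing.** Storey q-values (π0 from the λ-grid 0.05–0.95 with a
df = 3 smoothing spline evaluated at λ = 0.95, clipped to (0, 1]) with a BH
fallback; for fewer than 100 tests π0 is fixed at 1, where the spline
estimate would be noise. "Significant ASE" defaults to q < 0.05.

## Binding: GOMER occupancy and ASB

A motif is a position frequency matrix θ (rows = positions, columns =
A,C,G,T), pseudocounted by α = 0.01 per entry at load. The per-window score
is the PWM probability p_i = Π_j θ[j, base_j], and promoter occupancy
aggregates over all windows on both strands under the independent-sites
assumption: P_bound = 1 − Π_i (1 − p_i), computed in log space
(`-expm1(sum(log1p(-p)))`) so a perfect site yields exactly 1. The
probability-product mode is the pinned default; an affinity-saturation mode
(p_i = K_i/(1+K_i), K_i = Π θ/background, uniform background 0.25) is
available behind a flag, since the occupancy literature admits both
formulations and neither is canonical. Windows overlapping N are skipped
with a warning; other non-ACGT characters are errors. ASB is the difference
of P_bound between alleles, antisymmetric and bounded in [−1, 1] by
construction.

`snp_binding_report` attributes binding changes to individual SNPs by the
best window score overlapping each discriminating position in each allele;
rows are ranked by absolute score change rather than relative change,
because near-zero background windows produce huge relative changes with no
binding relevance.

## Cis mapping: ASB against ASE

For each TF and hybrid, ASB is correlated with the hybrid-specific ASE
log-ratios across genes (positive R = activator-consistent). Genes with
near-zero ASB are retained — most ASB values are near zero because most TFs
do not bind most promoters, and filtering them would bias the null. The
null distribution permutes the *gene labels of the ASE vector* within a
hybrid, which preserves the correlation structure of ASB across TFs (many
motifs respond to the same SNP); the two-sided empirical p is
(1 + #{|R_null| ≥ |R_obs|}) / (n_perm + 1). Pooled observed-versus-permuted
correlation distributions are compared by a two-sample K-S test; both
per-hybrid and across-hybrid poolings are exposed, with the across-hybrid
pooling used in validation because a 50-motif pool gives the K-S statistic
little resolution. Per-motif significance uses the analytic Spearman test
with Bonferroni correction, with the permutation p carried alongside.

## Trans mapping: CSE and TF activity

Expression for CSE is TMM-normalized across all libraries jointly and
averaged over replicates, giving Expr(a, b) per (gene, query allele a,
partner b). Then CSE(a, b) = 2(Expr(a,b)+ε) / ((Expr(a,c)+ε)+(Expr(a,d)+ε))
with ε = 0.5 normalized counts guarding division by zero; genes with both
backgrounds zero before pseudocounting are flagged invalid and excluded
from tests.

TF target sets come from motif scores (best single-window score per
promoter, averaged across strains): genes with at least half the maximum
observed score, floored at the top 50 and capped at the top 10% of scored
genes, ties broken lexicographically. Targets and non-targets are compared
by a Welch t-test on log2 CSE — log because CSE is a right-skewed ratio,
Welch because the groups are very unequal in size. Per (TF, foreground), the
three query parents are tested separately for the sign-consistency
requirement and pooled for the single p-value that enters one BH family
across all complete (TF, foreground) pairs (α = 0.1); a pair is significant
only if q ≤ 0.1 *and* all three per-query mean differences share a sign.
Pooling for the p and using per-query results only for consistency yields
one row per (TF, foreground), matching how such results are naturally
tabulated.

A consequence worth knowing: because CSE is relative to background
contexts, a genuine activity increase of TF t in strain b also depresses
CSE of t's targets in foregrounds whose backgrounds include b. Symmetric
"down" calls for the same TF in other contexts are therefore expected
companions of a true "up" call, not false positives.

## Directional allelic selection and enrichment

An allele of parent s is maximally (minimally) expressed when its ASE is
significant at q < 0.05 with consistent sign, oriented toward s, in all
three hybrids containing s, restricted to UDA genes. This is an explicit
significance-and-sign rule, not a rank statistic. Enrichment of these sets
against GMT collections is a one-sided hypergeometric upper tail with BH
correction (default universe: the UDA set), reporting fold enrichment
(overlap/set) / (category∩universe/universe).

## The synthetic-data generator

The generator emulates the statistical structure of a four-strain,
six-hybrid, three-replicate study:

* **Sequences.** Uniform-composition ancestral promoters (200 bp) and ORFs
  (500 bp); each strain mutates independently at snp_rate/2 per bp so
  pairwise divergence is ~snp_rate (default 0.005 ≈ 1 SNP/200 bp).
  Substitutions only — coordinates stay aligned; indels are a non-goal.
* **Counts.** μ[g, col] = L[col]/n_genes · 2^cis[g, allele] · Π_TF
  activity(TF, partner)^target(g, TF), with NB noise (variance μ + φμ²) and
  column totals drawn from `library_size_range`. Trans activity acts on an
  allele through its hybrid *partner's* TF activities, which is precisely
  the contrast CSE measures. The default φ = 0.05 (biological CV ≈ 22%) is
  a modelling choice typical of replicate RNA-seq in this setting, not a
  measured value; it is the single knob that most affects ASE power.
* **Plants.** `plant_motifs` embeds a motif's consensus at a recorded
  offset (same offset in all strains) and can disrupt one strain's copy by
  a single substitution at the motif's highest-information position,
  optionally lowering that allele's expression by `cis_link_log2` — the
  intact-versus-broken binding site polymorphism that links ASB to ASE.
* **Reads.** Uniform read starts along the ORF of the labelled allele,
  random strand, independent substitution errors; labels retained.

All randomness flows from one seed with fixed per-operation offsets, so
identical configurations reproduce byte-identical outputs and partial
re-runs stay reproducible.

What passing the synthetic validation shows — and what it does not: the
generator matches the pipeline's distributional assumptions (NB counts,
common dispersion, substitution-only divergence, independent binding
sites). Real libraries add unmodelled structure: alignment bias toward the
reference allele, indel divergence, correlated dispersion, nucleosome and
chromatin effects on binding, and motif redundancy between paralogous TFs.
Calibration and power measured here are therefore upper bounds on real-data
behaviour, and per-gene causal attribution of ASE to a specific TF is
explicitly out of scope.

## Validation scale and observed behaviour

The packaged validation (tests and `scripts/acceptance.R`) uses problem
sizes chosen to exercise every stage at study scale while staying quick on
one CPU: 2,000 genes for ASE calibration/recovery, 1,000 genes × 50 TFs ×
six hybrids with 1,000 permutations for cis mapping, 1,000 genes × 8 TFs ×
20 seeded repetitions for CSE recovery, and a 300-gene demo pipeline run
twice for manifest-identical reproducibility.

Two honest findings from this validation are pinned rather than hidden.
First, with φ = 0.05, per-allele means near 200 and three replicates, the
exact test recovers planted |log2| = 1 cis effects at q < 0.05 with ~75%
power (the standard-error floor of a log fold change at this dispersion is
≈ 0.27, and edgeR's exact test measures the same on identical data); the
empirical FDR stays below 5% and the effect-size estimate is unbiased to
within 0.02. Second, in the planted cis-map study, decoy motifs are *not*
a clean null — windows overlapping a disruption SNP respond to it, so
decoys inherit a little real signal; decoy calibration is therefore
demonstrated on a matched no-link simulation, where their permutation
p-values are uniform.

## Numerical and degenerate-input choices

* GOMER products and complements are computed in log space; P_bound is
  exact at 0 (promoter shorter than motif) and 1 (a probability-1 window).
* The exact test's conditional distribution is renormalized in log space;
  the probability-ordering comparison uses a 1 + 1e−10 relative slack so
  ties at the observed probability are included deterministically.
* Dispersion optimization runs on log φ over [1e−6, 5] with an explicit
  boundary check returning the lower bound when the likelihood is
  monotone decreasing (no overdispersion signal).
* Welch's test is hand-rolled so identical constant groups return t = 0,
  p = 1 instead of erroring; under-sized groups are flagged untestable and
  excluded from the BH family.
* `NAm` is used as the default name of the North American strain because a
  literal `NA` string is indistinguishable from missingness in tabular
  round-trips.

## Known limitations

No indel handling, no multi-gene read ambiguity, no tagwise dispersion, no
isoform resolution; GOMER treats windows as independent and ignores
chromatin; CSE requires exactly four strains (one foreground, two
backgrounds per query); enrichment assumes the supplied GMT is the full
annotation universe of interest.
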