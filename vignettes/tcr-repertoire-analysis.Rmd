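---
title: "Models and methods behind tcrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tcrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tcrep` analyses T cell receptor beta-chain (TCR-β) immune repertoires: it
takes sequencing reads covering the CDR3 region (real or simulated), calls
the germline V and J gene segments, extracts the CDR3, collapses reads into
clonotypes, and computes the expansion, diversity, gene-usage, sharing and
amplification-bias statistics that repertoire studies report. This vignette
explains the underlying models, the tunable parameters, the numerical
conventions, and the boundaries of what the simulation-based validation can
show.

## The biological setting

A TCR-β chain is assembled by somatic recombination of V, D and J gene
segments. Exonuclease trimming of the segment ends and random non-templated
(N) nucleotide insertion at the two junctions make the third
complementarity-determining region (CDR3) hypervariable, so the CDR3
nucleotide sequence — here keyed together with the V and J family — serves
as a clonotype identifier. By IMGT convention the CDR3 is delimited by a
conserved cysteine near the V end and the conserved phenylalanine of the
J-segment F-G-X-G motif. `tcrep` reports the CDR3 *without* those anchor
residues, matching how expanded clones are conventionally printed (e.g.
`ATAGLAGETQY` for the package's worked TRBV15–TRBJ2-5 example).

In autoimmune settings such as type 1 diabetes (T1D), a few clones expand
massively: clones holding at least 1% of a sample's reads are called
highly-expanded clones (HECs), everything below that lowly-expanded clones
(LECs). The package's statistics quantify that skew and compare it across
cohort arms.

## Diversity statistics

For clone frequencies $p_1,\dots,p_n$ the normalized Shannon entropy is

$$H = \frac{-\sum_{i=1}^{n} p_i \log p_i}{\log n},$$

which maps any repertoire to $[0,1]$: 1 for a perfectly even repertoire, 0
for a single clone ($n = 1$ returns 0 by convention, since $\log 1 = 0$
leaves the ratio undefined). The log base cancels; natural logarithms are
used internally. Entropy is computed on nucleotide-level clonotypes by
default (the finest observed partition); `diversity_report(level = "aa")`
gives the amino-acid-level variant for sensitivity analysis. $n$ is the
number of *observed* clonotypes — no richness extrapolation is attempted.

Two numerical caveats are worth knowing. First, frequencies must be
positive and sum to 1 within $10^{-6}$ (they are renormalized internally);
zero frequencies are an input error rather than being silently dropped.
Second, while the unnormalized Shannon sum can only decrease when two
clones are merged, the *normalized* index can increase, because $\log n$
shrinks too — e.g. $\{0.999, 5\times10^{-4}, 5\times10^{-4}\}$ has
$H = 0.0079$ but merging the two rare clones gives $H = 0.0114$. The test
suite therefore asserts merge-monotonicity on the unnormalized sum.

HEC calling uses an *inclusive* threshold: frequency $\ge$ 1% is expanded.
The `hec_ratio` is the total read fraction held by HECs. Both respond
monotonically to the threshold, and a sample can hold at most
$1/\text{threshold}$ HECs.

## The annotation model

Reads are annotated in three steps:

1. **Pair merging** (for overlapping paired-end data): a quality-aware
   overlap merger scores every candidate overlap of at least `min_overlap`
   bases as `matches − 2·mismatches`, requires the mismatch rate to stay
   under `max_mismatch_rate`, and resolves overlap disagreements toward the
   higher-Phred base (ties to mate 1; score ties to the longer overlap).
2. **Germline alignment**: each read is aligned against every V segment
   with a *glocal* dynamic-programming alignment — the germline segment
   aligned end to end, the read locally — scoring match +1, mismatch −1,
   linear gap −2 (implemented in C++; exhaustive over the reference, no
   heuristic seeding). The read suffix 3′ of the V match is then aligned
   against every J segment the same way. Identity is
   matches/aligned-columns × 100 over that segment-spanning alignment.
   Requiring the segment to align end to end is what makes the identity
   filter meaningful: a purely local alignment of a random read can find a
   short high-identity island and sail past any threshold, whereas its
   glocal identity sits near the random-match level. Score ties break to
   the lexicographically smallest segment id, making calls deterministic.
   D segments are not assigned (no D-level statistic is computed).
3. **CDR3 extraction and productivity**: the conserved anchor codons are
   located on the read by a second glocal pass against only the conserved
   part of the segment (V up to and including the Cys codon; J from the
   Phe codon onward) — the bases beyond the anchors are exactly the ones
   junctional trimming removes, and letting them compete for alignment can
   otherwise shift gaps into the anchor codon. The CDR3 is the nucleotide
   span strictly between the anchor codons; a rearrangement is productive
   when that anchor-to-anchor span is a multiple of 3 and the translation
   contains no stop codon. Translation never applies initiator-codon rules
   (a CDR3 starting with CTG is Leu, not Met).

The identity filter keeps reads whose V *and* J identities are at least the
threshold (default 70%). The boundary is inclusive: the exclusion rule
("identity below 70% is excluded") is read literally, so exactly 70.0
passes. Unproductive reads are retained in the annotation table with
`productive = FALSE` but never enter clonotype frequencies — the frequency
denominator is productive, filter-passing reads only, since only those
carry a countable CDR3.

Coordinates are 0-based half-open internally; the AIRR-style output table
carries 1-based positions only where human-readable.

## The synthetic repertoire generator

Because deep repertoire data are rarely redistributable, the package ships
a ground-truthed generator whose defaults emulate the two regimes the
analysis is designed to distinguish:

* `even_lognormal` — near-even, control-like repertoires: clone
  frequencies are normalized $\exp \mathcal{N}(0, \sigma^2)$ with
  `lognormal_sigma` defaulting to 1 (σ = 0 gives an exactly uniform
  repertoire; σ = 2 approximates the heavier, power-law-like skew of real
  peripheral blood).
* `hec_dominated` — the autoimmune-like regime: `n_expanded` clones
  (default 22) jointly hold `expanded_mass` (default 0.77) of the reads,
  the published median for T1D CD4⁺ samples. Expanded frequencies are
  drawn as $0.01 + (\text{mass} - 0.01\,n_e)\cdot\text{Dirichlet}(2)$ — an
  exact floored Dirichlet that guarantees every expanded clone meets the
  1% HEC definition while summing exactly to the target mass. Requesting
  $n_e \times 0.01 > \text{mass}$ is an infeasibility error.

Rearrangements are built as V-segment (3′-trimmed) + N-insertion +
trimmed D + N-insertion + J-segment (5′-trimmed). Trimming lengths are
geometric with mean 2 nt per flank, capped at the available bases so the
conserved anchors always survive; each N region is uniform on 0–10 nt.
Draws are redrawn until productive by default. Because the geometric cap
collapses rather than re-draws, the junction-length law is exactly
enumerable by convolution — the test suite checks simulated CDR3 lengths
against that independent enumeration with a chi-square test.

Sequencing is modeled as multinomial read sampling with optional per-base
substitution error (indels are deliberately omitted so CDR3-length
statistics reflect junctional biology, not error); paired mode splits each
fragment into two mates overlapping by a configured number of bases. PCR
amplification bias multiplies each clone's frequency by
$\exp\mathcal{N}(0, \sigma_c^2 \cdot \text{cycles})$ — independent
lognormal per-cycle deviations, with $\sigma_c = 0.076$ as the regime
matching a per-cycle bias near 1.076 accumulating to about 2.09-fold over
10 cycles. No efficiency saturation is modeled.

What the generator does *not* emulate: thymic selection and HLA
restriction (clone sequences are exchangeable), PCR chimeras and
crossover artifacts, indel sequencing error, UMI structure, and any
antigen-driven correlation between samples. Passing recovery tests on
simulated data therefore demonstrates the *pipeline's* correctness, not
robustness to every real-data pathology; with substitution error enabled
and no error-correction clustering (none is applied, matching the
analysis being reproduced), sequencing error inflates singleton
clonotypes, which is why recovery tests run error-free.

## Clonotypes, usage and sharing

Clonotypes are keyed by (CDR3 nucleotide sequence, V family, J family);
allele-level calls collapse to families for all statistics. Cross-sample
sharing works at the amino-acid level only (two nucleotide clonotypes
translating to one peptide merge there), and a match across samples does
not require V/J identity.

Usage profiles, VJ combination matrices and CDR3-length spectratypes are
read-weighted by default (`weight = "clone"` is available), over family
lists fixed by the reference so vectors align cohort-wide; VJ matrix
marginals equal the usage vectors exactly. Pairwise Pearson correlation of
usage vectors compares gene-usage structure between samples; a
zero-variance vector yields `NA` (undefined), never 0.

Shared-clone records cover every CDR3 that is a HEC in at least one
case-group sample and classify each as **type 1** (present — expanded or
not — in at least one non-case sample) or **type 2** (absent from every
non-case sample), a partition. Records rank by the number of case samples
in which the clone is expanded, ties broken lexicographically. The
"over half" summary counts clones expanded in strictly more than half of
the case samples. No significance test is attached to sharing: the full
ranked list is emitted and any display truncation is a plotting choice.

## Cohort comparison

Group comparisons use the classical unpaired two-tailed *t*-test. The
package defaults to the pooled-variance (Student) form; note that plain
`t.test()` in R defaults to the Welch form — the reference analysis names
only "unpaired 2-tailed t-test", so the choice is genuinely ambiguous and
`var_equal = FALSE` switches to Welch. When both groups are constant with
equal means the test returns $t = 0, p = 1$ by convention; constant groups
with unequal means are an error rather than an infinite statistic. Raw
p-values are reported without multiplicity correction (none is applied in
the analysis being reproduced); the comparison table prints them together
so users can correct downstream.

Simulation calibration (frequency-level, 9-vs-6 samples as in the cohort
design): on 2000 null cohorts the test rejects at close to its nominal 5%,
and with the case arm in the `hec_dominated` regime the entropy difference
reaches $p < 0.05$ in at least 95 of 100 seeded cohorts.

## PCR amplification-bias estimation

Multiplex PCR can amplify clones unevenly. The estimator compares two
sequencings of the same template at cycle numbers $c_1 < c_2$: each
clone's expected high-cycle count is its low-cycle count scaled by the
depth ratio, the per-clone fold variation is
$v = \max(\text{obs}/\text{exp},\ \text{exp}/\text{obs})$, clones are
binned by low-cycle count into log-spaced bins (merged to keep at least 20
clones per bin), and the accumulated bias $k$ is the intercept-only
least-squares level of the bin means, with a linear regression on
$\log_{10}$ count reported as a diagnostic. The per-cycle bias is
$k^{1/(c_2-c_1)}$, an exact algebraic identity of the outputs. This is one
admissible reading of an under-specified published regression; it is
chosen because it reproduces the $k^{1/\Delta c}$ accumulation arithmetic
and is robust to depth differences.

Two properties to keep in mind: $v \ge 1$ elementwise, so $k \ge 1$ by
construction; and multinomial sampling noise is *not* subtracted, so at
low counts $k$ upper-bounds pure amplification bias. In the simulated
cycle series, per-clone log-bias accumulates *across* cycle points (the
25-cycle product inherits the 15-cycle bias plus fresh deviations for the
10 extra cycles), matching the interpretation that low-to-high-cycle
variation reflects only the added cycles. The companion
`vgene_usage_stability()` check reports the mean absolute relative
deviation of V-family usage between cycle points over the top families —
a family-level primer-balance diagnostic.

## Problem sizes and test design

The validation suite runs entirely on the built-in synthetic reference
(10 V, 2 D, 7 J families) at sizes chosen to keep the full suite around a
minute while leaving comfortable statistical margins: clonotype-recovery
at 2×10⁵ error-free reads over 10³ clones (total-variation distance
< 0.02 — note the sampling floor $E[\mathrm{TV}] \approx 0.4 \sum_i
\sqrt{p_i} / \sqrt{N}$ makes this bound meaningful only for realistically
skewed repertoires, so that test uses `lognormal_sigma = 2`), annotation
recovery on 10⁴ reads, bias recovery on 10⁴ clones at 10⁶ reads per cycle
point, 2000 null cohorts for type-I calibration, and 100 seeded cohorts
for power. Fixed seeds make every stochastic test reproducible; none of
the generator defaults were tuned to the tests.

## Known limitations

* The built-in reference is synthetic: family names and anchor motifs are
  realistic, sequences are not real germline alleles. Swap in a real
  reference via `load_germline()` (FASTA + anchor sidecar) for real data.
* The aligner is exhaustive dynamic programming against a small reference;
  for references with hundreds of alleles a seeded aligner would be
  preferable.
* No UMI handling, no error-correction clustering, no D-segment calls, no
  per-family over-usage test (the last is deliberately unimplemented: no
  defensible test/threshold/correction is specified in the analysis being
  reproduced, and guessing one would invite misuse).
* Cohort tests adjust for nothing (age, sex, HLA); with the small arm
  sizes typical of pilot repertoire studies, confounding is a real risk
  that the statistics here do not address.
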