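# tcrep

Analysis and simulation of T cell receptor beta-chain (TCR-β) immune
repertoires in R.

Repertoire sequencing reads the hypervariable CDR3 region of the TCR-β
chain across millions of T cells, turning "how clonal is this person's
T cell compartment?" into a measurable quantity. In autoimmune disease a
handful of clones can expand to dominate the repertoire; quantifying that
skew — and asking whether the same expanded clones recur across patients —
requires a pipeline from raw reads to clonotype statistics. `tcrep`
provides that pipeline for analysts working with TCR-β amplicon data or
studying the statistical behaviour of repertoire metrics:

* a **ground-truthed simulator** of VDJ rearrangement (geometric trimming,
  uniform N-insertions, productivity selection), clone-abundance regimes
  (near-even lognormal vs. HEC-dominated), multinomial sequencing with
  substitution error, and per-cycle multiplicative PCR bias;
* **annotation**: quality-aware paired-end merging, exhaustive glocal
  alignment to germline V/J segments (match +1, mismatch −1, gap −2, in
  C++), a ≥70% identity filter, IMGT-convention CDR3 extraction between
  the conserved Cys and Phe anchors, and productivity calling;
* **clonotype tables** keyed by (CDR3 nt, V family, J family) with
  amino-acid-level aggregation;
* **diversity and expansion statistics**: highly-expanded-clone (HEC)
  calling at the inclusive ≥1% threshold, HEC ratio, and the normalized
  Shannon entropy
  `H = −Σ pᵢ log pᵢ / log n ∈ [0, 1]` (1 = maximally even, 0 = one clone);
* **V/J usage** profiles, pairwise Pearson usage correlations, V×J
  combination matrices, CDR3-length spectratypes;
* **cross-sample sharing**: per-sample HEC/LEC/absent status for every
  case-expanded CDR3, classified as type 1 (present in non-case samples)
  or type 2 (case-unique);
* **cohort comparison** via the classical unpaired two-tailed *t*-test
  (pooled variance by default, Welch optional);
* **PCR amplification-bias estimation** from cycle-series experiments:
  accumulated fold bias `k` and per-cycle bias `k^(1/Δcycles)`.

A small synthetic germline reference (10 V, 2 D, 7 J families with IMGT
anchor metadata) ships with the package so everything runs without
downloads; real references load from FASTA plus a tab-separated anchor
table.

## Worked example

Simulate one autoimmune-like sample — 1000 clones of which 22 expanded
clones jointly hold 77% of reads — sequence it, annotate, and summarise:

```r
library(tcrep)

db    <- builtin_toy_reference()
model <- repertoire_model(1000, "hec_dominated", n_expanded = 22,
                          expanded_mass = 0.77, lognormal_sigma = 1, seed = 1)
truth <- simulate_repertoire(model, db)
sim   <- simulate_reads(truth, sequencing_model(n_reads = 2e4))
ann   <- annotate_reads(sim$reads, db)
s     <- build_clonotypes(ann, sample_id = "T1D_01", group = "T1D", subset = "CD4")

diversity_report(s)
#>   sample_id group subset n_clones entropy hec_count hec_ratio
#> 1    T1D_01   T1D    CD4      872   0.633        22     0.768
```

All 22 planted expansions are recovered as HECs holding 76.8% of reads
(sampling noise around the planted 77%), and the normalized entropy of
0.633 sits far below the ~0.93 of a near-even control sample — the
separation the cohort statistics exploit. The dominant V×J combination and
a two-arm entropy comparison:

```r
vj_matrix(s, db)$dominant
#>   v_family j_family fraction
#> 1 TRBV28   TRBJ2-3    0.0732

tt <- ttest_unpaired(c(0.62, 0.58, 0.71, 0.65, 0.60),  # case entropies
                     c(0.93, 0.95, 0.91))              # control entropies
sprintf("t = %.2f, p = %.2e", tt$t, tt$p)
#> [1] "t = -9.50, p = 7.77e-05"
```

`run_pipeline(demo_config("out"))` runs the full simulate → annotate →
clonotype → diversity → usage → sharing → comparison chain over a
9 T1D / 4 T2D / 6 control cohort and writes every stage table plus a
manifest; `inst/scripts/tcrep-pipeline.R` wraps it for the shell. See the
vignette in `vignettes/` for the models, parameter choices and numerical
conventions.

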