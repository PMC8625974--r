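---
title: "cernakit: methods, design decisions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cernakit: methods, design decisions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernakit)
```

## The model

`cernakit` infers lncRNA–miRNA–mRNA competing-endogenous-RNA (ceRNA)
networks from a staged bulk expression design: lncRNA and mRNA abundances
(FPKM-like), miRNA abundances (TPM-like), several developmental stages with
replicated samples (the default design is four stages, E8/E13/D1/D10, with
three replicates each, i.e. 12 samples). The ceRNA hypothesis predicts
three observable signatures for a genuine sponge interaction, and the
pipeline turns each into a filter:

1. a miRNA and its targets (the lncRNA and the mRNA) are *anti-correlated*
   across samples, because the miRNA represses both;
2. the lncRNA and the mRNA are *positively co-expressed*, because they
   respond to the same regulatory context and compete for the same miRNA;
3. the two transcripts share *more miRNA partners than chance predicts*
   given how many partners each has individually.

The filters are applied in cascade, after a differential-expression gate
that restricts the analysis to stage-responsive genes, and before a
subcellular-localization gate that removes nuclear lncRNAs (miRNA-mediated
repression happens in the cytoplasm, so a nuclear lncRNA cannot sponge).

### The shared-sponge test

For a candidate lncRNA–mRNA pair, let K and n be their respective retained
miRNA partner counts after the anti-correlation filter, k the number of
shared partners, and N the size of the miRNA universe. Under the null that
the two partner sets are drawn independently, the shared count follows a
hypergeometric distribution and the pair's significance is the upper tail
`hypergeom_sf(k, K, n, N)` = P(X ≥ k), evaluated with log-gamma binomial
coefficients for stability and verified in the test suite against
exhaustive enumeration for every parameter combination with N ≤ 12
(absolute error ≤ 1e-12).

**Choice of universe (open in the source procedure).** The procedure this
package re-implements never states what N is, nor whether K and n are
counted before or after the correlation filter. We condition the test on
the same filtered pair sets that define k: N is the number of distinct
miRNAs appearing in *any* retained miRNA–ceRNA pair, and K and n are
retained partner counts. Anything else would mix filtered overlap counts
with unfiltered marginals and bias the test. This choice has a visible
consequence at desk scale: with few retained miRNAs the test is
intentionally weak (k = K = n = 1 gives p = 1/N, which at N = 20 cannot
pass α = 0.05), which is also the statistically honest behavior — a single
shared miRNA among a handful is not evidence of sponging.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `fdr` | 0.05 | probability | DE gate, BH-adjusted per comparison |
| `lfc` | 1 | log2 fold change | DE effect-size gate |
| `pseudocount` | 1 | abundance | stabilizes log fold changes at low abundance |
| `rho_threshold` | −0.85 | Spearman ρ | anti-correlation gate, strict `<` |
| `pcc_threshold` | 0.9 | Pearson r | co-expression gate, strict `>` |
| `alpha_sponge` | 0.05 | probability | sponge-test gate, strict `<`, unadjusted |
| `top_k` | 5 | count | hub lncRNAs by connectivity degree |
| `stem_c` | 1 | profile units | per-step change bound of trend profiles |
| `stem_m` | 20 | count | model profiles (ids 0–19) |
| `stem_alpha` | 0.05 | probability | trend-profile significance |

All thresholds are the printed values of the procedure the package
re-implements; all comparisons are strict inequalities, matching its
`<`/`>` glyphs exactly (a pair with ρ = −0.85, r = 0.9, or p = 0.05 is
dropped). `alpha_sponge` is applied to raw p-values by default because the
source procedure used raw p < 0.05; `adjust_sponge = TRUE` switches to BH.

## Design decisions

**Differential expression is a documented substitute.** The original
analysis ran count-based negative-binomial models (DESeq2/edgeR). This
pipeline consumes FPKM/TPM abundance matrices, not counts, so it uses
Welch's two-sided t-test on `log2(x + 1)` behind a pluggable interface
(`method = "welch_log"`), BH adjustment within each comparison, and the
same thresholds. Zero-variance groups are resolved analytically (equal
means → p = 1, different means → p = 0) so that noise-free synthetic data
remains testable; `stats::t.test()` would error on constant input.
Dispersion estimation and shrinkage are deliberately out of scope. DE genes
are pooled as the *union* over the six comparisons, because network
construction uses all DE genes; the alternative (stage-adjacent
comparisons only) is not what a pooled DE total implies.

**Pearson co-expression is computed on `log2(x + pseudocount)`.** The
source procedure does not state the scale. On raw abundances with a
20–30-fold stage trend and independent multiplicative noise, the population
Pearson correlation between two noisy proportional genes is bounded well
below 1 (≈ 0.92–0.96 at σ(log2) = 0.25) because the highest-abundance
samples dominate the moments; a strict r > 0.9 gate would then drop a large
fraction of genuine pairs for reasons unrelated to biology. Correlating on
the log scale is standard practice in co-expression analysis (WGCNA and
relatives) and restores the intended behavior. Spearman is rank-based and
unaffected by the choice. `log_transform = FALSE` restores raw-scale
correlation.

**Seed-match target prediction is canonical and oracle-verifiable.** Sites
are anchored on occurrences of the seed-core match (reverse complement of
miRNA positions 2–7) and classified by their extensions: position-8 match
and/or an adenosine opposite miRNA position 1 give 8mer, 7mer-m8, 7mer-A1,
or 6mer. Each core occurrence yields exactly one site of its maximal class,
so sub-patterns of a stronger site are never double-reported. The A1
position requires a target adenosine regardless of miRNA position 1
(the TargetScan convention). G:U wobble, mismatched seeds, and
thermodynamic scoring are out of scope — energy-based predictions enter via
`intersect_targets()`, which takes external tables and keeps pairs present
in every source. Coordinates are 0-based half-open on the target's sense
strand; T and U are interchangeable on input.

**Graph semantics.** The network stores sponge (lncRNA–miRNA) and target
(miRNA–mRNA) edges only; lncRNA–mRNA co-expression is recoverable from the
retained pair table and is not materialized as edges. Connectivity degree
counts distinct incident edges (not triplet multiplicity), matching what a
graph tool reports. Hub ranking breaks degree ties lexicographically by id
so hub lists are reproducible; the source procedure does not mention ties.
Each retained pair expands into one triplet per shared miRNA, which
reproduces the pair-to-interaction arithmetic of the source narrative.
lncRNAs absent from the localization table are excluded with a warning
(conservative; `keep_unlocalized = TRUE` flips this).

**Trend clustering.** Candidate profiles are all integer shapes of length
T starting at 0 with per-step changes bounded by c — (2c+1)^(T−1)
sequences minus the flat one. Model profiles are chosen by greedy
farthest-point selection under the correlation distance d = 1 − r, seeded
at the most-decreasing profile, then re-indexed 0..m−1 in lexicographic
order so the monotone-decreasing profile is id 0 and the monotone-increasing
one id m−1. Defaults T = 4, c = 1, m = 20 make ids span 0–19, consistent
with the id vocabulary of the published analysis (whose exact parameters
are unreported; reproducing its platform-specific profile numbering on real
data is a non-goal). Genes are assigned to the profile minimizing d over
stage means (ties to the lower id; constant-mean genes excluded with a
message). Significance uses an exact null — all T! stage-order permutations
of each gene's means (24 at T = 4), expected counts e_j as the per-profile
share of null assignments, and a binomial tail P(Binomial(G, e_j/G) ≥ o_j).
Profiles classify as increasing/decreasing by the sign of their net change;
net-zero profiles are labeled "complex" rather than forced into either
category.

## The synthetic world

`simulate_timecourse()` generates the statistical structure the cascade
assumes, with a known ground truth:

- **Planted trends.** Planted miRNAs follow a monotone increasing geometric
  stage trend (default fold change 3 per stage, ~27-fold overall); their
  partnered lncRNAs/mRNAs follow the mirrored decreasing trend scaled by a
  per-gene baseline drawn from `base_abundance_range` (20–200 abundance
  units). The decreasing direction mirrors the high-embryonic-expression
  hub narrative of the source study; the magnitude guarantees
  |log2FC| > 1 per adjacent comparison with margin. With `noise_sd = 0`
  the within-stage replicates tie and average ranks are exactly linear, so
  planted Spearman correlations are exactly −1 and planted Pearson
  correlations are 1.
- **Noise.** Multiplicative log-normal noise, `noise_sd` in log2 units
  (default 0.25), independent per observation. Decoy genes get a flat
  baseline plus noise; their pairwise correlations follow the null.
- **Shared sponges.** Planted miRNAs are grouped `mirnas_per_pair` (default
  3) per lncRNA–mRNA pair, so the sponge test sees k = 3 overlaps. This is
  deliberate: with one miRNA per pair the test gives p = 1/N, which sits at
  the α boundary for small N and would make recovery knife-edged rather
  than a property of the planted structure.
- **Sequences.** miRNAs are 22-nt uniform RNA; targets are uniform DNA
  (400 nt lncRNA, 300 nt mRNA) with one canonical site per planted
  (miRNA, target) relation, cycling through the four site classes. Site
  flanks are pinned so the planted class is exactly what a scanner
  recovers. The background is screened: no seed-core match of *any*
  simulated miRNA occurs anywhere except the planted windows, and miRNA
  seed cores are drawn so they cannot embed in one another's site
  footprints. An unscreened uniform background would plant ~1 accidental
  6mer per few hundred nt per 30 miRNAs and generate false triplets even in
  the noise-free world, destroying the clean acceptance surface; screening
  trades a small amount of sequence realism for an exact ground truth.
- **Localization.** Planted lncRNAs are always cytoplasmic; decoys are
  cytoplasmic with probability `frac_cytoplasmic` (default 0.75,
  representative of genuine localization distributions) and otherwise
  Nucleus/Ribosome/Exosome.

**What a green test does and does not establish.** The generator emulates
monotone stage trends, mirrored miRNA–target anti-correlation, planted seed
sites, and decoys with null structure. It does *not* emulate read-level
sampling noise, length or GC biases, secondary structure, partial
repression (planted correlations are near-perfect by construction),
correlated decoy co-expression modules, or miRNA biogenesis. Recovering
100% of planted triplets therefore validates the *gating logic and its
plumbing* — thresholds, strictness, counting, determinism — not the
statistical power of the cascade on real tissue data, where effect sizes
are weaker and confounding is richer.

## Numerical choices and degenerate inputs

- `hypergeom_sf` sums `exp(lchoose(...))` terms and clips at 1; enumeration
  agreement ≤ 1e-12 for N ≤ 12 is asserted in the acceptance suite.
- Correlations reject constant vectors (undefined variance) with an error;
  the pair filter catches this per pair, skips it, and warns. Results are
  clamped to [−1, 1] against floating-point overshoot.
- `bh_adjust` is the literal step-up (cumulative minimum from the largest
  p), permutation-equivariant, validated against an independent oracle and
  `stats::p.adjust` to 1e-12.
- Assignment ties in trend clustering go to the lower profile id; greedy
  selection ties go to the lexicographically smallest value vector; hub
  ties go to the lexicographically smallest id. All orderings in output
  tables are deterministic (sorted), so byte-identical reruns are a tested
  invariant — including the GML export, whose creator timestamp is pinned.
- Expression matrices are written with 17 significant digits so read-back
  reproduces doubles exactly.
- The run report's file manifest stores paths relative to the output
  directory so identical runs into different directories remain
  byte-identical.

## Limitations

- The DE substitute is a two-sample t-test on log abundances: adequate for
  the large planted effects the pipeline is validated on, underpowered and
  mis-specified relative to count models on real low-count data.
- The sponge test inherits the universe-definition ambiguity discussed
  above; its p-values are conditional on the correlation filter and are
  not corrected for the number of candidate pairs by default.
- Correlations use all individual samples (not stage means); with few
  stages and replicates the two choices can disagree near the thresholds.
- Seed matching is sequence-only: no accessibility, conservation, or
  expression-weighted scoring.
- The trend-profile machinery is a reproducible stand-in for the published
  short-time-series clustering tool, not a re-implementation of its exact
  selection internals; profile ids match only under the defaults stated
  here.
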