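---
title: "Detecting and dating divergent haplotype blocks with hapblockr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating divergent haplotype blocks with hapblockr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`hapblockr` analyses diploid SNP genotype matrices for extended,
non-recombining haplotype blocks segregating between two groups of
samples (canonically highland and lowland populations of a species with
otherwise panmictic structure). The analysis rests on three model
components.

**Estimation.** All estimators are *phase-free*: diploid genotypes enter
only through per-site allele counts and observed heterozygote fractions,
so phased and unphased data are treated identically.

* π is the Nei–Li mean pairwise difference between haplotypes,
  computed per site as `2p(1-p) · m/(m-1)` for `m` called haplotypes
  (the unbiased pairing correction; the brute-force enumeration over all
  allele pairs gives the identical value, and the test suite asserts
  this equivalence to 1e-12).
* θ_w accumulates `1/a(m_s)` per segregating site with `a(m)` the
  harmonic number of the site's called haplotype count; without
  missingness this reduces to the textbook `S / a(2n)`.
* d_XY is the mean cross-group difference
  `Σ p_a(1-p_b) + p_b(1-p_a)` per callable bp.
* Between-group differentiation uses the Weir–Cockerham (1984)
  variance components a (among populations), b (among individuals
  within populations) and c (within individuals): single-site estimate
  `a/(a+b+c)`, multi-site estimate `Σa/Σ(a+b+c)` (ratio of sums).
  Sites monomorphic overall or with fewer than two called diploids in a
  population are flagged undefined and excluded from sums — the data
  model retains missing genotypes rather than imputing, so every
  estimator defines its own handling.
* Population distance matrices use a Reynolds-type coancestry evaluated
  from allele counts alone (the haploid reduction of the 1984
  components, i.e. samples of 2n alleles with no within-individual
  term), combined across loci as a ratio of sums. Like every unbiased
  moment estimator it is slightly negative for identical sample
  frequencies; window-level uses floor negative values at zero.

**Null model.** The drift-only null is a clean two-population split
without gene flow or recombination, simulated backward in time: within
each population k lineages coalesce at rate k(k−1) with time in units of
4N₀ generations (the ms convention), all lineages merge at the join time
`T`, and exactly one mutation per locus is placed on a branch drawn with
probability proportional to branch length, its descendants carrying the
derived allele. `T` is tied to the observed genome-wide differentiation
through `T = -ln(1 - F_ST)/2`; chromosomes are paired consecutively into
diploids (lineages are exchangeable, and the test suite checks mean
F_ST is invariant to random re-pairing). Per-locus F_ST uses the same
Weir–Cockerham code path as the empirical scan. The engine is validated
distributionally against an independent coalescent simulator (msprime)
by a two-sample KS test, and against the analytic identity
`E[F_ST] ≈ 1 - exp(-2T)`.

Note on time units: the scaled time passed to the engine follows the ms
convention (4N₀ generations) because the null is specified as an
ms-style command; the haplodiploid bookkeeping elsewhere in the package
(N_E = θ_w/3μ) uses the inheritance scalar 3. The two conventions meet
only in the interpretation of `T` in generations, not in any computation
performed here.

**Dating.** Haplotype split ages are `d_XY / (2μ)` generations with
μ = 5.27×10⁻⁹ mutations/bp/generation and one-year generations by
default (both settable via `clock_params()`). Confidence intervals are
percentile bootstrap over non-overlapping 10-kbp windows (2,000
replicates by default), with windows weighted by their callable length —
unweighted means over unequal windows would bias d_XY.

# Key parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `fst_threshold` | 0.5 | F_ST | outlier SNP definition for region delineation |
| `merge_gap` | 1e6 | bp | max gap between outliers within one region |
| `het_threshold` | 0.88 | fraction | het call: sample heterozygous at >88% of outlier SNPs |
| `hom_threshold` | 0.60 | fraction | hom call: clear majority of outlier genotypes |
| `window` | 1e4 | bp | windows for d_XY bootstrap and quartet topologies |
| `boot_reps` | 2000 | – | bootstrap replicates per region |
| `mu` | 5.27e-9 | /bp/gen | molecular clock rate |
| `inheritance_scalar` | 3 | – | haplodiploid N_E scaling |
| `t_join` | 0.01833 | 4N₀ gen | null split time implied by F_ST = 0.036 |

Two defaults deserve comment.

*`hom_threshold = 0.60`.* In blocks whose founder divergence only
moderately exceeds the within-haplotype diversity, a substantial
minority of outlier SNPs segregate within one haplotype class rather
than between classes, so true homozygotes match well below 100% of
outlier genotypes — compositions around 75% hom-alt are typical for the
weaker of two blocks in both real and synthetic data. A threshold of
0.80 misclassifies essentially every such homozygote as ambiguous; 0.60
is a clear-majority rule that still rejects genuinely mixed
compositions (a 40/20/40 sample remains ambiguous, with dosage by
majority and exact ties flagged).

*`merge_gap` at desk scale.* The 1 Mbp default suits real genomes with
tens-of-megabase chromosomes, where two sub-blocks separated by a
misoriented scaffold should be reported as one linked region (the
pipeline additionally emits a fine-grained sub-block table at
`subblock_gap`). On the synthetic genome (1–1.2 Mbp chromosomes) the
analyses use 5 kbp: the calibrated background itself produces isolated
F_ST > 0.5 sites at a rate of about 1.1×10⁻⁴ per SNP (the same tail the
drift null shows), and the merge distance must be small enough that
such an isolated outlier near a block does not get merged into its
bounds, yet comfortably above the largest expected within-block outlier
gap (~1–2 kbp for the weaker block). With 5 kbp the expected number of
background outliers falling within merge distance of a block bound is
about 0.02 per dataset.

# The synthetic-data generator

`synth_config()` encodes the study conditions the analysis assumes:

* four populations (two localities × two habitats; 10/10/10/9 diploids)
  whose background SNPs follow a structured coalescent — the habitat
  pair within each locality splits at `t_hab = 0.046` and the
  localities at `t_loc = 0.09` (ms units). `t_hab` was calibrated once,
  numerically, so the realized habitat-partition Weir–Cockerham F_ST is
  0.036; the deeper locality split makes the locality grouping the
  dominant window topology, as in the data the package targets.
* two embedded blocks: 500 kbp at founder divergence `d_block` =
  3.34%/bp with highland-haplotype frequencies 0.93 (highland
  populations) vs 0.08 (lowland), and 700 kbp at 1.34%/bp with 0.93 vs
  0.21; within-haplotype diversity θ_h/θ_l per class as in the target
  system (0.20/0.69 and 0.52/0.72 %/bp). Each sample draws two
  haplotype copies per block from its population's frequency; founder
  sites are Bernoulli along the block and all copies of a class are
  identical at them (no recombination), so hom/het genotype patterns
  emerge naturally.
* within-class variation is placed on the copies of one class with
  derived frequencies from the neutral SFS (P(i) ∝ 1/i) restricted to
  the minor range i ≤ M/2. Derived variants that have reached majority
  within a class are observationally indistinguishable from founder
  differences, so they belong to the founder-divergence budget: the
  founder density is set to `d_block` minus the analytically computed
  cross-class contribution of the within-class term, which makes the
  expected d_XY between homozygous classes equal `d_block` exactly and
  keeps within-class π at its θ target.
* an outgroup allele table at 6.9% divergence covering 78% of sites,
  with ancestral states recorded per site (66% of founder differences
  on the highland branch, biased toward codon positions 1/2 inside CDS
  so the highland branch accrues a higher non-synonymous fraction);
  gene models tiled over both strands at 8% coding fraction with an
  in-frame non-stop reference sequence; a depth table with a
  configurable highland coverage depression over block sites; 1%
  missing genotypes.

The truth record stores, per block, the realized per-sample haplotype
pair, the realized span of sites whose full-call habitat F_ST exceeds
0.5 (the correct reference for bound-recovery scoring, since
within-class sites can be outliers too), founder density after
inflation correction, and per-site ancestral allele, branch and type.
Because haplotype copies are drawn per sample, a weakly differentiated
block can occasionally realize frequencies whose F_ST falls below the
outlier threshold; the truth record then contains zero outlier sites
and a scan that reports nothing there is scored as consistent.

What the generator does **not** emulate: linkage disequilibrium decay
within the background (background SNPs are exchangeable unlinked loci),
read-level error structure and imputation artifacts, recombination or
gene flux between block haplotypes, segmental duplications (depth
anomalies are injected directly), and reference bias beyond the
convention that the reference sequence carries the lowland haplotype.
Passing the end-to-end tests therefore demonstrates correctness of the
estimators and of the detection/classification/dating logic under the
stated generative model, not robustness to alignment artifacts.

# Numerical and convention choices

* Coordinates are 1-based inclusive throughout (VCF convention);
  BED export is the only 0-based half-open surface. Region length is
  `last − first + 1`; note that published region tables of this kind
  are not always internally consistent between printed bounds and
  printed lengths, and this package always reports the inclusive
  arithmetic of its own bounds.
* Region-level F_ST is reported both as ratio-of-sums over all SNPs in
  the region (`region_fst`, the default) and as the mean of site
  estimates (`mean_site_fst`), since either convention appears in
  practice.
* The null-distribution summary reports the multi-locus ratio-of-sums
  mean and the mean of per-locus ratios separately. Single-SNP
  Weir–Cockerham ratios are strongly noisy and their plain mean sits
  well below the parametric F_ST (about 0.023 against 0.036 at the
  default model); the ratio-of-sums combination is the aggregation
  comparable to an empirical genome-wide value, and is what the
  acceptance script reports.
* Depth masking retains sites whose depth lies within
  `[0.3×, 3.0×]` of the cohort average (configurable) and whose
  genotyped-sample fraction is at least 0.5. A symmetric percentage
  band around the average is ill-defined as an upper bound
  ("within 30% of the average" cannot mask high-coverage repeats), so
  the band is symmetric on the log scale instead.
* Quartet topologies per window are classified by the four-point
  condition on the window's pairwise Reynolds matrix (equivalent to
  neighbor joining for four taxa, deterministic and faster); ties and
  windows with fewer than `min_snps = 10` SNPs are `unresolved` rather
  than arbitrarily assigned; negative pair estimates are floored at 0
  before the pair sums.
* Neighbor joining clamps negative branch lengths to zero and moves the
  deficit to the sister branch at the same node, preserving path
  lengths through the parent. Ultrametric ties resolve arbitrarily with
  a zero-length internal branch.
* Fixed differences tolerate `max_missing = 0` missing genotypes per
  group by default (configurable), and any heterozygote disqualifies a
  site. Multi-SNP codons are evaluated per SNP against the reference
  codon.
* The bootstrap uses the percentile interval; with a single distinct
  window value the interval has zero width.

# Problem sizes

The test suite and the acceptance analyses run at desk scale, chosen as
the package's own validation sizes: synthetic genomes of ~2.8 Mbp with
~90k SNPs across 39 samples; 20 generator seeds for the end-to-end
recovery properties; 10⁵–10⁶ loci for the null distribution (the C++
engine simulates about 10⁶ single-SNP genealogies of 78 lineages in a
few seconds); 8×10³ loci for the KS cross-validation against msprime;
1,000–2,000 bootstrap replicates per region.

# Known limitations

* The classification rule assumes exactly two deeply diverged
  haplotype classes per region; nested or more-than-two-class
  polymorphism would surface as ambiguous calls.
* d_XY denominators rely on a supplied callable length (region width by
  default); with real data the user should supply the post-mask
  callable length, otherwise per-bp statistics are deflated by the
  masked fraction.
* The null model excludes migration, growth and recombination by
  design (they would homogenize the descendant populations, making the
  null conservative in that direction only).
* Branch assignment by parsimony against a single outgroup is blind to
  homoplasy; at 6.9% outgroup divergence roughly 2% of polarized sites
  are misassigned, an error the test suite accounts for when scoring
  against truth.
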