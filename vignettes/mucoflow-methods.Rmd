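---
title: "mucoflow: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mucoflow: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucoflow)
```

mucoflow implements the computational layer of diet–microbiota–mucus
studies: composite FMT donor selection, compositional microbiome
post-processing, beta diversity on a phylogeny, ex vivo mucus function
metrics, standard-curve assay quantification, and exact small-sample
nonparametric statistics. This vignette explains the models behind each
component, the parameters that matter, the numerical conventions, and what
the synthetic-data generators do and do not emulate.

## Donor selection by rank aggregation

Human donors for FMT are chosen in two stages. First, each participant's
improvement on six metabolic parameters — waist-to-hip ratio, body mass
index, free fat mass, cholesterol, triglycerides, fasting glucose — is
ranked (1 = largest improvement), and the six ranks are combined by their
mean (Borda aggregation). Second, the shortlisted top responders (default
10) are ranked by the magnitude of their paired pre/post gut-community
shift under Bray–Curtis and weighted UniFrac, these two ranks again combined
by mean, and the final donors (default 5) minimize the mean of the metabolic
and gut ranks.

Design choices made where the procedure was genuinely open:

* **Combination rule.** "Combining rankings" admits mean, sum or median;
  mean rank with mean-rank tie sharing is used because it is the simplest
  auditable rule and sum is equivalent up to scale. The rule is recorded in
  the pipeline manifest.
* **Improvement directions.** A decrease is improvement for waist-to-hip
  ratio, BMI, cholesterol, triglycerides and glucose. "Free fat mass" is
  ambiguous between fat-free mass (increase good) and fat mass (decrease
  good); the default treats it as fat-free mass, and `defaultDirections()`
  makes the choice explicit and overridable rather than hard-coded.
* **Scale of improvement.** Raw pre−post deltas are ranked by default; a
  `percent = TRUE` flag ranks percent-of-baseline instead. Rank aggregation
  is invariant to any strictly monotone per-criterion transform, so this
  choice only matters when baselines vary widely.
* **Tie-break.** Final ordering ties are broken lexicographically on
  (metabolic rank, participant id) — deterministic and logged in the audit
  table that `selectDonors()` returns.

## Beta diversity

`brayCurtis()` computes `Σ|x−y| / Σ(x+y)`. Samples are converted to
proportions first by default: the package's contract that dissimilarities
are invariant to per-sample sequencing depth cannot hold on raw counts, so
proportions-first is the default and `proportions = FALSE` exposes the
raw-count formula for parity with other tools.

`weightedUnifrac()` assigns each branch the fraction of a sample's total
abundance descending through it (one post-order traversal over the `ape`
edge table, multifurcations allowed) and returns
`Σ b|p^x − p^y| / Σ b(p^x + p^y)`. Among the several weighted-UniFrac
normalizations in the literature this is the generalized-UniFrac α = 1 form;
it is bounded in [0, 1], reduces to Bray–Curtis on proportions for a star
tree with equal branch lengths, and is unchanged by collapsing zero-length
branches (all three properties are tested). `normalized = FALSE` returns the
raw branch-weighted numerator. Unrooted trees are rejected with a pointer to
midpoint rooting rather than silently rooted, and abundance taxa missing
from the tree are an error that names them.

## Compositional processing

* **Filtering.** The low-abundance rule is *keep iff (present in ≥
  `minSamples` samples AND total count ≥ `minTotal`)*, defaults 2 and 10.
  The underlying published phrasing is grammatically ambiguous between this
  reading and its complement; both thresholds are parameters so the other
  reading is one flag away. The filter is idempotent and reports removed
  taxa.
* **CLR.** `clr_i = log(x_i + c) − mean_j log(x_j + c)` with additive
  pseudocount `c = 1` on counts, the common default when zero handling is
  unstated; `c` is a parameter. Rows (samples) sum to 0 within 1e-9.
* **Shannon.** Natural log, the convention when no base is stated; uniform
  over k taxa gives `ln k`.
* **Rarefaction.** Sampling without replacement to an exact depth,
  deterministic under a seed that never leaks into (or reads) the caller's
  RNG state. The rarefaction depth is a required argument because no default
  is defensible across data sets.
* **Core genera / detection.** A genus is "detected" when its relative
  abundance is strictly positive — no abundance floor — and core when
  detected in at least the prevalence fraction (25% and 80% are the
  conventional screens) of a group's samples. Higher prevalence always gives
  a subset.
* **Group-maximum normalization.** Per genus, group mean relative abundances
  are scaled so the best group is 100%; an all-zero genus is `NA`
  (undefined), never 0/0.

## Mucus function

**Growth rate.** Thickness is measured at five sites per explant at 0 and
45 min; the per-timepoint value is the site mean and the rate is the
difference divided by elapsed minutes (µm/min). The estimator is exactly
linear in a uniform additive change of the late thicknesses, and recovers a
planted rate exactly at zero noise — healthy mouse colonic mucus grows at
roughly 2 µm/min, which anchors the generator defaults.

**Penetrability.** Inputs are post-segmentation bead coordinates (the z axis
toward the lumen) and an epithelial reference, either a plane height or a
gridded height field interpolated bilinearly (`pracma::interp2`). The
per-bead distance is the *vertical* offset `z − h(x, y)`, matching z-stack
acquisition with a height-field epithelium; 3D nearest-point distance is out
of scope. The mucus surface of an image is the center of the modal 5 µm bin
of the distance histogram — 5 µm is the confocal z-step, and the bin width
is a parameter since the optimal bandwidth depends on acquisition. Ties
break toward the larger distance so a genuine surface accumulation beats a
crypt-floor artifact. Beads below the epithelium are flagged and excluded
(QC-counted); beads above the detected surface are treated as excess,
unwashed beads and excluded from the denominator. The reported fraction is
`#(distance ≤ 10 µm) / #(0 ≤ distance ≤ surface)` per image, averaged over a
mouse's 2–3 images. Whether the denominator should include beads above the
surface is not settled in the literature; the in-mucus denominator is used
and recorded. Distance distributions are summarized as median and quartiles
with the linear-interpolation convention (R's type 7), recorded in output
metadata. Fewer than 50 usable beads make the mode unreliable; the function
then asks for an externally supplied surface height instead of guessing.

## Assay quantification

Standard curves are ordinary least squares (signal on concentration, or Cq
on log10 copies); a constant-signal series yields slope 0 with r² reported
as undefined rather than 1. Enzyme activity divides the curve-inverted
released concentration by incubation time (default 45 min) and protein
input; duplicates are averaged on the signal scale before inversion, and a
signal below the blank/intercept is floored at zero activity with a QC flag
rather than reported negative. Per-mouse enzyme shares divide each activity
by the mouse's total (undefined for an all-zero mouse). qPCR copies are
`10^((Cq − intercept)/slope)` rescaled to the 10 ng RNA reporting basis, with
an extrapolation warning outside the standard range. CFU/g multiplies the
colony count by dilution and suspension volume over plated volume and
sample mass; zero colonies are reported *at* the single-colony limit of
detection and flagged censored. All CFU factors are explicit parameters
because plating constants vary between protocols.

Metabolomics preprocessing divides peak areas by sample weight, imputes
missing values per metabolite at 20% of its minimum positive normalized
value, then log10-transforms (log base unstated in common protocols; 10 is
the metabolomics convention). The significance screen requires both a group
fold change ≥ 1.5 (or ≤ 1/1.5) and a two-sided exact Mann–Whitney p < 0.05.
The fold change is computed on weight-normalized, *unlogged* group means,
the common metabolomics convention; "nonparametric t test" is implemented as
the Mann–Whitney U test.

## Exact statistics

All four procedures are implemented from first principles; standard library
routines (`wilcox.test`, `p.adjust`, `vegan::vegdist`) appear only as
independent oracles in the test suite.

* **Mann–Whitney U.** U from rank sums with mid-ranks. Without ties and
  `n1 + n2 ≤ 30`, the exact null counts of U are built by dynamic
  programming (the Gaussian-binomial recurrence, O(n1 · n1 · n2) time) and
  the two-sided p is `min(1, 2 × min(P(U ≤ u), P(U ≥ u)))`. This reproduces
  the canonical complete-separation series — at n = 4 vs 6:
  0.0095, 0.0190, 0.0381, 0.0667, 0.1143 for U = 0…4 — to the printed four
  decimals. Ties or larger samples switch to a tie-corrected normal
  approximation with a 0.5 continuity correction (whether legacy software
  applied one is unknowable; the `TestResult` records `exact` and
  `tie_corrected` so the path is always auditable).
* **Wilcoxon signed-rank.** Zero differences dropped; exact two-sided p over
  the `2^n` equiprobable sign assignments (DP over rank sums) for up to 25
  nonzero untied differences, else the tie-corrected approximation.
* **Spearman.** rho is the Pearson correlation of mid-ranks. For n ≤ 8 the
  p-value is the exact permutation tail `P(|rho_perm| ≥ |rho_obs|)` over all
  n! permutations (with a 1e-12 comparison tolerance against floating-point
  equality); beyond that, the t approximation with n − 2 df. Constant input
  yields `NA`, reported as missing rather than 0.
* **Benjamini–Hochberg.** The step-up rule, returned in input order, capped
  at 1; adjusted values never fall below raw ones and preserve their order.
* **Correlation screen.** The `topN = 30` most abundant genera are screened
  against a per-sample phenotype (e.g. mucus growth rate) on CLR or relative
  abundance, BH-adjusted across exactly the screened set.

## What the synthetic generators emulate

Every pipeline input can be generated with planted ground truth from a
single `simConfig()`; one global seed feeds per-generator derived seed
streams, so adding a generator never perturbs the draws of another, and
identical configs are bit-identical. Null settings (zero effect, zero noise,
zero shift) propagate to exactly zero downstream estimates, which the tests
exploit.

* **Cohort** (default 67 participants, 5 planted responders): six metabolic
  parameters with realistic middle-aged baselines; responders improve by
  `responderEffect` (default 10% of baseline), everyone receives zero-mean
  noise of sd `noiseSd` (default 5%) — the default regime places the planted
  effect at twice the noise.
* **Paired communities**: a random rooted bifurcating tree with exponential
  branch lengths; log-normal baseline compositions Poisson-sampled to
  integer counts at a target depth, so tables are integer-valued as real ASV
  tables are; the post sample displaces the log abundances by
  `shiftScale × (1 + responderBonus)` for responders. `responderBonus = 2`
  (responders shift three times the baseline scale) makes the planted
  responders unambiguous on both beta-diversity metrics, mirroring how
  conspicuous the selected donors' shifts are in practice: with a smaller
  bonus the realized shift of a responder can overlap the non-responder
  distribution because a few dominant taxa carry most of the dissimilarity.
  At `shiftScale = 0` the post counts are copied from the pre counts so the
  null is exact, not merely centered.
* **Bead clouds**: a smooth sinusoidal epithelial height field; bead depths
  from an exponential law (mean `beadLambda`) truncated at the mucus surface
  plus a surface mode holding `surfaceFrac` of the beads — sedimented beads
  localized to the surface with ± half a z-step (2.5 µm) of symmetric error.
  The one-parameter exponential-plus-mode mixture produces both penetrable
  and impenetrable regimes. Ground truth records the realized per-image
  fraction of in-mucus beads within 10 µm — precisely the estimand of
  `penetrability()` — and the symmetric mode makes the modal-bin-center
  surface convention unbiased for it. Defaults (`beadLambda = 29`,
  `beadSurfaceHeight = 97.5`, `surfaceFrac = 0.3`) plant that fraction at
  ≈ 0.25, chosen from the truncated-exponential arithmetic
  `(1−s)·P(d ≤ 10) / ((1−s) + s/2)`.
* **Mucus experiment**: five sites × two timepoints per mouse;
  `T_45 = T_0 + 45 × rate + noise`. Group rates are explicit arguments
  (`groupRates`) because the config object deliberately carries only
  generic scales.
* **Assay plates**: a serial two-fold dilution standard series with Gaussian
  signal noise, plus duplicate unknown wells generated from planted
  activities through the same line.
* **Metabolite tables**: log-normal intensities, a planted subset multiplied
  by `foldChange` (default 3) in the treated group, peak areas scaled by
  per-sample weights, and missing-at-random entries.

What the generators do **not** emulate: read-level sequencing error and
denoising, compositional correlation structure between taxa, batch effects,
image-level noise (bead clouds start at coordinates, as post-segmentation
exports do), or biologically structured missingness in metabolomics. A
passing recovery test therefore demonstrates that the estimators are correct
and well-calibrated for their declared models, not that they are robust to
every artifact of real data.

## Problem sizes and numerical conventions

The validation suite enumerates brute-force oracles where they are feasible:
all Mann–Whitney group sizes with `n1 + n2 ≤ 12` against full assignment
enumeration, signed-rank up to n = 10 against all `2^n` sign vectors,
Spearman up to n = 8 against all n! permutations, weighted UniFrac on 100
random trees with ≤ 8 leaves against a per-branch descendant-sum oracle, and
BH on 1000 random vectors against the reference step-up. Recovery and
calibration use 100 seeded replicates (donor selection at the full 67 × 6
design; penetrability at 750 beads × 3 images) and 10,000 null draws for the
exact Mann–Whitney type-I error at n = 4 vs 6 — sizes at which the binomial
error of the estimated rates is comfortably below the margins being checked.
Comparison tolerances are 1e-12 where two exact routes must agree and 1e-9
for compositional sum constraints.

Degenerate inputs are contracts, not corner cases: zero-total samples,
all-zero dissimilarity pairs, constant correlation inputs, all-zero enzyme
totals and all-missing metabolites each produce a named error, an `NA`, or a
flagged value — never a silent 0/0.

## Limitations

Rank aggregation is unweighted: all six metabolic criteria count equally, as
do the two beta-diversity metrics. The weighted UniFrac normalization is
fixed per call and recorded, but no attempt is made to infer which variant
an external ordination used. The penetrability surface estimator assumes the
bead-density mode marks the mucus surface; preparations with heavy bead
wash-off may need the explicit `surface` argument. The exact tests switch to
approximations in the presence of ties, which is flagged but means p-values
on heavily tied data are not exact. The pipeline's correlation stage screens
a fixed number of genera; it does not model compositional dependence between
tests beyond BH control.
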