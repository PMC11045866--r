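# mucoflow

Analysis toolkit for studies that link dietary fiber, the gut microbiota and
colonic mucus function. The package covers the computational arc of a
human-to-mouse fecal microbiota transplantation (FMT) study: selecting human
donors by combining metabolic-improvement rankings with microbiota-shift
rankings, post-processing amplicon count tables compositionally, quantifying
ex vivo mucus growth and 3D bead penetrability, converting plate/qPCR/CFU
readings through standard curves, and the exact small-sample nonparametric
statistics these experiments rely on — all implemented from first principles
and exercised end to end on synthetic data with planted ground truth.

## What it computes

**Composite donor ranking.** For each of the six metabolic parameters
(waist-to-hip ratio, BMI, free fat mass, cholesterol, triglycerides,
fasting glucose), participants are ranked by improvement
`Δ_p = s_p (x_p^pre − x_p^post)` (sign `s_p` encodes whether a decrease or an
increase is the improvement) with 1 = largest; the combined metabolic score
is the mean of the six ranks (Borda aggregation, ties share the mean rank).
The top responders are re-ranked by their paired pre/post community shifts
under two beta-diversity metrics, and the final donors minimize the mean of
the metabolic and gut ranks.

**Beta diversity.** Bray–Curtis dissimilarity
`BC(x, y) = Σ|x_i − y_i| / Σ(x_i + y_i)` on per-sample proportions, and
weighted UniFrac on a rooted phylogeny: with `p_i` the fraction of a sample's
abundance descending through branch `i` of length `b_i`,

```
WU(x, y) = Σ_i b_i |p_i^x − p_i^y|  /  Σ_i b_i (p_i^x + p_i^y)
```

computed in one post-order traversal (the generalized-UniFrac α = 1
normalization; a raw variant is available).

**Compositional processing.** Prevalence/abundance filtering (keep a taxon
iff present in ≥ 2 samples and total count ≥ 10, both parameters exposed),
relative abundance, centered log-ratio transform
`clr_i = log(x_i + 1) − mean_j log(x_j + 1)`, observed taxa and Shannon
diversity, seeded rarefaction without replacement, core-genus detection at
25%/80% prevalence, and group-maximum normalization of genus abundances.

**Mucus function.** Growth rate `(mean T_45 − mean T_0) / 45` µm/min over
five measurement sites per explant; bead penetrability from confocal bead
coordinates: vertical distance of each bead to the interpolated epithelial
height, the mucus surface as the bead-density mode (5 µm bins, ties toward
the lumen), and the fraction of in-mucus beads within 10 µm of the
epithelium, averaged over a mouse's images.

**Assay quantification.** Least-squares standard curves; endpoint enzyme
activity in µM·min⁻¹·mg⁻¹ with duplicate averaging and blank flooring;
qPCR copies per 10 ng RNA by inverting a Cq vs log10(copies) curve; CFU/g
with limit-of-detection censoring; metabolomics preprocessing (weight
normalization, missing values imputed at 20% of the per-metabolite minimum
positive value, log10) and a fold-change ≥ 1.5 + exact Mann–Whitney p < 0.05
significance screen.

**Exact statistics.** Mann–Whitney U with the null distribution enumerated
by dynamic programming (exact for n1+n2 ≤ 30 without ties), Wilcoxon
signed-rank over the 2^n sign assignments, Spearman correlation with full
permutation p-values at small n, and Benjamini–Hochberg step-up adjustment.
Two-sided exact p = min(1, 2 × min tail).

## Worked example

```r
library(mucoflow)

## exact Mann-Whitney at n = 4 vs 6 with complete separation
mannWhitneyExact(c(5.1, 4.8, 5.6, 4.9), c(7.2, 8.1, 7.9, 8.4, 7.5, 8.8))
#> Mann-Whitney U: statistic = 0, p = 0.009524 (exact, n1 = 4, n2 = 6)

## composite donor selection on a synthetic 67-participant cohort
cfg <- simConfig(seed = 1)
coh <- genCohort(cfg)
met <- rankMetabolic(coh$cohort)
top <- met$participant_id[1:10]
com <- genPairedCommunities(cfg, participants = top)
gut <- rankMicrobiotaShift(communityShifts(com$table, com$tree))
sel <- selectDonors(met, gut)
sel$donors
#> [1] "P42" "P22" "P47" "P27" "P20"
coh$truth$responder_ids     # the five planted responders
#> [1] "P20" "P22" "P27" "P42" "P47"

## mucus penetrability from a synthetic bead cloud (750 beads x 3 images)
bc  <- genBeadCloud(cfg, nBeads = 750, nImages = 3)
pen <- penetrability(bc$cloud)
pen$images[, c("mucus_surface_um", "n_beads_in_mucus", "fraction_within_zone")]
#>   mucus_surface_um n_beads_in_mucus fraction_within_zone
#> 1             97.5              633                0.250
#> 2             97.5              644                0.222
#> 3             97.5              631                0.260
round(pen$perMouse$fraction_within_zone, 3)   # mouse mean over images
#> [1] 0.244
round(mean(bc$truth$fraction_within_zone), 3) # planted ground truth
#> [1] 0.244
```

The five donors recovered are exactly the planted responders, and the
per-mouse fraction of beads within 10 µm of the epithelium matches the
generator's planted value. `runPipeline(simConfig(seed = 1), outDir = "out")`
runs every stage, writes tidy CSVs plus a JSON manifest of every numeric
decision, and `makeReport()` renders a text summary.

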