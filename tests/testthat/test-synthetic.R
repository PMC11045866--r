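test_that("configs validate and name the offending field", {
  expect_error(simConfig(nResponders = 10, nParticipants = 5), "nResponders")
  expect_error(simConfig(shiftScale = -1), "shiftScale")
  expect_error(simConfig(noiseSd = -0.1), "noiseSd")
  expect_error(simConfig(seed = 1.5), "seed")
})

test_that("all generators are bit-identical under the same seed and differ across seeds", {
  cfg <- simConfig(seed = 42, nParticipants = 12, nResponders = 2, nTaxa = 10)
  a <- genCohort(cfg); b <- genCohort(cfg)
  expect_identical(a, b)
  ca <- genPairedCommunities(cfg); cb <- genPairedCommunities(cfg)
  expect_identical(counts(ca$table), counts(cb$table))
  expect_identical(ape::write.tree(ca$tree), ape::write.tree(cb$tree))
  expect_identical(genBeadCloud(cfg, 100), genBeadCloud(cfg, 100))
  expect_identical(genMucusExperiment(cfg), genMucusExperiment(cfg))
  expect_identical(genAssayPlate(cfg), genAssayPlate(cfg))
  expect_identical(genMetaboliteTable(cfg), genMetaboliteTable(cfg))
  cfg2 <- simConfig(seed = 43, nParticipants = 12, nResponders = 2, nTaxa = 10)
  expect_false(identical(genCohort(cfg2), a))
  # written CSV is byte-identical across runs
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeCohort(genCohort(cfg)$cohort, f1)
  writeCohort(genCohort(cfg)$cohort, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("null cohort configurations give exactly zero deltas", {
  cfg <- simConfig(seed = 3, nParticipants = 8, nResponders = 3,
                   responderEffect = 0, noiseSd = 0)
  coh <- genCohort(cfg)$cohort
  for (p in names(defaultDirections())) {
    expect_equal(coh[[paste0(p, "_post")]], coh[[paste0(p, "_pre")]])
  }
})

test_that("cohort has the configured size and planted responders exist in it", {
  cfg <- simConfig(seed = 9)
  res <- genCohort(cfg)
  expect_equal(nrow(res$cohort), 67)
  expect_true(all(res$truth$responder_ids %in% res$cohort$participant_id))
  expect_length(res$truth$responder_ids, 5)
})

test_that("paired communities sit on a valid tree and respect the null shift", {
  cfg <- simConfig(seed = 5, nTaxa = 12, nParticipants = 4, nResponders = 1)
  com <- genPairedCommunities(cfg)
  expect_equal(length(com$tree$tip.label), 12)
  expect_true(all(com$tree$edge.length > 0))
  expect_true(ape::is.rooted(com$tree))
  expect_true(all(counts(com$table) >= 0))
  expect_setequal(rownames(counts(com$table)), com$tree$tip.label)
  # zero shift -> identical pre/post counts and zero Bray-Curtis
  cfg0 <- simConfig(seed = 5, nTaxa = 12, nParticipants = 4, nResponders = 1,
                    shiftScale = 0)
  com0 <- genPairedCommunities(cfg0)
  sh <- communityShifts(com0$table, com0$tree)
  expect_equal(sh$bc_shift, rep(0, 4))
  expect_equal(sh$wu_shift, rep(0, 4))
  expect_error(genPairedCommunities(simConfig(nTaxa = 2)), "nTaxa")
})

test_that("mean pre/post dissimilarity increases with the shift scale", {
  meanShift <- function(scale) {
    mean(vapply(1:20, function(s) {
      cfg <- simConfig(seed = s, nTaxa = 15, nParticipants = 3,
                       nResponders = 0, shiftScale = scale)
      com <- genPairedCommunities(cfg)
      mean(communityShifts(com$table, com$tree)$bc_shift)
    }, numeric(1)))
  }
  shifts <- vapply(c(0.1, 0.4, 1, 2), meanShift, numeric(1))
  expect_false(is.unsorted(shifts))
})

test_that("bead clouds have the requested size and self-consistent ground truth", {
  cfg <- simConfig(seed = 7)
  bc <- genBeadCloud(cfg, nBeads = 750)
  expect_equal(nrow(beads(bc$cloud)), 750)
  # recompute the truth from the emitted coordinates: depth = z - h(x, y)
  d <- beadDistances(bc$cloud)
  inMucus <- d$distance_um <= cfg$beadSurfaceHeight
  expect_equal(sum(d$distance_um[inMucus] <= 10) / sum(inMucus),
               bc$truth$fraction_within_zone, tolerance = 1e-9)
  # lambda -> 0 with no surface mode: every bead within 10 um
  bc0 <- genBeadCloud(simConfig(seed = 7, beadLambda = 0), nBeads = 200,
                      surfaceFrac = 0)
  expect_equal(bc0$truth$fraction_within_zone, 1)
  expect_true(all(beadDistances(bc0$cloud)$distance_um <= 1e-9))
})

test_that("mucus experiment has five sites per timepoint and exact null recovery", {
  cfg <- simConfig(seed = 2, noiseSd = 0)
  exp <- genMucusExperiment(cfg, groupRates = c(g1 = 2, g2 = 0),
                            nMicePerGroup = 3)
  counts <- table(exp$series$mouse_id, exp$series$time_min)
  expect_true(all(counts == 5))
  rates <- growthRate(exp$series)
  expect_equal(rates$rate_um_min[rates$group == "g1"], rep(2, 3))
  expect_equal(rates$rate_um_min[rates$group == "g2"], rep(0, 3))
})

test_that("a zero-rate group recovers a mean rate within 3 SE of zero", {
  cfg <- simConfig(seed = 4, noiseSd = 0.5)  # 22.5 um noise on T45
  exp <- genMucusExperiment(cfg, groupRates = c(null = 0), nMicePerGroup = 50)
  rates <- growthRate(exp$series)$rate_um_min
  se <- sd(rates) / sqrt(length(rates))
  expect_lte(abs(mean(rates)), 3 * se)
})

test_that("assay plates carry a two-fold dilution series and exact no-noise lines", {
  cfg <- simConfig(seed = 8, noiseSd = 0)
  pl <- genAssayPlate(cfg)
  std <- pl$plate[pl$plate$role == "standard", ]
  expect_equal(std$x_value[-1] / std$x_value[-nrow(std)],
               rep(0.5, nrow(std) - 1))
  sc <- fitStandardCurve(std$x_value, std$signal)
  expect_equal(slope(sc), pl$truth$slope)
  expect_equal(intercept(sc), pl$truth$intercept)
  # planted activities recovered within 5% under small noise
  cfgN <- simConfig(seed = 8, noiseSd = 0.01 * 0.005)
  ok <- vapply(1:50, function(s) {
    p <- genAssayPlate(simConfig(seed = s, noiseSd = 0.01 * 0.005))
    st <- p$plate[p$plate$role == "standard", ]
    cu <- fitStandardCurve(st$x_value, st$signal)
    w <- p$plate[p$plate$analyte == "bglucosidase" & p$plate$role == "sample", ]
    act <- enzymeActivity(w$signal, cu, timeMin = p$truth$timeMin,
                          proteinMg = p$truth$proteinMg)$activity
    abs(act / p$truth$activities[["bglucosidase"]] - 1) < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
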