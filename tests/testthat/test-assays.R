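test_that("standard curve recovers an exact line and reports degenerate fits", {
  sc <- fitStandardCurve(c(1, 2, 4, 8), 2 * c(1, 2, 4, 8) + 1)
  expect_equal(slope(sc), 2)
  expect_equal(intercept(sc), 1)
  expect_equal(rSquared(sc), 1)
  flat <- fitStandardCurve(c(1, 2, 4, 8), rep(3, 4))
  expect_equal(slope(flat), 0)
  expect_true(is.na(rSquared(flat)))
  expect_error(fitStandardCurve(c(1, 1, 2, 2), 1:4), "distinct")
  # refitting the fitted values returns identical parameters (idempotence)
  x <- c(1, 3, 9, 27, 81)
  sc1 <- fitStandardCurve(x, 0.4 * x + 5 + c(0.1, -0.2, 0.05, 0, -0.03))
  fitted <- slope(sc1) * x + intercept(sc1)
  sc2 <- fitStandardCurve(x, fitted)
  expect_equal(slope(sc2), slope(sc1))
  expect_equal(intercept(sc2), intercept(sc1))
})

test_that("noisy planted standard curves are recovered within analytic OLS error", {
  x <- 200 / 2^(0:7)
  sdNoise <- 0.02
  set.seed(77)
  ok <- vapply(1:500, function(i) {
    y <- 0.005 * x + 0.04 + rnorm(length(x), 0, sdNoise)
    sc <- fitStandardCurve(x, y)
    seSlope <- sdNoise / sqrt(sum((x - mean(x))^2))
    abs(slope(sc) - 0.005) <= 4 * seSlope
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("enzyme activity averages duplicates and floors sub-blank signals", {
  sc <- fitStandardCurve(c(0, 10, 20, 40), c(0, 10, 20, 40))  # identity line
  # 45 uM released in 45 min with 0.01 mg protein -> 100 uM/min/mg
  ea <- enzymeActivity(45, sc, timeMin = 45, proteinMg = 0.01)
  expect_equal(ea$activity, 100)
  expect_equal(ea$qc_flag, "ok")
  # duplicates (40, 50) -> activity from mean 45
  dup <- enzymeActivity(c(40, 50), sc, timeMin = 45, proteinMg = 0.01)
  expect_equal(dup$activity, 100)
  # zero released -> 0; below blank floored with flag
  expect_equal(enzymeActivity(0, sc, proteinMg = 0.01)$activity, 0)
  neg <- enzymeActivity(-5, sc, proteinMg = 0.01)
  expect_equal(neg$activity, 0)
  expect_equal(neg$qc_flag, "below_blank")
})

test_that("activity shares sum to one per mouse and all-zero mice are undefined", {
  acts <- data.frame(mouse_id = rep(c("m1", "m2", "m3"), each = 2),
                     enzyme = rep(c("e1", "e2"), 3),
                     activity = c(3, 1, 5, 0, 0, 0))
  sh <- normalizeActivities(acts)
  expect_equal(sh$share[sh$mouse_id == "m1"], c(0.75, 0.25))
  expect_equal(sh$share[sh$mouse_id == "m2"], c(1, 0))
  expect_true(all(is.na(sh$share[sh$mouse_id == "m3"])))
  # six-enzyme hand check
  six <- data.frame(mouse_id = "m", enzyme = paste0("e", 1:6),
                    activity = c(10, 5, 25, 0, 40, 20))
  expect_equal(normalizeActivities(six)$share, c(10, 5, 25, 0, 40, 20) / 100)
})

test_that("qPCR copy numbers invert the log10 standard curve", {
  # 100% efficiency line: Cq = 40 - 3.3219 * log10(copies)
  lg <- 1:5
  sc <- fitStandardCurve(lg, 40 - 3.3219 * lg)
  expect_warning(one <- qpcrCopies(40, sc), "extrapolating")
  expect_equal(one, 1, tolerance = 1e-6)
  # cq = intercept + slope * k -> 10^k copies
  for (k in c(2, 3.5)) {
    expect_warning(
      copies <- qpcrCopies(intercept(sc) + slope(sc) * k, sc),
      if (k < min(lg) || k > max(lg)) "extrapolat" else NA)
    expect_equal(copies, 10^k, tolerance = 1e-6)
  }
  # 5-point synthetic dilution series round-trips within 1%
  set.seed(12)
  truth <- 10^(2:6)
  cq <- 38 - 3.4 * log10(truth) + rnorm(5, 0, 0.003)
  sc2 <- fitStandardCurve(log10(truth), cq)
  est <- qpcrCopies(cq, sc2)
  expect_true(all(abs(est / truth - 1) < 0.01))
  # rescaling to the 10 ng basis
  expect_equal(suppressWarnings(qpcrCopies(40, sc, rnaInputNg = 5)), 2,
               tolerance = 1e-6)
})

test_that("CFU per gram follows the dilution-plating arithmetic", {
  r <- cfuPerGram(30, 1e4, 0.1, 0.05, 1)
  expect_equal(r$cfu_per_g, 6e7)
  expect_false(r$censored)
  # zero colonies reported at the limit of detection, censored
  z <- cfuPerGram(0, 1e4, 0.1, 0.05, 1)
  expect_true(z$censored)
  expect_equal(z$cfu_per_g, z$lod)
  expect_equal(z$lod, 2e6)
  # doubling sample mass halves CFU/g
  expect_equal(cfuPerGram(30, 1e4, 0.1, 0.1, 1)$cfu_per_g, 3e7)
})

test_that("metabolomics preprocessing imputes at 20% of the minimum positive value", {
  tab <- data.frame(
    sample_id = rep(c("s1", "s2", "s3"), 3),
    metabolite = rep(c("a", "b", "c"), each = 3),
    peak_area = c(100, 200, NA, 30, NA, 90, NA, NA, NA),
    sample_weight_mg = rep(c(10, 20, 10), 3),
    group = rep(c("g1", "g1", "g2"), 3))
  expect_warning(out <- metabolomicsPreprocess(tab), "c")
  expect_false("c" %in% out$metabolite)
  a <- out[out$metabolite == "a", ]
  # weight-normalized: 10, 10, missing -> LOD = 2
  expect_equal(a$normalized, c(10, 10, 2))
  expect_equal(a$log_intensity, log10(c(10, 10, 2)))
  expect_equal(a$imputed, c(FALSE, FALSE, TRUE))
  b <- out[out$metabolite == "b", ]
  # normalized: 3, missing, 9 -> LOD = 0.6
  expect_equal(b$normalized, c(3, 0.6, 9))
  # no missing values -> identity up to weight division
  full <- tab[tab$metabolite == "a", ]
  full$peak_area <- c(100, 200, 50)
  outFull <- metabolomicsPreprocess(full)
  expect_equal(outFull$normalized, full$peak_area / full$sample_weight_mg)
  # commutes with sample reordering
  perm <- tab[c(5, 2, 8, 1, 9, 4, 7, 3, 6), ]
  expect_warning(outPerm <- metabolomicsPreprocess(perm), "c")
  key <- function(d) d[order(d$metabolite, d$sample_id),
                       c("metabolite", "sample_id", "normalized")]
  expect_equal(key(outPerm), key(out), ignore_attr = TRUE)
})

test_that("metabolite significance needs both the fold change and the exact p", {
  mk <- function(v1, v2, met = "m") {
    data.frame(sample_id = paste0("s", seq_len(length(v1) + length(v2))),
               metabolite = met,
               normalized = c(v1, v2),
               group = rep(c("g1", "g2"), c(length(v1), length(v2))))
  }
  # complete separation at n = 6 vs 6 gives p = 0.0022; FC 2 -> significant
  hit <- significantMetabolites(mk(1:6, 2 * (1:6) + 6.5))
  expect_true(hit$significant)
  # strong p but FC below 1.5 -> not significant
  nearMiss <- significantMetabolites(mk(seq(100, 105), seq(140, 145) + 0.1))
  expect_true(nearMiss$p_value < 0.05)
  expect_true(nearMiss$fold_change < 1.5)
  expect_false(nearMiss$significant)
  # big FC but overlapping groups -> p too large
  noP <- significantMetabolites(mk(c(1, 60, 2, 70), c(50, 3, 80, 4)))
  expect_false(noP$significant)
})

test_that("planted fold changes are recovered exactly in a low-noise table", {
  cfg <- simConfig(seed = 101, noiseSd = 0.01)
  met <- genMetaboliteTable(cfg, nMetabolites = 20, nPlanted = 5,
                            foldChange = 3, nPerGroup = 6, missingRate = 0)
  proc <- metabolomicsPreprocess(met$table)
  sig <- significantMetabolites(proc)
  expect_setequal(sig$metabolite[sig$significant],
                  names(met$truth$planted_fold_changes))
})
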