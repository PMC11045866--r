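test_that("low-abundance filter implements the keep rule and is idempotent", {
  at <- toyTable()
  # t4: present in 1 sample, total 500 -> removed despite high abundance
  f <- filterLowAbundance(at)
  expect_false("t4" %in% rownames(counts(f)))
  expect_true(all(c("t1", "t3", "t5") %in% rownames(counts(f))))
  expect_equal(ncol(counts(f)), 4)  # samples unchanged
  expect_true("t4" %in% attr(f, "removed")$taxon)
  # boundary: present in 3 samples, total 9 -> removed; total 10 -> kept
  m <- matrix(c(3L, 3L, 3L, 0L, 4L, 3L, 3L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("lo", "hi"), paste0("s", 1:4)))
  fb <- filterLowAbundance(AbundanceTable(m))
  expect_equal(rownames(counts(fb)), "hi")
  # identity thresholds
  f0 <- filterLowAbundance(at, minSamples = 0, minTotal = 0)
  expect_equal(counts(f0), counts(at))
  # idempotence
  expect_equal(counts(filterLowAbundance(f)), counts(f))
})

test_that("relative abundance columns sum to one and errors name zero samples", {
  at <- toyTable()
  rel <- relativeAbundance(at)
  expect_equal(unname(colSums(compValues(rel))), rep(1, 4))
  expect_equal(compTransform(rel), "relative")
  m <- matrix(c(2L, 2L, 0L, 0L), 2,
              dimnames = list(c("a", "b"), c("s1", "szero")))
  expect_error(relativeAbundance(AbundanceTable(m)), "szero")
  m2 <- matrix(c(2L, 2L), 2, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(compValues(relativeAbundance(AbundanceTable(m2)))[, 1]),
               c(0.5, 0.5))
})

test_that("CLR transform matches the direct formula and sums to zero", {
  m <- matrix(c(9L, 0L, 0L), 3, dimnames = list(c("a", "b", "c"), "s1"))
  clr <- clrTransform(AbundanceTable(m), pseudocount = 1)
  direct <- log(c(10, 1, 1)) - mean(log(c(10, 1, 1)))
  expect_equal(unname(compValues(clr)[, 1]), direct)
  # symmetry: equal counts give all zeros
  m4 <- matrix(rep(1L, 4), 4, dimnames = list(paste0("t", 1:4), "s"))
  expect_equal(unname(compValues(clrTransform(AbundanceTable(m4)))[, 1]),
               rep(0, 4))
  expect_error(clrTransform(toyTable(), pseudocount = 0), "positive")
  # property: zero column sums for arbitrary tables
  set.seed(31)
  cfg <- simConfig(seed = 31, nTaxa = 20, nParticipants = 3, nResponders = 0)
  tab <- genPairedCommunities(cfg)$table
  expect_equal(max(abs(colSums(compValues(clrTransform(tab))))), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(colSums(compValues(relativeAbundance(tab))) - 1)), 0,
               tolerance = 1e-9)
})

test_that("alpha diversity gives ln k for uniform and 0 for single-taxon samples", {
  k <- 7
  m <- matrix(rep(10L, k), k, dimnames = list(paste0("t", 1:k), "u"))
  a <- alphaDiversity(AbundanceTable(m))
  expect_equal(a$shannon, log(k))
  expect_equal(a$observed, k)
  m1 <- matrix(c(42L, 0L), 2, dimnames = list(c("a", "b"), "s"))
  a1 <- alphaDiversity(AbundanceTable(m1))
  expect_equal(a1$observed, 1L)
  expect_equal(a1$shannon, 0)
  # hand computation for p = (0.5, 0.25, 0.25)
  m2 <- matrix(c(2L, 1L, 1L), 3, dimnames = list(c("a", "b", "c"), "s"))
  expect_equal(alphaDiversity(AbundanceTable(m2))$shannon,
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
})

test_that("rarefaction hits the exact depth, is seeded, and preserves support direction", {
  at <- toyTable()
  depth <- min(colSums(counts(at)))
  r1 <- rarefyTable(at, depth, seed = 5)
  r2 <- rarefyTable(at, depth, seed = 5)
  expect_identical(counts(r1), counts(r2))
  expect_equal(unname(colSums(counts(r1))), rep(depth, 4))
  # absent taxa stay absent
  expect_true(all(counts(r1)[counts(at) == 0] == 0))
  # depth equal to a sample total reproduces that sample exactly
  full <- rarefyTable(at, depth, seed = 1)
  shallowest <- which.min(colSums(counts(at)))
  expect_equal(counts(full)[, shallowest], counts(at)[, shallowest])
  expect_error(rarefyTable(at, 10000, seed = 1), "exceeds")
})

test_that("rarefied counts are unbiased for taxon proportions", {
  m <- matrix(c(60L, 30L, 10L), 3, dimnames = list(c("a", "b", "c"), "s"))
  at <- AbundanceTable(m)
  depth <- 20
  draws <- vapply(1:200, function(s) counts(rarefyTable(at, depth, seed = s))[, 1],
                  numeric(3))
  expected <- depth * c(0.6, 0.3, 0.1)
  se <- sqrt(depth * c(0.6, 0.3, 0.1) * c(0.4, 0.7, 0.9)) / sqrt(200)
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se))
})

test_that("core genera reproduce hand-enumerated sets and nest by prevalence", {
  # group A (s1, s2): Ga in both (t1 or t3 > 0), Gb in s2 only, Gc in both
  rel <- relativeAbundance(toyTable())
  core80 <- coreGenera(rel, 0.8)
  expect_equal(core80$A, c("Ga", "Gc"))
  expect_equal(core80$B, c("Ga", "Gc"))
  core25 <- coreGenera(rel, 0.25)
  expect_true(all(core80$A %in% core25$A))
  expect_true("Gb" %in% core25$A)
  # boundary: 4 of 5 samples at prevalence 0.8 is core
  m <- rbind(t = c(1L, 1L, 1L, 1L, 0L), filler = rep(1L, 5))
  colnames(m) <- paste0("s", 1:5)
  tax <- data.frame(genus = c("G", "F"), row.names = c("t", "filler"))
  tab <- AbundanceTable(m, taxonomy = tax,
                        groups = setNames(rep("grp", 5), paste0("s", 1:5)))
  expect_equal(coreGenera(relativeAbundance(tab), 0.8)$grp, c("F", "G"))
  # 3 of 5 at prevalence 0.8 is not core
  m2 <- m; m2["t", 4] <- 0L
  tab2 <- AbundanceTable(m2, taxonomy = tax,
                         groups = setNames(rep("grp", 5), paste0("s", 1:5)))
  expect_equal(coreGenera(relativeAbundance(tab2), 0.8)$grp, "F")
  expect_error(coreGenera(relativeAbundance(AbundanceTable(m, taxonomy = tax)),
                          0.8), "group")
})

test_that("group-maximum normalization scales group means against the best group", {
  # three groups with genus means (2, 1, 4) -> (50, 25, 100)
  m <- matrix(c(2L, 1L, 4L,
                2L, 3L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("tA", "tB"), c("s1", "s2", "s3")))
  tab <- AbundanceTable(m,
                        taxonomy = data.frame(genus = c("GA", "GB"),
                                              row.names = c("tA", "tB")),
                        groups = c(s1 = "g1", s2 = "g2", s3 = "g3"))
  rel <- CompositionTable(matrix(as.numeric(m), 2, 3,
                                 dimnames = dimnames(m)), "relative",
                          taxonomy = taxonomy(tab),
                          groups = sampleGroups(tab))
  pct <- groupMaxNormalize(rel)
  expect_equal(unname(pct["GA", ]), c(50, 25, 100))
  expect_equal(unname(pct["GB", ]), c(100 * 2 / 3, 100, 0))
  # single group -> always 100 where nonzero
  rel1 <- CompositionTable(matrix(c(1, 2), 2, 1,
                                  dimnames = list(c("tA", "tB"), "s1")),
                           "relative",
                           taxonomy = taxonomy(tab), groups = c(s1 = "g"))
  expect_equal(unname(groupMaxNormalize(rel1)[, 1]), c(100, 100))
  # all-zero genus undefined
  relz <- CompositionTable(matrix(c(0, 0, 0, 1, 1, 1), nrow = 2, byrow = TRUE,
                                  dimnames = dimnames(m)), "relative",
                           taxonomy = taxonomy(tab),
                           groups = c(s1 = "g1", s2 = "g2", s3 = "g3"))
  expect_true(all(is.na(groupMaxNormalize(relz)["GA", ])))
})

test_that("assignment rate counts non-missing labels", {
  tax <- data.frame(genus = c(rep("g", 3), NA, ""))
  expect_equal(assignmentRate(tax), 60)
  expect_error(assignmentRate(data.frame(phylum = "p")), "genus")
})
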