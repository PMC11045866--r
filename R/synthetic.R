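## Synthetic-data generators with planted ground truth. Every generator draws
## from its own seed stream derived from the global seed, so adding or
## reordering generators never perturbs the others, and identical configs
## give identical outputs.

#' Simulation configuration
#'
#' Central parameter object for all generators. Defaults reflect the study
#' design the generators emulate: a 67-participant fiber-intervention cohort
#' with a small planted responder subset, paired pre/post communities on a
#' shared phylogeny, and bead clouds whose penetration depths follow a
#' truncated exponential with a dense mode at the mucus surface.
#'
#' @param seed integer seed; identical configs give bit-identical outputs.
#' @param nParticipants cohort size (default 67).
#' @param nResponders planted strong responders (default 5).
#' @param responderEffect mean improvement of responders per metabolic
#'   parameter, as a fraction of baseline (default 0.1).
#' @param nTaxa taxa on the shared tree (default 50, >= 3).
#' @param nSamplesPerGroup samples per experimental group (default 8).
#' @param shiftScale nonnegative scale of the pre-to-post community
#'   displacement (default 0.5).
#' @param beadLambda mean bead penetration depth, um (default 29; with the
#'   other defaults the planted fraction of beads within 10 um of the
#'   epithelium is about 0.25).
#' @param beadSurfaceHeight mucus surface height above the epithelium, um
#'   (default 97.5).
#' @param noiseSd nonnegative noise scale; interpreted per generator (a
#'   fraction of baseline for the cohort, signal units for plates; see the
#'   individual generators). Default 0.05.
#' @return a validated `simConfig` list.
#' @export
simConfig <- function(seed = 1L, nParticipants = 67L, nResponders = 5L,
                      responderEffect = 0.1, nTaxa = 50L,
                      nSamplesPerGroup = 8L, shiftScale = 0.5,
                      beadLambda = 29, beadSurfaceHeight = 97.5,
                      noiseSd = 0.05) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid config field '", field, "': ", msg,
                          call. = FALSE)
  }
  chk(isCount(seed), "seed", "must be a nonnegative integer")
  chk(isCount(nParticipants) && nParticipants >= 1, "nParticipants",
      "must be a positive integer")
  chk(isCount(nResponders), "nResponders", "must be a nonnegative integer")
  chk(nResponders <= nParticipants, "nResponders",
      "must not exceed nParticipants")
  chk(is.finite(responderEffect) && responderEffect >= 0, "responderEffect",
      "must be >= 0")
  chk(isCount(nTaxa), "nTaxa", "must be a nonnegative integer")
  chk(isCount(nSamplesPerGroup) && nSamplesPerGroup >= 1, "nSamplesPerGroup",
      "must be a positive integer")
  chk(is.finite(shiftScale) && shiftScale >= 0, "shiftScale", "must be >= 0")
  chk(is.finite(beadLambda) && beadLambda >= 0, "beadLambda", "must be >= 0")
  chk(is.finite(beadSurfaceHeight) && beadSurfaceHeight > 0,
      "beadSurfaceHeight", "must be > 0")
  chk(is.finite(noiseSd) && noiseSd >= 0, "noiseSd", "must be >= 0")
  structure(list(seed = as.integer(seed),
                 nParticipants = as.integer(nParticipants),
                 nResponders = as.integer(nResponders),
                 responderEffect = responderEffect,
                 nTaxa = as.integer(nTaxa),
                 nSamplesPerGroup = as.integer(nSamplesPerGroup),
                 shiftScale = shiftScale, beadLambda = beadLambda,
                 beadSurfaceHeight = beadSurfaceHeight, noiseSd = noiseSd),
            class = "simConfig")
}

participantIds <- function(config) {
  sprintf("P%02d", seq_len(config$nParticipants))
}

#' Planted responder ids of a configuration
#'
#' The responder subset is drawn once from its own seed stream, so the cohort
#' and community generators agree on who the responders are.
#'
#' @param config a [simConfig()].
#' @return character vector of participant ids.
#' @export
plantedResponders <- function(config) {
  ids <- participantIds(config)
  withSeed(deriveSeed(config$seed, "cohort"),
           sort(sample(ids, config$nResponders)))
}

# Realistic middle-aged baselines for the six metabolic parameters
# (mean, sd): WHR, BMI (kg/m^2), fat-free mass (kg), total cholesterol
# (mmol/l), triglycerides (mmol/l), fasting glucose (mmol/l).
metabolicBaselines <- list(
  waist_to_hip_ratio = c(0.92, 0.08), body_mass_index = c(27, 3.5),
  free_fat_mass = c(55, 8), cholesterol = c(5.3, 1.0),
  triglycerides = c(1.5, 0.5), glucose = c(5.6, 0.6)
)

#' Synthetic paired metabolic cohort
#'
#' One row per participant with pre and post values for the six metabolic
#' parameters. Planted responders receive improvement deltas of mean
#' `responderEffect * baseline` (in the direction that counts as
#' improvement) plus noise; non-responders receive zero-mean noise of sd
#' `noiseSd * baseline`. With `responderEffect = 0` and `noiseSd = 0` all
#' deltas are exactly zero.
#'
#' @param config a [simConfig()].
#' @param directions improvement directions, see [defaultDirections()].
#' @return list with `cohort` (data.frame) and `truth`
#'   (`list(responder_ids)`).
#' @export
genCohort <- function(config, directions = defaultDirections()) {
  stopIfNot(inherits(config, "simConfig"), "config must come from simConfig()")
  ids <- participantIds(config)
  responders <- plantedResponders(config)
  cohort <- withSeed(deriveSeed(config$seed, "cohort") + 1L, {
    df <- data.frame(participant_id = ids,
                     sex = sample(c("m", "f"), length(ids), replace = TRUE))
    for (p in names(metabolicBaselines)) {
      b <- metabolicBaselines[[p]]
      pre <- rnorm(length(ids), b[1], b[2])
      pre <- pmax(pre, b[1] * 0.3)
      eff <- ifelse(ids %in% responders, config$responderEffect, 0)
      delta <- eff * pre + rnorm(length(ids), 0, config$noiseSd * pre)
      post <- if (directions[[p]] == "decrease") pre - delta else pre + delta
      df[[paste0(p, "_pre")]] <- pre
      df[[paste0(p, "_post")]] <- post
    }
    df
  })
  list(cohort = cohort, truth = list(responder_ids = responders))
}

#' Synthetic paired pre/post communities on a shared phylogeny
#'
#' Builds a random rooted bifurcating tree with exponential branch lengths
#' and, per participant, a log-normal baseline community; the post sample is
#' the baseline displaced in log space by `shiftScale * (1 + responderBonus)`
#' for responders (`shiftScale` alone otherwise), rescaled to the target
#' depth and Poisson-sampled to integer counts. With `shiftScale = 0` the
#' post counts equal the pre counts exactly.
#'
#' @param config a [simConfig()] with `nTaxa >= 3`.
#' @param participants ids to simulate (default: the whole cohort).
#' @param responderBonus extra displacement factor for planted responders
#'   (default 2, i.e. responders shift three times as much).
#' @param depth target reads per sample (default 10000).
#' @return list with `table` (an [AbundanceTable], samples named
#'   `<id>_pre`/`<id>_post`), `tree` (rooted `phylo`) and `truth`
#'   (`responder_ids`, per-participant displacement used).
#' @export
genPairedCommunities <- function(config, participants = NULL,
                                 responderBonus = 2, depth = 10000L) {
  stopIfNot(inherits(config, "simConfig"), "config must come from simConfig()")
  stopIfNot(config$nTaxa >= 3, "nTaxa must be >= 3")
  if (is.null(participants)) participants <- participantIds(config)
  responders <- plantedResponders(config)
  taxa <- sprintf("taxon_%03d", seq_len(config$nTaxa))
  out <- withSeed(deriveSeed(config$seed, "communities"), {
    tree <- ape::rtree(config$nTaxa, br = stats::rexp)
    tree$tip.label <- taxa
    # genus/phylum labels; a minority of taxa stay unassigned at genus level,
    # as in real amplicon tables
    nGenera <- max(3L, config$nTaxa %/% 4L)
    genus <- sprintf("Genus%02d", sample.int(nGenera, config$nTaxa,
                                             replace = TRUE))
    genus[runif(config$nTaxa) < 0.13] <- NA_character_
    tax <- data.frame(
      phylum = sprintf("Phylum%d",
                       1L + (as.integer(factor(genus, exclude = NULL)) %% 4L)),
      genus = genus, row.names = taxa)
    logMu <- rnorm(config$nTaxa, 0, 1.5)
    cnt <- matrix(0L, config$nTaxa, 2 * length(participants),
                  dimnames = list(taxa, paste0(rep(participants, each = 2),
                                               c("_pre", "_post"))))
    displacement <- setNames(
      config$shiftScale * (1 + ifelse(participants %in% responders,
                                      responderBonus, 0)),
      participants)
    for (pid in participants) {
      logPre <- logMu + rnorm(config$nTaxa, 0, 0.7)
      lamPre <- exp(logPre) / sum(exp(logPre)) * depth
      pre <- rpois(config$nTaxa, lamPre)
      if (displacement[[pid]] == 0) {
        post <- pre
      } else {
        logPost <- logPre + displacement[[pid]] * rnorm(config$nTaxa)
        lamPost <- exp(logPost) / sum(exp(logPost)) * depth
        post <- rpois(config$nTaxa, lamPost)
      }
      cnt[, paste0(pid, "_pre")] <- pre
      cnt[, paste0(pid, "_post")] <- post
    }
    list(tree = tree, cnt = cnt, displacement = displacement, tax = tax)
  })
  list(table = AbundanceTable(out$cnt, taxonomy = out$tax), tree = out$tree,
       truth = list(responder_ids = intersect(responders, participants),
                    displacement = out$displacement))
}

# Smooth synthetic epithelial height field over a square footprint (um).
epitheliumField <- function(extent = 200, step = 20, base = 15, amp = 4) {
  x <- seq(0, extent, by = step)
  y <- seq(0, extent, by = step)
  h <- outer(x, y, function(xx, yy) {
    base + amp * sin(xx / 45) + amp * cos(yy / 60)
  })
  list(x = x, y = y, h = h)
}

#' Synthetic 3D bead cloud over a smooth epithelium
#'
#' Bead heights above the epithelium are drawn from an exponential law with
#' mean `beadLambda`, truncated at the mucus surface (`beadSurfaceHeight`),
#' plus a dense mode at the surface holding a fraction `surfaceFrac` of the
#' beads: sedimented beads that did not penetrate, localized to the surface
#' with a symmetric +/- `modeSpread` um error (the z-step localization
#' limit), so some of them sit nominally above it. Ground truth records, per
#' image, the realized fraction of in-mucus beads (true depth at most the
#' surface height) within `zoneUm` of the epithelium -- the quantity
#' [penetrability()] estimates.
#'
#' @param config a [simConfig()].
#' @param nBeads beads per image (>= 1; the emulated images carry 500-1000).
#' @param nImages images to generate (default 1).
#' @param mouseId mouse label (default "m1").
#' @param surfaceFrac fraction of beads in the surface mode (default 0.3;
#'   0 disables the mode).
#' @param modeSpread half-width of the surface mode, um (default 2.5, half
#'   the confocal z-step).
#' @param zoneUm zone for the ground-truth fraction (default 10 um).
#' @return list with `cloud` (a [BeadCloud-class]) and `truth` (data.frame of
#'   per-image realized `fraction_within_zone`, plus the surface height).
#' @export
genBeadCloud <- function(config, nBeads, nImages = 1L, mouseId = "m1",
                         surfaceFrac = 0.3, modeSpread = 2.5, zoneUm = 10) {
  stopIfNot(inherits(config, "simConfig"), "config must come from simConfig()")
  stopIfNot(isCount(nBeads) && nBeads >= 1, "nBeads must be >= 1")
  stopIfNot(surfaceFrac >= 0 && surfaceFrac < 1, "surfaceFrac must be in [0, 1)")
  epi <- epitheliumField()
  H <- config$beadSurfaceHeight
  lam <- config$beadLambda
  res <- withSeed(deriveSeed(config$seed, "beads"), {
    perImage <- lapply(seq_len(nImages), function(i) {
      x <- runif(nBeads, min(epi$x), max(epi$x))
      y <- runif(nBeads, min(epi$y), max(epi$y))
      atSurface <- runif(nBeads) < surfaceFrac
      u <- runif(nBeads)
      depth <- if (lam == 0) {
        rep(0, nBeads)
      } else {
        -lam * log(1 - u * (1 - exp(-H / lam)))
      }
      depth[atSurface] <- H + runif(sum(atSurface), -modeSpread, modeSpread)
      data.frame(image_id = sprintf("%s_img%d", mouseId, i),
                 mouse_id = mouseId, x_um = x, y_um = y,
                 depth_um = depth)
    })
    do.call(rbind, perImage)
  })
  h <- epithelialHeight(epi, res$x_um, res$y_um)
  beadsDf <- data.frame(image_id = res$image_id, mouse_id = res$mouse_id,
                        x_um = res$x_um, y_um = res$y_um,
                        z_um = h + res$depth_um)
  truth <- do.call(rbind, lapply(split(res, res$image_id), function(img) {
    inMucus <- img$depth_um <= H
    data.frame(image_id = img$image_id[1],
               fraction_within_zone =
                 sum(img$depth_um[inMucus] <= zoneUm) / sum(inMucus),
               surface_um = H, row.names = NULL)
  }))
  rownames(truth) <- NULL
  list(cloud = BeadCloud(beadsDf, epithelium = epi), truth = truth)
}

#' Synthetic mucus-thickness experiment
#'
#' Per mouse, `nSites` measurement sites at two timepoints; the late
#' thickness is `thickness(t0) + (t1 - t0) * groupRate + noise`. With
#' `noiseUm = 0` the group rate is recovered exactly by [growthRate()].
#'
#' @param config a [simConfig()].
#' @param groupRates named numeric vector of true growth rates (um/min) per
#'   group.
#' @param nMicePerGroup mice per group (default `config$nSamplesPerGroup`).
#' @param nSites sites per mouse per timepoint (default 5).
#' @param times the two timepoints in minutes (default `c(0, 45)`).
#' @param baselineUm mean baseline thickness (default 80 um; sites vary
#'   around it with sd 10 um).
#' @param noiseUm sd of the measurement noise on the late thickness, um
#'   (default `45 * config$noiseSd`, i.e. `noiseSd` um/min on the rate
#'   scale).
#' @return list with `series` (data.frame: `mouse_id`, `group`, `site`,
#'   `time_min`, `thickness_um`) and `truth` (named vector of group rates).
#' @export
genMucusExperiment <- function(config, groupRates = c(chow = 2, wsd = 0.7),
                               nMicePerGroup = config$nSamplesPerGroup,
                               nSites = 5L, times = c(0, 45),
                               baselineUm = 80, noiseUm = 45 * config$noiseSd) {
  stopIfNot(inherits(config, "simConfig"), "config must come from simConfig()")
  stopIfNot(!is.null(names(groupRates)) && length(groupRates) >= 1,
            "groupRates must be a named vector")
  stopIfNot(length(times) == 2 && times[2] > times[1],
            "times must be two increasing timepoints")
  dt <- times[2] - times[1]
  series <- withSeed(deriveSeed(config$seed, "mucus"), {
    rows <- lapply(names(groupRates), function(g) {
      lapply(seq_len(nMicePerGroup), function(m) {
        t0 <- baselineUm + rnorm(nSites, 0, 10)
        t1 <- t0 + dt * groupRates[[g]] + rnorm(nSites, 0, noiseUm)
        data.frame(mouse_id = sprintf("%s_m%02d", g, m), group = g,
                   site = rep(seq_len(nSites), 2),
                   time_min = rep(times, each = nSites),
                   thickness_um = pmax(c(t0, t1), 0))
      })
    })
    do.call(rbind, unlist(rows, recursive = FALSE))
  })
  rownames(series) <- NULL
  list(series = series, truth = groupRates)
}

#' Synthetic assay plate with a two-fold standard dilution series
#'
#' Standards follow `signal = slope * concentration + intercept + noise` over
#' a serial two-fold dilution from `topConcUm`; unknown wells are generated
#' in duplicate from planted enzyme activities via the same line
#' (`concentration = activity * timeMin * proteinMg`).
#'
#' @param config a [simConfig()]; `config$noiseSd` is the sd of the signal
#'   noise (signal units).
#' @param activities named vector of planted activities (uM min^-1 mg^-1) for
#'   the unknown samples.
#' @param topConcUm top standard concentration (default 200 uM).
#' @param nDilutions dilution steps (default 8, >= 4).
#' @param slope,intercept true line parameters (defaults 0.005, 0.04).
#' @param timeMin,proteinMg assay conditions (defaults 45 min, 0.01 mg).
#' @return list with `plate` (data.frame: `well`, `analyte`, `role`,
#'   `x_value`, `signal`) and `truth` (`slope`, `intercept`, `activities`).
#' @export
genAssayPlate <- function(config, activities = c(bglucosidase = 100,
                                                 bxylosidase = 40),
                          topConcUm = 200, nDilutions = 8L,
                          slope = 0.005, intercept = 0.04,
                          timeMin = 45, proteinMg = 0.01) {
  stopIfNot(inherits(config, "simConfig"), "config must come from simConfig()")
  stopIfNot(topConcUm > 0, "topConcUm must be positive")
  stopIfNot(isCount(nDilutions) && nDilutions >= 4, "need >= 4 dilution steps")
  conc <- topConcUm / 2^(seq_len(nDilutions) - 1)
  plate <- withSeed(deriveSeed(config$seed, "plate"), {
    std <- data.frame(well = sprintf("S%02d", seq_along(conc)),
                      analyte = "4NP_standard", role = "standard",
                      x_value = conc,
                      signal = slope * conc + intercept +
                        rnorm(length(conc), 0, config$noiseSd))
    unk <- do.call(rbind, lapply(names(activities), function(a) {
      released <- activities[[a]] * timeMin * proteinMg
      data.frame(well = paste0(a, c("_1", "_2")), analyte = a,
                 role = "sample", x_value = NA_real_,
                 signal = slope * released + intercept +
                   rnorm(2, 0, config$noiseSd))
    }))
    rbind(std, unk)
  })
  rownames(plate) <- NULL
  list(plate = plate,
       truth = list(slope = slope, intercept = intercept,
                    activities = activities, timeMin = timeMin,
                    proteinMg = proteinMg))
}

#' Synthetic metabolite peak table with planted fold changes
#'
#' Log-normal baseline intensities per metabolite; a planted subset is
#' multiplied by `foldChange` in the second group. Peak areas are the
#' intensities times the per-sample weight; a fraction of entries is set
#' missing at random.
#'
#' @param config a [simConfig()]; `config$noiseSd` scales the log-normal
#'   within-group spread (sdlog).
#' @param nMetabolites total metabolites (default 20).
#' @param nPlanted metabolites carrying the fold change (default 5).
#' @param foldChange planted group-2/group-1 ratio (default 3).
#' @param nPerGroup samples per group (default 6).
#' @param missingRate probability an entry is missing (default 0.1; planted
#'   metabolites are never fully missing).
#' @return list with `table` (data.frame: `sample_id`, `group`, `metabolite`,
#'   `peak_area`, `sample_weight_mg`) and `truth` (named planted fold
#'   changes).
#' @export
genMetaboliteTable <- function(config, nMetabolites = 20L, nPlanted = 5L,
                               foldChange = 3, nPerGroup = 6L,
                               missingRate = 0.1) {
  stopIfNot(inherits(config, "simConfig"), "config must come from simConfig()")
  stopIfNot(nPlanted <= nMetabolites, "nPlanted must not exceed nMetabolites")
  mets <- sprintf("met_%02d", seq_len(nMetabolites))
  res <- withSeed(deriveSeed(config$seed, "metabolites"), {
    planted <- sort(sample(mets, nPlanted))
    samples <- data.frame(
      sample_id = sprintf("s%02d", seq_len(2 * nPerGroup)),
      group = rep(c("control", "treated"), each = nPerGroup),
      sample_weight_mg = rnorm(2 * nPerGroup, 50, 5))
    rows <- do.call(rbind, lapply(mets, function(m) {
      base <- rlnorm(1, meanlog = 5, sdlog = 1)
      mu <- ifelse(samples$group == "treated" & m %in% planted,
                   base * foldChange, base)
      intensity <- rlnorm(nrow(samples), meanlog = log(mu),
                          sdlog = config$noiseSd)
      area <- intensity * samples$sample_weight_mg
      miss <- runif(nrow(samples)) < missingRate
      # never blank out a whole metabolite
      if (all(miss)) miss[1] <- FALSE
      area[miss] <- NA_real_
      data.frame(sample_id = samples$sample_id, group = samples$group,
                 metabolite = m, peak_area = area,
                 sample_weight_mg = samples$sample_weight_mg)
    }))
    list(rows = rows, planted = planted)
  })
  rownames(res$rows) <- NULL
  list(table = res$rows,
       truth = list(planted_fold_changes =
                      setNames(rep(foldChange, length(res$planted)),
                               res$planted)))
}
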