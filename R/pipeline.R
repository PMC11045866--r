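## End-to-end orchestration over synthetic data: simulate -> donor ranking ->
## diversity shifts -> mucus metrics -> taxa-phenotype correlation -> assay
## quantification, with tidy CSV outputs and a JSON run manifest.

pipelineStages <- c("donors", "diversity", "mucus", "correlate", "assays")

#' Run the full synthetic-to-report pipeline
#'
#' Executes the enabled stages on data from the synthetic generators and, if
#' `outDir` is given, writes each stage's tidy CSV outputs plus a JSON
#' manifest recording the seed, every numeric decision (zone and bin widths,
#' pseudocount, ranking directions, shortlist sizes, thresholds) and the md5
#' of every written file. Deterministic under a fixed config.
#'
#' @param config a [simConfig()].
#' @param outDir output directory (created if missing); `NULL` = no files.
#' @param stages subset of `c("donors", "diversity", "mucus", "correlate",
#'   "assays")` to run (default all).
#' @param topMetabolic,nDonors donor-selection sizes (defaults 10 and 5).
#' @param zoneUm,binUm penetrability parameters (defaults 10 and 5 um).
#' @param pseudocount CLR pseudocount (default 1).
#' @param fcThreshold,pThreshold metabolite significance thresholds
#'   (defaults 1.5 and 0.05).
#' @return named list of stage results plus `manifest`.
#' @export
runPipeline <- function(config = simConfig(), outDir = NULL,
                        stages = pipelineStages,
                        topMetabolic = 10L, nDonors = 5L,
                        zoneUm = 10, binUm = 5, pseudocount = 1,
                        fcThreshold = 1.5, pThreshold = 0.05) {
  stopIfNot(inherits(config, "simConfig"), "config must come from simConfig()")
  stages <- match.arg(stages, pipelineStages, several.ok = TRUE)
  results <- list()
  files <- character(0)
  emit <- function(df, name) {
    if (!is.null(outDir)) {
      if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
      path <- file.path(outDir, paste0(name, ".csv"))
      utils::write.csv(df, path, row.names = FALSE)
      files <<- c(files, path)
    }
  }
  runStage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  com <- NULL
  if (any(c("donors", "diversity", "correlate") %in% stages)) {
    com <- genPairedCommunities(config)
  }

  if ("donors" %in% stages) {
    results$donors <- runStage("donors", function() {
      coh <- genCohort(config)
      metabolic <- rankMetabolic(coh$cohort)
      topSet <- metabolic$participant_id[seq_len(topMetabolic)]
      sub <- com$table[, c(paste0(topSet, "_pre"), paste0(topSet, "_post"))]
      shifts <- communityShifts(sub, com$tree)
      gut <- rankMicrobiotaShift(shifts)
      sel <- selectDonors(metabolic, gut, topMetabolic = topMetabolic,
                          nDonors = nDonors)
      emit(metabolic, "metabolic_ranking")
      emit(gut, "gut_ranking")
      emit(sel$audit, "donor_audit")
      list(selection = sel, metabolic = metabolic, gut = gut,
           shifts = shifts, truth = coh$truth)
    })
  }

  if ("diversity" %in% stages) {
    results$diversity <- runStage("diversity", function() {
      filtered <- filterLowAbundance(com$table)
      alpha <- alphaDiversity(filtered)
      emit(alpha, "alpha_diversity")
      list(alpha = alpha, filtered = filtered)
    })
  }

  if ("mucus" %in% stages) {
    results$mucus <- runStage("mucus", function() {
      exp <- genMucusExperiment(config)
      rates <- growthRate(exp$series)
      bc <- genBeadCloud(config, nBeads = 750, nImages = 3)
      pen <- penetrability(bc$cloud, zoneUm = zoneUm, binUm = binUm)
      emit(rates, "growth_rates")
      emit(pen$images, "penetrability_images")
      emit(pen$perMouse, "penetrability_per_mouse")
      list(rates = rates, penetrability = pen, truth_rates = exp$truth,
           truth_beads = bc$truth)
    })
  }

  if ("correlate" %in% stages) {
    results$correlate <- runStage("correlate", function() {
      pre <- com$table[, grep("_pre$", colnames(counts(com$table)))]
      clr <- clrTransform(filterLowAbundance(pre),
                          pseudocount = pseudocount)
      rel <- relativeAbundance(filterLowAbundance(pre))
      # planted phenotype: driven by the most abundant genus plus noise
      gv <- genusAbundance(clr)
      topGenus <- names(which.max(rowMeans(genusAbundance(rel))))
      phenotype <- withSeed(deriveSeed(config$seed, "pipeline"), {
        gv[topGenus, ] + rnorm(ncol(gv), 0, stats::sd(gv[topGenus, ]) / 2)
      })
      screen <- correlateTaxaPhenotype(clr, phenotype, topN = 30,
                                       ranking = rel)
      emit(screen, "genus_phenotype_correlations")
      list(screen = screen, planted_genus = topGenus)
    })
  }

  if ("assays" %in% stages) {
    results$assays <- runStage("assays", function() {
      pl <- genAssayPlate(config)
      std <- pl$plate[pl$plate$role == "standard", ]
      curve <- fitStandardCurve(std$x_value, std$signal)
      acts <- do.call(rbind, lapply(
        split(pl$plate[pl$plate$role == "sample", ],
              pl$plate$analyte[pl$plate$role == "sample"]),
        function(w) {
          ea <- enzymeActivity(w$signal, curve,
                               timeMin = pl$truth$timeMin,
                               proteinMg = pl$truth$proteinMg)
          data.frame(mouse_id = "m1", enzyme = w$analyte[1],
                     activity = ea$activity, qc_flag = ea$qc_flag)
        }))
      shares <- normalizeActivities(acts)
      met <- genMetaboliteTable(config)
      proc <- metabolomicsPreprocess(met$table)
      sig <- significantMetabolites(proc, fcThreshold = fcThreshold,
                                    pThreshold = pThreshold)
      emit(shares, "enzyme_shares")
      emit(sig, "significant_metabolites")
      list(curve = curve, shares = shares, metabolites = sig,
           truth = met$truth)
    })
  }

  manifest <- list(
    package = "mucoflow",
    seed = config$seed,
    config = unclass(config),
    stages = stages,
    parameters = list(
      topMetabolic = topMetabolic, nDonors = nDonors, zoneUm = zoneUm,
      binUm = binUm, pseudocount = pseudocount, fcThreshold = fcThreshold,
      pThreshold = pThreshold, directions = as.list(defaultDirections()),
      rank_combination = "mean rank (Borda), ties share the mean rank",
      unifrac_normalization = "sum b(px+py) (generalized alpha = 1)",
      bray_curtis = "proportions-first",
      quartiles = "linear interpolation (type 7)",
      shannon_log_base = "natural"
    ),
    outputs = if (length(files) > 0) {
      as.list(setNames(unname(tools::md5sum(files)), basename(files)))
    } else list()
  )
  if (!is.null(outDir)) {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results$manifest <- manifest
  results
}

#' Human-readable summary of a pipeline run
#'
#' @param results list returned by [runPipeline()].
#' @param path optional file to write the report to.
#' @return character vector of report lines (invisibly when written).
#' @export
makeReport <- function(results, path = NULL) {
  lines <- c("mucoflow pipeline report",
             paste0("seed: ", results$manifest$seed), "")
  sec <- function(title, body) c(paste0("== ", title, " =="), body, "")
  lines <- c(lines, sec("Donor selection", if (is.null(results$donors)) {
    "not run"
  } else {
    c(paste("selected donors:",
            paste(results$donors$selection$donors, collapse = ", ")),
      utils::capture.output(print(results$donors$selection$audit)))
  }))
  lines <- c(lines, sec("Mucus function", if (is.null(results$mucus)) {
    "not run"
  } else {
    rates <- results$mucus$rates
    byGroup <- aggregate(rate_um_min ~ group, data = rates, FUN = mean)
    c("mean growth rate (um/min) per group:",
      utils::capture.output(print(byGroup)),
      "penetrability (fraction of beads within the near-epithelium zone):",
      utils::capture.output(print(results$mucus$penetrability$perMouse)))
  }))
  lines <- c(lines, sec("Genus-phenotype correlations",
                        if (is.null(results$correlate)) {
    "not run"
  } else {
    utils::capture.output(print(head(results$correlate$screen, 10)))
  }))
  lines <- c(lines, sec("Assays", if (is.null(results$assays)) {
    "not run"
  } else {
    c(utils::capture.output(print(results$assays$shares)),
      "significant metabolites:",
      utils::capture.output(
        print(results$assays$metabolites[
          results$assays$metabolites$significant, ])))
  }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
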