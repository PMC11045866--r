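## Standard-curve based quantification: carbohydrate hydrolase (CAZy)
## activity, qPCR copy numbers, CFU per gram and metabolomics preprocessing.

#' Fit a linear standard curve
#'
#' Ordinary least squares of signal on x (concentration, or log10 copies for
#' qPCR). A constant-signal series yields slope 0 with `rSquared()` reported
#' as `NA` (undefined), not 1.
#'
#' @param x predictor values (>= 4 points, >= 3 distinct).
#' @param signal measured response.
#' @return a [StandardCurve-class].
#' @examples
#' sc <- fitStandardCurve(1:5, 2 * (1:5) + 1)
#' slope(sc); intercept(sc); rSquared(sc)
#' @export
fitStandardCurve <- function(x, signal) {
  stopIfNot(length(x) == length(signal), "x and signal must have equal length")
  stopIfNot(length(x) >= 4, "need at least 4 standard points")
  stopIfNot(length(unique(x)) >= 3, "need at least 3 distinct x values")
  stopIfNot(all(is.finite(x)) && all(is.finite(signal)),
            "standard points must be finite")
  fit <- lm(signal ~ x)
  ss_tot <- sum((signal - mean(signal))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(fit$residuals^2) / ss_tot
  new("StandardCurve",
      points = data.frame(x = x, signal = signal),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r_squared = r2)
}

#' Enzyme activity from endpoint signal
#'
#' Converts an endpoint absorbance/fluorescence reading into enzyme activity:
#' replicate signals are averaged, the released product concentration is read
#' off the standard curve (`(signal - intercept) / slope`, uM), and activity
#' is `concentration / (timeMin * proteinMg)` in uM min^-1 mg^-1. Readings
#' below the curve intercept (blank) give negative concentrations; these are
#' floored at zero activity and flagged.
#'
#' @param signal numeric vector of replicate signals for one sample/enzyme.
#' @param curve a [StandardCurve-class] of signal vs concentration (uM).
#' @param timeMin incubation time in minutes (default 45).
#' @param proteinMg protein input in mg.
#' @return list: `activity` (uM min^-1 mg^-1), `concentration_um`,
#'   `replicates` (the input signals), `qc_flag` (`"below_blank"` or `"ok"`).
#' @export
enzymeActivity <- function(signal, curve, timeMin = 45, proteinMg) {
  stopIfNot(is(curve, "StandardCurve"), "curve must be a StandardCurve")
  stopIfNot(timeMin > 0, "timeMin must be positive")
  stopIfNot(proteinMg > 0, "proteinMg must be positive")
  stopIfNot(slope(curve) != 0, "degenerate standard curve (zero slope)")
  conc <- (mean(signal) - intercept(curve)) / slope(curve)
  flag <- if (conc < 0) "below_blank" else "ok"
  conc <- max(conc, 0)
  list(activity = conc / (timeMin * proteinMg), concentration_um = conc,
       replicates = signal, qc_flag = flag)
}

#' Relative contribution of each enzyme to total activity
#'
#' Per mouse, activities of the individual enzymes are summed and each
#' enzyme's share of the total is returned; shares sum to 1. A mouse whose
#' activities are all zero is undefined and reported as `NA`.
#'
#' @param activities data.frame with columns `mouse_id`, `enzyme`,
#'   `activity`.
#' @return the input with a `share` column added.
#' @export
normalizeActivities <- function(activities) {
  need <- c("mouse_id", "enzyme", "activity")
  stopIfNot(is.data.frame(activities) && all(need %in% names(activities)),
            "activities needs columns: ", paste(need, collapse = ", "))
  stopIfNot(all(activities$activity >= 0), "activities must be nonnegative")
  res <- lapply(split(activities, activities$mouse_id), function(m) {
    tot <- sum(m$activity)
    m$share <- if (tot > 0) m$activity / tot else NA_real_
    m
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out
}

#' qPCR transcript copies from Cq
#'
#' Inverts a standard curve fitted as Cq vs log10(copies):
#' `copies = 10^((cq - intercept) / slope)`, then rescales the per-reaction
#' copies to the reporting basis of copies per 10 ng RNA. A Cq outside the
#' range of the standards triggers an extrapolation warning.
#'
#' @param cq observed quantification cycle(s).
#' @param curve [StandardCurve-class] fitted with `x = log10(copies)`,
#'   `signal = Cq`.
#' @param rnaInputNg RNA(-equivalent) input per reaction in ng (default 10,
#'   i.e. no rescaling).
#' @return copies per 10 ng RNA, same length as `cq`.
#' @examples
#' sc <- fitStandardCurve(x = 1:5, signal = 40 - 3.3219 * (1:5))
#' qpcrCopies(40, sc)  # ~1 copy
#' @export
qpcrCopies <- function(cq, curve, rnaInputNg = 10) {
  stopIfNot(is(curve, "StandardCurve"), "curve must be a StandardCurve")
  stopIfNot(slope(curve) != 0, "degenerate standard curve (zero slope)")
  stopIfNot(rnaInputNg > 0, "rnaInputNg must be positive")
  rng <- range(curve@points$signal)
  if (any(cq < rng[1] - 1e-9 | cq > rng[2] + 1e-9)) {
    warning("Cq outside the standard range [", signif(rng[1], 4), ", ",
            signif(rng[2], 4), "]; extrapolating")
  }
  10^((cq - intercept(curve)) / slope(curve)) * (10 / rnaInputNg)
}

#' Colony-forming units per gram of sample
#'
#' `CFU/g = colonies * dilutionFactor / platedVolumeMl * suspensionVolumeMl /
#' sampleMassG`. Zero colonies are reported at the limit of detection (the
#' value corresponding to a single colony) and flagged censored.
#'
#' @param colonies nonnegative colony count.
#' @param dilutionFactor total dilution of the plated suspension (e.g. 1e4).
#' @param platedVolumeMl volume plated (ml).
#' @param sampleMassG sample wet mass (g).
#' @param suspensionVolumeMl volume the sample was suspended in (ml).
#' @return list: `cfu_per_g`, `censored` (TRUE when at the detection limit),
#'   `lod` (the limit of detection on the same scale).
#' @examples
#' cfuPerGram(30, 1e4, 0.1, 0.05, 1)$cfu_per_g  # 6e7
#' @export
cfuPerGram <- function(colonies, dilutionFactor, platedVolumeMl, sampleMassG,
                       suspensionVolumeMl) {
  stopIfNot(isCount(colonies), "colonies must be a nonnegative integer")
  stopIfNot(dilutionFactor > 0 && platedVolumeMl > 0 && sampleMassG > 0 &&
              suspensionVolumeMl > 0, "all volumes/factors must be positive")
  perColony <- dilutionFactor / platedVolumeMl * suspensionVolumeMl / sampleMassG
  if (colonies == 0) {
    list(cfu_per_g = perColony, censored = TRUE, lod = perColony)
  } else {
    list(cfu_per_g = colonies * perColony, censored = FALSE, lod = perColony)
  }
}

#' Metabolomics table preprocessing
#'
#' Standard targeted-metabolomics preprocessing: peak areas are divided by
#' sample weight, per-metabolite missing values are imputed at the limit of
#' detection (20% of that metabolite's minimum positive weight-normalized
#' value), and intensities are log10 transformed. Metabolites with no
#' positive value are dropped with a warning.
#'
#' @param table data.frame with columns `sample_id`, `metabolite`,
#'   `peak_area` (NA = missing), `sample_weight_mg` and optionally `group`.
#' @param lodFraction LOD as a fraction of the minimum positive value
#'   (default 0.2).
#' @return the table with added columns `normalized` (weight-normalized,
#'   imputed) `log_intensity` (log10 of it) and `imputed` (logical).
#' @export
metabolomicsPreprocess <- function(table, lodFraction = 0.2) {
  need <- c("sample_id", "metabolite", "peak_area", "sample_weight_mg")
  stopIfNot(is.data.frame(table) && all(need %in% names(table)),
            "table needs columns: ", paste(need, collapse = ", "))
  stopIfNot(all(table$sample_weight_mg > 0), "sample weights must be positive")
  stopIfNot(all(is.na(table$peak_area) | table$peak_area >= 0),
            "peak areas must be nonnegative or NA")
  table$normalized <- table$peak_area / table$sample_weight_mg
  res <- lapply(split(table, table$metabolite), function(m) {
    pos <- m$normalized[!is.na(m$normalized) & m$normalized > 0]
    if (length(pos) == 0) return(NULL)
    lod <- lodFraction * min(pos)
    m$imputed <- is.na(m$normalized)
    m$normalized[m$imputed] <- lod
    m
  })
  dropped <- names(res)[vapply(res, is.null, logical(1))]
  if (length(dropped) > 0) {
    warning("dropping metabolite(s) with no positive value: ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, c(res[!vapply(res, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  out$log_intensity <- log10(out$normalized)
  out
}

#' Differentially abundant metabolites
#'
#' A metabolite is significant iff its between-group fold change on the
#' weight-normalized (unlogged) group means is at least `fcThreshold` in
#' either direction AND the two-sided exact Mann-Whitney p-value is below
#' `pThreshold`.
#'
#' @param processed output of [metabolomicsPreprocess()] with a `group`
#'   column taking exactly two values.
#' @param fcThreshold fold-change threshold (default 1.5).
#' @param pThreshold p-value threshold (default 0.05).
#' @return data.frame per metabolite: `fold_change` (group2 / group1),
#'   `p_value`, `significant`.
#' @export
significantMetabolites <- function(processed, fcThreshold = 1.5,
                                   pThreshold = 0.05) {
  stopIfNot("group" %in% names(processed), "processed needs a 'group' column")
  grp <- sort(unique(as.character(processed$group)))
  stopIfNot(length(grp) == 2, "exactly two groups are required")
  res <- lapply(split(processed, processed$metabolite), function(m) {
    v1 <- m$normalized[m$group == grp[1]]
    v2 <- m$normalized[m$group == grp[2]]
    stopIfNot(length(v1) >= 2 && length(v2) >= 2,
              "each group needs >= 2 observations per metabolite")
    fc <- mean(v2) / mean(v1)
    p <- pValue(mannWhitneyExact(v1, v2))
    data.frame(metabolite = m$metabolite[1], fold_change = fc, p_value = p,
               significant = (fc >= fcThreshold | fc <= 1 / fcThreshold) &
                 p < pThreshold)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
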