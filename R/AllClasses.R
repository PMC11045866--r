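#' AbundanceTable: taxa-by-sample count container
#'
#' An `AbundanceTable` holds a nonnegative integer count matrix with taxa as
#' rows and samples as columns (the SummarizedExperiment convention; the
#' on-disk TSV exchange format is samples x taxa, see [readAbundanceTable()]).
#' Optional genus/phylum taxonomy lives in `rowData`, per-sample group labels
#' in `colData$group`.
#'
#' @param counts nonnegative integer matrix, taxa x samples, with dimnames.
#' @param taxonomy optional data.frame with one row per taxon (rownames =
#'   taxon ids) and columns such as `genus` and `phylum`; `NA` marks an
#'   unassigned rank.
#' @param groups optional named character vector mapping sample id to group
#'   label.
#' @param x an `AbundanceTable` (or `CompositionTable`).
#'
#' @return `AbundanceTable()` returns an AbundanceTable object. `taxonomy()`
#'   returns the taxonomy data.frame (or NULL), `sampleGroups()` the named
#'   group vector (or NULL).
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' at <- AbundanceTable(m)
#' counts(at)
#' @aliases taxonomy sampleGroups counts
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

#' CompositionTable: real-valued compositional transform of an AbundanceTable
#'
#' Same axes as [AbundanceTable] but real values: per-sample relative
#' abundances (columns sum to 1) or centered log-ratios (columns sum to 0).
#' The `transform` slot records which.
#'
#' @param values real matrix, taxa x samples.
#' @param transform `"relative"` or `"clr"`.
#' @inheritParams AbundanceTable
#' @export
setClass("CompositionTable",
  contains = "SummarizedExperiment",
  representation(transform = "character")
)

#' BeadCloud: 3D microsphere coordinates over an epithelial surface
#'
#' Post-segmentation bead coordinates from confocal z-stacks of the colonic
#' mucus layer, one or more images, plus the epithelial reference surface.
#' The z axis points from the epithelium toward the lumen. The epithelium is
#' either a constant plane height (single number, um) or a gridded height
#' field `list(x =, y =, h =)` with `h` an `length(x) x length(y)` matrix.
#'
#' @param beads data.frame with columns `image_id`, `mouse_id`, `x_um`,
#'   `y_um`, `z_um`.
#' @param epithelium single numeric plane height (um) or a
#'   `list(x, y, h)` gridded height field.
#' @param x a `BeadCloud`.
#' @return `BeadCloud()` returns a BeadCloud; `beads()` its coordinate
#'   data.frame; `epithelium()` the height-field description.
#' @aliases beads epithelium
#' @export
setClass("BeadCloud", representation(beads = "data.frame", epithelium = "ANY"))

setValidity("BeadCloud", function(object) {
  b <- object@beads
  need <- c("image_id", "mouse_id", "x_um", "y_um", "z_um")
  if (!all(need %in% names(b))) {
    return(paste("beads must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(b) > 0 && !all(is.finite(b$x_um) & is.finite(b$y_um) & is.finite(b$z_um))) {
    return("bead coordinates must be finite")
  }
  e <- object@epithelium
  ok <- (is.numeric(e) && length(e) == 1 && is.finite(e)) ||
    (is.list(e) && all(c("x", "y", "h") %in% names(e)))
  if (!ok) return("epithelium must be a plane height or a list(x, y, h) grid")
  TRUE
})

#' StandardCurve: least-squares calibration line
#'
#' Ordinary least-squares fit of signal against concentration (or log10
#' copies for qPCR), used to convert raw readings into quantities.
#'
#' @param x a `StandardCurve`.
#' @return `slope()`, `intercept()` and `rSquared()` return the fitted
#'   parameters; `rSquared()` is `NA` when the fit is degenerate (constant
#'   response).
#' @aliases slope intercept rSquared
#' @export
setClass("StandardCurve", representation(
  points = "data.frame", slope = "numeric", intercept = "numeric",
  r_squared = "numeric"
))

#' TestResult: outcome of a nonparametric hypothesis test
#'
#' Shared result container for the exact Mann-Whitney U and Wilcoxon
#' signed-rank tests: the statistic, the two-sided p-value, the method label,
#' whether the p-value came from exact enumeration, the sample sizes and
#' whether a tie correction was applied on the approximate path.
#'
#' @param x a `TestResult`.
#' @return `pValue()` returns the two-sided p-value in (0, 1]; `statistic()`
#'   the test statistic.
#' @aliases pValue statistic
#' @export
setClass("TestResult", representation(
  statistic = "numeric", p_value = "numeric", method = "character",
  exact = "logical", n1 = "integer", n2 = "integer", tie_corrected = "logical"
))

setValidity("TestResult", function(object) {
  p <- object@p_value
  if (length(p) != 1 || is.na(p) || p <= 0 || p > 1) return("p_value must be in (0, 1]")
  TRUE
})

#' CorrelationResult: Spearman correlation outcome
#'
#' @param x a `CorrelationResult`.
#' @return `pValue()` returns the p-value, `statistic()` the rank correlation
#'   rho in [-1, 1] (NA when an input is constant).
#' @export
setClass("CorrelationResult", representation(
  rho = "numeric", p_value = "numeric", p_adjusted = "numeric", n = "integer",
  exact = "logical"
))

## ---- constructors -----------------------------------------------------

#' @rdname AbundanceTable
#' @export
AbundanceTable <- function(counts, taxonomy = NULL, groups = NULL) {
  stopIfNot(is.matrix(counts), "counts must be a matrix")
  stopIfNot(!is.null(rownames(counts)) && !is.null(colnames(counts)),
            "counts must have taxon rownames and sample colnames")
  stopIfNot(!anyDuplicated(rownames(counts)), "duplicate taxon ids")
  stopIfNot(!anyDuplicated(colnames(counts)), "duplicate sample ids")
  stopIfNot(all(is.finite(counts)) && all(counts >= 0) &&
              all(counts == round(counts)), "counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  rd <- if (is.null(taxonomy)) {
    S4Vectors::DataFrame(row.names = rownames(counts))
  } else {
    stopIfNot(all(rownames(counts) %in% rownames(taxonomy)),
              "taxonomy must cover every taxon id")
    S4Vectors::DataFrame(taxonomy[rownames(counts), , drop = FALSE])
  }
  cd <- if (is.null(groups)) {
    S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    stopIfNot(all(colnames(counts) %in% names(groups)),
              "groups must cover every sample id")
    S4Vectors::DataFrame(group = unname(groups[colnames(counts)]),
                         row.names = colnames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd
  )
  new("AbundanceTable", se)
}

#' @rdname CompositionTable-class
#' @export
CompositionTable <- function(values, transform, taxonomy = NULL, groups = NULL) {
  transform <- match.arg(transform, c("relative", "clr"))
  stopIfNot(is.matrix(values) && all(is.finite(values)),
            "values must be a finite numeric matrix")
  rd <- if (is.null(taxonomy)) {
    S4Vectors::DataFrame(row.names = rownames(values))
  } else {
    S4Vectors::DataFrame(taxonomy[rownames(values), , drop = FALSE])
  }
  cd <- if (is.null(groups)) {
    S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    S4Vectors::DataFrame(group = unname(groups[colnames(values)]),
                         row.names = colnames(values))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values), rowData = rd, colData = cd
  )
  new("CompositionTable", se, transform = transform)
}

#' @rdname BeadCloud-class
#' @export
BeadCloud <- function(beads, epithelium = 0) {
  new("BeadCloud", beads = as.data.frame(beads), epithelium = epithelium)
}

## ---- accessors ---------------------------------------------------------

#' @rdname AbundanceTable
#' @export
setMethod("counts", "AbundanceTable", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' Values of a CompositionTable
#' @param x a `CompositionTable`.
#' @return the taxa-by-sample real matrix.
#' @export
compValues <- function(x) {
  stopIfNot(is(x, "CompositionTable"), "not a CompositionTable")
  SummarizedExperiment::assay(x, "values")
}

#' Which transform a CompositionTable carries ("relative" or "clr")
#' @param x a `CompositionTable`.
#' @export
compTransform <- function(x) x@transform

#' @rdname AbundanceTable
#' @export
setMethod("taxonomy", "SummarizedExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (ncol(rd) == 0) NULL else as.data.frame(rd)
})

#' @rdname AbundanceTable
#' @export
setMethod("sampleGroups", "SummarizedExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"group" %in% names(cd)) return(NULL)
  setNames(as.character(cd$group), rownames(cd))
})

#' @rdname BeadCloud-class
#' @export
setMethod("beads", "BeadCloud", function(x) x@beads)

#' @rdname BeadCloud-class
#' @export
setMethod("epithelium", "BeadCloud", function(x) x@epithelium)

#' @rdname StandardCurve-class
#' @export
setMethod("slope", "StandardCurve", function(x) x@slope)

#' @rdname StandardCurve-class
#' @export
setMethod("intercept", "StandardCurve", function(x) x@intercept)

#' @rdname StandardCurve-class
#' @export
setMethod("rSquared", "StandardCurve", function(x) x@r_squared)

#' @rdname TestResult-class
#' @export
setMethod("pValue", "TestResult", function(x) x@p_value)

#' @rdname TestResult-class
#' @export
setMethod("statistic", "TestResult", function(x) x@statistic)

#' @rdname CorrelationResult-class
#' @export
setMethod("pValue", "CorrelationResult", function(x) x@p_value)

#' @rdname CorrelationResult-class
#' @export
setMethod("statistic", "CorrelationResult", function(x) x@rho)

## ---- show --------------------------------------------------------------

setMethod("show", "BeadCloud", function(object) {
  b <- object@beads
  cat("BeadCloud:", nrow(b), "beads in", length(unique(b$image_id)),
      "image(s) from", length(unique(b$mouse_id)), "mouse/mice\n")
  e <- object@epithelium
  if (is.numeric(e) && length(e) == 1) {
    cat("  epithelium: plane at z =", e, "um\n")
  } else {
    cat("  epithelium: gridded height field,", length(e$x), "x", length(e$y), "\n")
  }
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf("StandardCurve: signal = %.6g * x + %.6g (r^2 = %s, %d points)\n",
              object@slope, object@intercept,
              ifelse(is.na(object@r_squared), "NA",
                     sprintf("%.4f", object@r_squared)),
              nrow(object@points)))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%s, n1 = %d, n2 = %d%s)\n",
              object@method, object@statistic, object@p_value,
              if (object@exact) "exact" else "approximate",
              object@n1, object@n2,
              if (object@tie_corrected) ", tie-corrected" else ""))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Spearman correlation: rho = %.4f, p = %.4g%s (n = %d, %s)\n",
              object@rho, object@p_value,
              if (length(object@p_adjusted) && !is.na(object@p_adjusted))
                sprintf(", p_adj = %.4g", object@p_adjusted) else "",
              object@n, if (object@exact) "exact" else "approximate"))
})
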