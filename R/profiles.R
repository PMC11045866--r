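## Post-ASV-table compositional processing: prevalence/abundance filtering,
## relative abundance, CLR, alpha diversity, rarefaction, core genera and
## group-maximum normalization.

#' Filter low-abundance taxa
#'
#' Keeps a taxon iff it is present (count > 0) in at least `minSamples`
#' samples AND its total count is at least `minTotal`. The sample axis is
#' unchanged. The removed taxa are attached as attribute `"removed"` (a
#' data.frame with per-taxon prevalence and total).
#'
#' @param table an [AbundanceTable].
#' @param minSamples minimum number of samples with a positive count
#'   (default 2).
#' @param minTotal minimum total count across samples (default 10).
#' @return a filtered [AbundanceTable]; idempotent.
#' @export
filterLowAbundance <- function(table, minSamples = 2L, minTotal = 10L) {
  stopIfNot(is(table, "AbundanceTable"), "table must be an AbundanceTable")
  stopIfNot(minSamples >= 0 && minTotal >= 0, "thresholds must be >= 0")
  cnt <- counts(table)
  stopIfNot(nrow(cnt) > 0 && ncol(cnt) > 0, "empty table")
  prevalence <- rowSums(cnt > 0)
  total <- rowSums(cnt)
  keep <- prevalence >= minSamples & total >= minTotal
  removed <- data.frame(taxon = rownames(cnt)[!keep],
                        prevalence = prevalence[!keep],
                        total = total[!keep], row.names = NULL)
  out <- table[keep, ]
  attr(out, "removed") <- removed
  out
}

#' Relative abundance
#'
#' Divides each sample's counts by the sample total, so every sample (column)
#' sums to 1.
#'
#' @param table an [AbundanceTable].
#' @return a [CompositionTable-class] with `transform = "relative"`.
#' @export
relativeAbundance <- function(table) {
  stopIfNot(is(table, "AbundanceTable"), "table must be an AbundanceTable")
  cnt <- counts(table)
  tot <- colSums(cnt)
  zero <- colnames(cnt)[tot == 0]
  if (length(zero) > 0) {
    stop("zero-total sample(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  vals <- sweep(cnt, 2, tot, "/")
  CompositionTable(vals, "relative", taxonomy = taxonomy(table),
                   groups = sampleGroups(table))
}

#' Centered log-ratio transform
#'
#' Per sample, `clr_i = log(x_i + pseudocount) - mean_j log(x_j +
#' pseudocount)`; every sample (column) sums to 0. The additive pseudocount
#' handles zero counts.
#'
#' @param table an [AbundanceTable].
#' @param pseudocount positive real added to every count (default 1).
#' @return a [CompositionTable-class] with `transform = "clr"`.
#' @export
clrTransform <- function(table, pseudocount = 1) {
  stopIfNot(is(table, "AbundanceTable"), "table must be an AbundanceTable")
  stopIfNot(length(pseudocount) == 1 && is.finite(pseudocount) &&
              pseudocount > 0, "pseudocount must be a positive real")
  lg <- log(counts(table) + pseudocount)
  vals <- sweep(lg, 2, colMeans(lg), "-")
  CompositionTable(vals, "clr", taxonomy = taxonomy(table),
                   groups = sampleGroups(table))
}

#' Alpha diversity per sample
#'
#' Observed taxa (count > 0) and the Shannon index `-sum p_i ln p_i` over the
#' nonzero proportions (natural log).
#'
#' @param table an [AbundanceTable]; all sample totals must be positive.
#' @return data.frame with columns `sample`, `observed`, `shannon`.
#' @export
alphaDiversity <- function(table) {
  stopIfNot(is(table, "AbundanceTable"), "table must be an AbundanceTable")
  cnt <- counts(table)
  tot <- colSums(cnt)
  zero <- colnames(cnt)[tot == 0]
  if (length(zero) > 0) {
    stop("zero-total sample(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  shannon <- vapply(seq_len(ncol(cnt)), function(j) {
    p <- cnt[, j] / tot[j]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  data.frame(sample = colnames(cnt), observed = colSums(cnt > 0),
             shannon = shannon, row.names = NULL)
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads; deterministic under `seed` and independent of the caller's RNG
#' state.
#'
#' @param table an [AbundanceTable].
#' @param depth target depth; must not exceed any sample total.
#' @param seed integer seed.
#' @return a rarefied [AbundanceTable] with every sample total equal to
#'   `depth`.
#' @export
rarefyTable <- function(table, depth, seed) {
  stopIfNot(is(table, "AbundanceTable"), "table must be an AbundanceTable")
  stopIfNot(isCount(depth) && depth > 0, "depth must be a positive integer")
  cnt <- counts(table)
  tot <- colSums(cnt)
  shallow <- colnames(cnt)[tot < depth]
  if (length(shallow) > 0) {
    stop("depth ", depth, " exceeds sample total(s): ",
         paste(shallow, collapse = ", "), call. = FALSE)
  }
  out <- withSeed(seed, {
    apply(cnt, 2, function(col) {
      drawn <- sample(rep.int(seq_along(col), col), depth, replace = FALSE)
      tabulate(drawn, nbins = length(col))
    })
  })
  dimnames(out) <- dimnames(cnt)
  AbundanceTable(out, taxonomy = taxonomy(table), groups = sampleGroups(table))
}

# Aggregate a composition table to genus level (sum of member taxa values;
# only meaningful for relative abundances). NA genus = unassigned, dropped.
genusAbundance <- function(comp) {
  tax <- taxonomy(comp)
  stopIfNot(!is.null(tax) && "genus" %in% names(tax),
            "genus-level taxonomy is required")
  vals <- compValues(comp)
  genus <- as.character(tax[rownames(vals), "genus"])
  keep <- !is.na(genus) & genus != ""
  rowsum(vals[keep, , drop = FALSE], genus[keep])
}

#' Core genera per group at a prevalence threshold
#'
#' A genus is core for a group if it is detected (relative abundance > 0) in
#' at least `prevalence` of the group's samples. Requires genus-level
#' taxonomy and per-sample group labels.
#'
#' @param comp a relative-abundance [CompositionTable-class].
#' @param prevalence fraction in (0, 1], e.g. 0.25 or 0.80.
#' @return named list of character vectors, one per group. Higher prevalence
#'   always yields a subset of lower prevalence.
#' @export
coreGenera <- function(comp, prevalence) {
  stopIfNot(is(comp, "CompositionTable"), "comp must be a CompositionTable")
  stopIfNot(length(prevalence) == 1 && prevalence > 0 && prevalence <= 1,
            "prevalence must lie in (0, 1]")
  groups <- sampleGroups(comp)
  stopIfNot(!is.null(groups), "per-sample group labels are required")
  gv <- genusAbundance(comp)
  lapply(split(names(groups), groups), function(samps) {
    det <- rowMeans(gv[, samps, drop = FALSE] > 0)
    sort(rownames(gv)[det >= prevalence])
  })
}

#' Group-maximum normalization of genus abundances
#'
#' Per genus, computes the group mean relative abundance, sets the group with
#' the highest mean to 100 and scales the others to `100 * mean / max`. A
#' genus with zero abundance in every group is reported as `NA` (undefined),
#' not 0/0.
#'
#' @param comp a relative-abundance [CompositionTable-class] with group
#'   labels.
#' @return matrix of percentages, genera x groups.
#' @export
groupMaxNormalize <- function(comp) {
  stopIfNot(is(comp, "CompositionTable"), "comp must be a CompositionTable")
  groups <- sampleGroups(comp)
  stopIfNot(!is.null(groups) && length(unique(groups)) >= 1,
            "at least one group is required")
  gv <- genusAbundance(comp)
  groupMeans <- vapply(split(names(groups), groups), function(samps) {
    rowMeans(gv[, samps, drop = FALSE])
  }, numeric(nrow(gv)))
  if (is.null(dim(groupMeans))) {
    groupMeans <- matrix(groupMeans, nrow = nrow(gv),
                         dimnames = list(rownames(gv),
                                         names(split(names(groups), groups))))
  }
  mx <- apply(groupMeans, 1, max)
  out <- 100 * groupMeans / mx
  out[mx == 0, ] <- NA_real_
  out
}

#' Percentage of taxa assigned at a taxonomic rank
#'
#' The share of taxa whose taxonomy carries a non-missing label at `rank`
#' (e.g. the fraction of ASVs assigned to the genus level), as a percentage.
#'
#' @param taxonomy data.frame of per-taxon lineage labels; `NA`/`""` =
#'   unassigned.
#' @param rank column name to assess (default `"genus"`).
#' @return percentage in `[0, 100]`.
#' @examples
#' tax <- data.frame(genus = c("Blautia", NA, "Bacteroides"))
#' assignmentRate(tax)  # 66.67
#' @export
assignmentRate <- function(taxonomy, rank = "genus") {
  stopIfNot(is.data.frame(taxonomy) && rank %in% names(taxonomy),
            "taxonomy must be a data.frame with a '", rank, "' column")
  lab <- as.character(taxonomy[[rank]])
  100 * sum(!is.na(lab) & lab != "") / length(lab)
}
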