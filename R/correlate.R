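## Genus-phenotype correlation screen: Spearman correlation of the most
## abundant genera against a per-sample phenotype, BH-adjusted.

#' Correlate genus abundances with a phenotype
#'
#' Selects the `topN` genera by mean relative abundance, computes the
#' Spearman correlation of each genus's abundance (CLR or relative, whichever
#' `comp` carries) with the per-sample phenotype, and adjusts the p-values by
#' Benjamini-Hochberg across the screened genera. When the table holds CLR
#' values, the ranking of genera uses a companion relative-abundance table if
#' supplied, otherwise the CLR means.
#'
#' @param comp a [CompositionTable-class] with genus-level taxonomy (the
#'   values correlated with the phenotype).
#' @param phenotype named numeric vector over exactly the table's samples
#'   (e.g. mucus growth rate per mouse).
#' @param topN number of most-abundant genera to screen (default 30); if
#'   fewer genera exist, all are used with a warning.
#' @param ranking optional relative-abundance [CompositionTable-class] used
#'   only to pick the top genera.
#' @return data.frame per screened genus: `genus`, `mean_abundance`, `rho`,
#'   `p_value`, `p_adjusted`, ordered by `p_value`.
#' @export
correlateTaxaPhenotype <- function(comp, phenotype, topN = 30L,
                                   ranking = NULL) {
  stopIfNot(is(comp, "CompositionTable"), "comp must be a CompositionTable")
  gv <- genusAbundance(comp)
  stopIfNot(!is.null(names(phenotype)), "phenotype must be named by sample")
  stopIfNot(setequal(names(phenotype), colnames(gv)),
            "phenotype must be defined for exactly the table's samples")
  stopIfNot(all(is.finite(phenotype)), "phenotype values must be finite")
  phenotype <- phenotype[colnames(gv)]
  rankBy <- if (is.null(ranking)) gv else {
    rv <- genusAbundance(ranking)
    stopIfNot(setequal(rownames(rv), rownames(gv)),
              "ranking table must hold the same genera")
    rv[rownames(gv), colnames(gv), drop = FALSE]
  }
  meanAb <- rowMeans(rankBy)
  if (nrow(gv) < topN) {
    warning("only ", nrow(gv), " genera available; screening all of them")
    topN <- nrow(gv)
  }
  top <- names(sort(meanAb, decreasing = TRUE))[seq_len(topN)]
  res <- lapply(top, function(g) {
    ct <- spearmanCorrelation(gv[g, ], phenotype)
    data.frame(genus = g, mean_abundance = meanAb[[g]],
               rho = ct@rho, p_value = ct@p_value)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  ok <- !is.na(out$p_value)
  out$p_adjusted <- NA_real_
  if (any(ok)) out$p_adjusted[ok] <- bhAdjust(out$p_value[ok])
  out[order(out$p_value), ]
}
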