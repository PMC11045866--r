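## Plain-text exchange formats: TSV feature tables (samples x taxa on disk),
## two-column taxonomy/group TSVs, CSV panels, Newick trees (via ape) and
## square TSV distance matrices.

#' Read / write an abundance table as TSV
#'
#' On disk the feature table is samples x taxa: first column `sample_id`,
#' header row of taxon ids, integer cells. In memory the [AbundanceTable] is
#' taxa x samples.
#'
#' @param path file path.
#' @param taxonomyPath optional two-column TSV (`taxon_id`,
#'   semicolon-delimited `lineage` as `phylum;genus`; empty rank = NA).
#' @param groupsPath optional two-column TSV (`sample_id`, `group`).
#' @return an [AbundanceTable].
#' @export
readAbundanceTable <- function(path, taxonomyPath = NULL, groupsPath = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(ncol(df) >= 2, "feature table needs a sample column plus taxa")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  taxonomy <- if (!is.null(taxonomyPath)) {
    tx <- utils::read.delim(taxonomyPath, stringsAsFactors = FALSE)
    parts <- strsplit(tx[[2]], ";", fixed = TRUE)
    tidy <- function(i) {
      v <- vapply(parts, function(p) if (length(p) >= i) trimws(p[i]) else "",
                  character(1))
      ifelse(v == "", NA_character_, v)
    }
    data.frame(phylum = tidy(1), genus = tidy(2), row.names = tx[[1]])
  } else NULL
  groups <- if (!is.null(groupsPath)) {
    gr <- utils::read.delim(groupsPath, stringsAsFactors = FALSE)
    setNames(gr[[2]], gr[[1]])
  } else NULL
  AbundanceTable(t(m), taxonomy = taxonomy, groups = groups)
}

#' @rdname readAbundanceTable
#' @param table an [AbundanceTable] to write.
#' @export
writeAbundanceTable <- function(table, path) {
  m <- t(counts(table))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square distance matrix as TSV (sample ids on both axes)
#'
#' @param d symmetric numeric matrix with dimnames.
#' @param path file path.
#' @export
writeDistanceMatrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort metabolic panel CSV
#'
#' One row per participant; `participant_id`, `sex` and `<param>_pre` /
#' `<param>_post` columns for the six metabolic parameters.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readCohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readCohort
#' @param cohort cohort data.frame to write.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
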