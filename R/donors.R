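## Composite FMT donor selection: six metabolic improvement rankings combined
## by mean rank (Borda), microbiota-shift rankings on the top metabolic
## responders, and the final combined selection.

metabolicParameters <- c("waist_to_hip_ratio", "body_mass_index",
                         "free_fat_mass", "cholesterol", "triglycerides",
                         "glucose")

#' Default improvement directions for the six metabolic parameters
#'
#' `"decrease"` means a drop from pre to post is an improvement. The default
#' treats free fat mass as fat-free mass, where an increase is the
#' improvement; this is configurable because the quantity name is ambiguous.
#'
#' @return named character vector over the six parameters.
#' @export
defaultDirections <- function() {
  c(waist_to_hip_ratio = "decrease", body_mass_index = "decrease",
    free_fat_mass = "increase", cholesterol = "decrease",
    triglycerides = "decrease", glucose = "decrease")
}

# Rank with 1 = best (largest improvement); ties share the mean rank.
rankDesc <- function(v) rank(-v, ties.method = "average")

#' Metabolic responder ranking
#'
#' Per parameter, improvement is `pre - post` when a decrease is good and
#' `post - pre` when an increase is good; participants are ranked by
#' descending improvement (1 = largest, ties share the mean rank). The
#' combined metabolic score is the mean of the six per-parameter ranks, and
#' the overall metabolic ranking orders participants by ascending score.
#' Participants with any missing value are excluded with a warning.
#'
#' @param cohort data.frame with `participant_id` and `<param>_pre` /
#'   `<param>_post` columns for the six metabolic parameters.
#' @param directions named character vector (`"decrease"`/`"increase"`) over
#'   the six parameters; see [defaultDirections()].
#' @param percent rank percent-of-baseline improvement instead of the raw
#'   delta (default FALSE).
#' @return data.frame with per-parameter ranks, `combined_score` and
#'   `metabolic_rank`, ordered by `metabolic_rank`.
#' @export
rankMetabolic <- function(cohort, directions = defaultDirections(),
                          percent = FALSE) {
  stopIfNot(is.data.frame(cohort) && "participant_id" %in% names(cohort),
            "cohort must be a data.frame with a participant_id column")
  stopIfNot(all(metabolicParameters %in% names(directions)),
            "directions must cover all six metabolic parameters")
  stopIfNot(all(directions[metabolicParameters] %in% c("decrease", "increase")),
            "directions must be 'decrease' or 'increase'")
  stopIfNot(nrow(cohort) >= 2, "need at least 2 participants")
  cols <- c(paste0(metabolicParameters, "_pre"),
            paste0(metabolicParameters, "_post"))
  stopIfNot(all(cols %in% names(cohort)),
            "cohort is missing pre/post columns")
  complete <- stats::complete.cases(cohort[, cols])
  if (any(!complete)) {
    warning("excluding participant(s) with missing values: ",
            paste(cohort$participant_id[!complete], collapse = ", "))
    cohort <- cohort[complete, , drop = FALSE]
  }
  improvements <- vapply(metabolicParameters, function(p) {
    pre <- cohort[[paste0(p, "_pre")]]
    post <- cohort[[paste0(p, "_post")]]
    imp <- if (directions[[p]] == "decrease") pre - post else post - pre
    if (percent) imp <- imp / abs(pre)
    imp
  }, numeric(nrow(cohort)))
  ranks <- apply(improvements, 2, rankDesc)
  combined <- rowMeans(ranks)
  out <- data.frame(participant_id = cohort$participant_id, ranks,
                    combined_score = combined,
                    metabolic_rank = rank(combined, ties.method = "average"),
                    row.names = NULL, check.names = FALSE)
  out[order(out$metabolic_rank, out$participant_id), ]
}

#' Microbiota-shift ranking
#'
#' Ranks participants by descending Bray-Curtis shift and descending weighted
#' UniFrac shift (1 = largest shift) and combines the two rankings by mean
#' rank into the overall gut bacterial ranking.
#'
#' @param shifts data.frame with columns `participant`, `bc_shift`,
#'   `wu_shift` (see [communityShifts()]).
#' @return data.frame with the two per-metric ranks, `combined_score` and
#'   `gut_rank`, ordered by `gut_rank`.
#' @export
rankMicrobiotaShift <- function(shifts) {
  stopIfNot(is.data.frame(shifts) &&
              all(c("participant", "bc_shift", "wu_shift") %in% names(shifts)),
            "shifts needs columns participant, bc_shift, wu_shift")
  stopIfNot(all(is.finite(shifts$bc_shift)) && all(is.finite(shifts$wu_shift)),
            "both shift metrics are required for every participant")
  bcRank <- rankDesc(shifts$bc_shift)
  wuRank <- rankDesc(shifts$wu_shift)
  combined <- (bcRank + wuRank) / 2
  out <- data.frame(participant_id = shifts$participant,
                    bc_rank = bcRank, wu_rank = wuRank,
                    combined_score = combined,
                    gut_rank = rank(combined, ties.method = "average"),
                    row.names = NULL)
  out[order(out$gut_rank, out$participant_id), ]
}

#' Composite donor selection
#'
#' The two-stage selection: take the `topMetabolic` best metabolic responders,
#' rank those by their microbiota shifts, then combine the metabolic rank
#' (recomputed within the eligible set) and the gut rank by mean and return
#' the `nDonors` best. Ties in the overall score are broken lexicographically
#' on (metabolic rank, participant id).
#'
#' @param metabolic result of [rankMetabolic()] over the whole cohort.
#' @param gut result of [rankMicrobiotaShift()] computed on the
#'   `topMetabolic` responders only (its participants must be exactly the
#'   metabolic top set).
#' @param topMetabolic size of the metabolic shortlist (default 10).
#' @param nDonors number of donors to return (default 5).
#' @return list with `donors` (character vector, best first) and `audit`
#'   (data.frame with all per-stage ranks and the overall score).
#' @export
selectDonors <- function(metabolic, gut, topMetabolic = 10L, nDonors = 5L) {
  stopIfNot(nDonors <= topMetabolic, "nDonors must not exceed topMetabolic")
  stopIfNot(nrow(metabolic) >= topMetabolic,
            "cohort smaller than the metabolic shortlist")
  topSet <- metabolic$participant_id[order(metabolic$metabolic_rank,
                                           metabolic$participant_id)][seq_len(topMetabolic)]
  stopIfNot(setequal(gut$participant_id, topSet),
            "gut ranking must cover exactly the top metabolic responders")
  stopIfNot(nDonors <= nrow(gut), "nDonors exceeds the eligible set")
  sub <- metabolic[match(topSet, metabolic$participant_id), ]
  metaRank <- rank(sub$combined_score, ties.method = "average")
  gutRank <- gut$gut_rank[match(topSet, gut$participant_id)]
  overall <- (metaRank + gutRank) / 2
  audit <- data.frame(participant_id = topSet,
                      metabolic_rank_cohort = sub$metabolic_rank,
                      metabolic_rank_eligible = metaRank,
                      gut_rank = gutRank,
                      overall_score = overall,
                      row.names = NULL)
  ord <- order(audit$overall_score, audit$metabolic_rank_eligible,
               audit$participant_id)
  audit <- audit[ord, ]
  audit$overall_rank <- seq_len(nrow(audit))
  list(donors = audit$participant_id[seq_len(nDonors)], audit = audit)
}
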