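#' @import methods
#' @importFrom stats rnorm rexp rpois rlnorm runif quantile sd lm coef
#'   pnorm pt setNames aggregate median
#' @importFrom utils head write.csv read.csv
#' @importFrom tools md5sum
#' @importFrom BiocGenerics counts
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom jsonlite write_json
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators never perturb each other or the session.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-generator seed stream derived from the global seed: adding a generator
# must not perturb the draws of the others. Kept below 2^31.
deriveSeed <- function(seed, stream) {
  offsets <- c(
    cohort = 101L, communities = 211L, beads = 307L, mucus = 401L,
    plate = 503L, metabolites = 601L, rarefy = 701L, pipeline = 809L
  )
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]]) %% 2147483629)
}

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)

isCount <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0
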