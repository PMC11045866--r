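## Between-sample dissimilarities: Bray-Curtis on abundance vectors and
## weighted UniFrac on a rooted phylogeny, computed by a single post-order
## branch traversal.

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, in `[0, 1]`. Each vector
#' is converted to proportions first by default, which makes the result
#' invariant to per-sample sequencing depth; `proportions = FALSE` applies
#' the formula to the raw counts (then only a common rescaling of both
#' vectors leaves it unchanged).
#'
#' @param x,y nonnegative numeric vectors of equal length, not both all zero.
#' @param proportions normalize each vector to sum 1 first (default TRUE).
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' brayCurtis(c(6, 2), c(2, 6))  # 0.5
#' @export
brayCurtis <- function(x, y, proportions = TRUE) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(all(is.finite(c(x, y))) && all(x >= 0) && all(y >= 0),
            "abundances must be finite and nonnegative")
  stopIfNot(sum(x) > 0 || sum(y) > 0, "both vectors are all zero")
  if (proportions) {
    stopIfNot(sum(x) > 0 && sum(y) > 0,
              "cannot take proportions of an all-zero sample")
    x <- x / sum(x)
    y <- y / sum(y)
  }
  sum(abs(x - y)) / sum(x + y)
}

# Validate a phylogeny against a taxon set: rooted, branch lengths present
# and nonnegative, unique tip labels, every abundance taxon on the tree.
checkTree <- function(tree, taxa) {
  stopIfNot(inherits(tree, "phylo"), "tree must be an ape 'phylo' object")
  stopIfNot(ape::is.rooted(tree),
            "tree must be rooted; midpoint-root it externally (e.g. phytools::midpoint.root)")
  stopIfNot(!is.null(tree$edge.length), "tree must have branch lengths")
  stopIfNot(all(is.finite(tree$edge.length)) && all(tree$edge.length >= 0),
            "branch lengths must be nonnegative")
  stopIfNot(!anyDuplicated(tree$tip.label), "duplicate tip labels")
  extra <- setdiff(taxa, tree$tip.label)
  if (length(extra) > 0) {
    stop("taxa absent from the tree: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Per-branch descendant proportions for one sample, by post-order traversal.
# Returns a vector over tree edges: the fraction of the sample's total
# abundance descending through each edge.
branchProportions <- function(p, tree) {
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  acc <- numeric(nTip + nNode)
  acc[seq_len(nTip)] <- p
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  # accumulate child masses into parents in post-order
  for (k in seq_len(nrow(edges))) {
    acc[edges[k, 1]] <- acc[edges[k, 1]] + acc[edges[k, 2]]
  }
  acc[tree$edge[, 2]]
}

#' Weighted UniFrac distance
#'
#' Branch-length-weighted difference of descendant abundance proportions on a
#' shared rooted phylogeny. With `p_i` the fraction of a sample's total
#' abundance descending through branch `i` (one post-order traversal) and
#' `b_i` its length, the normalized form is
#' `sum b_i |p_i^x - p_i^y| / sum b_i (p_i^x + p_i^y)`, which lies in
#' `[0, 1]` (the generalized-UniFrac alpha = 1 normalization). The raw
#' (unnormalized) numerator is returned with `normalized = FALSE`.
#'
#' @param x,y abundance vectors named by taxon; every taxon must be a tip of
#'   `tree` (tree tips missing from the vectors are treated as zero). Totals
#'   must be positive.
#' @param tree rooted `phylo` with branch lengths; multifurcations allowed.
#' @param normalized divide by `sum b_i (p_i^x + p_i^y)` (default TRUE).
#' @return the distance (in `[0, 1]` when normalized).
#' @export
weightedUnifrac <- function(x, y, tree, normalized = TRUE) {
  stopIfNot(!is.null(names(x)) && !is.null(names(y)),
            "abundance vectors must be named by taxon")
  stopIfNot(length(x) == length(y) && setequal(names(x), names(y)),
            "x and y must cover the same taxa")
  checkTree(tree, names(x))
  stopIfNot(all(is.finite(x)) && all(is.finite(y)) &&
              all(x >= 0) && all(y >= 0), "abundances must be nonnegative")
  stopIfNot(sum(x) > 0 && sum(y) > 0, "zero-total sample")
  tips <- tree$tip.label
  px <- setNames(numeric(length(tips)), tips)
  py <- px
  px[names(x)] <- x / sum(x)
  py[names(y)] <- y / sum(y)
  bx <- branchProportions(unname(px), tree)
  by <- branchProportions(unname(py), tree)
  b <- tree$edge.length
  num <- sum(b * abs(bx - by))
  if (!normalized) return(num)
  den <- sum(b * (bx + by))
  if (den == 0) return(0)
  num / den
}

#' Pre/post community shift of one participant
#'
#' The two beta-diversity dissimilarities between a participant's samples
#' before and after an intervention, used to rank microbiota responders.
#'
#' @param pre,post abundance vectors named by taxon.
#' @param tree rooted phylogeny covering the taxa.
#' @return named numeric: `bc_shift` (Bray-Curtis on proportions) and
#'   `wu_shift` (normalized weighted UniFrac).
#' @export
pairedShift <- function(pre, post, tree) {
  c(bc_shift = brayCurtis(pre, post, proportions = TRUE),
    wu_shift = weightedUnifrac(pre, post, tree))
}

#' Pre/post shifts for every participant in a paired abundance table
#'
#' Expects a table whose samples are named `<participant>_pre` /
#' `<participant>_post` (as emitted by [genPairedCommunities()]).
#'
#' @param table an [AbundanceTable].
#' @param tree rooted phylogeny covering the taxa.
#' @return data.frame with columns `participant`, `bc_shift`, `wu_shift`.
#' @export
communityShifts <- function(table, tree) {
  cnt <- counts(table)
  ids <- colnames(cnt)
  pre <- grep("_pre$", ids, value = TRUE)
  participants <- sub("_pre$", "", pre)
  missing <- participants[!paste0(participants, "_post") %in% ids]
  if (length(missing) > 0) {
    stop("missing post sample for participant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  res <- t(vapply(participants, function(pid) {
    pairedShift(setNames(cnt[, paste0(pid, "_pre")], rownames(cnt)),
                setNames(cnt[, paste0(pid, "_post")], rownames(cnt)),
                tree)
  }, numeric(2)))
  data.frame(participant = participants,
             bc_shift = res[, "bc_shift"], wu_shift = res[, "wu_shift"],
             row.names = NULL)
}

#' Pairwise distance matrix over the samples of an abundance table
#'
#' @param table an [AbundanceTable].
#' @param metric `"bray_curtis"` or `"weighted_unifrac"`.
#' @param tree required for weighted UniFrac.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(table, metric = c("bray_curtis", "weighted_unifrac"),
                           tree = NULL) {
  metric <- match.arg(metric)
  cnt <- counts(table)
  n <- ncol(cnt)
  d <- matrix(0, n, n, dimnames = list(colnames(cnt), colnames(cnt)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      xi <- setNames(cnt[, i], rownames(cnt))
      xj <- setNames(cnt[, j], rownames(cnt))
      d[i, j] <- d[j, i] <- if (metric == "bray_curtis") {
        brayCurtis(xi, xj, proportions = TRUE)
      } else {
        stopIfNot(!is.null(tree), "weighted UniFrac requires a tree")
        weightedUnifrac(xi, xj, tree)
      }
    }
  }
  d
}
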