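# Independent brute-force oracles used to validate the exact-test and
# UniFrac implementations on small instances.

# Full-enumeration Mann-Whitney: counts of U over all choose(n, n1)
# assignments of the ranks 1..n to the first group.
bruteMWCounts <- function(n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  u <- colSums(combos) - n1 * (n1 + 1) / 2
  tabulate(u + 1, nbins = n1 * n2 + 1)
}

bruteMWPvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cnt <- bruteMWCounts(n1, n2)
  total <- sum(cnt)
  lower <- sum(cnt[seq_len(u + 1)]) / total
  upper <- sum(cnt[seq(u + 1, length(cnt))]) / total
  min(1, 2 * min(lower, upper))
}

# Full 2^n sign enumeration for the Wilcoxon signed-rank statistic.
bruteSignedRankPvalue <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  lower <- mean(ws <= w)
  upper <- mean(ws >= w)
  min(1, 2 * min(lower, upper))
}

# Full n! permutation Spearman p-value via the rank-distance formula
# rho = 1 - 6 * sum d^2 / (n (n^2 - 1)) (valid for distinct ranks), an
# algebraic route independent of the package's Pearson-on-ranks path.
bruteSpearmanPvalue <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rhoOf <- function(p) 1 - 6 * sum((rx - ry[p])^2) / (n * (n^2 - 1))
  obs <- rhoOf(seq_len(n))
  perms <- allPerms(n)
  rhos <- apply(perms, 1, rhoOf)
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(rep.int(k, nrow(sub)), sub + (sub >= k))
  }))
}

# Per-branch descendant-tip-sum weighted UniFrac, enumerating the tip set of
# every edge directly instead of traversing.
bruteWeightedUnifrac <- function(x, y, tree, normalized = TRUE) {
  px <- x[tree$tip.label] / sum(x)
  py <- y[tree$tip.label] / sum(y)
  nTip <- length(tree$tip.label)
  descTips <- function(node) {
    if (node <= nTip) return(node)
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], descTips))
  }
  num <- 0; den <- 0
  for (k in seq_len(nrow(tree$edge))) {
    tips <- descTips(tree$edge[k, 2])
    pa <- sum(px[tips]); pb <- sum(py[tips])
    num <- num + tree$edge.length[k] * abs(pa - pb)
    den <- den + tree$edge.length[k] * (pa + pb)
  }
  if (!normalized) return(num)
  if (den == 0) 0 else num / den
}

# Small deterministic abundance fixture: 5 taxa x 4 samples with taxonomy
# and two groups.
toyTable <- function() {
  m <- matrix(c(
    10L, 0L, 3L, 7L,
    0L, 20L, 1L, 0L,
    5L, 5L, 5L, 5L,
    0L, 0L, 500L, 0L,
    2L, 3L, 4L, 1L), nrow = 5, byrow = TRUE,
    dimnames = list(paste0("t", 1:5), paste0("s", 1:4)))
  tax <- data.frame(phylum = paste0("P", c(1, 1, 2, 2, 1)),
                    genus = c("Ga", "Gb", "Ga", NA, "Gc"),
                    row.names = paste0("t", 1:5))
  AbundanceTable(m, taxonomy = tax,
                 groups = c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
}

randomAbundanceVector <- function(taxa) {
  setNames(stats::rpois(length(taxa), 20) + 1, taxa)
}
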