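## Exact small-sample nonparametric statistics, implemented from first
## principles: the exact Mann-Whitney U and Wilcoxon signed-rank null
## distributions are enumerated by dynamic programming, Spearman p-values by
## full permutation at small n, and Benjamini-Hochberg by the step-up rule.

# Number of ways to obtain each U value for group sizes n1, n2 (no ties).
# Classic DP over the generating function prod_{k=1..n1} (1-q^(n2+k))/(1-q^k):
# equivalently f(n1, n2, u) = f(n1-1, n2, u-n2) + f(n1, n2-1, u).
# Returns counts for U = 0 .. n1*n2; sums to choose(n1+n2, n1).
mwCountDistribution <- function(n1, n2) {
  maxU <- n1 * n2
  # counts[u + 1] = number of rank configurations with U = u
  counts <- numeric(maxU + 1)
  counts[1] <- 1
  # build up by adding the n1 observations of group x one at a time;
  # adding the i-th allows increments 0..n2, i.e. polynomial multiplication
  # by (1 + q + ... + q^n2) restricted to partitions with at most i parts.
  # Standard iterative form: for each i in 1..n1, counts <- counts *
  # (1 - q^(n2+i)) / (1 - q^i).
  for (i in seq_len(n1)) {
    # multiply by 1/(1 - q^i): cumulative sums with stride i
    if (i <= maxU) {
      for (u in seq(i, maxU)) counts[u + 1] <- counts[u + 1] + counts[u + 1 - i]
    }
    # multiply by (1 - q^(n2+i))
    k <- n2 + i
    if (k <= maxU) {
      for (u in seq(maxU, k)) counts[u + 1] <- counts[u + 1] - counts[u + 1 - k]
    }
  }
  counts
}

#' Exact Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U test with the small-sample null distribution
#' enumerated exactly. U is computed from rank sums with mid-ranks for ties.
#' When there are no ties and `n1 + n2 <= exactLimit`, the two-sided p-value
#' is exact: `p = min(1, 2 * min(P(U <= u), P(U >= u)))` with the U null
#' distribution counted by dynamic programming. With ties or larger samples a
#' normal approximation with tie correction (and optional continuity
#' correction) is used and flagged `exact = FALSE`.
#'
#' @param x,y numeric samples (unpaired).
#' @param exactLimit exact enumeration used when `n1 + n2` is at most this
#'   (default 30) and there are no ties.
#' @param continuity apply a 0.5 continuity correction on the approximate
#'   path (default TRUE).
#' @return a [TestResult-class] with `statistic` = U of the first sample.
#' @examples
#' mannWhitneyExact(c(1, 2, 3, 4), c(5, 6, 7, 8, 9, 10))  # p = 0.0095
#' @export
mannWhitneyExact <- function(x, y, exactLimit = 30L, continuity = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopIfNot(length(x) >= 1 && length(y) >= 1, "both samples must be non-empty")
  stopIfNot(all(is.finite(c(x, y))), "samples must be finite")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # mid-ranks for ties
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  hasTies <- anyDuplicated(c(x, y)) > 0
  if (!hasTies && n1 + n2 <= exactLimit) {
    cnt <- mwCountDistribution(n1, n2)
    total <- sum(cnt)
    u <- round(u1)
    lower <- sum(cnt[seq_len(u + 1)]) / total
    upper <- sum(cnt[seq(u + 1, length(cnt))]) / total
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE; tiecorr <- FALSE
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tab <- table(c(x, y))
    tieTerm <- sum(tab^3 - tab)
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - tieTerm / (nt * (nt - 1)))
    tiecorr <- tieTerm > 0
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- if (continuity) 0.5 else 0
      z <- (u1 - mu - sign(u1 - mu) * cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      p <- max(p, .Machine$double.xmin)
    }
    exact <- FALSE
  }
  new("TestResult", statistic = u1, p_value = p,
      method = "Mann-Whitney U", exact = exact,
      n1 = as.integer(n1), n2 = as.integer(n2), tie_corrected = tiecorr)
}

# Counts of signed-rank statistic W+ = w over the 2^n equiprobable sign
# assignments (no ties in |d|): DP over inclusion of each rank 1..n.
signedRankCountDistribution <- function(n) {
  maxW <- n * (n + 1) / 2
  counts <- numeric(maxW + 1)
  counts[1] <- 1
  for (k in seq_len(n)) {
    shifted <- c(numeric(k), counts[seq_len(maxW + 1 - k)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; `W+` is the sum of ranks of the positive
#' differences among ranks of `|d|`. With no ties among the nonzero `|d|` and
#' `n <= exactLimit`, the two-sided p-value is exact over the `2^n`
#' equiprobable sign assignments; otherwise a tie-corrected normal
#' approximation is used. If every difference is zero the test is degenerate
#' and `p = 1` is returned with `exact = FALSE`.
#'
#' @param pre,post paired numeric samples of equal length.
#' @param exactLimit exact path used for up to this many nonzero differences
#'   (default 25).
#' @param continuity continuity correction on the approximate path.
#' @return a [TestResult-class] with `statistic` = W+.
#' @examples
#' wilcoxonSignedRankExact(c(1, 2, 3, 4, 5), c(2, 4, 5, 7, 9))  # p = 0.0625
#' @export
wilcoxonSignedRankExact <- function(pre, post, exactLimit = 25L,
                                    continuity = TRUE) {
  stopIfNot(length(pre) == length(post) && length(pre) >= 1,
            "pre and post must be paired samples of equal length")
  d <- as.numeric(post) - as.numeric(pre)
  stopIfNot(all(is.finite(d)), "differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new("TestResult", statistic = 0, p_value = 1,
               method = "Wilcoxon signed-rank", exact = FALSE,
               n1 = 0L, n2 = 0L, tie_corrected = FALSE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  hasTies <- anyDuplicated(abs(d)) > 0
  if (!hasTies && n <= exactLimit) {
    cnt <- signedRankCountDistribution(n)
    total <- 2^n
    wInt <- round(w)
    lower <- sum(cnt[seq_len(wInt + 1)]) / total
    upper <- sum(cnt[seq(wInt + 1, length(cnt))]) / total
    p <- min(1, 2 * min(lower, upper))
    exact <- TRUE; tiecorr <- FALSE
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    tiecorr <- anyDuplicated(abs(d)) > 0
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- if (continuity) 0.5 else 0
      z <- (w - mu - sign(w - mu) * cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      p <- max(p, .Machine$double.xmin)
    }
    exact <- FALSE
  }
  new("TestResult", statistic = w, p_value = p,
      method = "Wilcoxon signed-rank", exact = exact,
      n1 = as.integer(n), n2 = as.integer(n), tie_corrected = tiecorr)
}

# All permutations of 1..n as an (n! x n) matrix; only used for small n.
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(rep.int(k, nrow(sub)), sub + (sub >= k))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Pearson correlation of two numeric vectors; NA if either is constant.
pearson <- function(a, b) {
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  sum((a - mean(a)) * (b - mean(b))) / ((length(a) - 1) * sa * sb)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' `rho` is the Pearson correlation of mid-ranks. For `n <= exactLimit` the
#' two-sided p-value is exact: the proportion of the `n!` permutations of one
#' rank vector with `|rho|` at least as large as observed. For larger `n` a
#' t approximation with `n - 2` degrees of freedom is used. A constant input
#' yields `rho = NA` with `p = NA`.
#'
#' @param x,y numeric samples of equal length, `n >= 3`.
#' @param exactLimit exact permutation p-value up to this n (default 8).
#' @return a [CorrelationResult-class].
#' @export
spearmanCorrelation <- function(x, y, exactLimit = 8L) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  stopIfNot(n >= 3, "need n >= 3")
  stopIfNot(all(is.finite(c(x, y))), "inputs must be finite")
  rx <- rank(x); ry <- rank(y)
  rho <- pearson(rx, ry)
  if (is.na(rho)) {
    return(new("CorrelationResult", rho = NA_real_, p_value = NA_real_,
               p_adjusted = NA_real_, n = as.integer(n), exact = FALSE))
  }
  if (n <= exactLimit) {
    perms <- allPermutations(n)
    rhoPerm <- apply(perms, 1, function(idx) pearson(rx, ry[idx]))
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    exact <- TRUE
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    p <- max(p, .Machine$double.xmin)
    exact <- FALSE
  }
  new("CorrelationResult", rho = rho, p_value = p, p_adjusted = NA_real_,
      n = as.integer(n), exact = exact)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: sort p ascending, `adj_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, returned in the input order.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
  stopIfNot(length(p) >= 1, "empty p-value vector")
  stopIfNot(all(is.finite(p)) && all(p > 0) && all(p <= 1),
            "p-values must lie in (0, 1]")
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  scaled <- sorted * m / seq_len(m)
  # running minimum from the largest p downwards (step-up)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
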