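#' Two-sided Mann-Whitney U test
#'
#' U is computed from midranks (ties share the average rank). The two-sided
#' p-value is exact (from the null distribution of U) when the combined
#' sample size is at most 12 and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' Degenerate inputs (all values identical) give p = 1.
#'
#' @param x,y nonempty numeric vectors.
#' @return list with `U` (statistic for `x`, i.e. the number of (x, y) pairs
#'   with x > y counting ties as 1/2), `p` (two-sided), and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    ph_argument_error("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) ph_argument_error("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (N <= 12L && !ties) {
    u_min <- min(U, n1 * n2 - U)
    p <- min(1, 2 * stats::pwilcox(u_min, n1, n2))
    return(list(U = U, p = p, method = "exact"))
  }
  tab <- table(c(x, y))
  tie_term <- sum(tab^3 - tab)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  d <- U - n1 * n2 / 2
  d <- sign(d) * max(0, abs(d) - 0.5)       # continuity correction
  z <- d / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the standard rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables whose probability is at most
#' the observed table's, with a relative slack of 1e-12 for floating-point
#' ties. The odds ratio is the sample odds ratio ad/bc (with `Inf`, 0, or
#' `NaN` when cells are zero), not a conditional MLE.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list with `odds_ratio` and `p` (two-sided).
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # p = 34/70
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) ph_argument_error("'tab' must be 2x2")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    ph_argument_error("'tab' must contain nonnegative integer counts")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  if (a + b + c_ + d == 0) ph_argument_error("'tab' must have a positive total")
  r1 <- a + b; c1 <- a + c_; c2 <- b + d
  kk <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(kk, c1, c2, r1)
  pobs <- stats::dhyper(a, c1, c2, r1)
  p <- min(1, sum(probs[probs <= pobs * (1 + 1e-12)]))
  num <- a * d; den <- b * c_
  odds_ratio <- if (den > 0) num / den else if (num > 0) Inf else NaN
  list(odds_ratio = odds_ratio, p = p)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of the midranks. The two-sided p-value is
#' exact (full permutation null, computed by a subset-sum dynamic program
#' that handles midrank ties) for n <= 10, and uses the t-distribution
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom otherwise.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return list with `rho`, `p` (two-sided), `n`, and `method`.
#' @export
spearman_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) ph_argument_error("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) ph_argument_error("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) ph_argument_error("pairs must not contain NA")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    ph_validation_error("degenerate input: one of the variables is constant")
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    p <- spearman_exact_p(rx, ry, rho)
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = min(1, 2 * stats::pt(-abs(tstat), df = n - 2)),
       n = n, method = "t-approximation")
}

# Exact two-sided permutation p-value for Spearman's rho.
# Midranks are multiples of 1/2, so 2*rank is integer and S = sum(X * Y[perm])
# with X = 2*rx, Y = 2*ry is integer. The distribution of S over all n!
# permutations is built by dynamic programming over subsets of positions:
# dist[mask] = counts over S of assigning X[1..popcount(mask)] to the
# positions in mask. rho is linear in S, so tail counts transfer directly.
spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  X <- as.integer(round(2 * rx)); Y <- as.integer(round(2 * ry))
  smax <- sum(sort(X) * sort(Y))
  dist <- vector("list", 2^n)
  dist[[1L]] <- c(1, numeric(smax))          # index i holds count for S = i - 1
  pos_bits <- 2^(seq_len(n) - 1L)
  for (mask in seq_len(2^n - 1L)) {
    k <- sum(bitwAnd(mask, pos_bits) > 0L)   # next X index to place
    acc <- numeric(smax + 1L)
    for (j in seq_len(n)) {
      if (bitwAnd(mask, pos_bits[j]) == 0L) next
      prev <- dist[[mask - pos_bits[j] + 1L]]
      sh <- X[k] * Y[j]
      acc[(sh + 1L):(smax + 1L)] <- acc[(sh + 1L):(smax + 1L)] + prev[seq_len(smax + 1L - sh)]
    }
    dist[[mask + 1L]] <- acc
  }
  counts <- dist[[2^n]]
  svals <- seq(0L, smax)
  mx <- mean(rx); my <- mean(ry)
  denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  rho_s <- (svals / 4 - n * mx * my) / denom
  sum(counts[abs(rho_s) >= abs(rho_obs) - 1e-12]) / factorial(n)
}
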