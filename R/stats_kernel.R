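# Self-contained statistical primitives used across the package.
#
# These are deliberately independent implementations; the corresponding base
# R routines serve as cross-checking oracles in the test suite only.

test_result <- function(statistic, p_value, n, method, direction = NA,
                        note = "") {
  list(statistic = statistic, p_value = min(max(p_value, 0), 1), n = n,
       method = method, direction = direction, note = note)
}

# Distribution of the Wilcoxon signed-rank statistic W+ for n untied ranks:
# counts[w + 1] = number of sign patterns with rank sum w, via the subset-sum
# polynomial product over ranks 1..n.
signed_rank_counts <- function(n) {
  counts <- 1
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts)
    counts <- c(counts, rep(0, r)) + shifted
  }
  counts
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests symmetry of `values` around `mu`. Zero differences are discarded
#' (classic Wilcoxon convention, not Pratt). The null distribution is exact
#' (full enumeration of sign patterns) for n <= 25 without ties in the
#' absolute differences; otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param values Numeric vector.
#' @param mu Hypothesized center.
#' @return A list: `statistic` (W+, sum of positive-difference ranks),
#'   `p_value` (two-sided), `n` (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(values, mu = 0) {
  if (length(values) < 1) stop("need at least one value")
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(test_result(0, 1, 0, "wilcoxon signed-rank (all zero differences)"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !ties) {
    counts <- signed_rank_counts(n)
    total <- 2^n
    lower <- sum(counts[seq_len(W + 1)]) / total        # P(W+ <= W)
    upper <- sum(counts[(W + 1):length(counts)]) / total # P(W+ >= W)
    p <- min(1, 2 * min(lower, upper))
    return(test_result(W, p, n, "wilcoxon signed-rank (exact)"))
  }
  mu_W <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu_W - 0.5 * sign(W - mu_W)) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  test_result(W, p, n, "wilcoxon signed-rank (normal approximation)")
}

# Null counts of the Mann-Whitney U statistic for group sizes m, n (no
# ties): counts[u + 1] = number of orderings with U = u. U is distributed as
# the number of partitions of u into at most m parts each <= n, with
# generating function prod_{k=1..m} (1 - q^{n+k}) / (1 - q^k); computed by
# truncated series arithmetic.
rank_sum_counts <- function(m, n) {
  maxdeg <- m * n
  poly <- c(1, rep(0, maxdeg))          # coefficients of q^0 .. q^maxdeg
  for (k in seq_len(m)) {
    # multiply by (1 - q^{n+k})
    s <- n + k
    if (s <= maxdeg)
      poly <- poly - c(rep(0, s), poly[seq_len(maxdeg + 1 - s)])
    # divide by (1 - q^k): y[i] = x[i] + y[i - k]
    for (i in (k + 1):(maxdeg + 1))
      poly[i] <- poly[i] + poly[i - k]
  }
  round(poly)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares the locations of two independent samples. Exact null
#' distribution when the smaller group has at most 8 observations and there
#' are no ties; otherwise normal approximation with mid-ranks, tie
#' correction and continuity correction. Two-sided.
#'
#' @param x,y Numeric vectors.
#' @return A list: `statistic` (U for group `x`), `p_value`, `n`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (min(m, n) <= 8 && !ties) {
    counts <- rank_sum_counts(m, n)
    total <- sum(counts)
    lower <- sum(counts[seq_len(U + 1)]) / total
    upper <- sum(counts[(U + 1):length(counts)]) / total
    p <- min(1, 2 * min(lower, upper))
    return(test_result(U, p, m + n, "wilcoxon rank-sum (exact)"))
  }
  N <- m + n
  mu_U <- m * n / 2
  tie_tab <- table(r)
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- (U - mu_U - 0.5 * sign(U - mu_U)) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  test_result(U, p, N, "wilcoxon rank-sum (normal approximation)")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; p-value from the t approximation with
#' n - 2 degrees of freedom, two-sided.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list: `statistic` (rho), `p_value`, `n`, `method`, `note`
#'   (flags degenerate input).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  sx <- sqrt(sum((rx - mean(rx))^2))
  sy <- sqrt(sum((ry - mean(ry))^2))
  if (sx == 0 || sy == 0)
    return(test_result(NA_real_, NA_real_, n, "spearman",
                       note = "zero rank variance; correlation undefined"))
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) / (sx * sy)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  test_result(rho, p, n, "spearman (t approximation)")
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Rows are \{focal category, other categories\}; columns are the two groups
#' compared (e.g. rearranged blocks vs whole genomes). No continuity
#' correction, df = 1.
#'
#' @param a,b,c,d Cell counts: `a`,`b` = focal/other in group 1; `c`,`d` =
#'   focal/other in group 2.
#' @return A list: `statistic` (X^2), `p_value`, `n`, `method`, `note`
#'   (flags zero margins and low expected counts).
#' @export
chi2_2x2 <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  if (any(o < 0)) stop("counts must be non-negative")
  N <- sum(o)
  row1 <- a + c; row2 <- b + d
  col1 <- a + b; col2 <- c + d
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0)
    return(test_result(0, 1, N, "chi-square 2x2",
                       note = "zero margin; test undefined, p set to 1"))
  e <- c(row1 * col1, row2 * col1, row1 * col2, row2 * col2) / N
  x2 <- sum((o - e)^2 / e)
  note <- if (any(e < 5)) "expected count < 5" else ""
  test_result(x2, stats::pchisq(x2, df = 1, lower.tail = FALSE), N,
              "chi-square 2x2 (df = 1, no continuity correction)",
              note = note)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted q-values in input order; monotone, capped at 1, never
#'   smaller than the raw p.
#' @export
bh_adjust <- function(pvalues) {
  n <- length(pvalues)
  if (n == 0) return(numeric(0))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
  pmax(q, pvalues)
}

#' Least-squares quadratic fit
#'
#' Fits y = a + b x + c x^2 by QR least squares.
#'
#' @param x,y Numeric vectors; `x` must have at least 3 distinct values.
#' @return A list: `a`, `b`, `c`, `rmse` (root-mean-square residual),
#'   `fitted`.
#' @export
fit_quadratic <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(unique(x)) < 3)
    stop("quadratic fit needs at least 3 distinct x values")
  X <- cbind(1, x, x^2)
  qrX <- qr(X)
  if (qrX$rank < 3) stop("degenerate (collinear) design")
  coefs <- qr.coef(qrX, y)
  fitted <- as.numeric(X %*% coefs)
  list(a = unname(coefs[1]), b = unname(coefs[2]), c = unname(coefs[3]),
       rmse = sqrt(mean((y - fitted)^2)), fitted = fitted)
}
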