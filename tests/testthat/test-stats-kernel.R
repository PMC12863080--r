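test_that("signed-rank exact branch matches enumeration and wilcox.test", {
  # n = 10, all values below mu, no ties: the most extreme pattern
  r <- wilcoxon_signed_rank(1:10, mu = 100)
  expect_equal(r$p_value, 2 / 2^10)
  expect_match(r$method, "exact")

  expect_equal(wilcoxon_signed_rank(rep(5, 4), mu = 5)$p_value, 1)

  set.seed(42)
  for (i in 1:20) {
    x <- sample(1000, sample(5:20, 1))
    mu <- 500.5
    mine <- wilcoxon_signed_rank(x, mu)
    base <- stats::wilcox.test(x, mu = mu, exact = TRUE)
    expect_equal(mine$p_value, base$p.value, tolerance = 1e-12,
                 info = paste("rep", i))
    expect_equal(mine$statistic, unname(base$statistic))
  }
})

test_that("signed-rank approximation agrees with wilcox.test and the exact tail", {
  set.seed(43)
  for (i in 1:10) {
    x <- rnorm(40) + 0.2
    mine <- wilcoxon_signed_rank(x)
    base <- stats::wilcox.test(x, exact = FALSE, correct = TRUE)
    expect_equal(mine$p_value, base$p.value, tolerance = 1e-10)
  }
  # exact and approximate branches agree at the boundary n = 25
  set.seed(44)
  x <- sample(10000, 25)
  mu <- 5000.5
  exact_p <- wilcoxon_signed_rank(x, mu)$p_value
  approx_p <- stats::wilcox.test(x, mu = mu, exact = FALSE,
                                 correct = TRUE)$p.value
  expect_lt(abs(exact_p - approx_p) / exact_p, 0.10)
})

test_that("rank-sum test matches enumeration and wilcox.test", {
  # fully separated groups of 5: exact two-sided 2 / C(10,5)
  r <- wilcoxon_rank_sum(1:5, 11:15)
  expect_equal(r$p_value, 2 / choose(10, 5))

  set.seed(45)
  for (i in 1:20) {
    x <- sample(10000, sample(3:8, 1))
    y <- sample(20000, sample(5:30, 1))
    mine <- wilcoxon_rank_sum(x, y)
    base <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(mine$p_value, base$p.value, tolerance = 1e-12,
                 info = paste("rep", i))
  }
  # ties force the mid-rank normal approximation
  x <- c(1, 2, 2, 3, 5, 6, 6, 8, 9, 10, 11, 3)
  y <- c(2, 3, 3, 4, 6, 7, 9, 9, 12, 14, 1, 5)
  mine <- wilcoxon_rank_sum(x, y)
  base <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, base$p.value, tolerance = 1e-10)
  expect_match(mine$method, "approximation")
})

test_that("spearman correlation matches cor.test's t approximation", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$statistic, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$statistic, -1)
  set.seed(46)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- 0.4 * x + rnorm(30)
    mine <- spearman_cor(x, y)
    base <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(mine$statistic, unname(base$estimate), tolerance = 1e-12)
  }
  # tie handling: mid-ranks, same rho as cor on ranks
  x <- c(1, 2, 2, 3, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6)
  expect_equal(spearman_cor(x, y)$statistic,
               stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_true(grepl("zero rank variance",
                    spearman_cor(rep(1, 5), 1:5)$note))
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("chi-square 2x2 matches the textbook formula and chisq.test", {
  expect_equal(chi2_2x2(10, 90, 100, 900)$statistic, 0)
  expect_equal(chi2_2x2(10, 90, 100, 900)$p_value, 1)
  expect_equal(chi2_2x2(20, 80, 100, 900)$statistic, 9.3537415,
               tolerance = 1e-6)
  z <- chi2_2x2(0, 10, 0, 90)
  expect_equal(z$p_value, 1)
  expect_match(z$note, "zero margin")

  set.seed(47)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    mine <- chi2_2x2(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
    base <- stats::chisq.test(tab, correct = FALSE)
    expect_equal(mine$statistic, unname(base$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, unname(base$p.value), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches p.adjust and its defining properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(48)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
  }
})

test_that("quadratic fit recovers exact data and rejects degenerate designs", {
  x <- c(-2, 0, 1, 3, 7)
  y <- 2.5 - 1.25 * x + 0.75 * x^2
  fit <- fit_quadratic(x, y)
  expect_equal(c(fit$a, fit$b, fit$c), c(2.5, -1.25, 0.75),
               tolerance = 1e-9)
  expect_equal(fit$rmse, 0, tolerance = 1e-9)
  expect_error(fit_quadratic(c(1, 1, 2, 2), 1:4), "distinct")

  # noisy recovery close to lm's answer
  set.seed(49)
  xn <- seq(0, 10, length.out = 40)
  yn <- 1 + 2 * xn + 0.3 * xn^2 + rnorm(40, sd = 0.5)
  fit2 <- fit_quadratic(xn, yn)
  co <- unname(coef(stats::lm(yn ~ xn + I(xn^2))))
  expect_equal(c(fit2$a, fit2$b, fit2$c), co, tolerance = 1e-9)
})
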