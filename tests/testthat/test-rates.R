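test_that("planted events reproduce the canonical block counts", {
  idp <- core_order(1:100)
  expect_equal(plant_rearrangements(idp, list())$order$families,
               idp$families)

  inv <- plant_rearrangements(idp, list(
    list(type = "inversion", start = 10, len = 5)))$order
  expect_equal(find_blocks(idp, inv)$n_blocks, 2)

  tr <- plant_rearrangements(idp, list(
    list(type = "translocation", start = 10, len = 5, dest = 30)))$order
  expect_equal(find_blocks(idp, tr)$n_blocks, 3)

  # an arc wrapping the origin inverts correctly
  wrap <- plant_rearrangements(idp, list(
    list(type = "inversion", start = 98, len = 6)))$order
  expect_equal(find_blocks(idp, wrap)$n_blocks, 2)
})

test_that("random simulation respects k and the segment-length law", {
  set.seed(4)
  idp <- core_order(1:50)
  pars <- sim_params(50, seg_len_dist = list(kind = "uniform", min = 2,
                                             max = 5))
  sim <- simulate_rearrangements(idp, 7, pars)
  expect_length(sim$truth, 7)
  lens <- vapply(sim$truth, function(e) e$len, numeric(1))
  expect_true(all(lens >= 2 & lens <= 5))
  expect_setequal(sim$order$families, idp$families)
  expect_equal(simulate_rearrangements(idp, 0, pars)$order$families,
               idp$families)
})

test_that("calibration recovers exact quadratics and sane simulations", {
  # noiseless mapping blocks = 1 + 2k is recovered to machine precision
  k <- 0:10
  fit <- fit_quadratic(k, 1 + 2 * k)
  expect_equal(fit$a, 1, tolerance = 1e-9)
  expect_equal(fit$b, 2, tolerance = 1e-9)
  expect_equal(fit$c, 0, tolerance = 1e-9)

  m <- calibrate_blocks_to_events(
    sim_params(300, k_grid = 0:12, replicates = 40, seed = 12))
  expect_equal(m$mean_blocks[1], 1)            # k = 0 -> identity genome
  expect_gt(m$b, 0)
  expect_true(all(diff(m$mean_blocks) >= 0))   # monotone calibration curve
  # the identity genome contributes a floor of one block while each event
  # adds ~2.5, so the LS intercept sits somewhat below 1
  expect_gt(m$value_at_zero, 0.2)
  expect_lt(m$value_at_zero, 1.2)

  expect_error(calibrate_blocks_to_events(
    sim_params(50, k_grid = c(0, 1), replicates = 2)), "k_grid")
})

test_that("event prediction inverts the model parsimoniously", {
  lin <- structure(list(a = 1, b = 2, c = 0), class = "quadratic_model")
  expect_equal(predict_events(5, lin), 2)
  expect_equal(predict_events(1, lin), 0)

  quad <- structure(list(a = 1, b = 2, c = -0.05),
                    class = "quadratic_model")
  # round trip: predict(model(k)) == k on the fitted range
  for (k in c(1, 3, 7)) {
    B <- quad$a + quad$b * k + quad$c * k^2
    expect_equal(predict_events(B, quad), k, tolerance = 1e-8)
  }
  expect_error(predict_events(0.5, lin), "impossible")
  # beyond the quadratic's maximum: linear extrapolation with a warning
  expect_warning(n <- predict_events(50, quad), "extrapolation")
  expect_gt(n, 0)
})

test_that("median predicted events track the planted count", {
  set.seed(31)
  C <- 200
  model <- calibrate_blocks_to_events(
    sim_params(C, k_grid = 0:12, replicates = 50, seed = 31))
  idp <- core_order(seq_len(C))
  pars <- sim_params(C)
  for (k in c(2, 5)) {
    est <- replicate(60, {
      sim <- simulate_rearrangements(idp, k, pars)
      B <- suppressWarnings(find_blocks(idp, sim$order)$n_blocks)
      predict_events(B, model)
    })
    expect_lte(abs(stats::median(est) - k), 1)
  }
})

test_that("substitution counting skips gapped and ambiguous columns", {
  aln <- as_alignment(c(a = "ACGT", b = "ACGT"))
  expect_equal(pairwise_substitutions(aln, "a", "b"),
               list(S = 0, L_eff = 4, L = 4))
  aln2 <- as_alignment(c(a = "ACGT", b = "ACGA"))
  expect_equal(pairwise_substitutions(aln2, "a", "b")$S, 1)
  aln3 <- as_alignment(c(a = "AC-T", b = "ACGT"))
  r <- pairwise_substitutions(aln3, "a", "b")
  expect_equal(r$L_eff, 3)
  expect_equal(r$S, 0)
  aln4 <- as_alignment(c(a = "ACNT", b = "AGGT"))
  r4 <- pairwise_substitutions(aln4, "a", "b")
  expect_equal(r4$L_eff, 3)
  expect_equal(r4$S, 1)
  expect_error(pairwise_substitutions(aln, "a", "zz"), "absent")
})

test_that("B_cs follows its definition and scaling laws", {
  expect_equal(rearrangement_rate(0, 1000, 100, 1e6), 0)
  expect_equal(rearrangement_rate(2, 1000, 100, 1e6), 2e-11)
  expect_error(rearrangement_rate(2, 1000, 0, 1e6), "S = 0")
  b1 <- rearrangement_rate(3, 500, 50, 2e5)
  expect_equal(rearrangement_rate(3, 500, 100, 2e5), b1 / 2)
  expect_equal(rearrangement_rate(3, 1000, 50, 2e5), b1 / 2)
  expect_equal(rearrangement_rate(3, 500, 50, 4e5), b1 / 2)
})
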