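test_that("likelihood_ratio reproduces the pinned pattern evaluations", {
  m <- multinomial_model()
  expect_equal(likelihood_ratio(pattern_counts(1, 0, 0, 0), m), 0.58 / 0.0023)
  expect_equal(likelihood_ratio(pattern_counts(0, 0, 0, 0), m), 1)
  expect_equal(likelihood_ratio(pattern_counts(1, 0, 0, 3), m),
               (0.58 / 0.0023) * (0.313 / 0.9943)^3)
  expect_equal(likelihood_ratio(pattern_counts(0, 3, 0, 36), m),
               (0.10 / 0.0020)^3 * (0.313 / 0.9943)^36)
  # a single non-recurrent or multiple hit alone is only mild evidence
  expect_lt(likelihood_ratio(pattern_counts(0, 1, 0, 4), m), 2.08)
})

test_that("likelihood_ratio equals the multinomial PMF ratio and its MC estimate", {
  m <- multinomial_model()
  set.seed(11)
  for (i in 1:25) {
    n <- sample(0:6, 4, replace = TRUE)
    lr <- likelihood_ratio(pattern_counts(n[1], n[2], n[3], n[4]), m, cap = Inf)
    pmf_ratio <- dmultinom(n, prob = m$p_path) / dmultinom(n, prob = m$p_null)
    expect_equal(lr, pmf_ratio)
  }
  # a sampling estimator of the pattern probability converges to the PMF
  n_obs <- c(2, 1, 0, 2)
  draws <- rmultinom(40000, size = sum(n_obs), prob = m$p_path)
  emp <- mean(colSums(draws == n_obs) == 4)
  pmf <- dmultinom(n_obs, prob = m$p_path)
  expect_lt(abs(emp - pmf), 3 * sqrt(pmf * (1 - pmf) / 40000))
})

test_that("likelihood_ratio factorizes over count addition and is monotone", {
  m <- multinomial_model()
  set.seed(7)
  for (i in 1:20) {
    a <- sample(0:5, 4, replace = TRUE)
    b <- sample(0:5, 4, replace = TRUE)
    expect_equal(
      likelihood_ratio(pattern_counts(a[1] + b[1], a[2] + b[2],
                                      a[3] + b[3], a[4] + b[4]), m, cap = Inf),
      likelihood_ratio(a, m, cap = Inf) * likelihood_ratio(b, m, cap = Inf),
      tolerance = 1e-10)
  }
  base <- likelihood_ratio(c(1, 1, 0, 2), m, cap = Inf)
  expect_gt(likelihood_ratio(c(2, 1, 0, 2), m, cap = Inf), base)
  expect_gt(likelihood_ratio(c(1, 2, 0, 2), m, cap = Inf), base)
  expect_lt(likelihood_ratio(c(1, 1, 0, 3), m, cap = Inf), base)
})

test_that("guards: OddsPath cap and zero null probability", {
  m <- multinomial_model()
  expect_warning(op <- likelihood_ratio(pattern_counts(3, 0, 0, 0), m),
                 "capped")
  expect_equal(op, 1e6)
  m0 <- multinomial_model(p_null = c(0, 0.0043, 0.0014, 0.9943))
  expect_error(likelihood_ratio(pattern_counts(1, 0, 0, 0), m0), "infinite")
  expect_equal(likelihood_ratio(pattern_counts(0, 1, 0, 0), m0), 0.10 / 0.0043)
})

test_that("posterior conversion matches Tavtigian's formula and inverts", {
  expect_equal(posterior_from_oddspath(252, 0.10), 25.2 / 26.1)
  expect_equal(posterior_from_oddspath(1, 0.37), 0.37)
  post <- posterior_from_oddspath(c(1, 10, 1e3, 1e6, 1e9), 0.1)
  expect_true(all(diff(post) > 0))
  expect_gt(posterior_from_oddspath(1e9, 0.1), 1 - 1e-8)
  set.seed(3)
  op <- 10^runif(50, -6, 6)
  expect_equal(oddspath_from_posterior(posterior_from_oddspath(op, 0.1), 0.1),
               op, tolerance = 1e-12)
})

test_that("evidence bands are half-open at the Tavtigian cut points", {
  expect_equal(band_from_oddspath(350), "very_strong")
  expect_equal(band_from_oddspath(252), "strong")
  expect_equal(band_from_oddspath(18.7), "strong")
  expect_equal(band_from_oddspath(4.33), "moderate")
  expect_equal(band_from_oddspath(2.08), "supporting")
  expect_equal(band_from_oddspath(2.0799), "not_met")
  expect_equal(band_from_oddspath(1), "not_met")
})

test_that("oddspath_grid enumerates all compositions with consistent values", {
  m <- multinomial_model()
  g1 <- oddspath_grid(1, m)
  expect_equal(nrow(g1), choose(5, 4))
  expect_true(all(g1$n0 == g1$N - g1$n1 - g1$n2 - g1$n3))

  for (mx in c(3, 10, 25)) {
    expect_equal(nrow(oddspath_grid(mx, m)), choose(mx + 4, 4))
  }

  g <- oddspath_grid(6, m)
  row <- g[g$N == 1 & g$n1 == 1, ]
  expect_equal(row$oddspath, likelihood_ratio(pattern_counts(1, 0, 0, 0), m))
  expect_equal(row$band, "strong")

  # holding the hit counts fixed, more hit-free carriers never raises OddsPath
  key <- paste(g$n1, g$n2, g$n3)
  for (k in unique(key)) {
    sub <- g[key == k, ]
    sub <- sub[order(sub$n0), ]
    expect_true(all(diff(sub$oddspath) <= 1e-12))
  }
})

test_that("presence-based comparator rule disagrees with OddsPath where expected", {
  expect_equal(original_pp4(pattern_counts(1, 0, 0, 3)), "strong")
  expect_equal(band_from_oddspath(likelihood_ratio(pattern_counts(1, 0, 0, 3))),
               "moderate")
  expect_equal(original_pp4(pattern_counts(0, 1, 0, 0)), "moderate")
  expect_equal(original_pp4(pattern_counts(0, 0, 2, 1)), "moderate")
  expect_equal(original_pp4(pattern_counts(0, 0, 0, 5)), "not_met")
})

test_that("estimate_model_from_cohort recovers generating vectors and edge cases", {
  m <- multinomial_model()
  set.seed(19)
  n_car <- 10000
  counts <- as.vector(rmultinom(1, n_car, m$p_path))
  carriers <- pattern_cohort("ANCHOR", counts[1], counts[2], counts[3], counts[4])
  nulls <- noncarrier_cohort(2, 3, 1, 494)
  co <- rbind(carriers, nulls)
  est <- estimate_model_from_cohort(co, "ANCHOR")
  se <- sqrt(m$p_path * (1 - m$p_path) / n_car)
  expect_true(all(abs(est$p_path - m$p_path) <= 3 * se))
  expect_equal(attr(est, "n_path"), n_car)

  # all anchor carriers with one hotspot hit, no smoothing
  co2 <- rbind(pattern_cohort("A", 4, 0, 0, 0), noncarrier_cohort(0, 0, 0, 10))
  est2 <- estimate_model_from_cohort(co2, "A")
  expect_equal(unname(est2$p_path), c(1, 0, 0, 0))

  expect_error(estimate_model_from_cohort(nulls, "ANCHOR"), "no evaluable carriers")
  expect_error(estimate_model_from_cohort(carriers, "ANCHOR"), "non-carrier")
})

test_that("null-pattern frequencies from the aggregated-series marginals", {
  # 32685 evaluable non-carrier cases: 139 with a single somatic variant
  # (74 of them hotspots), 47 with multiple, 32499 with none
  co <- rbind(pattern_cohort("ANCHOR", 3, 1, 0, 1),
              noncarrier_cohort(74, 65, 47, 32499))
  est <- estimate_model_from_cohort(co, "ANCHOR")
  expect_equal(attr(est, "n_null"), 32685)
  single_frac <- est$p_null[["single_recurrent"]] + est$p_null[["single_nonrecurrent"]]
  expect_equal(round(100 * single_frac, 2), 0.43)
  expect_equal(round(100 * est$p_null[["multiple"]], 2), 0.14)
  expect_equal(round(unname(est$p_null), 4), c(0.0023, 0.0020, 0.0014, 0.9943))
})

test_that("multinomial_model rejects malformed parameters", {
  expect_error(multinomial_model(p_path = c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  expect_error(multinomial_model(prior = 0), "prior")
  expect_error(multinomial_model(prior = 1), "prior")
  expect_error(multinomial_model(p_path = c(0.58, 0.10, 0.007)), "four values")
})
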