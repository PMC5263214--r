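# Exact closed-form layer for ordered marker triplets.

test_that("Haldane map function round-trips and guards its domain", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(0.25), -0.5 * log(0.5))
  rho <- seq(0.01, 0.49, by = 0.01)
  expect_equal(haldane_inverse(haldane(rho)), rho, tolerance = 1e-12)
  expect_true(all(diff(haldane(rho)) > 0))
  expect_error(haldane(0.5), "0.5")
  expect_error(haldane(-0.01), "0.5")
  expect_error(haldane_inverse(-1), "non-negative")
})

test_that("triplet distribution reproduces the middle-error closed forms", {
  # printed genotypic frequency for (-1,-1,-1):
  # 0.5 * [(1 - e)(1 - t12)(1 - t23) + e * t12 * t23], middle marker error e
  grid <- expand.grid(t12 = c(0.05, 0.1, 0.3), t23 = c(0.1, 0.2, 0.45),
                      e = c(0, 0.01, 0.2))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    d <- triplet_distribution(triplet_model(g$t12, g$t23, eps2 = g$e))
    expect_equal(d[["-1,-1,-1"]],
                 0.5 * ((1 - g$e) * (1 - g$t12) * (1 - g$t23) +
                          g$e * g$t12 * g$t23),
                 tolerance = 1e-12)
    expect_equal(d[["-1,-1,+1"]],
                 0.5 * ((1 - g$e) * (1 - g$t12) * g$t23 +
                          g$e * g$t12 * (1 - g$t23)),
                 tolerance = 1e-12)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    # symmetry under global sign flip
    expect_equal(d[["-1,+1,-1"]], d[["+1,-1,+1"]], tolerance = 1e-15)
    expect_equal(d[["-1,-1,-1"]], d[["+1,+1,+1"]], tolerance = 1e-15)
  }
  expect_equal(triplet_distribution(triplet_model(0.1, 0.2))[["-1,-1,-1"]],
               0.36, tolerance = 1e-12)
  d0 <- triplet_distribution(triplet_model(1e-12, 1e-12))
  expect_equal(d0[["-1,-1,-1"]], 0.5, tolerance = 1e-9)
})

test_that("distribution-derived moments match the correlation and RF closed forms", {
  # oracle: E[Mi Mj] and P(Mi != Mj) summed over the 8 cells
  grid <- expand.grid(t12 = c(0.05, 0.15), t23 = c(0.1, 0.3),
                      e1 = c(0, 0.1), e2 = c(0, 0.05), e3 = c(0, 0.2))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    m <- triplet_model(g$t12, g$t23, g$e1, g$e2, g$e3)
    d <- triplet_distribution(m)
    st <- attr(d, "states")
    for (pair in list(c(1, 2, m$theta12), c(2, 3, m$theta23),
                      c(1, 3, m$theta13))) {
      i <- pair[1]; j <- pair[2]; th <- pair[3]
      r_oracle <- sum(d * st[, i] * st[, j])
      rf_oracle <- sum(d[st[, i] != st[, j]])
      expect_equal(r_oracle, expected_correlation(th, m$eps[i], m$eps[j]),
                   tolerance = 1e-12)
      expect_equal(rf_oracle, expected_observed_rf(th, m$eps[i], m$eps[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("printed correlation and observed-RF values are reproduced", {
  expect_equal(expected_correlation(0.1), 0.8)
  expect_equal(expected_correlation(0.1, 0.1, 0), 0.64)
  expect_equal(expected_correlation(0.1) * expected_correlation(0.2), 0.48)
  m <- triplet_model(0.1, 0.2)
  expect_equal(expected_correlation(m$theta13), 0.48, tolerance = 1e-12)
  expect_equal(expected_observed_rf(0.1), 0.1)
  expect_equal(expected_observed_rf(0.1, 0.05, 0), 0.14)
  expect_equal(expected_observed_rf(0.1, 0.05, 0.05), 0.176)
  expect_error(expected_correlation(0.6), "0, 0.5")
  expect_error(expected_observed_rf(0.1, 0.5), "0, 0.5")
})

test_that("partial correlation handles the chain identities", {
  # non-adjacent pair given the clean intermediate: exactly zero
  expect_identical(partial_correlation(0.48, 0.8, 0.6), 0)
  # adjacent pair given the far marker
  expect_equal(partial_correlation(0.8, 0.64, 0.8), 0.6247, tolerance = 1e-4)
  expect_equal(partial_correlation(0.3 * 0.7, 0.3, 0.7), 0)
  expect_error(partial_correlation(0.5, 1, 0.5), "degenerate")
})

test_that("middle-marker error moves partial correlations monotonically", {
  t12 <- 0.1; t23 <- 0.2
  eps <- seq(0.001, 0.49, length.out = 200)
  p12 <- p13 <- numeric(length(eps))
  for (k in seq_along(eps)) {
    e <- eps[k]
    r12 <- expected_correlation(t12, 0, e)
    r23 <- expected_correlation(t23, e, 0)
    r13 <- expected_correlation(t12) * expected_correlation(t23)
    p12[k] <- partial_correlation(r12, r13, r23)   # (M1, M2~ | M3)
    p13[k] <- partial_correlation(r13, r12, r23)   # (M1, M3 | M2~)
  }
  expect_true(all(diff(p12) < 0))   # decreasing in error rate
  expect_true(all(diff(p13) > 0))   # increasing in error rate
})

test_that("error-configuration inequality chains hold for flank partials", {
  # rho(M1 M3 | M2~) under the four (e1, e3) error settings, with M2 in error
  flank_partial <- function(t12, t23, e1, e2, e3) {
    r12 <- expected_correlation(t12, e1, e2)
    r23 <- expected_correlation(t23, e2, e3)
    r13 <- expected_correlation(t12) * expected_correlation(t23) *
      (1 - 2 * e1) * (1 - 2 * e3)
    partial_correlation(r13, r12, r23)
  }
  e <- 0.08
  for (th in list(c(0.1, 0.1), c(0.2, 0.1), c(0.1, 0.2))) {
    t12 <- th[1]; t23 <- th[2]
    p_no   <- flank_partial(t12, t23, 0, e, 0)   # only M2 in error
    p_m1   <- flank_partial(t12, t23, e, e, 0)
    p_m3   <- flank_partial(t12, t23, 0, e, e)
    p_both <- flank_partial(t12, t23, e, e, e)
    expect_true(0 < p_both)
    expect_true(p_both < min(p_m1, p_m3))
    expect_true(max(p_m1, p_m3) < p_no)
    expect_true(p_no < 1)
    if (t12 == t23) expect_equal(p_m1, p_m3, tolerance = 1e-12)
    if (t12 > t23) expect_true(p_m1 > p_m3)
    if (t23 > t12) expect_true(p_m3 > p_m1)
  }
})

test_that("theoretical N.N.Stress follows the middle-error law", {
  expect_equal(theoretical_nn_stress(triplet_model(0.1, 0.2, eps2 = 0.05)),
               -log(0.9), tolerance = 1e-12)
  expect_equal(100 * theoretical_nn_stress(triplet_model(0.1, 0.2, eps2 = 0.01)),
               2.0203, tolerance = 1e-4)
  # zero when the middle marker is clean, any flank errors
  for (e1 in c(0, 0.1, 0.3)) for (e3 in c(0, 0.2, 0.4)) {
    expect_equal(theoretical_nn_stress(triplet_model(0.15, 0.3, e1, 0, e3)),
                 0, tolerance = 1e-12)
    # and depends only on eps2 otherwise
    expect_equal(theoretical_nn_stress(triplet_model(0.15, 0.3, e1, 0.07, e3)),
                 -log(1 - 2 * 0.07), tolerance = 1e-12)
  }
})
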