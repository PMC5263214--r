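# DH meiosis simulator, error and missingness channels, scenarios.

test_that("zero map distance forces co-segregation and seeds reproduce", {
  map <- genetic_map(c("A", "B"), "1", c(5, 5))
  g <- sim_dh(map, 500, seed = 11)
  expect_identical(g[, "A"], g[, "B"])
  g2 <- sim_dh(map, 500, seed = 11)
  expect_identical(unclass(g), unclass(g2))
  g3 <- sim_dh(map, 500, seed = 12)
  expect_false(identical(unclass(g), unclass(g3)))
  expect_error(sim_dh(map, 0), "at least 1")
})

test_that("adjacent recombinant fraction matches the inverse Haldane rate", {
  d <- 300 / 199               # cM, the benchmark spacing
  theta <- (1 - exp(-2 * d / 100)) / 2
  expect_equal(theta, 0.01485, tolerance = 1e-3)
  n <- 100000
  g <- sim_dh(genetic_map(c("A", "B"), "1", c(0, d)), n, seed = 5)
  rf <- mean(g[, "A"] != g[, "B"])
  se <- sqrt(theta * (1 - theta) / n)
  expect_lt(abs(rf - theta), 3 * se)
})

test_that("marginal allele frequencies are balanced and intervals independent", {
  map <- genetic_map(paste0("M", 1:4), "1", c(0, 20, 40, 60))
  n <- 50000
  g <- sim_dh(map, n, seed = 7)
  freq <- colMeans(g == 1)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / n)))
  # recombination indicators of disjoint intervals are uncorrelated
  rec1 <- g[, 1] != g[, 2]
  rec3 <- g[, 3] != g[, 4]
  expect_lt(abs(cor(rec1, rec3)), 3 / sqrt(n))
})

test_that("error channel flips scores at the requested rate and is pure", {
  map <- genetic_map(c("A", "B"), "1", c(0, haldane(0.1) * 100))
  n <- 100000
  g <- sim_dh(map, n, seed = 3)
  g_before <- unclass(g)
  ge <- apply_genotyping_errors(g, c(A = 0.05, B = 0), seed = 4)
  expect_identical(unclass(g), g_before)           # input untouched
  # Table-3 law: observed RF = theta + eps (1 - 2 theta)
  rf_obs <- mean(ge[, "A"] != ge[, "B"])
  expected <- expected_observed_rf(0.1, 0.05, 0)
  expect_lt(abs(rf_obs - expected),
            3 * sqrt(expected * (1 - expected) / n))
  expect_equal(expected, 0.14)
  # zero rate is the identity
  expect_identical(unclass(apply_genotyping_errors(g, 0, seed = 1)),
                   unclass(g))
  # near-0.5 rate destroys association
  g5 <- apply_genotyping_errors(g, c(A = 0.5 - 1e-9, B = 0), seed = 6)
  expect_lt(abs(mean(g5[, "A"] * g5[, "B"])), 3 / sqrt(n))
  expect_error(apply_genotyping_errors(g, 0.5), "0, 0.5")
})

test_that("error channel attenuates correlations by exactly (1 - 2 eps)", {
  map <- genetic_map(c("A", "B"), "1", c(0, haldane(0.2) * 100))
  n <- 100000
  g <- sim_dh(map, n, seed = 8)
  r0 <- mean(g[, "A"] * g[, "B"])
  ge <- apply_genotyping_errors(g, c(A = 0.25, B = 0), seed = 9)
  r1 <- mean(ge[, "A"] * ge[, "B"])
  # conditional on the truth, E[r1] = (1 - 2 eps) r0
  expect_lt(abs(r1 - (1 - 0.5) * r0), 4 / sqrt(n))
})

test_that("missingness mask hits its rate, reproduces, and respects zero", {
  map <- genetic_map(paste0("M", 1:20), "1", seq(0, 95, by = 5))
  g <- sim_dh(map, 500, seed = 2)
  gm <- apply_missing(g, 0.1, seed = 21)
  frac <- mean(is.na(gm))
  cells <- length(gm)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / cells))
  expect_identical(unclass(apply_missing(g, 0, seed = 1)), unclass(g))
  gm2 <- apply_missing(g, 0.1, seed = 21)
  expect_identical(which(is.na(gm)), which(is.na(gm2)))
  expect_error(apply_missing(g, 1), "0, 1")
})

test_that("benchmark scenario has the designed shape and error placement", {
  sc <- sim_error_benchmark(seed = 1)
  expect_equal(dim(sc$observed), c(300, 200))
  expect_equal(dim(sc$truth), c(300, 200))
  expect_equal(sc$map$pos_cM[c(1, 200)], c(0, 300))
  expect_equal(diff(sc$map$pos_cM), rep(300 / 199, 199), tolerance = 1e-12)
  expect_equal(sc$error_markers, c(34L, 51L, 63L, 128L, 155L, 184L))
  clean <- setdiff(1:200, sc$error_markers)
  expect_identical(unclass(sc$truth)[, clean], unclass(sc$observed)[, clean])
  # the 5% marker disagrees with its truth at ~5%
  dis <- mean(sc$truth[, 63] != sc$observed[, 63])
  expect_lt(abs(dis - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("translocation hub induces pseudo-linkage across arms", {
  # arms of negligible length: all markers copy the hub
  g0 <- sim_translocation(translocation_spec(rep(1e-9, 4), 2), 200, seed = 1)
  for (k in 2:ncol(g0)) expect_identical(g0[, 1], g0[, k])
  # cross-hub RF composes the two arm distances via Haldane
  n <- 100000
  g <- sim_translocation(translocation_spec(c(10, 10), 1), n, seed = 2)
  rf <- mean(g[, 1] != g[, 2])
  expected <- haldane_inverse(0.2)     # 10 cM + 10 cM through the hub
  expect_lt(abs(rf - expected), 3 * sqrt(expected * (1 - expected) / n))
  expect_error(translocation_spec(c(10, -1), 2), "positive")
  expect_error(translocation_spec(c(10, 10), 0), ">= 1 marker")
})
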