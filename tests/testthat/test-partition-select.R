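# Preprocessing filters, dedup, linkage grouping, k-medoids.

test_that("heterozygote masking recodes and reports offenders", {
  raw <- matrix(c("a", "b", "h",
                  "b", "a", "-",
                  "h", "h", "a"), 3, 3, byrow = TRUE,
                dimnames = list(paste0("i", 1:3), paste0("M", 1:3)))
  g <- mask_heterozygotes(raw)
  expect_equal(unname(g[1, ]), c(-1L, 1L, NA))
  expect_equal(attr(g, "population"), "RIL")
  expect_equal(unname(g[2, ]), c(1L, -1L, NA))
  bad <- raw; bad[3, 2] <- "x"
  expect_error(mask_heterozygotes(bad), "i3, M2")
  allhet <- raw; allhet[, 3] <- "h"
  expect_warning(mask_heterozygotes(allhet), "all-missing")
})

test_that("missing-data filter removes markers first, then individuals", {
  g <- genotypes(cbind(A = c(-1, 1, -1, 1, -1),
                       B = c(NA, NA, 1, -1, 1),
                       C = c(NA, 1, -1, 1, 1),
                       D = c(-1, 1, 1, -1, 1)))
  # B is 40% missing -> removed at 0.3; afterwards ind 1 is 1/3 missing
  res <- filter_missing(g, max_marker_missing = 0.3,
                        max_indiv_missing = 0.3)
  expect_false("B" %in% colnames(res$genotypes))
  expect_false("ind1" %in% rownames(res$genotypes))
  expect_setequal(res$removed$name, c("B", "ind1"))
  expect_equal(res$removed$what, c("marker", "individual"))
  # with B retained (loose marker cutoff), ind1 is 2/4 missing -> removed;
  # ind2's 1/4 survives a 0.3 cutoff: order of operations matters
  res2 <- filter_missing(g, max_marker_missing = 1,
                         max_indiv_missing = 0.3)
  expect_true("B" %in% colnames(res2$genotypes))
  expect_false("ind1" %in% rownames(res2$genotypes))
  res3 <- filter_missing(g, 1, 1)
  expect_equal(dim(res3$genotypes), dim(g))
  expect_equal(nrow(res3$removed), 0)
})

test_that("duplicate and phase-flipped markers collapse, near-duplicates stay", {
  g <- genotypes(cbind(A = c(-1, 1, -1, NA),
                       B = c(-1, 1, -1, NA),      # exact duplicate of A
                       C = c(1, -1, 1, NA),       # sign flip of A
                       D = c(-1, 1, NA, NA),      # differs in missing mask
                       E = c(-1, -1, 1, 1)))
  dd <- dedup_markers(g)
  expect_setequal(colnames(dd$genotypes), c("A", "D", "E"))
  expect_setequal(dd$groups[["A"]], c("A", "B", "C"))
  expect_equal(dd$groups[["D"]], "D")
})

test_that("linkage groups are RF-threshold components with stable behaviour", {
  map2 <- genetic_map(sprintf("M%02d", 1:12), rep(c("1", "2"), each = 6),
                      rep(seq(0, 50, by = 10), 2))
  g <- sim_dh(map2, 300, seed = 71)
  rf <- estimate_rf(g)
  lg <- group_by_rf(rf, 0.2)
  expect_length(lg$groups, 2)
  expect_setequal(lg$groups[[1]], map2$marker[map2$chrom == "1"])
  expect_setequal(lg$groups[[2]], map2$marker[map2$chrom == "2"])
  # threshold above every estimate: one group; zero threshold: all singletons
  expect_length(group_by_rf(rf, 0.51)$groups, 1)
  expect_length(group_by_rf(rf, 0)$groups, 12)
  # group count non-increasing in threshold
  counts <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.51),
                   function(t) length(group_by_rf(rf, t)$groups), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # invariance to marker input order
  set.seed(72)
  perm <- sample(12)
  lgp <- group_by_rf(rf$rho[perm, perm], 0.2)
  expect_setequal(lapply(lgp$groups, sort), lapply(lg$groups, sort))
})

test_that("k-medoids selects one representative per cluster", {
  # two well-separated blobs on a line
  pos <- c(0, 1, 2, 20, 21, 22)
  d <- abs(outer(pos, pos, "-"))
  dimnames(d) <- list(paste0("M", 1:6), paste0("M", 1:6))
  km <- k_medoids(d, 2)
  expect_setequal(km$medoids, c("M2", "M5"))       # blob centres
  expect_equal(unname(km$clustering[1:3]), rep(km$clustering[["M1"]], 3))
  # k = p: every marker its own medoid, zero cost
  km_all <- k_medoids(d, 6)
  expect_setequal(km_all$medoids, colnames(d))
  expect_equal(km_all$cost, 0)
  # duplicated patterns: k = #distinct gives zero cost
  d2 <- d[c(1, 1, 4, 4), c(1, 1, 4, 4)]
  dimnames(d2) <- list(paste0("M", 1:4), paste0("M", 1:4))
  expect_equal(k_medoids(d2, 2)$cost, 0)
  expect_error(k_medoids(d, 7), "exceed")
  # singleton clusters carry a warning
  d3 <- d; d3["M6", ] <- d3[, "M6"] <- 50; d3["M6", "M6"] <- 0
  expect_warning(k_medoids(d3, 3), "singleton|isolated")
})
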