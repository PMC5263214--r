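# Pairwise recombination-frequency and correlation estimation, plus
# nearest-neighbour stress profiles along a marker order.

RF_CLAMP <- 0.5 - 1e-6

pairwise_counts <- function(geno) {
  obs <- !is.na(unclass(geno))
  storage.mode(obs) <- "double"
  crossprod(obs)
}

#' Estimate pairwise recombination frequencies
#'
#' For each pair of markers the fraction of pairwise-complete individuals
#' whose scores disagree.  Entries with fewer than `min_pairs`
#' pairwise-complete observations (including pairs with none) are set NA.
#'
#' @param geno A [genotypes()] matrix with `>= 2` markers.
#' @param min_pairs Minimum number of pairwise-complete observations for an
#'   entry to be considered reliable (default 10); unreliable entries are NA.
#' @return A list of class `pairwise_rf`: `rho` (p x p symmetric matrix,
#'   zero diagonal), `n_pairs` (pairwise-complete counts).
#' @examples
#' g <- genotypes(cbind(A = c(-1, -1, 1, 1), B = c(-1, -1, 1, -1)))
#' estimate_rf(g, min_pairs = 1)$rho["A", "B"]   # 0.25
#' @export
estimate_rf <- function(geno, min_pairs = 10) {
  stopifnot(inherits(geno, "genotypes"), ncol(geno) >= 2)
  x <- unclass(geno)
  x[is.na(x)] <- 0L
  storage.mode(x) <- "double"
  S <- crossprod(x)                      # sum of products over complete pairs
  N <- pairwise_counts(geno)
  rho <- (N - S) / (2 * N)
  rho[N < max(1, min_pairs)] <- NA_real_
  diag(rho) <- 0
  structure(list(rho = rho, n_pairs = N), class = "pairwise_rf")
}

#' Marker correlation matrix
#'
#' The correlation between two -1/+1 markers is estimated as the mean of
#' their products over pairwise-complete individuals (the scores have mean
#' 0 and variance 1 under the segregation model, so no centering is
#' applied).  On complete data it satisfies `r = 1 - 2 * rho` exactly,
#' where `rho` is the [estimate_rf()] estimate.
#'
#' @inheritParams estimate_rf
#' @return A list of class `pairwise_corr`: `r` (p x p, unit diagonal),
#'   `n_pairs`.  Entries with fewer than `min_pairs` complete pairs are NA.
#' @export
correlation_matrix <- function(geno, min_pairs = 10) {
  stopifnot(inherits(geno, "genotypes"), ncol(geno) >= 2)
  x <- unclass(geno)
  const <- apply(x, 2, function(col) {
    v <- col[!is.na(col)]
    length(v) > 0 && length(unique(v)) == 1
  })
  if (any(const))
    warning("constant marker column(s): ",
            paste(colnames(geno)[const], collapse = ", "))
  x[is.na(x)] <- 0L
  storage.mode(x) <- "double"
  S <- crossprod(x)
  N <- pairwise_counts(geno)
  r <- S / N
  r[N < max(1, min_pairs)] <- NA_real_
  diag(r) <- 1
  structure(list(r = r, n_pairs = N), class = "pairwise_corr")
}

clamp_rf <- function(rho, context = "RF") {
  bad <- !is.na(rho) & rho >= 0.5
  if (any(bad)) {
    warning(sum(bad), " ", context,
            " estimate(s) >= 0.5 clamped to 0.5 - 1e-6 before Haldane transform")
    rho[bad] <- RF_CLAMP
  }
  rho
}

#' Nearest-neighbour stress profile along a marker order
#'
#' For each interior marker `j` of the order, with neighbours `i` and `k`,
#' the stress is `100 * (d(rho_ij) + d(rho_jk) - d(rho_ik))` cM, where `d`
#' is the Haldane mapping function applied to observed recombination
#' frequencies.  Error-free interior markers have stress near zero; a
#' marker with genotyping error rate `eps` has expected stress
#' `-100 * log(1 - 2 * eps)` cM.  Terminal markers get NA.
#'
#' @param geno A [genotypes()] matrix.
#' @param order Marker names or column indices, length `>= 3`.
#' @param rf Optional precomputed [estimate_rf()] result.
#' @param min_pairs Passed to [estimate_rf()] when `rf` is NULL.
#' @return A `data.frame` with columns `marker`, `index_in_order`,
#'   `stress_cM`.
#' @examples
#' sc <- sim_dh(genetic_map(c("A", "B", "C"), "1", c(0, 10, 20)), 200, seed = 1)
#' nn_stress_profile(sc, c("A", "B", "C"))
#' @export
nn_stress_profile <- function(geno, order, rf = NULL, min_pairs = 10) {
  if (is.numeric(order)) order <- colnames(geno)[order]
  stopifnot(length(order) >= 3, all(order %in% colnames(geno)))
  if (is.null(rf)) rf <- estimate_rf(geno, min_pairs = min_pairs)
  m <- length(order)
  rho <- rf$rho[order, order, drop = FALSE]
  r_ij <- clamp_rf(rho[cbind(1:(m - 2), 2:(m - 1))], "flank RF")
  r_jk <- clamp_rf(rho[cbind(2:(m - 1), 3:m)], "flank RF")
  r_ik <- clamp_rf(rho[cbind(1:(m - 2), 3:m)], "outer RF")
  stress <- c(NA_real_,
              100 * (haldane(r_ij) + haldane(r_jk) - haldane(r_ik)),
              NA_real_)
  data.frame(marker = order, index_in_order = seq_len(m),
             stress_cM = stress, stringsAsFactors = FALSE)
}
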