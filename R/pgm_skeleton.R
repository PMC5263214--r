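# Order-independent PC-stable skeleton estimation over markers, using
# Fisher-z conditional-independence tests on the marker correlation matrix.

#' Fisher-z test of (partial) correlation
#'
#' Tests whether a (partial) correlation is zero: with
#' \eqn{z = \tanh^{-1}(r)} the statistic \eqn{\sqrt{n - s - 3}\,|z|} is
#' compared to a standard normal (two-sided).  The marker scores are binary
#' -1/+1, so the Gaussian reference distribution is an approximation; it is
#' the test conventionally used for constraint-based structure learning on
#' marker data.
#'
#' @param r Estimated (partial) correlation, `|r| <= 1`.
#' @param n Number of observations.
#' @param s Size of the conditioning set.
#' @param alpha Significance level; the pair is declared independent iff
#'   the p-value exceeds `alpha`.
#' @return A list of class `ci_test`: `r`, `n`, `s`, `statistic`,
#'   `p_value`, `independent`, `skipped` (TRUE when `n - s - 3 <= 0`, in
#'   which case no decision is made and `independent` is FALSE).
#' @examples
#' fisher_z_test(0.5, n = 100, s = 1)$statistic   # 5.382
#' @export
fisher_z_test <- function(r, n, s = 0, alpha = 0.05) {
  if (is.na(r)) stop("r is NA; degenerate estimates are handled by the caller")
  if (abs(r) > 1 + 1e-8) stop("|r| must not exceed 1")
  if (n - s - 3 <= 0) {
    return(structure(list(r = r, n = n, s = s, statistic = NA_real_,
                          p_value = NA_real_, independent = FALSE,
                          skipped = TRUE), class = "ci_test"))
  }
  r <- min(max(r, -1), 1)
  if (abs(r) == 1) {
    stat <- Inf; p <- 0
  } else {
    z <- 0.5 * log((1 + r) / (1 - r))
    stat <- sqrt(n - s - 3) * abs(z)
    p <- 2 * stats::pnorm(-stat)
  }
  structure(list(r = r, n = n, s = s, statistic = stat, p_value = p,
                 independent = p > alpha, skipped = FALSE),
            class = "ci_test")
}

as_corr_matrix <- function(x) {
  if (inherits(x, "pairwise_corr")) x$r
  else if (is.matrix(x)) x
  else stop("expected a correlation matrix or a 'pairwise_corr' object")
}

#' Partial correlation given a conditioning set
#'
#' Computes \eqn{\rho_{ij|S}} from a correlation matrix by recursive
#' application of the first-order formula, removing one conditioning
#' variable at a time.  With `S` empty it returns `r[i, j]`.
#'
#' @param corr Correlation matrix or [correlation_matrix()] result.
#' @param i,j Marker indices or names.
#' @param S Conditioning set (indices or names; possibly empty).
#' @return The partial correlation, or NA when the conditioning is
#'   degenerate (some intermediate partial correlation has magnitude 1).
#' @examples
#' R <- matrix(c(1, .8, .64, .8, 1, .8, .64, .8, 1), 3)
#' partial_cor(R, 1, 3, S = 2)   # 0: non-adjacent chain pair
#' @export
partial_cor <- function(corr, i, j, S = integer(0)) {
  R <- as_corr_matrix(corr)
  if (is.character(i)) i <- match(i, colnames(R))
  if (is.character(j)) j <- match(j, colnames(R))
  if (is.character(S)) S <- match(S, colnames(R))
  pcor_recurse(R, i, j, S)
}

pcor_recurse <- function(R, i, j, S) {
  if (length(S) == 0) return(R[i, j])
  k <- S[1]; rest <- S[-1]
  r_ij <- pcor_recurse(R, i, j, rest)
  r_ik <- pcor_recurse(R, i, k, rest)
  r_jk <- pcor_recurse(R, j, k, rest)
  if (anyNA(c(r_ij, r_ik, r_jk))) return(NA_real_)
  den2 <- (1 - r_ik^2) * (1 - r_jk^2)
  if (den2 <= 1e-12) return(NA_real_)
  (r_ij - r_ik * r_jk) / sqrt(den2)
}

#' PC-stable skeleton over markers
#'
#' Estimates the undirected conditional-independence graph of a set of
#' markers by the first (skeleton) phase of the PC-stable algorithm.  At
#' each level `l = 0, 1, 2, ...` every node's adjacency set is frozen;
#' each remaining edge `(i, j)` is tested against conditioning sets of
#' size `l` drawn from the frozen neighbourhoods of `i` and of `j`, and is
#' scheduled for removal on the first set that renders the pair
#' independent.  Removals are committed only after the level completes,
#' which makes the resulting edge set invariant to the order in which
#' markers appear in the input.
#'
#' Degenerate conditioning (an intermediate partial correlation of
#' magnitude 1, e.g. from duplicated markers) is treated as dependence:
#' the edge is kept and the event is counted in `n_degenerate`.
#'
#' @param x A [genotypes()] matrix (its correlation matrix is computed
#'   with [correlation_matrix()]), a `pairwise_corr` object, or a plain
#'   correlation matrix (then `n` is required).
#' @param n Number of observations; taken from `x` when it is a genotype
#'   matrix.
#' @param alpha Significance level of the conditional-independence tests
#'   (default 0.05).
#' @param max_cond Maximum conditioning-set size (default 3).
#' @param min_pairs Passed to [correlation_matrix()] for genotype input.
#' @return An object of class `pgm_skeleton`: `adj` (logical p x p),
#'   `markers`, `sepsets` (named list, `"A|B"` -> conditioning marker
#'   names), `alpha`, `n`, `max_cond`, `n_tests`, `n_degenerate`.
#' @examples
#' sc <- sim_dh(genetic_map(paste0("M", 1:5), "1", seq(0, 60, 15)), 300, seed = 1)
#' sk <- pc_skeleton(sc)
#' skeleton_edges(sk)
#' @export
pc_skeleton <- function(x, n = NULL, alpha = 0.05, max_cond = 3,
                        min_pairs = 10) {
  if (inherits(x, "genotypes")) {
    n <- nrow(x)
    R <- correlation_matrix(x, min_pairs = min_pairs)$r
  } else {
    R <- as_corr_matrix(x)
    if (is.null(n)) stop("n is required when a correlation matrix is supplied")
  }
  p <- ncol(R)
  if (is.null(colnames(R))) colnames(R) <- rownames(R) <- paste0("V", seq_len(p))
  markers <- colnames(R)
  if (anyNA(R)) {
    bad <- sort(which(is.na(R), arr.ind = TRUE)[1, ])
    stop("missing correlation entry for pair (", markers[bad[1]], ", ",
         markers[bad[2]], ")")
  }

  adj <- matrix(TRUE, p, p, dimnames = list(markers, markers))
  diag(adj) <- FALSE
  sepsets <- list()
  n_tests <- 0L; n_degen <- 0L

  crit <- stats::qnorm(1 - alpha / 2)
  # level 0: marginal tests, vectorized
  z <- suppressWarnings(atanh(pmin(pmax(R, -1), 1)))
  indep0 <- sqrt(n - 3) * abs(z) <= crit        # |r|=1 -> Inf -> dependent
  indep0[is.na(indep0)] <- FALSE
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    n_tests <- n_tests + 1L
    if (indep0[i, j]) {
      adj[i, j] <- adj[j, i] <- FALSE
      sepsets[[paste(markers[i], markers[j], sep = "|")]] <- character(0)
    }
  }

  l <- 0L
  repeat {
    l <- l + 1L
    if (l > max_cond) break
    frozen <- adj
    deg <- rowSums(frozen)
    if (!any(deg >= l + 1)) break                 # no testable edge left
    edges <- which(frozen & upper.tri(frozen), arr.ind = TRUE)
    if (nrow(edges) == 0) break
    to_remove <- list()
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      nb_i <- sort(setdiff(which(frozen[i, ]), j))
      nb_j <- sort(setdiff(which(frozen[j, ]), i))
      if (l == 1L && n - 4 > 0) {                 # vectorized fast path
        ks <- c(nb_i, setdiff(nb_j, nb_i))
        if (length(ks) == 0) next
        den2 <- (1 - R[i, ks]^2) * (1 - R[j, ks]^2)
        rp <- (R[i, j] - R[i, ks] * R[j, ks]) / sqrt(den2)
        degen <- den2 <= 1e-12 | !is.finite(rp)
        n_tests <- n_tests + length(ks)
        n_degen <- n_degen + sum(degen)
        rp[degen] <- 1                            # degenerate -> dependent
        stat <- sqrt(n - 4) * abs(atanh(pmin(pmax(rp, -1), 1)))
        hit <- which(stat <= crit)
        if (length(hit)) {
          to_remove[[length(to_remove) + 1L]] <-
            list(i = i, j = j, S = ks[hit[1]])
        }
        next
      }
      sets <- list()
      if (length(nb_i) >= l)
        sets <- c(sets, combn_list(nb_i, l))
      if (length(nb_j) >= l) {
        extra <- combn_list(nb_j, l)
        extra <- extra[!vapply(extra, function(s) all(s %in% nb_i), logical(1))]
        sets <- c(sets, extra)
      }
      for (S in sets) {
        rp <- pcor_recurse(R, i, j, S)
        n_tests <- n_tests + 1L
        if (is.na(rp)) { n_degen <- n_degen + 1L; next }
        tst <- fisher_z_test(rp, n, length(S), alpha)
        if (tst$skipped) next
        if (tst$independent) {
          to_remove[[length(to_remove) + 1L]] <- list(i = i, j = j, S = S)
          break
        }
      }
    }
    for (rm in to_remove) {                       # batch commit at level end
      adj[rm$i, rm$j] <- adj[rm$j, rm$i] <- FALSE
      sepsets[[paste(markers[rm$i], markers[rm$j], sep = "|")]] <-
        markers[rm$S]
    }
  }

  structure(list(adj = adj, markers = markers, sepsets = sepsets,
                 alpha = alpha, n = n, max_cond = max_cond,
                 n_tests = n_tests, n_degenerate = n_degen),
            class = "pgm_skeleton")
}

combn_list <- function(v, m) {
  if (length(v) == m) return(list(v))
  utils::combn(v, m, simplify = FALSE)
}

#' Edge list of a skeleton
#'
#' @param skeleton A [pc_skeleton()] result.
#' @return A two-column character matrix of edges (each once, i < j).
#' @export
skeleton_edges <- function(skeleton) {
  stopifnot(inherits(skeleton, "pgm_skeleton"))
  idx <- which(skeleton$adj & upper.tri(skeleton$adj), arr.ind = TRUE)
  cbind(from = skeleton$markers[idx[, 1]], to = skeleton$markers[idx[, 2]])
}

#' @export
print.pgm_skeleton <- function(x, ...) {
  cat(sprintf(
    "PC-stable skeleton: %d markers, %d edges (alpha = %g, n = %d, max |S| = %d)\n",
    length(x$markers), sum(x$adj) / 2, x$alpha, x$n, x$max_cond))
  if (x$n_degenerate > 0)
    cat(sprintf("  %d degenerate conditioning set(s) treated as dependence\n",
                x$n_degenerate))
  invisible(x)
}
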