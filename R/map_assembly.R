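# Linkage map assembly and the end-to-end pipeline driver.

#' Build a linkage map from a genotype matrix and a marker order
#'
#' Two-point map assembly: adjacent recombination frequencies are estimated
#' from the data, converted to Haldane distances, and accumulated into cM
#' positions starting at 0.  Each interior marker also gets its
#' nearest-neighbour stress (see [nn_stress_profile()]).
#'
#' @param geno A [genotypes()] matrix.
#' @param order Marker names (or indices) in map order, length `>= 2`;
#'   e.g. the `main_string` of a [diagonalize()] result.
#' @param min_pairs Passed to [estimate_rf()].
#' @return A `data.frame` of class `linkage_map` with columns `marker`,
#'   `rf_adj` (RF to the previous marker; NA for the first),
#'   `d_adj_cM`, `position_cM`, `nn_stress_cM`.
#' @examples
#' g <- sim_dh(genetic_map(paste0("M", 1:4), "1", c(0, 10, 20, 30)), 300, seed = 1)
#' build_map(g, paste0("M", 1:4))
#' @export
build_map <- function(geno, order, min_pairs = 10) {
  if (is.numeric(order)) order <- colnames(geno)[order]
  stopifnot(length(order) >= 2, all(order %in% colnames(geno)))
  rf <- estimate_rf(geno, min_pairs = min_pairs)
  m <- length(order)
  rho_adj <- rf$rho[cbind(order[-m], order[-1])]
  if (anyNA(rho_adj))
    stop("missing adjacent RF estimate in the supplied order")
  rho_adj <- clamp_rf(rho_adj, "adjacent RF")
  d_adj <- c(NA, 100 * haldane(rho_adj))
  pos <- cumsum(c(0, 100 * haldane(rho_adj)))
  stress <- if (m >= 3)
    nn_stress_profile(geno, order, rf = rf)$stress_cM else rep(NA_real_, m)
  structure(data.frame(marker = order, rf_adj = c(NA, rho_adj),
                       d_adj_cM = d_adj, position_cM = pos,
                       nn_stress_cM = stress, stringsAsFactors = FALSE),
            class = c("linkage_map", "data.frame"))
}

#' Run the full mapping pipeline
#'
#' Executes the complete workflow: obtain data (from file or simulation),
#' preprocess (optional missing-data filters and duplicate collapsing),
#' form linkage groups by RF threshold (optional), estimate a PC-stable
#' skeleton per group, order markers by diagonalization, classify
#' pulled-aside markers, and build a cM map over the main string of each
#' group.  When `out_dir` is given, all artifacts are written (genotype
#' CSV, matrices, SIF/GraphML graphs, map and classification TSVs) along
#' with a manifest.
#'
#' @param config A named list (or path to a `key = value` text file) with
#'   entries: one of `input` (genotype CSV path) or `scenario`
#'   (`"benchmark"` or `"translocation"`); `seed` (default 1); `n`
#'   (simulation size); `alpha` (default 0.05); `max_cond` (default 3);
#'   `rf_threshold` (linkage grouping threshold; omit for a single group);
#'   `k` (medoid count per group; omit to keep all markers);
#'   `max_marker_missing`, `max_indiv_missing` (fractions; default 1 =
#'   keep all); `dedup` (default FALSE); `min_pairs` (default 10);
#'   `out_dir` (optional output directory).
#' @return A list of class `pgmmap_pipeline`: `genotypes`, `groups`, and
#'   per-group `skeleton`, `order`, `classification`, `map`; plus `config`
#'   and, if written, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(
    list(seed = 1, n = 300, alpha = 0.05, max_cond = 3,
         max_marker_missing = 1, max_indiv_missing = 1, dedup = FALSE,
         min_pairs = 10), config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth_markers <- NULL
  geno <- stage("input", {
    if (!is.null(cfg$input)) {
      read_genotypes(cfg$input)
    } else if (identical(cfg$scenario, "benchmark")) {
      sc <- sim_error_benchmark(seed = cfg$seed, n = cfg$n)
      truth_markers <- names(sc$error_rates)
      sc$observed
    } else if (identical(cfg$scenario, "translocation")) {
      sim_translocation(translocation_spec(c(30, 30, 30, 30), 10),
                        cfg$n, seed = cfg$seed)
    } else stop("config needs 'input' or scenario 'benchmark'/'translocation'")
  })

  pre <- stage("preprocess", {
    res <- filter_missing(geno, cfg$max_marker_missing, cfg$max_indiv_missing)
    dd <- if (isTRUE(cfg$dedup)) dedup_markers(res$genotypes) else
      list(genotypes = res$genotypes, groups = NULL)
    list(genotypes = dd$genotypes, removed = res$removed,
         dup_groups = dd$groups)
  })
  g <- pre$genotypes

  rf <- stage("rf", estimate_rf(g, min_pairs = cfg$min_pairs))
  groups <- stage("group", {
    if (!is.null(cfg$rf_threshold)) group_by_rf(rf, cfg$rf_threshold)
    else structure(list(groups = list(colnames(g)),
                        membership = stats::setNames(rep(1L, ncol(g)),
                                                     colnames(g)),
                        threshold = NA_real_), class = "linkage_groups")
  })

  per_group <- lapply(seq_along(groups$groups), function(gi) {
    mk <- groups$groups[[gi]]
    if (!is.null(cfg$k) && cfg$k < length(mk)) {
      med <- k_medoids(rf$rho[mk, mk], cfg$k)
      mk <- med$medoids
    }
    sub <- genotypes(unclass(g)[, mk, drop = FALSE],
                     population = attr(g, "population"))
    if (length(mk) < 2)
      return(list(markers = mk, skeleton = NULL, order = NULL,
                  classification = NULL, map = NULL))
    sk <- stage("skeleton", pc_skeleton(sub, alpha = cfg$alpha,
                                        max_cond = cfg$max_cond,
                                        min_pairs = cfg$min_pairs))
    ord <- stage("order", diagonalize(sk))
    cls <- classify_markers(ord, truth = truth_markers)
    lm <- if (length(ord$main_string) >= 2)
      stage("map", build_map(sub, ord$main_string,
                             min_pairs = cfg$min_pairs)) else NULL
    list(markers = mk, skeleton = sk, order = ord, classification = cls,
         map = lm)
  })

  out <- structure(list(genotypes = g, removed = pre$removed,
                        dup_groups = pre$dup_groups, rf = rf,
                        groups = groups, results = per_group,
                        truth_markers = truth_markers, config = cfg),
                   class = "pgmmap_pipeline")
  if (!is.null(cfg$out_dir)) out$manifest <- write_pipeline(out, cfg$out_dir)
  out
}

#' @export
print.pgmmap_pipeline <- function(x, ...) {
  cat(sprintf("pgmmap pipeline: %d individuals x %d markers, %d group(s)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(x$groups$groups)))
  for (gi in seq_along(x$results)) {
    r <- x$results[[gi]]
    if (is.null(r$order)) next
    cat(sprintf("  group %d: %d markers, skeleton %d edges, main string %d, pulled aside %d\n",
                gi, length(r$markers), sum(r$skeleton$adj) / 2,
                length(r$order$main_string), length(r$order$pulled_aside)))
  }
  invisible(x)
}
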