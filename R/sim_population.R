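# Doubled-haploid population simulation under Haldane meiosis.
# Scores are -1/+1 (the two parental alleles), NA for missing.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Define a genetic map
#'
#' @param marker Character vector of unique marker names, in map order.
#' @param chrom Chromosome label per marker.
#' @param pos_cM Position in cM from the chromosome start; non-negative and
#'   non-decreasing within each chromosome.
#' @return A `data.frame` of class `genetic_map` with columns
#'   `marker`, `chrom`, `pos_cM`.
#' @examples
#' genetic_map(paste0("M", 1:5), "1", seq(0, 40, by = 10))
#' @export
genetic_map <- function(marker, chrom, pos_cM) {
  marker <- as.character(marker)
  chrom <- rep_len(as.character(chrom), length(marker))
  pos_cM <- as.numeric(pos_cM)
  stopifnot(length(pos_cM) == length(marker))
  if (anyDuplicated(marker)) stop("marker names must be unique")
  if (any(pos_cM < 0)) stop("positions must be non-negative")
  for (ch in unique(chrom)) {
    p <- pos_cM[chrom == ch]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", ch)
  }
  structure(data.frame(marker = marker, chrom = chrom, pos_cM = pos_cM,
                       stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

#' Construct a genotype matrix object
#'
#' A genotype matrix is an integer matrix of -1/+1 scores (NA = missing)
#' with individuals in rows and markers in columns, plus a population type
#' annotation (`"DH"` or `"RIL"`).
#'
#' @param scores Matrix with values in `{-1, 1, NA}`.
#' @param markers Marker names (defaults to existing column names).
#' @param ids Individual identifiers (defaults to existing row names).
#' @param population `"DH"` or `"RIL"`.
#' @return An integer matrix of class `genotypes`.
#' @export
genotypes <- function(scores, markers = colnames(scores),
                      ids = rownames(scores), population = "DH") {
  scores <- as.matrix(scores)
  if (!all(scores %in% c(-1, 1, NA)))
    stop("genotype scores must be -1, 1 or NA")
  population <- match.arg(population, c("DH", "RIL"))
  storage.mode(scores) <- "integer"
  if (is.null(markers)) markers <- paste0("M", seq_len(ncol(scores)))
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(scores)))
  if (anyDuplicated(markers)) stop("marker names must be unique")
  stopifnot(length(markers) == ncol(scores), length(ids) == nrow(scores))
  dimnames(scores) <- list(ids, markers)
  structure(scores, population = population, class = c("genotypes", "matrix"))
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("Genotype matrix (%s): %d individuals x %d markers, %.1f%% missing\n",
              attr(x, "population"), nrow(x), ncol(x),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Simulate a doubled-haploid population
#'
#' Each individual is an independent doubled gamete: the first marker of a
#' chromosome is -1 or +1 with probability 0.5 each, and each subsequent
#' marker equals its left neighbour with probability `1 - theta` or flips
#' with probability `theta`, where `theta` is the inverse Haldane transform
#' of the inter-marker distance.  Recombination events in adjacent intervals
#' are independent (no interference) and chromosomes segregate
#' independently.
#'
#' @param map A [genetic_map()].
#' @param n Number of individuals (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return A [genotypes()] matrix of dimension `n` x `nrow(map)`.
#' @examples
#' g <- sim_dh(genetic_map(paste0("M", 1:4), "1", c(0, 10, 20, 30)), 50, seed = 1)
#' @export
sim_dh <- function(map, n, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"))
  if (n < 1) stop("n must be at least 1")
  with_seed(seed, {
    p <- nrow(map)
    scores <- matrix(0L, n, p)
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      scores[, idx[1]] <- sample(c(-1L, 1L), n, replace = TRUE)
      if (length(idx) > 1) {
        d <- diff(map$pos_cM[idx]) / 100          # Morgans
        theta <- haldane_inverse(d)
        for (k in seq_along(d)) {
          flip <- stats::runif(n) < theta[k]
          scores[, idx[k + 1]] <- ifelse(flip, -scores[, idx[k]],
                                         scores[, idx[k]])
        }
      }
    }
    genotypes(scores, markers = map$marker,
              ids = sprintf("ind%03d", seq_len(n)), population = "DH")
  })
}

#' Apply locus-specific genotyping errors
#'
#' Each non-missing score at marker `k` independently flips sign with
#' probability `rates[k]`.  The input is not modified.
#'
#' @param geno A [genotypes()] matrix.
#' @param rates Either a single error rate or a vector over markers (may be
#'   named by marker); values in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return A new [genotypes()] matrix.
#' @examples
#' g <- sim_dh(genetic_map(c("A", "B"), "1", c(0, 10)), 20, seed = 1)
#' ge <- apply_genotyping_errors(g, c(A = 0.05, B = 0), seed = 2)
#' @export
apply_genotyping_errors <- function(geno, rates, seed = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  p <- ncol(geno)
  if (!is.null(names(rates))) {
    full <- stats::setNames(numeric(p), colnames(geno))
    bad <- setdiff(names(rates), colnames(geno))
    if (length(bad)) stop("unknown markers in rates: ", paste(bad, collapse = ", "))
    full[names(rates)] <- rates
    rates <- full
  } else rates <- rep_len(rates, p)
  if (any(rates < 0 | rates >= 0.5))
    stop("error rates must lie in [0, 0.5)")
  with_seed(seed, {
    out <- unclass(geno)
    flip <- sweep(matrix(stats::runif(length(geno)), nrow(geno)), 2, rates, "<")
    flip[is.na(out)] <- FALSE
    out[flip] <- -out[flip]
    genotypes(out, population = attr(geno, "population"))
  })
}

#' Set scores missing at random
#'
#' @param geno A [genotypes()] matrix.
#' @param rates Single missingness rate or per-marker vector, each in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A new [genotypes()] matrix with additional NA cells.
#' @export
apply_missing <- function(geno, rates, seed = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  rates <- rep_len(rates, ncol(geno))
  if (any(rates < 0 | rates >= 1)) stop("missingness rates must lie in [0, 1)")
  with_seed(seed, {
    out <- unclass(geno)
    drop <- sweep(matrix(stats::runif(length(geno)), nrow(geno)), 2, rates, "<")
    out[drop] <- NA_integer_
    genotypes(out, population = attr(geno, "population"))
  })
}

#' Benchmark doubled-haploid scenario with designed error markers
#'
#' The standard simulation benchmark used throughout the package: 200
#' markers evenly spaced on a single 300 cM chromosome (199 intervals of
#' 300/199 cM), 300 doubled-haploid individuals, and genotyping errors
#' applied to six designated markers -- 34, 51, 63, 128, 155 and 184 at
#' rates 1, 3, 5, 1, 3 and 5% respectively.  All other markers are
#' error-free.
#'
#' @param seed Integer seed; the truth and the error channel use distinct
#'   derived substreams.
#' @param n Number of individuals (default 300).
#' @return A list with elements `map` ([genetic_map()]), `truth` (error-free
#'   [genotypes()]), `observed` (after error application), `error_markers`
#'   (integer indices) and `error_rates`.
#' @examples
#' \donttest{
#' sc <- sim_error_benchmark(seed = 1)
#' dim(sc$observed)    # 300 x 200
#' }
#' @export
sim_error_benchmark <- function(seed = 1, n = 300) {
  p <- 200
  map <- genetic_map(sprintf("Marker%d", 1:p), "1",
                     seq(0, 300, length.out = p))
  error_markers <- c(34L, 51L, 63L, 128L, 155L, 184L)
  error_rates <- c(0.01, 0.03, 0.05, 0.01, 0.03, 0.05)
  truth <- sim_dh(map, n, seed = seed)
  rates <- numeric(p)
  rates[error_markers] <- error_rates
  observed <- apply_genotyping_errors(truth, rates, seed = seed + 10000L)
  list(map = map, truth = truth, observed = observed,
       error_markers = error_markers,
       error_rates = stats::setNames(error_rates,
                                     map$marker[error_markers]))
}

#' Specify a reciprocal-translocation scenario
#'
#' A reciprocal translocation suppresses recombination around the
#' breakpoint, so that markers on the four chromosome arms involved
#' co-segregate with the breakpoint region ("pseudo-linkage") and the
#' marker graph takes a cross-like shape.  The scenario is modelled as a
#' star of Markov chains: a latent hub variable represents the
#' co-segregating breakpoint region, and each arm extends outward from the
#' hub with Haldane transition probabilities.
#'
#' @param arm_lengths_cM Numeric vector (length >= 2, typically 4) of arm
#'   lengths in cM, all `> 0`.
#' @param markers_per_arm Markers on each arm (recycled), all `>= 1`;
#'   marker 1 of an arm is closest to the hub.
#' @param hub Label used for the breakpoint region in marker names.
#' @return An object of class `translocation_spec`.
#' @export
translocation_spec <- function(arm_lengths_cM, markers_per_arm, hub = "T") {
  if (length(arm_lengths_cM) < 2 || any(arm_lengths_cM <= 0))
    stop("need >= 2 arms with positive lengths")
  markers_per_arm <- rep_len(as.integer(markers_per_arm),
                             length(arm_lengths_cM))
  if (any(markers_per_arm < 1)) stop("each arm needs >= 1 marker")
  structure(list(arm_lengths_cM = arm_lengths_cM,
                 markers_per_arm = markers_per_arm, hub = hub),
            class = "translocation_spec")
}

#' Simulate pseudo-linked markers around a translocation breakpoint
#'
#' @param spec A [translocation_spec()].
#' @param n Number of individuals.
#' @param seed Optional integer seed.
#' @return A [genotypes()] matrix; attribute `arm` gives each marker's arm
#'   index and attribute `dist_cM` its distance from the hub.  Markers are
#'   named `<hub><arm letter><index>`, e.g. `"TA1"`.
#' @examples
#' g <- sim_translocation(translocation_spec(c(30, 30, 30, 30), 5), 100, seed = 1)
#' @export
sim_translocation <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "translocation_spec"))
  if (n < 1) stop("n must be at least 1")
  with_seed(seed, {
    n_arm <- length(spec$arm_lengths_cM)
    hub <- sample(c(-1L, 1L), n, replace = TRUE)
    cols <- list(); arm_idx <- integer(0); dist_cM <- numeric(0)
    for (a in seq_len(n_arm)) {
      m <- spec$markers_per_arm[a]
      pos <- seq_len(m) * spec$arm_lengths_cM[a] / m    # cM from hub
      theta <- haldane_inverse(diff(c(0, pos)) / 100)
      prev <- hub
      for (k in seq_len(m)) {
        flip <- stats::runif(n) < theta[k]
        cur <- ifelse(flip, -prev, prev)
        cols[[length(cols) + 1L]] <- cur
        prev <- cur
      }
      arm_idx <- c(arm_idx, rep(a, m))
      dist_cM <- c(dist_cM, pos)
    }
    scores <- do.call(cbind, cols)
    markers <- sprintf("%s%s%d", spec$hub, LETTERS[arm_idx],
                       unlist(lapply(spec$markers_per_arm, seq_len)))
    g <- genotypes(scores, markers = markers,
                   ids = sprintf("ind%03d", seq_len(n)))
    attr(g, "arm") <- arm_idx
    attr(g, "dist_cM") <- dist_cM
    g
  })
}
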