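# Preprocessing and partitioning: heterozygote masking, missing-data
# filters, duplicate collapsing, linkage grouping, k-medoids selection.

#' Mask heterozygous scores and recode to -1/+1
#'
#' For RIL-type data scored with parental symbols plus a heterozygote
#' class, sets every heterozygous cell to missing and maps the parental
#' symbols to -1/+1.  Unknown symbols raise an error listing their
#' coordinates.
#'
#' @param raw Character matrix (individuals x markers).
#' @param coding Named character vector mapping roles to symbols:
#'   `c(a = "a", b = "b", het = "h", missing = "-")`.
#' @return A [genotypes()] matrix with population type `"RIL"`.  All-missing
#'   columns trigger a warning.
#' @export
mask_heterozygotes <- function(raw,
                               coding = c(a = "a", b = "b", het = "h",
                                          missing = "-")) {
  raw <- as.matrix(raw)
  known <- c(coding[["a"]], coding[["b"]], coding[["het"]],
             coding[["missing"]], NA)
  bad <- which(matrix(!(raw %in% known), nrow(raw)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    lab <- apply(utils::head(bad, 5), 1, function(rc)
      sprintf("(%s, %s) = '%s'",
              if (is.null(rownames(raw))) rc[1] else rownames(raw)[rc[1]],
              if (is.null(colnames(raw))) rc[2] else colnames(raw)[rc[2]],
              raw[rc[1], rc[2]]))
    stop("unknown genotype symbol(s) at: ", paste(lab, collapse = ", "))
  }
  out <- matrix(NA_integer_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  out[raw == coding[["a"]]] <- -1L
  out[raw == coding[["b"]]] <- 1L
  g <- genotypes(out, population = "RIL")
  allmiss <- colSums(!is.na(g)) == 0
  if (any(allmiss))
    warning("all-missing marker column(s) after masking: ",
            paste(colnames(g)[allmiss], collapse = ", "))
  g
}

#' Filter markers and individuals by missing data
#'
#' Removes markers whose missing fraction exceeds `max_marker_missing`,
#' then (against the reduced marker set) individuals whose missing
#' fraction exceeds `max_indiv_missing`.
#'
#' @param geno A [genotypes()] matrix.
#' @param max_marker_missing,max_indiv_missing Maximum tolerated missing
#'   fraction in `[0, 1]` (or absolute counts if `> 1`).
#' @return A list: `genotypes` (filtered), `removed` (`data.frame` with
#'   columns `name`, `what`, `n_missing`, `fraction`).
#' @export
filter_missing <- function(geno, max_marker_missing = 1,
                           max_indiv_missing = 1) {
  stopifnot(inherits(geno, "genotypes"))
  as_frac <- function(x, denom) if (x > 1) x / denom else x
  removed <- data.frame(name = character(0), what = character(0),
                        n_missing = integer(0), fraction = numeric(0),
                        stringsAsFactors = FALSE)
  mm <- colSums(is.na(geno))
  drop_m <- mm / nrow(geno) > as_frac(max_marker_missing, nrow(geno))
  if (any(drop_m))
    removed <- rbind(removed, data.frame(
      name = colnames(geno)[drop_m], what = "marker",
      n_missing = mm[drop_m], fraction = mm[drop_m] / nrow(geno)))
  g <- genotypes(unclass(geno)[, !drop_m, drop = FALSE],
                 population = attr(geno, "population"))
  im <- rowSums(is.na(g))
  drop_i <- im / ncol(g) > as_frac(max_indiv_missing, ncol(g))
  if (any(drop_i))
    removed <- rbind(removed, data.frame(
      name = rownames(g)[drop_i], what = "individual",
      n_missing = im[drop_i], fraction = im[drop_i] / ncol(g)))
  g <- genotypes(unclass(g)[!drop_i, , drop = FALSE],
                 population = attr(geno, "population"))
  rownames(removed) <- NULL
  list(genotypes = g, removed = removed)
}

#' Collapse duplicate markers
#'
#' Markers with identical score-plus-missing patterns, or patterns that
#' are exact global sign flips of each other (the two linkage phases are
#' equivalent), are collapsed to a single representative (the first by
#' column order).
#'
#' @param geno A [genotypes()] matrix.
#' @return A list: `genotypes` (unique markers), `groups` (named list
#'   mapping each representative to its member markers).
#' @export
dedup_markers <- function(geno) {
  stopifnot(inherits(geno, "genotypes"))
  keys <- apply(unclass(geno), 2, function(col) {
    s <- ifelse(is.na(col), "N", ifelse(col > 0, "+", "-"))
    first <- col[!is.na(col)][1]
    if (!is.na(first) && first > 0)       # canonical phase
      s <- chartr("+-", "-+", s)
    paste(s, collapse = "")
  })
  reps <- !duplicated(keys)
  groups <- split(colnames(geno), factor(keys, levels = unique(keys)))
  names(groups) <- colnames(geno)[reps]
  list(genotypes = genotypes(unclass(geno)[, reps, drop = FALSE],
                             population = attr(geno, "population")),
       groups = groups)
}

#' Form linkage groups by recombination-frequency threshold
#'
#' Two markers are linked iff their estimated recombination frequency is
#' strictly below `threshold`; linkage groups are the connected components
#' of the resulting graph.
#'
#' @param rf A [estimate_rf()] result (or plain RF matrix).
#' @param threshold Linkage threshold on the RF scale (e.g. 0.2).
#' @return An object of class `linkage_groups`: `groups` (list of marker
#'   name vectors, by decreasing size), `membership` (named integer
#'   vector), `threshold`.
#' @export
group_by_rf <- function(rf, threshold) {
  rho <- if (inherits(rf, "pairwise_rf")) rf$rho else rf
  if (anyNA(rho)) stop("RF matrix has missing entries among analyzed markers")
  A <- rho < threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  markers <- colnames(rho)
  first_name <- vapply(seq_len(comp$no), function(c)
    min(markers[comp$membership == c]), character(1))
  ord <- order(-comp$csize, first_name)
  groups <- lapply(ord, function(c) markers[comp$membership == c])
  membership <- stats::setNames(match(comp$membership, ord), markers)
  structure(list(groups = groups, membership = membership,
                 threshold = threshold),
            class = "linkage_groups")
}

#' @export
print.linkage_groups <- function(x, ...) {
  cat(sprintf("%d linkage group(s) at RF threshold %g: sizes %s\n",
              length(x$groups), x$threshold,
              paste(lengths(x$groups), collapse = ", ")))
  invisible(x)
}

#' Select representative markers by k-medoids (PAM)
#'
#' Partitions markers around medoids using the recombination frequency (or
#' any dissimilarity) matrix: greedy BUILD initialization followed by SWAP
#' steps until the total within-cluster dissimilarity no longer decreases.
#' The procedure is deterministic; `seed` is accepted for interface
#' symmetry with the stochastic operations.
#'
#' @param dist A symmetric dissimilarity matrix with zero diagonal (e.g.
#'   the `rho` matrix from [estimate_rf()]), or a `pairwise_rf` object.
#' @param k Number of medoids, `1 <= k <= p`.
#' @param seed Ignored (deterministic); kept for a uniform interface.
#' @return A list: `medoids` (marker names), `clustering` (named integer
#'   vector), `cost` (total dissimilarity to medoids).  Singleton clusters
#'   trigger a warning, as they typically flag low-quality or isolated
#'   markers.
#' @export
k_medoids <- function(dist, k, seed = NULL) {
  d <- if (inherits(dist, "pairwise_rf")) dist$rho else dist
  p <- ncol(d)
  if (k > p) stop("k must not exceed the number of markers")
  if (anyNA(d)) stop("dissimilarity matrix has missing entries")
  if (k == p) {
    return(list(medoids = colnames(d),
                clustering = stats::setNames(seq_len(p), colnames(d)),
                cost = 0))
  }
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
  medoids <- colnames(d)[fit$id.med]
  clustering <- stats::setNames(as.integer(fit$clustering), colnames(d))
  cost <- sum(d[cbind(seq_len(p), fit$id.med[fit$clustering])])
  sizes <- tabulate(clustering, nbins = k)
  if (any(sizes == 1))
    warning(sum(sizes == 1),
            " singleton cluster(s): low-quality or isolated marker(s)")
  list(medoids = medoids, clustering = clustering, cost = cost)
}
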