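# Frequentist diagonal ordering: permute the skeleton's adjacency matrix so
# that as many 1-entries as possible lie on the first super-diagonal, then
# extract the main linear marker string.

order_score <- function(A, perm) {
  if (length(perm) < 2) return(0L)
  sum(A[cbind(perm[-length(perm)], perm[-1])])
}

#' Diagonal ordering of a marker skeleton
#'
#' Finds a permutation of the markers maximizing the number of
#' permutation-adjacent pairs that are skeleton edges (equivalently, the
#' number of 1-entries on the first super-diagonal of the permuted
#' adjacency matrix).  Each connected component is ordered independently:
#' components with at most 10 nodes are solved exactly by dynamic
#' programming over vertex subsets; larger components are ordered by greedy
#' path extension from low-degree nodes followed by 2-opt segment-reversal
#' improvement.  Components are concatenated by decreasing size.  Ties are
#' broken by marker name, so the result is deterministic.
#'
#' The *main string* is the longest consecutive run of the permutation in
#' which every adjacent pair is an edge; markers outside it are *pulled
#' aside* -- on a chain-structured skeleton these are the markers (e.g.
#' with genotyping errors) that the graph could not place in line.
#'
#' @param skeleton A [pc_skeleton()] result, or a logical/0-1 adjacency
#'   matrix with dimnames.
#' @return An object of class `marker_order`: `permutation` (marker
#'   names), `score`, `main_string`, `pulled_aside`, `strings` (all maximal
#'   edge-consecutive runs, longest first).
#' @examples
#' A <- matrix(0, 5, 5, dimnames = list(paste0("M", 1:5), paste0("M", 1:5)))
#' A[cbind(1:4, 2:5)] <- 1; A <- A + t(A)
#' diagonalize(A[c(3, 1, 5, 2, 4), c(3, 1, 5, 2, 4)])$score   # 4
#' @export
diagonalize <- function(skeleton) {
  A <- as_adjacency(skeleton)
  p <- ncol(A)
  markers <- colnames(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize
  # components by decreasing size, ties by smallest member name
  first_name <- vapply(seq_along(sizes), function(c)
    min(markers[comp$membership == c]), character(1))
  comp_order <- order(-sizes, first_name)
  perm <- integer(0)
  for (c in comp_order) {
    idx <- which(comp$membership == c)
    idx <- idx[order(markers[idx])]
    sub <- A[idx, idx, drop = FALSE]
    local <- if (length(idx) <= 10) exact_order(sub) else heuristic_order(sub)
    perm <- c(perm, idx[local])
  }
  build_marker_order(A, perm)
}

as_adjacency <- function(skeleton) {
  if (inherits(skeleton, "pgm_skeleton")) {
    A <- skeleton$adj
  } else if (is.matrix(skeleton)) {
    A <- skeleton != 0
    if (is.null(colnames(A)))
      colnames(A) <- rownames(A) <- paste0("V", seq_len(ncol(A)))
  } else stop("expected a 'pgm_skeleton' or an adjacency matrix")
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  diag(A) <- FALSE
  storage.mode(A) <- "integer"
  A
}

build_marker_order <- function(A, perm) {
  markers <- colnames(A)
  score <- order_score(A, perm)
  # maximal runs where consecutive pairs are edges
  p <- length(perm)
  runs <- list(); start <- 1
  if (p > 1) {
    linked <- A[cbind(perm[-p], perm[-1])] > 0
    for (k in seq_along(linked)) {
      if (!linked[k]) { runs[[length(runs) + 1]] <- perm[start:k]; start <- k + 1 }
    }
  }
  runs[[length(runs) + 1]] <- perm[start:p]
  lens <- lengths(runs)
  runs <- runs[order(-lens, vapply(runs, function(r) min(markers[r]),
                                   character(1)))]
  main <- markers[runs[[1]]]
  structure(list(permutation = markers[perm], score = score,
                 main_string = main,
                 pulled_aside = setdiff(markers, main),
                 strings = lapply(runs, function(r) markers[r])),
            class = "marker_order")
}

#' @export
print.marker_order <- function(x, ...) {
  cat(sprintf("Marker order over %d markers: score %d, main string %d, pulled aside %d\n",
              length(x$permutation), x$score, length(x$main_string),
              length(x$pulled_aside)))
  invisible(x)
}

# exact optimum by DP over vertex subsets: f[mask, v] = best number of
# super-diagonal edges of an arrangement of `mask` ending at v
exact_order <- function(A) {
  m <- ncol(A)
  if (m == 1) return(1L)
  f <- matrix(-1L, 2^m, m)
  from <- matrix(0L, 2^m, m)
  for (v in 1:m) f[2^(v - 1), v] <- 0L
  bits <- 2^(0:(m - 1))
  for (mask in 1:(2^m - 1)) {
    members <- which(bitwAnd(mask, bits) > 0)
    rest <- setdiff(1:m, members)
    if (length(rest) == 0) next
    for (v in members) {
      fv <- f[mask, v]
      if (fv < 0) next
      for (u in rest) {
        nm <- mask + 2^(u - 1)
        val <- fv + A[v, u]
        if (val > f[nm, u]) { f[nm, u] <- val; from[nm, u] <- v }
      }
    }
  }
  full <- 2^m - 1
  v <- which.max(f[full, ])
  perm <- integer(m); mask <- full
  for (k in m:1) {
    perm[k] <- v
    prev <- from[mask, v]
    mask <- mask - 2^(v - 1)
    v <- prev
  }
  perm
}

heuristic_order <- function(A) {
  m <- ncol(A)
  unvisited <- rep(TRUE, m)
  paths <- list()
  deg <- rowSums(A)
  while (any(unvisited)) {
    cand <- which(unvisited)
    udeg <- vapply(cand, function(v) sum(A[v, ] * unvisited), numeric(1))
    start <- cand[order(udeg, cand)][1]          # prefer degree-1 ends
    path <- start; unvisited[start] <- FALSE
    for (dir in 1:2) {                           # extend head then tail
      repeat {
        end <- if (dir == 1) path[length(path)] else path[1]
        nxt <- which(A[end, ] > 0 & unvisited)
        if (length(nxt) == 0) break
        udeg <- vapply(nxt, function(v) sum(A[v, ] * unvisited), numeric(1))
        v <- nxt[order(udeg, nxt)][1]            # prefer chain continuations
        path <- if (dir == 1) c(path, v) else c(v, path)
        unvisited[v] <- FALSE
      }
    }
    paths[[length(paths) + 1]] <- path
  }
  paths <- paths[order(-lengths(paths), vapply(paths, `[`, integer(1), 1))]
  perm <- unlist(paths)
  two_opt(A, perm)
}

# 2-opt segment reversals until no single reversal improves the score
two_opt <- function(A, perm) {
  p <- length(perm)
  if (p < 3) return(perm)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        left <- if (i > 1) perm[i - 1] else 0L
        right <- if (j < p) perm[j + 1] else 0L
        old <- (if (left) A[left, perm[i]] else 0L) +
               (if (right) A[perm[j], right] else 0L)
        new <- (if (left) A[left, perm[j]] else 0L) +
               (if (right) A[perm[i], right] else 0L)
        if (new > old) {
          perm[i:j] <- perm[j:i]
          improved <- TRUE
        }
      }
    }
  }
  perm
}

#' Exhaustive diagonal ordering (testing oracle)
#'
#' Enumerates permutations to find a provably optimal super-diagonal score.
#' Intended as an independent oracle for [diagonalize()] on small graphs.
#'
#' @param skeleton A [pc_skeleton()] result or adjacency matrix with at
#'   most 10 nodes.
#' @return A `marker_order`, with a globally optimal `score`.
#' @export
brute_force_diagonalize <- function(skeleton) {
  A <- as_adjacency(skeleton)
  p <- ncol(A)
  if (p > 10) stop("exhaustive search refused for more than 10 nodes")
  if (p == 1) return(build_marker_order(A, 1L))
  best_score <- -1L; best <- NULL
  if (p <= 8) {
    perms <- all_perms(p)
    sc <- perm_scores(A, perms)
    k <- which.max(sc)
    best <- perms[k, ]; best_score <- sc[k]
  } else {
    tail_perms <- all_perms(p - 2)
    for (i in 1:p) for (j in setdiff(1:p, i)) {
      rest <- setdiff(1:p, c(i, j))
      perms <- cbind(i, j, matrix(rest[tail_perms], nrow(tail_perms)))
      sc <- perm_scores(A, perms)
      k <- which.max(sc)
      if (sc[k] > best_score) { best_score <- sc[k]; best <- perms[k, ] }
    }
  }
  build_marker_order(A, best)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- vector("list", n)
  for (i in 1:n) {
    rest <- setdiff(1:n, i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

perm_scores <- function(A, perms) {
  sc <- integer(nrow(perms))
  for (k in 1:(ncol(perms) - 1))
    sc <- sc + A[cbind(perms[, k], perms[, k + 1])]
  sc
}

#' Classify markers by ordering outcome
#'
#' Labels each marker as lying on the main linear string or pulled aside,
#' and, when the designed-error markers are known (simulation truth),
#' reports detection status: a marker is detected iff it is a
#' designed-error marker and was pulled aside.
#'
#' @param order A [diagonalize()] result.
#' @param truth Optional character vector of designed-error marker names.
#' @return A `data.frame` with columns `marker`, `status`
#'   (`"in_string"`/`"pulled_aside"`), and when `truth` is given also
#'   `designed_error` and `detected`.
#' @export
classify_markers <- function(order, truth = NULL) {
  stopifnot(inherits(order, "marker_order"))
  out <- data.frame(marker = order$permutation,
                    status = ifelse(order$permutation %in% order$main_string,
                                    "in_string", "pulled_aside"),
                    stringsAsFactors = FALSE)
  if (!is.null(truth)) {
    out$designed_error <- out$marker %in% truth
    out$detected <- out$designed_error & out$status == "pulled_aside"
  }
  out
}
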