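# Readers and writers for genotype CSV, map/matrix TSV, SIF/GraphML graph
# exports, flat key-value configs and run manifests.  All writers are
# deterministic given their inputs so reruns are byte-identical.

#' Read a genotype matrix from CSV
#'
#' Expected layout: header row of marker names, first column individual
#' ids, cells either numeric (`-1`, `1`, `NA`) or letter-coded (`a`, `b`,
#' optional `h` for heterozygote which is masked to missing, `NA`/`-` for
#' missing).
#'
#' @param path CSV file path.
#' @param coding `"numeric"` or `"ab"`; `"auto"` (default) detects from
#'   the cell values.
#' @param population Population type annotation, `"DH"` or `"RIL"`.
#' @return A [genotypes()] matrix.
#' @export
read_genotypes <- function(path, coding = c("auto", "numeric", "ab"),
                           population = "DH") {
  coding <- match.arg(coding)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("expected an id column plus marker columns")
  if (anyDuplicated(names(df)))
    stop("duplicate marker names in header: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  ids <- df[[1]]
  x <- as.matrix(df[, -1, drop = FALSE])
  vals <- unique(stats::na.omit(c(x)))
  if (coding == "auto")
    coding <- if (all(vals %in% c("-1", "1", ""))) "numeric" else "ab"
  if (coding == "numeric") {
    bad <- which(matrix(!(x %in% c("-1", "1", "", NA)), nrow(x)),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("bad symbol '%s' at (%s, %s)", x[bad[1, 1], bad[1, 2]],
                   ids[bad[1, 1]], colnames(x)[bad[1, 2]]))
    scores <- matrix(as.integer(ifelse(x == "", NA, x)), nrow(x),
                     dimnames = list(ids, colnames(x)))
    genotypes(scores, population = population)
  } else {
    x[x == "" | x == "NA"] <- NA
    rownames(x) <- ids
    mask_heterozygotes(x, coding = c(a = "a", b = "b", het = "h",
                                     missing = "-"))
  }
}

#' Write a genotype matrix to CSV
#'
#' @param geno A [genotypes()] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(id = rownames(geno), unclass(geno), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a genetic map from TSV (columns marker, chrom, pos_cM)
#' @param path TSV file path.
#' @return A [genetic_map()].
#' @export
read_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  genetic_map(df$marker, df$chrom, df$pos_cM)
}

#' Write a table (map, stress profile, classification, ...) as TSV
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a named matrix as TSV with marker-name headers
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(marker = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

order_attrs <- function(skeleton, order = NULL, truth = NULL) {
  status <- rep(NA_character_, length(skeleton$markers))
  names(status) <- skeleton$markers
  if (!is.null(order)) {
    cls <- classify_markers(order, truth = truth)
    status[cls$marker] <- cls$status
  }
  status
}

#' Export a skeleton as SIF (Cytoscape simple interaction format)
#'
#' One `A pp B` line per edge; isolated nodes get a bare `A` line so the
#' node set is complete.
#'
#' @param skeleton A [pc_skeleton()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(skeleton, path) {
  ed <- skeleton_edges(skeleton)
  lines <- if (nrow(ed)) paste(ed[, 1], "pp", ed[, 2]) else character(0)
  isolated <- setdiff(skeleton$markers,
                      unique(c(ed[, 1], ed[, 2])))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Export a skeleton as GraphML with node attributes
#'
#' Node attributes: `status` (`in_string` / `pulled_aside`, when an order
#' is supplied) and `designed_error` (when simulation truth is supplied).
#'
#' @param skeleton A [pc_skeleton()] result.
#' @param path Output path.
#' @param order Optional [diagonalize()] result.
#' @param truth Optional designed-error marker names.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(skeleton, path, order = NULL, truth = NULL) {
  g <- igraph::graph_from_adjacency_matrix(skeleton$adj, mode = "undirected")
  status <- order_attrs(skeleton, order, truth)
  if (!all(is.na(status)))
    g <- igraph::set_vertex_attr(g, "status", value = unname(status))
  if (!is.null(truth))
    g <- igraph::set_vertex_attr(g, "designed_error",
                                 value = skeleton$markers %in% truth)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values are
#' converted to numeric or logical where possible.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  out <- lapply(kv, function(x) {
    v <- x[2]
    if (toupper(v) %in% c("TRUE", "FALSE")) as.logical(v)
    else if (!is.na(suppressWarnings(as.numeric(v)))) as.numeric(v)
    else v
  })
  stats::setNames(out, vapply(kv, `[`, character(1), 1))
}

#' Write all pipeline artifacts plus a manifest
#'
#' @param pipeline A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a named character vector (file tag -> path),
#'   invisibly written to `manifest.txt`.
#' @export
write_pipeline <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(tag, path) paths[[tag]] <<- path
  put("genotypes", write_genotypes(pipeline$genotypes,
                                   file.path(out_dir, "genotypes.csv")))
  put("rf_matrix", write_matrix_tsv(round(pipeline$rf$rho, 6),
                                    file.path(out_dir, "rf.tsv")))
  for (gi in seq_along(pipeline$results)) {
    r <- pipeline$results[[gi]]
    if (is.null(r$skeleton)) next
    pre <- file.path(out_dir, sprintf("group%02d", gi))
    put(sprintf("group%02d_sif", gi), write_sif(r$skeleton,
                                                paste0(pre, ".sif")))
    put(sprintf("group%02d_graphml", gi),
        write_graphml(r$skeleton, paste0(pre, ".graphml"), order = r$order,
                      truth = pipeline$truth_markers))
    put(sprintf("group%02d_class", gi),
        write_tsv(r$classification, paste0(pre, "_markers.tsv")))
    if (!is.null(r$map))
      put(sprintf("group%02d_map", gi),
          write_tsv(r$map, paste0(pre, "_map.tsv")))
  }
  cfg <- pipeline$config
  cfg$out_dir <- NULL
  manifest <- c(
    vapply(cfg, function(v) paste(v, collapse = ","), character(1)),
    files = paste(basename(unlist(paths)), collapse = ","))
  writeLines(paste(names(manifest), "=", manifest),
             file.path(out_dir, "manifest.txt"))
  invisible(paths)
}
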