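#' Pairwise distance matrix for one frame
#'
#' Euclidean distances between all selected atoms of one trajectory frame,
#' in Angstrom.
#'
#' @param ensemble a `coordinate_ensemble`.
#' @param frame_index 1-based frame index.
#' @return an object of class `distance_matrix` with fields `values`
#'   (symmetric m x m matrix, zero diagonal) and `frame_index`.
#' @export
pairwise_distances <- function(ensemble, frame_index) {
  x <- frame_coords(ensemble, frame_index)
  v <- unname(as.matrix(stats::dist(x)))
  structure(list(values = v, frame_index = frame_index),
            class = "distance_matrix")
}

validate_distance_values <- function(v) {
  if (!is.matrix(v) || nrow(v) != ncol(v))
    stop("integrity error: distance matrix must be square")
  if (!all(is.finite(v)))
    stop("integrity error: non-finite distances")
  if (any(v < 0))
    stop("integrity error: negative distances")
  if (any(abs(diag(v)) > 1e-10))
    stop("integrity error: distance matrix diagonal must be zero")
  if (max(abs(v - t(v))) > 1e-8)
    stop("integrity error: distance matrix must be symmetric")
  invisible(TRUE)
}

#' Build a weighted contact graph from a distance matrix
#'
#' An undirected edge links residues `i < j` iff their distance `d` is
#' strictly below `cutoff`; its weight is `1 - d/cutoff`, so contacts at
#' zero distance weigh 1 and the weight decays linearly to 0 at the cutoff.
#' Pairs exactly at the cutoff are excluded, so zero-weight edges never
#' occur. Disconnected graphs and isolated nodes are allowed.
#'
#' @param dm a `distance_matrix` (or a plain symmetric matrix).
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @return an object of class `contact_graph` with fields `n_nodes`,
#'   `edges` (data.frame `i`, `j`, `weight` with `i < j`) and `cutoff`.
#' @export
build_contact_graph <- function(dm, cutoff = 10) {
  if (inherits(dm, "distance_matrix")) dm <- dm$values
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("argument error: cutoff must be a positive number")
  validate_distance_values(dm)
  m <- nrow(dm)
  sel <- which(upper.tri(dm) & dm < cutoff, arr.ind = TRUE)
  d <- dm[sel]
  o <- order(sel[, 1], sel[, 2])
  edges <- data.frame(i = as.integer(sel[o, 1]), j = as.integer(sel[o, 2]),
                      weight = 1 - d[o] / cutoff)
  structure(list(n_nodes = m, edges = edges, cutoff = cutoff),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d nodes, %d edges, cutoff %g A\n",
              x$n_nodes, nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Dense weighted adjacency matrix of a contact graph
#' @param graph a `contact_graph`.
#' @return symmetric `n_nodes x n_nodes` numeric matrix.
#' @export
adjacency_matrix <- function(graph) {
  a <- matrix(0, graph$n_nodes, graph$n_nodes)
  e <- graph$edges
  if (nrow(e)) {
    a[cbind(e$i, e$j)] <- e$weight
    a[cbind(e$j, e$i)] <- e$weight
  }
  a
}

#' Convert every frame of an ensemble into a contact graph
#'
#' @param ensemble a `coordinate_ensemble`.
#' @param cutoff contact cutoff in Angstrom.
#' @return an object of class `graph_series`: list of `contact_graph`s
#'   sharing one node set and cutoff.
#' @export
build_graph_series <- function(ensemble, cutoff = 10) {
  nf <- n_frames(ensemble)
  if (nf < 1L) stop("integrity error: empty ensemble")
  graphs <- lapply(seq_len(nf), function(f)
    build_contact_graph(pairwise_distances(ensemble, f), cutoff))
  structure(list(graphs = graphs, n_nodes = n_atoms(ensemble), cutoff = cutoff),
            class = "graph_series")
}

#' @export
print.graph_series <- function(x, ...) {
  cat(sprintf("<graph_series> %d frames on %d nodes, cutoff %g A\n",
              length(x$graphs), x$n_nodes, x$cutoff))
  invisible(x)
}

#' Edge-list text export / import of a graph series
#'
#' One block per frame: a `graph <index> <n_edges>` line then one
#' `i j weight` line per edge. Used for fixtures and interoperability.
#'
#' @param series a `graph_series`.
#' @param path file path.
#' @return `write_graph_series` returns `path` invisibly;
#'   `read_graph_series` a `graph_series`.
#' @export
write_graph_series <- function(series, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#mdembed-graphs v1",
               sprintf("n_nodes %d", series$n_nodes),
               sprintf("cutoff %.10g", series$cutoff)), con)
  for (f in seq_along(series$graphs)) {
    e <- series$graphs[[f]]$edges
    writeLines(sprintf("graph %d %d", f, nrow(e)), con)
    if (nrow(e))
      writeLines(sprintf("%d %d %.15g", e$i, e$j, e$weight), con)
  }
  invisible(path)
}

#' @rdname write_graph_series
#' @export
read_graph_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1] != "#mdembed-graphs v1")
    stop("parse error at line 1: missing '#mdembed-graphs v1' header")
  n_nodes <- as.integer(strsplit(lines[2], " ")[[1]][2])
  cutoff <- as.numeric(strsplit(lines[3], " ")[[1]][2])
  graphs <- list(); ln <- 4L
  while (ln <= length(lines)) {
    hdr <- strsplit(lines[ln], " ", fixed = TRUE)[[1]]
    if (hdr[1] != "graph" || length(hdr) != 3L)
      stop(sprintf("parse error at line %d: expected graph header", ln))
    ne <- as.integer(hdr[3])
    if (ln + ne > length(lines))
      stop(sprintf("parse error at line %d: truncated edge block", ln))
    if (ne > 0L) {
      vals <- strsplit(lines[(ln + 1L):(ln + ne)], " ", fixed = TRUE)
      edges <- data.frame(
        i = as.integer(vapply(vals, `[`, "", 1L)),
        j = as.integer(vapply(vals, `[`, "", 2L)),
        weight = as.numeric(vapply(vals, `[`, "", 3L)))
    } else {
      edges <- data.frame(i = integer(), j = integer(), weight = numeric())
    }
    graphs[[length(graphs) + 1L]] <-
      structure(list(n_nodes = n_nodes, edges = edges, cutoff = cutoff),
                class = "contact_graph")
    ln <- ln + ne + 1L
  }
  structure(list(graphs = graphs, n_nodes = n_nodes, cutoff = cutoff),
            class = "graph_series")
}
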