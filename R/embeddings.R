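#' Embedding configuration
#'
#' Collects every knob of the four supported node-embedding methods in one
#' provenance-friendly object. Random-walk parameters follow the node2vec
#' conventions (`p` return parameter, `q` in-out parameter); neural
#' parameters cover GCN, GAT and GraphSAGE encoders trained under an
#' unsupervised link-prediction objective.
#'
#' @param method one of `"node2vec"`, `"gcn"`, `"gat"`, `"graphsage"`.
#' @param dimension embedding dimension `d` (default 64).
#' @param seed integer seed controlling all stochastic steps.
#' @param num_walks walks started per node per frame (node2vec).
#' @param walk_length steps per walk (node2vec).
#' @param p,q node2vec return / in-out bias parameters, both > 0.
#' @param window skip-gram context window (node2vec).
#' @param negative negative samples per positive pair (node2vec).
#' @param epochs training epochs (skip-gram or link-prediction).
#' @param learning_rate optimizer step size.
#' @param n_layers encoder depth (GNNs).
#' @param hidden hidden width (GNNs).
#' @param heads attention heads (GAT).
#' @param sample_sizes neighborhood sample sizes per layer (GraphSAGE).
#' @param negative_ratio negative:positive edge ratio for link prediction.
#' @param training_frame_sample fraction of frames the shared encoder is
#'   fitted on (GNNs); one encoder keeps embeddings comparable across frames.
#' @param max_training_frames hard cap on the number of training frames.
#' @return an object of class `embedding_config`.
#' @export
embedding_config <- function(method = c("node2vec", "gcn", "gat", "graphsage"),
                             dimension = 64L, seed = 1L,
                             num_walks = 10L, walk_length = 80L,
                             p = 1, q = 1, window = 5L, negative = 5L,
                             epochs = NULL, learning_rate = NULL,
                             n_layers = 2L, hidden = 64L, heads = 2L,
                             sample_sizes = c(10L, 10L),
                             negative_ratio = 1L,
                             training_frame_sample = 0.1,
                             max_training_frames = 64L) {
  method <- match.arg(method)
  if (dimension < 1L) stop("argument error: dimension must be >= 1")
  if (p <= 0 || q <= 0) stop("argument error: p and q must be > 0")
  if (num_walks < 1L || walk_length < 1L || window < 1L || negative < 1L ||
      n_layers < 1L || hidden < 1L || heads < 1L || negative_ratio < 1L)
    stop("argument error: counts must be >= 1")
  if (is.null(epochs)) epochs <- if (method == "node2vec") 5L else 40L
  if (is.null(learning_rate))
    learning_rate <- if (method == "node2vec") 0.025 else 0.01
  structure(list(method = method, dimension = as.integer(dimension),
                 seed = as.integer(seed),
                 num_walks = as.integer(num_walks),
                 walk_length = as.integer(walk_length),
                 p = p, q = q, window = as.integer(window),
                 negative = as.integer(negative),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 n_layers = as.integer(n_layers), hidden = as.integer(hidden),
                 heads = as.integer(heads),
                 sample_sizes = as.integer(sample_sizes),
                 negative_ratio = as.integer(negative_ratio),
                 training_frame_sample = training_frame_sample,
                 max_training_frames = as.integer(max_training_frames)),
            class = "embedding_config")
}

new_embedding_series <- function(frames, config, frame_index = seq_along(frames)) {
  dims <- vapply(frames, dim, integer(2))
  if (ncol(dims) && (length(unique(dims[1, ])) != 1L ||
                     length(unique(dims[2, ])) != 1L))
    stop("integrity error: all frame embeddings must share one |V| x d shape")
  structure(list(frames = frames, config = config, frame_index = frame_index),
            class = "embedding_series")
}

#' @export
print.embedding_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<embedding_series> %d frames, %d nodes x %d dims, method %s\n",
              length(x$frames), d[1], d[2], x$config$method))
  invisible(x)
}

#' Embed every frame of a graph series
#'
#' Dispatches to [node2vec_embed()] or [gnn_embed()] according to
#' `config$method`.
#'
#' @param series a `graph_series`.
#' @param config an [embedding_config()].
#' @return an `embedding_series`: one `|V| x d` matrix per frame.
#' @export
embed_graph_series <- function(series, config) {
  if (config$method == "node2vec") node2vec_embed(series, config)
  else gnn_embed(series, config)
}

#' Persist / restore an embedding series
#'
#' The matrices are written as one delimited text file (one block per
#' frame) with a JSON sidecar (`<path>.json`) recording the full
#' [embedding_config()] for provenance.
#'
#' @param series an `embedding_series`.
#' @param path file path.
#' @return `write_embedding_series` returns `path` invisibly;
#'   `read_embedding_series` an `embedding_series`.
#' @export
write_embedding_series <- function(series, path) {
  d <- dim(series$frames[[1]])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#mdembed-embeddings v1",
               sprintf("n_frames %d", length(series$frames)),
               sprintf("n_nodes %d", d[1]),
               sprintf("dimension %d", d[2])), con)
  for (f in seq_along(series$frames)) {
    writeLines(sprintf("frame %d", f), con)
    m <- series$frames[[f]]
    writeLines(apply(m, 1L, function(r) paste(sprintf("%.15g", r), collapse = " ")),
               con)
  }
  jsonlite::write_json(unclass(series$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding_series
#' @export
read_embedding_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "#mdembed-embeddings v1")
    stop("parse error at line 1: missing embeddings header")
  nf <- as.integer(strsplit(lines[2], " ")[[1]][2])
  nv <- as.integer(strsplit(lines[3], " ")[[1]][2])
  nd <- as.integer(strsplit(lines[4], " ")[[1]][2])
  frames <- vector("list", nf); ln <- 5L
  for (f in seq_len(nf)) {
    if (lines[ln] != sprintf("frame %d", f))
      stop(sprintf("parse error at line %d: expected frame header", ln))
    vals <- as.numeric(unlist(strsplit(lines[(ln + 1L):(ln + nv)], " ",
                                       fixed = TRUE)))
    frames[[f]] <- matrix(vals, nrow = nv, ncol = nd, byrow = TRUE)
    ln <- ln + nv + 1L
  }
  cfg <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    cl <- jsonlite::read_json(side, simplifyVector = TRUE)
    cfg <- structure(cl, class = "embedding_config")
  }
  new_embedding_series(frames, cfg)
}

## shared helpers --------------------------------------------------------

neighbor_lists <- function(graph) {
  n <- graph$n_nodes
  nbrs <- vector("list", n); wts <- vector("list", n)
  e <- graph$edges
  if (nrow(e)) {
    all_i <- c(e$i, e$j); all_j <- c(e$j, e$i); all_w <- c(e$weight, e$weight)
    o <- order(all_i, all_j)
    sp <- split(seq_along(all_i)[o], all_i[o])
    for (k in names(sp)) {
      v <- as.integer(k)
      nbrs[[v]] <- all_j[sp[[k]]]
      wts[[v]] <- all_w[sp[[k]]]
    }
  }
  for (v in seq_len(n)) {
    if (is.null(nbrs[[v]])) { nbrs[[v]] <- integer(); wts[[v]] <- numeric() }
  }
  list(nbrs = nbrs, wts = wts)
}

# Find an already-embedded graph with identical structure (content
# memoization: identical graphs must yield identical embeddings).
match_identical_graph <- function(graph, seen) {
  for (k in seq_along(seen)) {
    if (identical(seen[[k]]$edges, graph$edges) &&
        seen[[k]]$n_nodes == graph$n_nodes) return(k)
  }
  0L
}
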