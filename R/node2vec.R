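#' Second-order node2vec transition distribution
#'
#' Given the walk's previous and current node, the probability of stepping
#' to neighbor `x` of the current node is proportional to
#' `weight(current, x) * bias`, where the bias is `1/p` if `x` is the
#' previous node, `1` if `x` is adjacent to the previous node, and `1/q`
#' otherwise. With no previous node (first step of a walk) probabilities
#' are simply proportional to edge weights.
#'
#' @param graph a `contact_graph`.
#' @param previous_node previous node index, or `NULL` for the first step.
#' @param current_node current node index.
#' @param p return parameter (> 0).
#' @param q in-out parameter (> 0).
#' @return named numeric vector of probabilities over the neighbors of
#'   `current_node`, summing to 1.
#' @export
node2vec_transition_probs <- function(graph, previous_node, current_node,
                                      p = 1, q = 1) {
  nl <- neighbor_lists(graph)
  nbrs <- nl$nbrs[[current_node]]
  if (length(nbrs) == 0L) {
    cond <- structure(
      class = c("mdembed_walk_termination", "error", "condition"),
      list(message = sprintf(
        "walk termination: node %d has no neighbors", current_node),
        call = sys.call()))
    stop(cond)
  }
  w <- nl$wts[[current_node]]
  if (is.null(previous_node)) {
    pr <- w / sum(w)
  } else {
    prev_nbrs <- nl$nbrs[[previous_node]]
    bias <- ifelse(nbrs == previous_node, 1 / p,
                   ifelse(nbrs %in% prev_nbrs, 1, 1 / q))
    u <- w * bias
    pr <- u / sum(u)
  }
  names(pr) <- nbrs
  pr
}

# Sample the node2vec walk corpus for one graph. Walks that hit an
# isolated node (or start on one) are truncated, never an error.
sample_walks <- function(graph, num_walks, walk_length, p, q) {
  nl <- neighbor_lists(graph)
  n <- graph$n_nodes
  adj <- adjacency_matrix(graph) > 0
  walks <- vector("list", n * num_walks)
  k <- 0L
  for (rep in seq_len(num_walks)) {
    for (start in seq_len(n)) {
      walk <- integer(walk_length)
      walk[1] <- start
      len <- 1L
      prev <- 0L
      while (len < walk_length) {
        cur <- walk[len]
        nbrs <- nl$nbrs[[cur]]
        if (length(nbrs) == 0L) break
        w <- nl$wts[[cur]]
        if (prev == 0L) {
          u <- w
        } else {
          bias <- ifelse(nbrs == prev, 1 / p,
                         ifelse(adj[prev, nbrs], 1, 1 / q))
          u <- w * bias
        }
        nxt <- nbrs[sample.int(length(nbrs), 1L, prob = u)]
        len <- len + 1L
        walk[len] <- nxt
        prev <- cur
      }
      k <- k + 1L
      walks[[k]] <- walk[seq_len(len)]
    }
  }
  walks[seq_len(k)]
}

# Skip-gram with negative sampling on a walk corpus over an integer
# vocabulary 1..n_nodes. Mini-batch SGD with linearly decaying learning
# rate; fully deterministic given the RNG state on entry.
skipgram_fit <- function(walks, n_nodes, d, window, negative, epochs, lr0,
                         w_in = NULL, w_out = NULL) {
  centers <- integer(0); contexts <- integer(0)
  for (w in walks) {
    L <- length(w)
    if (L < 2L) next
    for (off in seq_len(min(window, L - 1L))) {
      centers <- c(centers, w[seq_len(L - off)], w[(off + 1L):L])
      contexts <- c(contexts, w[(off + 1L):L], w[seq_len(L - off)])
    }
  }
  if (is.null(w_in))
    w_in <- matrix(stats::runif(n_nodes * d, -0.5, 0.5) / d, n_nodes, d)
  if (is.null(w_out))
    w_out <- matrix(0, n_nodes, d)
  np <- length(centers)
  if (np == 0L) return(list(w_in = w_in, w_out = w_out))
  freq <- tabulate(unlist(walks), nbins = n_nodes)
  neg_p <- freq^0.75
  if (sum(neg_p) == 0) neg_p <- rep(1, n_nodes)
  neg_p <- neg_p / sum(neg_p)
  batch <- 512L
  total <- epochs * np
  done <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(np)
    for (b0 in seq(1L, np, by = batch)) {
      sel <- ord[b0:min(b0 + batch - 1L, np)]
      bs <- length(sel)
      cc <- centers[sel]; oo <- contexts[sel]
      lr <- lr0 * max(1e-4, 1 - done / total)
      vi <- w_in[cc, , drop = FALSE]
      grad_in <- matrix(0, bs, d)
      # positive pairs
      s <- 1 / (1 + exp(-rowSums(vi * w_out[oo, , drop = FALSE])))
      g <- s - 1
      grad_in <- grad_in + g * w_out[oo, , drop = FALSE]
      go_rows <- g * vi
      acc_out <- rowsum(go_rows, oo)
      out_idx <- as.integer(rownames(acc_out))
      w_out[out_idx, ] <- w_out[out_idx, ] - lr * acc_out
      # negative samples
      for (k in seq_len(negative)) {
        nn <- sample.int(n_nodes, bs, replace = TRUE, prob = neg_p)
        s <- 1 / (1 + exp(-rowSums(vi * w_out[nn, , drop = FALSE])))
        grad_in <- grad_in + s * w_out[nn, , drop = FALSE]
        acc_out <- rowsum(s * vi, nn)
        out_idx <- as.integer(rownames(acc_out))
        w_out[out_idx, ] <- w_out[out_idx, ] - lr * acc_out
      }
      acc_in <- rowsum(grad_in, cc)
      in_idx <- as.integer(rownames(acc_in))
      w_in[in_idx, ] <- w_in[in_idx, ] - lr * acc_in
      done <- done + bs
    }
  }
  list(w_in = w_in, w_out = w_out)
}

#' node2vec embedding of a graph series
#'
#' For each frame, biased second-order random walks are sampled under the
#' `p`/`q` rule and a skip-gram model with negative sampling is fitted on
#' the walk corpus; row `i` of the result is the learned vector of node
#' `i`. Frame `t+1`'s vectors warm-start from frame `t`'s fit, keeping
#' consecutive frames in a common orientation, and frames whose graph is
#' bit-identical to an already-embedded one reuse that embedding.
#' Deterministic under `config$seed`.
#'
#' @param series a `graph_series`.
#' @param config an [embedding_config()] with `method = "node2vec"`.
#' @return an `embedding_series`.
#' @export
node2vec_embed <- function(series, config) {
  if (config$method != "node2vec")
    stop("argument error: config$method must be 'node2vec'")
  n <- series$n_nodes
  if (n < 1L) stop("integrity error: empty graph")
  d <- config$dimension
  if (d >= n)
    warning(sprintf("embedding dimension d = %d >= |V| = %d", d, n))
  set.seed(config$seed)
  frames <- vector("list", length(series$graphs))
  memo_key <- character(0); memo_idx <- integer(0)
  w_in <- NULL; w_out <- NULL
  for (f in seq_along(series$graphs)) {
    g <- series$graphs[[f]]
    key <- sprintf("%d_%.14g_%.14g", nrow(g$edges), sum(g$edges$weight),
                   sum(g$edges$i * g$edges$j))
    hit <- 0L
    for (k in which(memo_key == key)) {
      if (identical(series$graphs[[memo_idx[k]]]$edges, g$edges)) { hit <- memo_idx[k]; break }
    }
    if (hit > 0L) {
      frames[[f]] <- frames[[hit]]
      next
    }
    walks <- sample_walks(g, config$num_walks, config$walk_length,
                          config$p, config$q)
    fit <- skipgram_fit(walks, n, d, config$window, config$negative,
                        config$epochs, config$learning_rate, w_in, w_out)
    w_in <- fit$w_in; w_out <- fit$w_out
    frames[[f]] <- w_in
    memo_key <- c(memo_key, key); memo_idx <- c(memo_idx, f)
  }
  new_embedding_series(frames, config)
}
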