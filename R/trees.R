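# Minimal CART-style trees (binary axis-aligned splits, histogram-limited
# candidate thresholds). Regression trees minimize SSE and also serve as
# the base learner of the gradient-boosting classifiers; classification
# trees minimize Gini impurity and back the bagged random forest. No
# pruning: ensembles control variance by bagging/shrinkage.

tree_best_split <- function(x, y, counts, min_bucket, n_bins) {
  n <- nrow(x)
  best <- list(cost = Inf)
  for (f in seq_len(ncol(x))) {
    v <- x[, f]
    ord <- order(v)
    vs <- v[ord]
    if (vs[1] == vs[n]) next
    pos <- which(vs[-n] < vs[-1])
    pos <- pos[pos >= min_bucket & (n - pos) >= min_bucket]
    if (length(pos) == 0L) next
    if (length(pos) > n_bins)
      pos <- pos[unique(round(seq(1L, length(pos), length.out = n_bins)))]
    if (is.null(counts)) {            # regression: SSE decrease
      ys <- y[ord]
      c1 <- cumsum(ys); c2 <- cumsum(ys^2)
      k <- pos
      left <- c2[k] - c1[k]^2 / k
      right <- (c2[n] - c2[k]) - (c1[n] - c1[k])^2 / (n - k)
      cost <- left + right
    } else {                          # classification: weighted Gini
      cc <- apply(counts[ord, , drop = FALSE], 2L, cumsum)
      if (is.null(dim(cc))) cc <- matrix(cc, nrow = 1L)
      k <- pos
      lk <- cc[k, , drop = FALSE]
      rk <- matrix(cc[n, ], length(k), ncol(cc), byrow = TRUE) - lk
      gl <- k - rowSums(lk^2) / k
      gr <- (n - k) - rowSums(rk^2) / (n - k)
      cost <- gl + gr
    }
    b <- which.min(cost)
    if (cost[b] < best$cost) {
      kb <- pos[b]
      best <- list(cost = cost[b], feat = f,
                   thr = (vs[kb] + vs[kb + 1L]) / 2)
    }
  }
  if (is.finite(best$cost)) best else NULL
}

tree_grow <- function(x, y, counts, depth, max_depth, min_split, min_bucket,
                      mtry, n_bins) {
  n <- nrow(x)
  make_leaf <- function() {
    if (is.null(counts)) list(leaf = TRUE, value = mean(y))
    else list(leaf = TRUE, value = colSums(counts) / n)
  }
  pure <- if (is.null(counts)) stats::var(y) < 1e-24
          else max(colSums(counts)) == n
  if (depth >= max_depth || n < min_split || isTRUE(pure)) return(make_leaf())
  feats <- if (mtry < ncol(x)) sort(sample.int(ncol(x), mtry)) else seq_len(ncol(x))
  sp <- tree_best_split(x[, feats, drop = FALSE], y, counts, min_bucket, n_bins)
  if (is.null(sp)) return(make_leaf())
  f <- feats[sp$feat]
  go_left <- x[, f] <= sp$thr
  sub <- function(m, keep) if (is.null(m)) NULL else m[keep, , drop = FALSE]
  list(leaf = FALSE, feat = f, thr = sp$thr,
       left = tree_grow(x[go_left, , drop = FALSE], y[go_left],
                        sub(counts, go_left), depth + 1L,
                        max_depth, min_split, min_bucket, mtry, n_bins),
       right = tree_grow(x[!go_left, , drop = FALSE], y[!go_left],
                         sub(counts, !go_left), depth + 1L,
                         max_depth, min_split, min_bucket, mtry, n_bins))
}

# y: numeric response (regression) or integer class index with n_classes set
tree_fit <- function(x, y, n_classes = NULL, max_depth = 6L, min_split = 10L,
                     min_bucket = 1L, mtry = ncol(x), n_bins = 32L) {
  counts <- NULL
  if (!is.null(n_classes)) {
    counts <- matrix(0, nrow(x), n_classes)
    counts[cbind(seq_len(nrow(x)), y)] <- 1
  }
  tree_grow(x, y, counts, 0L, max_depth, min_split, min_bucket, mtry, n_bins)
}

# returns numeric vector (regression) or matrix of class probabilities
tree_predict <- function(tree, x) {
  n <- nrow(x)
  out <- NULL
  assign_node <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) {
      if (is.null(dim(out))) out[idx] <<- node$value
      else out[idx, ] <<- matrix(node$value, length(idx), ncol(out), byrow = TRUE)
      return()
    }
    go_left <- x[idx, node$feat] <= node$thr
    assign_node(node$left, idx[go_left])
    assign_node(node$right, idx[!go_left])
  }
  probe <- tree
  while (!probe$leaf) probe <- probe$left
  out <- if (length(probe$value) > 1L) matrix(0, n, length(probe$value))
         else numeric(n)
  assign_node(tree, seq_len(n))
  out
}
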