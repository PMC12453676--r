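# Neural node-embedding encoders (GCN, GAT, GraphSAGE), trained with a
# shared parameter set on a sampled subset of frames under an unsupervised
# link-prediction objective: positives are observed edges, negatives are
# uniform non-edges, loss is binary cross-entropy on the sigmoid of
# embedding inner products. One shared encoder makes embeddings comparable
# across frames; inference is a deterministic full-neighborhood pass.

relu <- function(x) (x > 0) * x
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# rowsum() that always returns n rows (missing groups -> zero rows)
rowsum_full <- function(x, idx, n) {
  out <- matrix(0, n, ncol(x))
  rs <- rowsum(x, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

glorot <- function(fin, fout) {
  s <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -s, s), fin, fout)
}

# Frame-level tensors every architecture needs. Node features are the
# one-hot node identity plus the scaled weighted degree: identity is
# frame-constant so all frame-to-frame signal flows through the edges,
# and degree injects local geometry.
gnn_frame_data <- function(graph) {
  n <- graph$n_nodes
  a <- adjacency_matrix(graph)
  wdeg <- rowSums(a)
  x <- cbind(diag(n), wdeg / max(1, max(wdeg)))
  # GCN propagation: sym-normalized weighted adjacency with self loops
  at <- a + diag(n)
  dh <- 1 / sqrt(rowSums(at))
  p_gcn <- at * tcrossprod(dh)
  # full-neighborhood weighted mean (GraphSAGE inference aggregator)
  rs <- rowSums(a)
  m_full <- a / ifelse(rs > 0, rs, 1)
  m_full[rs == 0, ] <- 0
  # directed edge list with self loops (GAT attention support)
  e <- graph$edges
  src <- c(e$i, e$j, seq_len(n)); dst <- c(e$j, e$i, seq_len(n))
  w <- c(e$weight, e$weight, rep(1, n))
  list(n = n, a = a, x = x, p_gcn = p_gcn, m_full = m_full,
       att = list(src = src, dst = dst, logw = log(w)),
       pos = cbind(e$i, e$j))
}

## ---- GCN ---------------------------------------------------------------

gcn_init <- function(f_in, hidden, d, n_layers) {
  sizes <- c(f_in, rep(hidden, n_layers - 1L), d)
  params <- list()
  for (l in seq_len(n_layers))
    params[[paste0("W", l)]] <- glorot(sizes[l], sizes[l + 1L])
  params
}

gcn_forward <- function(params, fd) {
  L <- length(params)
  h <- fd$x
  cache <- list(ph = vector("list", L), pre = vector("list", L))
  for (l in seq_len(L)) {
    ph <- fd$p_gcn %*% h
    cache$ph[[l]] <- ph
    pre <- ph %*% params[[paste0("W", l)]]
    cache$pre[[l]] <- pre
    h <- if (l < L) relu(pre) else pre
  }
  list(z = h, cache = cache)
}

gcn_backward <- function(params, fd, cache, dz) {
  L <- length(params)
  grads <- list()
  dpre <- dz
  for (l in rev(seq_len(L))) {
    grads[[paste0("W", l)]] <- crossprod(cache$ph[[l]], dpre)
    if (l > 1L) {
      dh <- fd$p_gcn %*% (dpre %*% t(params[[paste0("W", l)]]))
      dpre <- dh * (cache$pre[[l - 1L]] > 0)
    }
  }
  grads
}

## ---- GraphSAGE ---------------------------------------------------------

sage_init <- function(f_in, hidden, d, n_layers) {
  sizes <- c(f_in, rep(hidden, n_layers - 1L), d)
  params <- list()
  for (l in seq_len(n_layers)) {
    params[[paste0("Ws", l)]] <- glorot(sizes[l], sizes[l + 1L])
    params[[paste0("Wn", l)]] <- glorot(sizes[l], sizes[l + 1L])
  }
  params
}

# Sampled-neighborhood weighted-mean aggregator used during training;
# inference passes m = fd$m_full (deterministic).
sage_sample_aggregator <- function(graph_nl, n, size) {
  m <- matrix(0, n, n)
  for (v in seq_len(n)) {
    nb <- graph_nl$nbrs[[v]]
    if (length(nb) == 0L) next
    if (length(nb) > size) {
      keep <- sample.int(length(nb), size)
      nb <- nb[keep]; w <- graph_nl$wts[[v]][keep]
    } else w <- graph_nl$wts[[v]]
    m[v, nb] <- w / sum(w)
  }
  m
}

sage_forward <- function(params, fd, aggregators) {
  L <- length(params) / 2L
  h <- fd$x
  cache <- list(h = vector("list", L), mh = vector("list", L),
                pre = vector("list", L), m = aggregators)
  for (l in seq_len(L)) {
    m <- aggregators[[l]]
    mh <- m %*% h
    cache$h[[l]] <- h; cache$mh[[l]] <- mh
    pre <- h %*% params[[paste0("Ws", l)]] + mh %*% params[[paste0("Wn", l)]]
    cache$pre[[l]] <- pre
    h <- if (l < L) relu(pre) else pre
  }
  list(z = h, cache = cache)
}

sage_backward <- function(params, fd, cache, dz) {
  L <- length(params) / 2L
  grads <- list()
  dpre <- dz
  for (l in rev(seq_len(L))) {
    grads[[paste0("Ws", l)]] <- crossprod(cache$h[[l]], dpre)
    grads[[paste0("Wn", l)]] <- crossprod(cache$mh[[l]], dpre)
    if (l > 1L) {
      dh <- dpre %*% t(params[[paste0("Ws", l)]]) +
        crossprod(cache$m[[l]], dpre %*% t(params[[paste0("Wn", l)]]))
      dpre <- dh * (cache$pre[[l - 1L]] > 0)
    }
  }
  grads
}

## ---- GAT ---------------------------------------------------------------

gat_init <- function(f_in, hidden, d, n_layers, heads) {
  hh <- max(1L, ceiling(hidden / heads))
  params <- list()
  sizes_in <- f_in
  for (l in seq_len(n_layers - 1L)) {
    for (k in seq_len(heads)) {
      params[[sprintf("W_%d_%d", l, k)]] <- glorot(sizes_in, hh)
      params[[sprintf("as_%d_%d", l, k)]] <- stats::runif(hh, -0.1, 0.1)
      params[[sprintf("ad_%d_%d", l, k)]] <- stats::runif(hh, -0.1, 0.1)
    }
    sizes_in <- hh * heads
  }
  params[["W_out"]] <- glorot(sizes_in, d)
  params[["as_out"]] <- stats::runif(d, -0.1, 0.1)
  params[["ad_out"]] <- stats::runif(d, -0.1, 0.1)
  params
}

gat_head_forward <- function(h, w, a_src, a_dst, att, n) {
  s <- h %*% w
  as_n <- drop(s %*% a_src); ad_n <- drop(s %*% a_dst)
  f_e <- ad_n[att$dst] + as_n[att$src]
  g_e <- ifelse(f_e > 0, f_e, 0.2 * f_e)
  lg <- g_e + att$logw
  gm <- rep(-Inf, n)
  for (grp in split(seq_along(lg), att$dst)) {
    gm[att$dst[grp[1]]] <- max(lg[grp])
  }
  u <- exp(lg - gm[att$dst])
  denom <- drop(rowsum_full(cbind(u), att$dst, n))
  alpha <- u / denom[att$dst]
  out <- rowsum_full(alpha * s[att$src, , drop = FALSE], att$dst, n)
  list(out = out, s = s, f_e = f_e, alpha = alpha)
}

gat_head_backward <- function(h, w, a_src, a_dst, att, n, hc, dout) {
  s <- hc$s; alpha <- hc$alpha
  dalpha <- rowSums(dout[att$dst, , drop = FALSE] * s[att$src, , drop = FALSE])
  ds <- rowsum_full(alpha * dout[att$dst, , drop = FALSE], att$src, n)
  t_i <- drop(rowsum_full(cbind(alpha * dalpha), att$dst, n))
  dg <- alpha * (dalpha - t_i[att$dst])
  df <- dg * ifelse(hc$f_e > 0, 1, 0.2)
  dad_n <- drop(rowsum_full(cbind(df), att$dst, n))
  das_n <- drop(rowsum_full(cbind(df), att$src, n))
  ds <- ds + outer(dad_n, a_dst) + outer(das_n, a_src)
  list(dW = crossprod(h, ds),
       da_src = drop(crossprod(s, das_n)),
       da_dst = drop(crossprod(s, dad_n)),
       dh = ds %*% t(w))
}

gat_forward <- function(params, fd, n_layers, heads) {
  n <- fd$n
  h <- fd$x
  cache <- list(layer = vector("list", n_layers))
  for (l in seq_len(n_layers - 1L)) {
    hcs <- vector("list", heads)
    outs <- vector("list", heads)
    for (k in seq_len(heads)) {
      hc <- gat_head_forward(h, params[[sprintf("W_%d_%d", l, k)]],
                             params[[sprintf("as_%d_%d", l, k)]],
                             params[[sprintf("ad_%d_%d", l, k)]],
                             fd$att, n)
      hcs[[k]] <- hc
      outs[[k]] <- relu(hc$out)
    }
    cache$layer[[l]] <- list(h_in = h, heads = hcs)
    h <- do.call(cbind, outs)
  }
  hc <- gat_head_forward(h, params$W_out, params$as_out, params$ad_out,
                         fd$att, n)
  cache$layer[[n_layers]] <- list(h_in = h, heads = list(hc))
  list(z = hc$out, cache = cache)
}

gat_backward <- function(params, fd, cache, dz, n_layers, heads) {
  n <- fd$n
  grads <- list()
  lc <- cache$layer[[n_layers]]
  bk <- gat_head_backward(lc$h_in, params$W_out, params$as_out,
                          params$ad_out, fd$att, n, lc$heads[[1]], dz)
  grads$W_out <- bk$dW; grads$as_out <- bk$da_src; grads$ad_out <- bk$da_dst
  dh <- bk$dh
  for (l in rev(seq_len(n_layers - 1L))) {
    lc <- cache$layer[[l]]
    hh <- ncol(lc$heads[[1]]$out)
    dh_in <- 0
    for (k in seq_len(heads)) {
      cols <- ((k - 1L) * hh + 1L):(k * hh)
      dout_k <- dh[, cols, drop = FALSE] * (lc$heads[[k]]$out > 0)
      bk <- gat_head_backward(lc$h_in, params[[sprintf("W_%d_%d", l, k)]],
                              params[[sprintf("as_%d_%d", l, k)]],
                              params[[sprintf("ad_%d_%d", l, k)]],
                              fd$att, n, lc$heads[[k]], dout_k)
      grads[[sprintf("W_%d_%d", l, k)]] <- bk$dW
      grads[[sprintf("as_%d_%d", l, k)]] <- bk$da_src
      grads[[sprintf("ad_%d_%d", l, k)]] <- bk$da_dst
      dh_in <- dh_in + bk$dh
    }
    dh <- dh_in
  }
  grads
}

## ---- shared training ---------------------------------------------------

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / (1 - b1^state$t)
    vh <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

sample_negative_edges <- function(fd, n_neg) {
  n <- fd$n
  adj <- fd$a > 0
  out_i <- integer(0); out_j <- integer(0)
  tries <- 0L
  while (length(out_i) < n_neg && tries < 20L) {
    ii <- sample.int(n, n_neg, replace = TRUE)
    jj <- sample.int(n, n_neg, replace = TRUE)
    ok <- ii != jj & !adj[cbind(ii, jj)]
    out_i <- c(out_i, ii[ok]); out_j <- c(out_j, jj[ok])
    tries <- tries + 1L
  }
  k <- min(n_neg, length(out_i))
  cbind(out_i[seq_len(k)], out_j[seq_len(k)])
}

link_prediction_grad <- function(z, pos, neg) {
  pairs <- rbind(pos, neg)
  y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  s <- rowSums(z[pairs[, 1], , drop = FALSE] * z[pairs[, 2], , drop = FALSE])
  loss <- mean(softplus(s) - y * s)
  g <- (1 / (1 + exp(-s)) - y) / length(s)
  dz <- rowsum_full(rbind(g * z[pairs[, 2], , drop = FALSE],
                          g * z[pairs[, 1], , drop = FALSE]),
                    c(pairs[, 1], pairs[, 2]), nrow(z))
  list(loss = loss, dz = dz)
}

#' Neural node embeddings for a graph series
#'
#' Trains one GCN, GAT, or GraphSAGE encoder (shared parameters) on a
#' uniformly sampled subset of frames under an unsupervised
#' link-prediction objective, then applies it to every frame with a
#' deterministic full-neighborhood forward pass. Identical graphs
#' therefore receive identical embeddings, and reruns under one seed are
#' bit-identical.
#'
#' @param series a `graph_series`.
#' @param config an [embedding_config()] with `method` in
#'   `"gcn"`, `"gat"`, `"graphsage"`.
#' @return an `embedding_series`.
#' @export
gnn_embed <- function(series, config) {
  if (!config$method %in% c("gcn", "gat", "graphsage"))
    stop("argument error: config$method must be gcn, gat or graphsage")
  nf <- length(series$graphs)
  if (nf < 1L || series$n_nodes < 1L) stop("integrity error: empty graph series")
  n <- series$n_nodes
  d <- config$dimension
  set.seed(config$seed)
  nt <- min(max(1L, ceiling(config$training_frame_sample * nf)),
            config$max_training_frames, nf)
  train_idx <- sort(sample.int(nf, nt))
  fds <- lapply(train_idx, function(f) gnn_frame_data(series$graphs[[f]]))
  nls <- lapply(train_idx, function(f) neighbor_lists(series$graphs[[f]]))
  f_in <- n + 1L
  L <- config$n_layers
  params <- switch(config$method,
    gcn = gcn_init(f_in, config$hidden, d, L),
    graphsage = sage_init(f_in, config$hidden, d, L),
    gat = gat_init(f_in, config$hidden, d, L, config$heads))
  st <- adam_init(params)
  sizes <- rep_len(config$sample_sizes, L)
  for (epoch in seq_len(config$epochs)) {
    for (k in sample.int(length(fds))) {
      fd <- fds[[k]]
      if (nrow(fd$pos) == 0L) next
      fw <- switch(config$method,
        gcn = gcn_forward(params, fd),
        graphsage = sage_forward(params, fd, lapply(seq_len(L), function(l)
          sage_sample_aggregator(nls[[k]], fd$n, sizes[l]))),
        gat = gat_forward(params, fd, L, config$heads))
      neg <- sample_negative_edges(fd, nrow(fd$pos) * config$negative_ratio)
      if (nrow(neg) == 0L) next
      lp <- link_prediction_grad(fw$z, fd$pos, neg)
      if (!is.finite(lp$loss))
        stop(sprintf("training-divergence error at epoch %d", epoch))
      grads <- switch(config$method,
        gcn = gcn_backward(params, fd, fw$cache, lp$dz),
        graphsage = sage_backward(params, fd, fw$cache, lp$dz),
        gat = gat_backward(params, fd, fw$cache, lp$dz, L, config$heads))
      upd <- adam_step(params, grads, st, config$learning_rate)
      params <- upd$params; st <- upd$state
    }
  }
  # deterministic inference over every frame
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    fd <- gnn_frame_data(series$graphs[[f]])
    fw <- switch(config$method,
      gcn = gcn_forward(params, fd),
      graphsage = sage_forward(params, fd,
                               rep(list(fd$m_full), L)),
      gat = gat_forward(params, fd, L, config$heads))
    frames[[f]] <- unname(as.matrix(fw$z))
  }
  new_embedding_series(frames, config)
}
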