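#' Flatten an embedding series into a per-frame feature table
#'
#' Row `t` is frame `t`'s `|V| x d` embedding matrix flattened node-major
#' (node 1 dims 1..d, node 2 dims 1..d, ...), mapping the whole graph of
#' one frame to a single vector of width `|V| * d`. Feature names are
#' `node{i}_dim{j}`.
#'
#' @param series an `embedding_series`.
#' @return an object of class `feature_table` carrying the matrix, the
#'   node/dimension geometry, and embedding provenance.
#' @export
flatten_embeddings <- function(series) {
  if (length(series$frames) == 0L) stop("integrity error: empty embedding series")
  dm <- dim(series$frames[[1]])
  v <- dm[1]; d <- dm[2]
  mats <- vapply(series$frames, function(m) {
    if (!identical(dim(m), dm))
      stop("integrity error: embedding shapes differ across frames")
    as.numeric(t(m))
  }, numeric(v * d))
  x <- t(mats)
  colnames(x) <- paste0("node", rep(seq_len(v), each = d),
                        "_dim", rep(seq_len(d), v))
  feature_table(x, n_nodes = v, dimension = d,
                provenance = series$config)
}

#' Construct a feature table
#' @param x numeric matrix, one row per frame, no missing values.
#' @param labels optional `state_label_series`.
#' @param n_nodes,dimension embedding geometry (used by the 1-D CNN).
#' @param provenance arbitrary provenance object (e.g. embedding config).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(x, labels = NULL, n_nodes = NULL, dimension = NULL,
                          provenance = NULL) {
  x <- as.matrix(x)
  if (anyNA(x) || !all(is.finite(x)))
    stop("integrity error: feature table contains missing or non-finite values")
  structure(list(x = x, labels = labels, n_nodes = n_nodes,
                 dimension = dimension, provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d frames x %d features%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) "" else " (labeled)"))
  invisible(x)
}

#' Recover the |V| x d embedding matrix from one flattened row
#' @param row numeric vector of length `n_nodes * dimension`.
#' @param n_nodes,dimension embedding geometry.
#' @return `n_nodes x dimension` matrix.
#' @export
unflatten_features <- function(row, n_nodes, dimension) {
  matrix(row, nrow = n_nodes, ncol = dimension, byrow = TRUE)
}

#' Attach per-frame labels to a feature table
#' @param table a `feature_table`.
#' @param labels a `state_label_series` (or character vector) aligned by
#'   frame index.
#' @return labeled `feature_table`.
#' @export
attach_labels <- function(table, labels) {
  if (is.character(labels)) labels <- state_label_series(labels)
  if (length(labels$labels) != nrow(table$x))
    stop(sprintf("alignment error: %d rows but %d labels",
                 nrow(table$x), length(labels$labels)))
  table$labels <- labels
  table
}

#' Stratified train/test split of a labeled feature table
#'
#' A single stratified random split (not cross-validation): train size is
#' `round(train_fraction * n)`; per-class allocations use largest-remainder
#' rounding so class proportions are preserved within one frame.
#'
#' @param table labeled `feature_table`.
#' @param train_fraction fraction of rows in the training set (default 0.70).
#' @param stratified preserve class proportions (default `TRUE`).
#' @param seed RNG seed.
#' @return list with `train` and `test` feature tables (disjoint,
#'   exhaustive) and the index vectors used.
#' @export
split_table <- function(table, train_fraction = 0.70, stratified = TRUE,
                        seed = 1L) {
  if (is.null(table$labels)) stop("argument error: table must be labeled")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("argument error: train_fraction must be in (0, 1)")
  y <- table$labels$labels
  n <- length(y)
  n_train <- round(train_fraction * n)
  set.seed(seed)
  if (stratified) {
    tb <- table(y)
    if (any(tb < 2L))
      stop(sprintf("stratification error: class '%s' has fewer than 2 members",
                   names(tb)[which.min(tb)]))
    target <- train_fraction * as.numeric(tb)
    base <- floor(target)
    rem <- n_train - sum(base)
    if (rem > 0) {
      extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    } else if (rem < 0) {
      red <- order(target - base)[seq_len(-rem)]
      base[red] <- base[red] - 1L
    }
    train_idx <- integer(0)
    for (k in seq_along(tb)) {
      members <- which(y == names(tb)[k])
      train_idx <- c(train_idx, sample(members, base[k]))
    }
    train_idx <- sort(train_idx)
  } else {
    train_idx <- sort(sample.int(n, n_train))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  subset_tab <- function(idx) {
    feature_table(table$x[idx, , drop = FALSE],
                  labels = state_label_series(y[idx], table$labels$label_set),
                  n_nodes = table$n_nodes, dimension = table$dimension,
                  provenance = table$provenance)
  }
  list(train = subset_tab(train_idx), test = subset_tab(test_idx),
       train_idx = train_idx, test_idx = test_idx,
       spec = list(train_fraction = train_fraction,
                   stratified = stratified, seed = seed))
}

#' Classifier specification
#'
#' @param model one of `"logistic_regression"`, `"random_forest"`,
#'   `"xgboost_style"`, `"lightgbm_style"`, `"neural_network"`,
#'   `"cnn_1d"`, `"support_vector"`.
#' @param hyperparameters named list overriding the model's defaults.
#' @param seed RNG seed for the fit.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(model = c("logistic_regression", "random_forest",
                                      "xgboost_style", "lightgbm_style",
                                      "neural_network", "cnn_1d",
                                      "support_vector"),
                            hyperparameters = list(), seed = 1L) {
  model <- match.arg(model)
  defaults <- switch(model,
    logistic_regression = list(lambda = 1e-3),
    random_forest = list(n_trees = 100L, max_depth = 10L, min_split = 5L),
    xgboost_style = list(n_rounds = 60L, max_depth = 3L, learning_rate = 0.1,
                         colsample = 0.5),
    lightgbm_style = list(n_rounds = 60L, max_depth = 6L, learning_rate = 0.1,
                          colsample = 0.3),
    neural_network = list(hidden = 64L, epochs = 30L, batch = 64L,
                          learning_rate = 1e-3, l2 = 1e-4),
    cnn_1d = list(filters = 8L, width = 5L, epochs = 30L, batch = 64L,
                  learning_rate = 1e-3),
    support_vector = list(lambda = 1e-3, iterations = 300L))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(model = model, hyperparameters = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

scale_stats <- function(x) {
  ctr <- colMeans(x)
  sc <- apply(x, 2L, stats::sd)
  sc[sc < 1e-12] <- 1
  list(center = ctr, scale = sc)
}

apply_scale <- function(x, st)
  sweep(sweep(x, 2L, st$center), 2L, st$scale, `/`)

softmax_rows <- function(s) {
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

## ---- model fitters -----------------------------------------------------

fit_gboost <- function(x, yi, k, hp) {
  n <- nrow(x)
  f <- matrix(0, n, k)
  y1 <- matrix(0, n, k); y1[cbind(seq_len(n), yi)] <- 1
  trees <- vector("list", hp$n_rounds)
  ncol_s <- max(1L, floor(hp$colsample * ncol(x)))
  for (r in seq_len(hp$n_rounds)) {
    p <- softmax_rows(f)
    round_trees <- vector("list", k)
    for (cls in seq_len(k)) {
      cols <- sort(sample.int(ncol(x), ncol_s))
      tr <- tree_fit(x[, cols, drop = FALSE], y1[, cls] - p[, cls],
                     max_depth = hp$max_depth, min_split = 20L,
                     min_bucket = 5L)
      round_trees[[cls]] <- list(tree = tr, cols = cols)
      f[, cls] <- f[, cls] +
        hp$learning_rate * tree_predict(tr, x[, cols, drop = FALSE])
    }
    trees[[r]] <- round_trees
  }
  list(trees = trees, lr = hp$learning_rate, k = k)
}

predict_gboost <- function(fit, x) {
  f <- matrix(0, nrow(x), fit$k)
  for (round_trees in fit$trees) {
    for (cls in seq_len(fit$k)) {
      rt <- round_trees[[cls]]
      f[, cls] <- f[, cls] + fit$lr * tree_predict(rt$tree, x[, rt$cols, drop = FALSE])
    }
  }
  max.col(f, ties.method = "first")
}

mlp_fit <- function(x, yi, k, hidden, epochs, batch, lr, l2) {
  n <- nrow(x); p <- ncol(x)
  w1 <- glorot(p, hidden); b1 <- numeric(hidden)
  w2 <- glorot(hidden, k); b2 <- numeric(k)
  params <- list(w1 = w1, b1 = rbind(b1), w2 = w2, b2 = rbind(b2))
  st <- adam_init(params)
  y1 <- matrix(0, n, k); y1[cbind(seq_len(n), yi)] <- 1
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = batch)) {
      sel <- ord[b0:min(b0 + batch - 1L, n)]
      xb <- x[sel, , drop = FALSE]; yb <- y1[sel, , drop = FALSE]
      h_pre <- sweep(xb %*% params$w1, 2L, params$b1, `+`)
      h <- relu(h_pre)
      z <- sweep(h %*% params$w2, 2L, params$b2, `+`)
      pr <- softmax_rows(z)
      dz <- (pr - yb) / length(sel)
      gr <- list(w2 = crossprod(h, dz) + l2 * params$w2,
                 b2 = rbind(colSums(dz)),
                 w1 = NULL, b1 = NULL)
      dh <- (dz %*% t(params$w2)) * (h_pre > 0)
      gr$w1 <- crossprod(xb, dh) + l2 * params$w1
      gr$b1 <- rbind(colSums(dh))
      upd <- adam_step(params, gr, st, lr)
      params <- upd$params; st <- upd$state
    }
  }
  params
}

mlp_predict_scores <- function(params, x) {
  h <- relu(sweep(x %*% params$w1, 2L, params$b1, `+`))
  sweep(h %*% params$w2, 2L, params$b2, `+`)
}

# 1-D CNN over the node axis: the flattened |V|*d vector is reshaped back
# to |V| x d with embedding dimensions as channels; convolution slides
# along the node axis (the only structured axis after flattening), then
# global average pooling and a softmax layer.
cnn_fit <- function(x, yi, k, v, d, filters, width, epochs, batch, lr) {
  n <- nrow(x)
  width <- min(width, v)
  npos <- v - width + 1L
  # im2col index template: for each position, the flat feature indices
  idx <- matrix(0L, npos, width * d)
  for (pp in seq_len(npos)) {
    nodes <- pp:(pp + width - 1L)
    idx[pp, ] <- as.integer(outer(seq_len(d), (nodes - 1L) * d, `+`))
  }
  kern <- glorot(width * d, filters); bk <- numeric(filters)
  w2 <- glorot(filters, k); b2 <- numeric(k)
  params <- list(kern = kern, bk = rbind(bk), w2 = w2, b2 = rbind(b2))
  st <- adam_init(params)
  y1 <- matrix(0, n, k); y1[cbind(seq_len(n), yi)] <- 1
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = batch)) {
      sel <- ord[b0:min(b0 + batch - 1L, n)]
      bs <- length(sel)
      xb <- x[sel, , drop = FALSE]
      # patches: (bs * npos) x (width*d)
      pm <- matrix(0, bs * npos, width * d)
      for (pp in seq_len(npos))
        pm[(pp - 1L) * bs + seq_len(bs), ] <- xb[, idx[pp, ], drop = FALSE]
      conv_pre <- sweep(pm %*% params$kern, 2L, params$bk, `+`)
      conv <- relu(conv_pre)
      pool <- matrix(0, bs, filters)         # global average over positions
      for (pp in seq_len(npos))
        pool <- pool + conv[(pp - 1L) * bs + seq_len(bs), , drop = FALSE]
      pool <- pool / npos
      z <- sweep(pool %*% params$w2, 2L, params$b2, `+`)
      pr <- softmax_rows(z)
      dz <- (pr - y1[sel, , drop = FALSE]) / bs
      dpool <- dz %*% t(params$w2)
      dconv <- matrix(0, bs * npos, filters)
      for (pp in seq_len(npos))
        dconv[(pp - 1L) * bs + seq_len(bs), ] <- dpool / npos
      dconv <- dconv * (conv_pre > 0)
      gr <- list(kern = crossprod(pm, dconv), bk = rbind(colSums(dconv)),
                 w2 = crossprod(pool, dz), b2 = rbind(colSums(dz)))
      upd <- adam_step(params, gr, st, lr)
      params <- upd$params; st <- upd$state
    }
  }
  list(params = params, idx = idx, npos = npos, filters = filters)
}

cnn_predict_scores <- function(fit, x) {
  n <- nrow(x)
  pool <- matrix(0, n, fit$filters)
  for (pp in seq_len(fit$npos)) {
    pm <- x[, fit$idx[pp, ], drop = FALSE]
    pool <- pool + relu(sweep(pm %*% fit$params$kern, 2L, fit$params$bk, `+`))
  }
  pool <- pool / fit$npos
  sweep(pool %*% fit$params$w2, 2L, fit$params$b2, `+`)
}

svm_fit <- function(x, yi, k, lambda, iterations) {
  # linear squared-hinge one-vs-rest, full-batch Adam
  p <- ncol(x)
  w <- matrix(0, p + 1L, k)        # last row = bias
  params <- list(w = w)
  st <- adam_init(params)
  xb <- cbind(x, 1)
  for (it in seq_len(iterations)) {
    s <- xb %*% params$w
    g <- matrix(0, p + 1L, k)
    for (cls in seq_len(k)) {
      yy <- ifelse(yi == cls, 1, -1)
      marg <- 1 - yy * s[, cls]
      act <- marg > 0
      g[, cls] <- -2 * crossprod(xb[act, , drop = FALSE],
                                 (yy * marg)[act]) / nrow(xb)
      g[seq_len(p), cls] <- g[seq_len(p), cls] + lambda * params$w[seq_len(p), cls]
    }
    upd <- adam_step(params, list(w = g), st, 0.05)
    params <- upd$params; st <- upd$state
  }
  params$w
}

#' Train a conformational-state classifier
#'
#' Features are standardized with training-set statistics for the linear,
#' neural and kernel-free margin models; tree ensembles consume raw
#' features. Every model is seed-deterministic.
#'
#' @param train_table labeled `feature_table`.
#' @param spec a [classifier_spec()].
#' @return object of class `mdembed_model` with a [predict][predict.mdembed_model]
#'   method.
#' @export
train_classifier <- function(train_table, spec) {
  if (is.null(train_table$labels))
    stop("argument error: training table must be labeled")
  y <- train_table$labels$labels
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("training error: need at least 2 classes, got 1")
  yi <- match(y, classes)
  k <- length(classes)
  x <- train_table$x
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  needs_scaling <- spec$model %in% c("logistic_regression", "neural_network",
                                     "cnn_1d", "support_vector")
  st <- NULL
  if (needs_scaling) {
    st <- scale_stats(x)
    x <- apply_scale(x, st)
  }
  fit <- switch(spec$model,
    logistic_regression = glmnet::glmnet(
      x, factor(yi), family = if (k == 2L) "binomial" else "multinomial",
      alpha = 0, lambda = hp$lambda, standardize = FALSE),
    random_forest = {
      mtry <- max(1L, floor(sqrt(ncol(x))))
      lapply(seq_len(hp$n_trees), function(b) {
        rows <- sample.int(nrow(x), replace = TRUE)
        list(rows = rows,
             tree = tree_fit(x[rows, , drop = FALSE], yi[rows],
                             n_classes = k, max_depth = hp$max_depth,
                             min_split = hp$min_split, mtry = mtry))
      })
    },
    xgboost_style = fit_gboost(x, yi, k, hp),
    lightgbm_style = fit_gboost(x, yi, k, hp),
    neural_network = mlp_fit(x, yi, k, hp$hidden, hp$epochs, hp$batch,
                             hp$learning_rate, hp$l2),
    cnn_1d = {
      v <- train_table$n_nodes; d <- train_table$dimension
      if (is.null(v) || is.null(d)) { v <- ncol(x); d <- 1L }
      cnn_fit(x, yi, k, v, d, hp$filters, hp$width, hp$epochs, hp$batch,
              hp$learning_rate)
    },
    support_vector = svm_fit(x, yi, k, hp$lambda, hp$iterations))
  structure(list(model = spec$model, fit = fit, classes = classes,
                 scaling = st, spec = spec,
                 n_nodes = train_table$n_nodes,
                 dimension = train_table$dimension),
            class = "mdembed_model")
}

#' Predict state labels for new frames
#' @param object an `mdembed_model`.
#' @param newdata a `feature_table` or numeric matrix.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.mdembed_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$x else as.matrix(newdata)
  if (!is.null(object$scaling)) x <- apply_scale(x, object$scaling)
  k <- length(object$classes)
  idx <- switch(object$model,
    logistic_regression = {
      pr <- stats::predict(object$fit, x, type = "class")
      as.integer(as.character(pr[, 1]))
    },
    random_forest = {
      votes <- matrix(0, nrow(x), k)
      for (b in object$fit) {
        pp <- tree_predict(b$tree, x)
        votes <- votes + pp
      }
      max.col(votes, ties.method = "first")
    },
    xgboost_style = predict_gboost(object$fit, x),
    lightgbm_style = predict_gboost(object$fit, x),
    neural_network = max.col(mlp_predict_scores(object$fit, x),
                             ties.method = "first"),
    cnn_1d = max.col(cnn_predict_scores(object$fit, x), ties.method = "first"),
    support_vector = max.col(cbind(x, 1) %*% object$fit, ties.method = "first"))
  object$classes[idx]
}

## ---- evaluation --------------------------------------------------------

#' Evaluation report from a confusion matrix
#'
#' Per-class recall is `diagonal / row-sum` -- the "class-specific
#' accuracy" of per-class comparison tables; overall accuracy is
#' `trace / total`. A class absent from the test set yields `NA` recall,
#' not zero.
#'
#' @param confusion square confusion matrix, rows = truth, columns =
#'   prediction.
#' @param classes class names (defaults to dimnames).
#' @param provenance optional provenance list.
#' @return object of class `evaluation_report`.
#' @export
report_from_confusion <- function(confusion, classes = NULL,
                                  provenance = NULL) {
  confusion <- as.matrix(confusion)
  if (is.null(classes))
    classes <- rownames(confusion) %||% paste0("class", seq_len(nrow(confusion)))
  dimnames(confusion) <- list(truth = classes, predicted = classes)
  support <- rowSums(confusion)
  pred_tot <- colSums(confusion)
  tp <- diag(confusion)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, NA_real_)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  structure(list(confusion = confusion,
                 recall = stats::setNames(recall, classes),
                 precision = stats::setNames(precision, classes),
                 f1 = stats::setNames(f1, classes),
                 support = stats::setNames(support, classes),
                 accuracy = sum(tp) / sum(confusion),
                 provenance = provenance),
            class = "evaluation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a fitted model on a labeled test table
#' @param model an `mdembed_model`.
#' @param test_table labeled `feature_table`.
#' @return an `evaluation_report`.
#' @export
evaluate_model <- function(model, test_table) {
  if (is.null(test_table$labels))
    stop("argument error: test table must be labeled")
  pred <- predict(model, test_table)
  truth <- test_table$labels$labels
  classes <- sort(unique(c(model$classes, truth)))
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  report_from_confusion(unclass(as.matrix(confusion)), classes,
                        provenance = list(model = model$model,
                                          seed = model$spec$seed))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> accuracy %.3f\n", x$accuracy))
  df <- data.frame(recall = round(x$recall, 3),
                   precision = round(x$precision, 3),
                   f1 = round(x$f1, 3), support = x$support)
  print(df)
  invisible(x)
}

#' Factorial benchmark over datasets and classifiers
#'
#' Runs the 70/30 split + train + evaluate cycle for every combination of
#' labeled feature tables (typically one per trajectory stride/size) and
#' classifier specifications, mirroring a per-class accuracy comparison
#' table: one row per (dataset, model), one column per class plus overall
#' accuracy. Failures in one cell are recorded and the sweep continues.
#'
#' @param tables named list of labeled `feature_table`s.
#' @param specs list of [classifier_spec()]s.
#' @param train_fraction,stratified,seed split parameters.
#' @return list with `reports` (nested), `table` (data.frame summary) and
#'   `errors`.
#' @export
benchmark_models <- function(tables, specs, train_fraction = 0.70,
                             stratified = TRUE, seed = 1L) {
  if (is.null(names(tables)))
    names(tables) <- paste0("dataset", seq_along(tables))
  rows <- list(); reports <- list(); errors <- list()
  for (tn in names(tables)) {
    sp <- split_table(tables[[tn]], train_fraction, stratified, seed)
    for (cs in specs) {
      cell <- paste(tn, cs$model, sep = "/")
      res <- tryCatch({
        fit <- train_classifier(sp$train, cs)
        evaluate_model(fit, sp$test)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[cell]] <- conditionMessage(res)
        next
      }
      reports[[cell]] <- res
      row <- c(list(dataset = tn, n_frames = nrow(tables[[tn]]$x),
                    model = cs$model),
               as.list(round(res$recall, 4)),
               list(accuracy = round(res$accuracy, 4)))
      rows[[cell]] <- as.data.frame(row, check.names = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame()
  list(reports = reports, table = tab, errors = errors)
}
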