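fake_embedding_series <- function(n_frames, v, d, seed = 1) {
  set.seed(seed)
  new_series <- list(
    frames = lapply(seq_len(n_frames), function(f) matrix(rnorm(v * d), v, d)),
    config = embedding_config("gcn", dimension = d, seed = seed))
  structure(new_series, class = "embedding_series")
}

test_that("flattening is node-major with width |V| * d and invertible", {
  es <- fake_embedding_series(3, 4, 3)
  ft <- flatten_embeddings(es)
  expect_equal(ncol(ft$x), 12L)
  expect_equal(colnames(ft$x)[1:4],
               c("node1_dim1", "node1_dim2", "node1_dim3", "node2_dim1"))
  # row-major (node-major) layout and round trip
  expect_equal(unflatten_features(ft$x[2, ], 4, 3), es$frames[[2]])
  # the 214-residue, d = 64 geometry gives width 13,696
  es_adk <- fake_embedding_series(2, 214, 64, seed = 2)
  expect_equal(ncol(flatten_embeddings(es_adk)$x), 13696L)
  # shape mismatch across frames is an integrity error
  es_bad <- es; es_bad$frames[[2]] <- matrix(0, 5, 3)
  expect_error(flatten_embeddings(es_bad), "integrity error")
})

test_that("label attachment validates length and label sets", {
  ft <- flatten_embeddings(fake_embedding_series(100, 3, 2))
  labs <- state_label_series(rep(c("A", "B"), 50))
  expect_s3_class(attach_labels(ft, labs), "feature_table")
  expect_error(attach_labels(ft, state_label_series(rep("A", 99))),
               "alignment error")
  expect_error(state_label_series(rep(c("A", "X"), 50), c("A", "B")),
               "validation error")
})

test_that("70/30 split is an exact stratified partition, reproducible by seed", {
  ft <- flatten_embeddings(fake_embedding_series(1000, 3, 2))
  y <- c(rep("A", 100), rep("B", 900))   # 10% minority class
  ft <- attach_labels(ft, state_label_series(y))
  sp <- split_table(ft, 0.70, TRUE, seed = 42)
  expect_equal(nrow(sp$train$x), 700L)
  expect_equal(nrow(sp$test$x), 300L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:1000)
  # stratified allocation of the 10% class within rounding
  expect_lte(abs(sum(sp$train$labels$labels == "A") - 70), 1)
  sp2 <- split_table(ft, 0.70, TRUE, seed = 42)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_table(ft, 0.70, TRUE, seed = 43)
  expect_false(identical(sp$train_idx, sp3$train_idx))
  # singleton class under stratification errors
  ft_bad <- attach_labels(
    flatten_embeddings(fake_embedding_series(11, 3, 2)),
    state_label_series(c(rep("A", 10), "B")))
  expect_error(split_table(ft_bad, 0.7, TRUE, 1), "stratification error")
  expect_error(split_table(ft, 1.5), "argument error")
})

test_that("logistic regression nails linearly separable classes", {
  set.seed(3)
  x <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 6), 100, 2))
  ft <- attach_labels(feature_table(x),
                      state_label_series(rep(c("A", "B"), each = 100)))
  fit <- train_classifier(ft, classifier_spec("logistic_regression", seed = 1))
  expect_equal(mean(predict(fit, ft) == ft$labels$labels), 1.0)
})

test_that("all seven model types run end-to-end and are seed-deterministic", {
  sim <- small_two_state(n_frames = 60, m = 10, seed = 19)
  gs <- build_graph_series(sim$ensemble, 10)
  es <- gnn_embed(gs, embedding_config("graphsage", dimension = 6, seed = 2,
                                       epochs = 5, hidden = 10,
                                       training_frame_sample = 0.3))
  ft <- attach_labels(flatten_embeddings(es), sim$labels)
  sp <- split_table(ft, 0.7, TRUE, seed = 7)
  models <- c("logistic_regression", "random_forest", "xgboost_style",
              "lightgbm_style", "neural_network", "cnn_1d", "support_vector")
  for (mdl in models) {
    cs <- classifier_spec(mdl, seed = 11)
    fit1 <- train_classifier(sp$train, cs)
    rep1 <- evaluate_model(fit1, sp$test)
    expect_true(is.finite(rep1$accuracy))
    fit2 <- train_classifier(sp$train, cs)
    rep2 <- evaluate_model(fit2, sp$test)
    expect_identical(rep1$confusion, rep2$confusion)   # report-identical rerun
  }
  # degenerate single-class input
  one_class <- attach_labels(
    feature_table(sp$train$x),
    state_label_series(rep("A", nrow(sp$train$x)), c("A", "B")))
  expect_error(train_classifier(one_class, classifier_spec("neural_network")),
               "training error")
})

test_that("permuted labels drop accuracy to the majority-class frequency", {
  set.seed(29)
  x <- rbind(matrix(rnorm(600, 0), 300, 2), matrix(rnorm(600, 5), 300, 2))
  y <- rep(c("A", "B"), each = 300)
  accs <- numeric(5)
  for (r in 1:5) {
    set.seed(200 + r)
    yp <- sample(y)
    ft <- attach_labels(feature_table(x), state_label_series(yp))
    sp <- split_table(ft, 0.7, TRUE, seed = r)
    fit <- train_classifier(sp$train, classifier_spec("logistic_regression",
                                                      seed = r))
    accs[r] <- evaluate_model(fit, sp$test)$accuracy
  }
  expect_lte(abs(mean(accs) - 0.5), 0.05)
})

test_that("evaluation-report arithmetic is self-consistent", {
  # perfect predictions
  perfect <- report_from_confusion(diag(c(5, 7)), c("A", "B"))
  expect_equal(unname(perfect$recall), c(1, 1))
  expect_equal(perfect$accuracy, 1)
  # the worked 2x2 example
  rep <- report_from_confusion(matrix(c(8, 4, 2, 6), 2, 2), c("A", "B"))
  expect_equal(unname(rep$recall), c(0.8, 0.6))
  expect_equal(rep$accuracy, 0.7)
  # identity: accuracy = trace/sum for random confusion matrices
  set.seed(31)
  for (r in 1:5) {
    cm <- matrix(rpois(9, 10), 3, 3)
    rp <- report_from_confusion(cm)
    expect_equal(rp$accuracy, sum(diag(cm)) / sum(cm))
    expect_equal(unname(rp$recall), diag(cm) / rowSums(cm))
  }
  # absent class: NA recall, not zero
  cm <- matrix(c(5, 0, 3, 0), 2, 2)
  expect_true(is.na(report_from_confusion(cm)$recall[2]))
})

test_that("benchmark sweeps the full factorial grid and records failures", {
  sim <- small_two_state(n_frames = 50, m = 8, seed = 37)
  es <- fake_embedding_series(50, 8, 4, seed = 3)
  ft <- attach_labels(flatten_embeddings(es), sim$labels)
  tables <- list(n50 = ft,
                 n25 = attach_labels(
                   flatten_embeddings(fake_embedding_series(25, 8, 4, 4)),
                   state_label_series(sim$labels$labels[1:25],
                                      sim$labels$label_set)))
  specs <- list(classifier_spec("logistic_regression", seed = 1),
                classifier_spec("support_vector", seed = 1))
  bm <- benchmark_models(tables, specs, seed = 5)
  expect_length(bm$reports, 4L)
  expect_equal(nrow(bm$table), 4L)
  expect_true(all(c("dataset", "model", "accuracy") %in% names(bm$table)))
})
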