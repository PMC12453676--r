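# End-to-end orchestration: validated config -> staged artifacts in a run
# directory with a machine-readable manifest. All randomness flows from
# one global seed via per-stage derived seeds, so stages are reproducible
# even when rerun in isolation.

stage_seed_offsets <- c(simulate = 101L, graphs = 211L, embed = 307L,
                        label = 401L, features = 503L, split = 601L,
                        train = 701L)

derive_seed <- function(seed, stage) {
  off <- stage_seed_offsets[[stage]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

#' Build and validate a pipeline run configuration
#'
#' Accepts either a named list or a path to a JSON config file. Unset
#' parameters fall back to package defaults; the fully resolved
#' configuration (every default made explicit) is what gets logged and
#' written into the run manifest, so a reader can audit exactly which
#' defaults applied.
#'
#' @param config named list or JSON file path.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("validation error: config file '%s' does not exist", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    input = list(topology = NULL, trajectory = NULL, selection = "calpha"),
    synthetic = NULL,
    stride = 1L,
    cutoff = 10,
    embedding = list(method = "graphsage", dimension = 16L),
    labeling = list(source = "density", k = 2L, grid_size = 128L,
                    threshold = 0.02, state_names = c("A", "B", "I"),
                    anchors = NULL, reference_frame = 1L),
    split = list(train_fraction = 0.70, stratified = TRUE),
    classifier = list(model = "logistic_regression", hyperparameters = list()),
    out_dir = "mdembed_run",
    seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  # JSON round-trips turn named vectors into lists (and can drop names on
  # atomic vectors), so configs must use objects for these; normalize here
  if (!is.null(cfg$synthetic$occupancies))
    cfg$synthetic$occupancies <- unlist(cfg$synthetic$occupancies)
  if (!is.null(cfg$labeling$state_names))
    cfg$labeling$state_names <- unlist(cfg$labeling$state_names)
  if (!is.null(cfg$labeling$anchors))
    cfg$labeling$anchors <- lapply(cfg$labeling$anchors, unlist)
  has_files <- !is.null(cfg$input$topology)
  has_synth <- !is.null(cfg$synthetic)
  if (!has_files && !has_synth)
    stop("validation error: config needs either input$topology or a synthetic block")
  if (has_files) {
    for (f in c(cfg$input$topology, cfg$input$trajectory)) {
      if (!file.exists(f))
        stop(sprintf("validation error: input file '%s' does not exist", f))
    }
  }
  if (cfg$stride < 1L) stop("validation error: stride must be >= 1")
  structure(cfg, class = "run_config")
}

log_line <- function(dir, ...) {
  cat(sprintf(...), "\n", sep = "", file = file.path(dir, "run.log"),
      append = TRUE)
}

#' Run the full pipeline from a configuration
#'
#' Stages: load/simulate -> contact graphs -> embeddings -> labels ->
#' features -> split -> train -> evaluate. Each stage's artifact is
#' persisted in the run directory and checksummed into `manifest.json`;
#' rerunning an identical config reproduces identical artifacts and
#' manifest. A stage failure aborts with the stage name; artifacts of
#' completed stages remain on disk.
#'
#' @param config a [run_config()] (or list/path accepted by it).
#' @param stages character vector of stages to run (default: all).
#' @return the run directory path, invisibly; the evaluation report is
#'   at `report.json` and the manifest at `manifest.json`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "graphs", "embed", "label",
                                    "features", "train")) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir <- cfg$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(dir, "run.log"))
  log_line(dir, "effective config: %s",
           jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"))
  artifacts <- character(0)
  run_stage <- function(name, f) {
    log_line(dir, "stage %s: start", name)
    out <- tryCatch(f(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    artifacts <<- c(artifacts, out)
    log_line(dir, "stage %s: wrote %s", name, paste(out, collapse = ", "))
  }

  ens_path <- file.path(dir, "ensemble.txt")
  true_lab_path <- file.path(dir, "labels_true.tsv")
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      if (!is.null(cfg$synthetic)) {
        sargs <- cfg$synthetic
        sargs$seed <- derive_seed(cfg$seed, "simulate")
        spec <- do.call(synthetic_spec, sargs)
        sim <- generate_ensemble(spec)
        ens <- sim$ensemble
        write_labels(sim$labels, true_lab_path)
      } else {
        ens <- load_ensemble(cfg$input$topology, cfg$input$trajectory,
                             cfg$input$selection)
      }
      if (cfg$stride > 1L) ens <- stride_ensemble(ens, cfg$stride)
      write_ensemble(ens, ens_path)
      c(ens_path, if (!is.null(cfg$synthetic)) true_lab_path)
    })
  }

  graphs_path <- file.path(dir, "graphs.txt")
  if ("graphs" %in% stages) {
    run_stage("graphs", function() {
      ens <- read_ensemble(ens_path)
      gs <- build_graph_series(ens, cfg$cutoff)
      write_graph_series(gs, graphs_path)
      graphs_path
    })
  }

  emb_path <- file.path(dir, "embeddings.txt")
  if ("embed" %in% stages) {
    run_stage("embed", function() {
      gs <- read_graph_series(graphs_path)
      eargs <- cfg$embedding
      eargs$seed <- derive_seed(cfg$seed, "embed")
      ec <- do.call(embedding_config, eargs)
      es <- embed_graph_series(gs, ec)
      write_embedding_series(es, emb_path)
      c(emb_path, paste0(emb_path, ".json"))
    })
  }

  lab_path <- file.path(dir, "labels.tsv")
  if ("label" %in% stages) {
    run_stage("label", function() {
      if (identical(cfg$labeling$source, "generative")) {
        if (!file.exists(true_lab_path))
          stop("generative labels requested but no synthetic stage output")
        file.copy(true_lab_path, lab_path, overwrite = TRUE)
        return(lab_path)
      }
      ens <- read_ensemble(ens_path)
      sup <- superpose(ens, cfg$labeling$reference_frame)
      pr <- pca_project(sup, k = cfg$labeling$k)
      fld <- estimate_density(pr$scores[, 1:2], cfg$labeling$grid_size)
      anchors <- cfg$labeling$anchors
      regions <- extract_regions(fld, cfg$labeling$threshold,
                                 state_names = cfg$labeling$state_names,
                                 anchors = anchors)
      labs <- assign_labels(pr$scores[, 1:2], regions)
      write_labels(labs, lab_path)
      utils::write.table(data.frame(frame_index = seq_len(nrow(pr$scores)),
                                    pc1 = pr$scores[, 1], pc2 = pr$scores[, 2]),
                         file.path(dir, "scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_regions_json(regions, file.path(dir, "regions.json"))
      plot_projection(pr$scores, labs, file.path(dir, "projection.png"))
      c(lab_path, file.path(dir, "scores.tsv"), file.path(dir, "regions.json"))
    })
  }

  feat_path <- file.path(dir, "features.tsv")
  if ("features" %in% stages) {
    run_stage("features", function() {
      es <- read_embedding_series(emb_path)
      ft <- flatten_embeddings(es)
      labs <- read_labels(lab_path)
      ft <- attach_labels(ft, labs)
      df <- as.data.frame(ft$x)
      df$label <- labs$labels
      utils::write.table(df, feat_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      feat_path
    })
  }

  report_path <- file.path(dir, "report.json")
  if ("train" %in% stages) {
    run_stage("train", function() {
      df <- utils::read.table(feat_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      labs <- df$label
      x <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
      es <- read_embedding_series(emb_path)
      ft <- attach_labels(
        feature_table(x, n_nodes = nrow(es$frames[[1]]),
                      dimension = ncol(es$frames[[1]])),
        state_label_series(labs))
      keep <- ft$labels$labels != "N"
      if (sum(keep) < nrow(ft$x)) {
        ft <- feature_table(ft$x[keep, , drop = FALSE],
                            labels = state_label_series(ft$labels$labels[keep]),
                            n_nodes = ft$n_nodes, dimension = ft$dimension)
        log_line(dir, "train: dropped %d non-state (N) frames", sum(!keep))
      }
      sp <- split_table(ft, cfg$split$train_fraction, cfg$split$stratified,
                        seed = derive_seed(cfg$seed, "split"))
      cs <- classifier_spec(cfg$classifier$model,
                            cfg$classifier$hyperparameters %||% list(),
                            seed = derive_seed(cfg$seed, "train"))
      fit <- train_classifier(sp$train, cs)
      rep <- evaluate_model(fit, sp$test)
      jsonlite::write_json(
        list(model = cs$model, seed = cfg$seed,
             split = cfg$split,
             accuracy = rep$accuracy,
             recall = as.list(rep$recall),
             precision = as.list(rep$precision),
             f1 = as.list(rep$f1),
             support = as.list(rep$support),
             confusion = unname(apply(rep$confusion, 1L, as.list))),
        report_path, auto_unbox = TRUE, digits = NA)
      report_path
    })
  }

  manifest <- list(
    package = "mdembed",
    version = as.character(utils::packageVersion("mdembed")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(cfg),
    stage_seeds = lapply(stats::setNames(nm = names(stage_seed_offsets)),
                         function(s) derive_seed(cfg$seed, s)),
    artifacts = lapply(stats::setNames(nm = basename(artifacts)), function(a)
      unname(tools::md5sum(file.path(dir, basename(a))))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `build-graphs`, `embed`, `label`, `features`,
#' `train`, `run` (all stages). Flags: `--config <path>` plus overrides
#' `--seed`, `--out-dir`, `--model`, `--train-fraction`,
#' `--stratified` / `--no-stratified`, `--stride`, `--cutoff`,
#' `--method` (embedding). Flags override config values.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return run directory path, invisibly.
#' @export
mdembed_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: mdembed <simulate|build-graphs|embed|label|features|train|run> [--config cfg.json] [flags]")
  sub <- args[1]; args <- args[-1]
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; args[i] }
    switch(a,
      "--config" = { opts$config <- take() },
      "--seed" = { opts$seed <- as.integer(take()) },
      "--out-dir" = { opts$out_dir <- take() },
      "--model" = { opts$classifier <- list(model = take()) },
      "--method" = { opts$embedding <- list(method = take()) },
      "--train-fraction" = { opts$split <- list(train_fraction = as.numeric(take())) },
      "--stratified" = { opts$split <- utils::modifyList(opts$split %||% list(), list(stratified = TRUE)) },
      "--no-stratified" = { opts$split <- utils::modifyList(opts$split %||% list(), list(stratified = FALSE)) },
      "--stride" = { opts$stride <- as.integer(take()) },
      "--cutoff" = { opts$cutoff <- as.numeric(take()) },
      stop(sprintf("unknown flag '%s'", a)))
    i <- i + 1L
  }
  stage_map <- list(simulate = "simulate",
                    "build-graphs" = "graphs",
                    embed = "embed", label = "label",
                    features = "features", train = "train",
                    run = c("simulate", "graphs", "embed", "label",
                            "features", "train"))
  if (is.null(stage_map[[sub]]))
    stop(sprintf("unknown subcommand '%s'", sub))
  base <- if (!is.null(opts$config)) run_config(opts$config) else list()
  cfg <- run_config(utils::modifyList(unclass(base), opts[setdiff(names(opts), "config")]))
  run_pipeline(cfg, stages = stage_map[[sub]])
}
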