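#' Run the full labeling-and-classification pipeline
#'
#' Orchestrates the stages simulate (or read) -> label -> features ->
#' train -> evaluate as one reproducible run: synthetic (or supplied)
#' treated and untreated spike tables are reduced to per-unit max-bin
#' delta-MFR values, treated units are labeled against the untreated
#' kernel-density null, baseline phenotype features are extracted and
#' joined with the labels, whole wells are held out, the model panel is
#' compared by stratified cross-validated AUC (Kruskal-Wallis), and the
#' boosted-tree ensemble is evaluated on the held-out wells. Every
#' intermediate artifact is persisted and a manifest records configuration
#' hash, seed, per-stage counts and derived sub-seeds.
#'
#' @param config A named list or path to a YAML file. Recognised fields
#'   (defaults in parentheses): `treated_path`/`untreated_path` (none; when
#'   absent a synthetic study is generated), `synth` (list passed to
#'   [synth_config()]), `baseline_window` (`c(0, 300)`),
#'   `treatment_window` (`c(300, 600)`), `bin_width` (30),
#'   `percentile_threshold` (10), `require_positive_delta` (TRUE),
#'   `models` (`c("tree","log","lda","knn","fnn")`), `cv_folds` (10),
#'   `n_holdout_wells` (2), `tune_budget` (0 = documented defaults, no
#'   search), `seed` (1).
#' @param out_dir Output directory for artifacts (created; default
#'   `tempfile("nocilabel_run")`).
#' @return A list with `labels`, `features`, `split`, `cv`, `model_comparison`,
#'   `model`, `report`, `pca`, `manifest` (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("nocilabel_run")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    treated_path = NULL, untreated_path = NULL, synth = list(),
    baseline_window = c(0, 300), treatment_window = c(300, 600),
    bin_width = 30, percentile_threshold = 10,
    require_positive_delta = TRUE,
    models = c("tree", "log", "lda", "knn", "fnn"),
    cv_folds = 10, n_holdout_wells = 2, tune_budget = 0, seed = 1L
  )
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$seed)) stop("a seed is mandatory", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\n(partial outputs under ", out_dir, ")", call. = FALSE)
    })
  }
  sub_seeds <- list(simulate = derive_seed(cfg$seed, 101L),
                    train = derive_seed(cfg$seed, 103L),
                    evaluate = derive_seed(cfg$seed, 107L))

  # -- stage: input (simulate or read) ---------------------------------
  input <- stage("input", {
    if (is.null(cfg$treated_path) || is.null(cfg$untreated_path)) {
      if (!is.null(cfg$treated_path) || !is.null(cfg$untreated_path)) {
        stop("supply both treated_path and untreated_path, or neither")
      }
      sc <- do.call(synth_config,
                    utils::modifyList(list(seed = sub_seeds$simulate),
                                      cfg$synth))
      study <- generate_study(sc, out_dir = out_dir)
      list(treated = study$treated, untreated = study$untreated,
           truth = study$truth)
    } else {
      list(
        treated = read_spike_table(cfg$treated_path, "treated",
                                   cfg$baseline_window,
                                   cfg$treatment_window),
        untreated = read_spike_table(cfg$untreated_path, "untreated",
                                     cfg$baseline_window,
                                     cfg$treatment_window)
      )
    }
  })

  # -- stage: label -----------------------------------------------------
  labels <- stage("label", {
    td <- response_deltas(input$treated, cfg$bin_width)
    ud <- response_deltas(input$untreated, cfg$bin_width)
    lab <- label_units(td, ud, cfg$percentile_threshold,
                       cfg$require_positive_delta)
    write_labels(lab, file.path(out_dir, "labels.csv"))
    lab
  })

  # -- stage: features --------------------------------------------------
  features <- stage("features", {
    ft <- build_feature_table(input$treated, labels = labels)
    write_features(ft, file.path(out_dir, "features.csv"))
    readr::write_csv(attr(ft, "exclusions"),
                     file.path(out_dir, "exclusions.csv"))
    ft
  })

  # -- stage: train -----------------------------------------------------
  trained <- stage("train", {
    split <- split_holdout(features, cfg$n_holdout_wells,
                           seed = sub_seeds$train)
    hps <- list()
    if (cfg$tune_budget > 0) {
      for (m in cfg$models) {
        tuned <- tune_hyperparameters(m, split$train,
                                      budget = cfg$tune_budget,
                                      seed = sub_seeds$train)
        hps[[m]] <- tuned$best
      }
    }
    cv <- crossval_auc(split$train, cfg$models, k = cfg$cv_folds,
                       hyperparameters = hps, seed = sub_seeds$train)
    comparison <- if (length(cfg$models) >= 2) compare_models(cv) else NULL
    model <- train_single_model("tree", split$train,
                                hps[["tree"]] %||% list(),
                                seed = sub_seeds$train)
    list(split = split, cv = cv, comparison = comparison, model = model,
         hyperparameters = hps)
  })

  # -- stage: evaluate --------------------------------------------------
  evaluated <- stage("evaluate", {
    report <- evaluate_holdout(trained$model, trained$split$test,
                               seed = sub_seeds$evaluate)
    pca <- pca_projection(trained$split$train, trained$split$test)
    metrics <- list(
      holdout = tidy(report),
      confusion = as.data.frame.table(report$confusion,
                                      responseName = "count"),
      roc = report$roc,
      importance = report$importance,
      confidence_curve = report$confidence_curve,
      cv_auc = tibble::as_tibble(trained$cv),
      model_comparison = trained$comparison,
      tuning = list(budget = cfg$tune_budget, nested = FALSE,
                    method = if (cfg$tune_budget > 0) "random_search"
                    else "defaults")
    )
    write_metrics(metrics, file.path(out_dir, "metrics.json"))
    list(report = report, pca = pca)
  })

  excl <- attr(features, "exclusions")
  n_units_in <- nrow(session_units(input$treated))
  manifest <- list(
    package_version = as.character(utils::packageVersion("nocilabel")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg[setdiff(names(cfg), c("treated_path", "untreated_path"))],
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    sub_seeds = sub_seeds,
    counts = list(
      treated_units = n_units_in,
      untreated_units = nrow(session_units(input$untreated)),
      labeled = nrow(labels),
      nociceptor_labels = sum(labels$label == POSITIVE_CLASS),
      features_retained = nrow(features),
      excluded = nrow(excl),
      train = nrow(trained$split$train),
      test = nrow(trained$split$test)
    ),
    test_wells = trained$split$test_wells
  )
  # count conservation across stages
  stopifnot(manifest$counts$labeled == manifest$counts$treated_units,
            manifest$counts$features_retained + manifest$counts$excluded ==
              manifest$counts$treated_units,
            manifest$counts$train + manifest$counts$test ==
              manifest$counts$features_retained)
  write_metrics(manifest, file.path(out_dir, "manifest.json"))
  writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
             file.path(out_dir, "run_timestamp.txt"))

  list(labels = labels, features = features, truth = input$truth,
       split = trained$split, cv = trained$cv,
       model_comparison = trained$comparison, model = trained$model,
       hyperparameters = trained$hyperparameters,
       report = evaluated$report, pca = evaluated$pca,
       manifest = manifest, out_dir = out_dir)
}
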