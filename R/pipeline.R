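#' Configuration of a full modelling run
#'
#' Collects every choice of the end-to-end workflow — preprocessing,
#' descriptor selection, hyperparameter tuning, training, validation,
#' y-randomization, applicability domain and (optionally) screening — into
#' one object consumed by [run_pipeline()]. One master seed derives each
#' stage's seed by a fixed offset, so every stage is individually
#' reproducible.
#'
#' @param table a labelled [descriptor_table()], or `NULL` when
#'   `input_csv` is given.
#' @param input_csv,id_column,label_column CSV input (see
#'   [read_descriptor_table()]).
#' @param model `"skn"` or `"cpann"`.
#' @param scaling `"leak-free"` (fit the scaler on the training split only,
#'   the default) or `"scale-first"` (fit on the full table before
#'   splitting, replicating protocols that scale before partitioning at the
#'   cost of test-statistic leakage).
#' @param correlation_threshold Pearson |r| cutoff of the filter.
#' @param train_fraction training fraction of the split.
#' @param sweep_sizes candidate descriptor counts for the VIP sweep, or
#'   `NULL` to skip the sweep and use `fixed_descriptors`.
#' @param fixed_descriptors descriptor names to use when the sweep is
#'   disabled (`NULL`: all retained descriptors).
#' @param sweep_trainer [classifier_spec()] used inside the sweep.
#' @param cv_folds folds for all cross-validation (default 10).
#' @param sides,epochs hyperparameter grid for map size and epochs; give
#'   single values to skip tuning.
#' @param class_weight SKN class-block weight.
#' @param yrand_iterations y-randomization repeats (reference protocol:
#'   100; `0` disables).
#' @param screening optional list with `background` and `actives`
#'   descriptor tables for a spike-in screen.
#' @param screening_fractions enrichment-factor fractions.
#' @param positive_class class scored in ROC/screening (default: first
#'   class of the label set).
#' @param seed master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(table = NULL, input_csv = NULL,
                            id_column = "id", label_column = "label",
                            model = c("skn", "cpann"),
                            scaling = c("leak-free", "scale-first"),
                            correlation_threshold = 0.90,
                            train_fraction = 0.7,
                            sweep_sizes = 14:35, fixed_descriptors = NULL,
                            sweep_trainer = classifier_spec("pls"),
                            cv_folds = 10, sides = c(6, 8), epochs = c(60),
                            class_weight = 1, yrand_iterations = 100,
                            screening = NULL,
                            screening_fractions = c(0.01, 0.10),
                            positive_class = NULL, seed = 1) {
  model <- match.arg(model)
  scaling <- match.arg(scaling)
  if (is.null(table) && is.null(input_csv))
    stop("provide `table` or `input_csv`")
  structure(
    list(table = table, input_csv = input_csv, id_column = id_column,
         label_column = label_column, model = model, scaling = scaling,
         correlation_threshold = correlation_threshold,
         train_fraction = train_fraction, sweep_sizes = sweep_sizes,
         fixed_descriptors = fixed_descriptors,
         sweep_trainer = sweep_trainer, cv_folds = cv_folds,
         sides = sides, epochs = epochs, class_weight = class_weight,
         yrand_iterations = yrand_iterations, screening = screening,
         screening_fractions = screening_fractions,
         positive_class = positive_class, seed = as.integer(seed)),
    class = "pipeline_config")
}

# Stage-seed derivation: master seed, folded into a safe range, plus a
# documented per-stage offset.
stage_seed <- function(seed, stage) {
  offsets <- c(split = 1L, sweep = 2L, tune = 3L, train = 4L, cv = 5L,
               yrand = 6L)
  (seed %% 10000019L) * 10L + offsets[[stage]]
}

#' Run the full modelling workflow
#'
#' Executes, in order: zero-variance and correlation filtering, scaling
#' (leak-free or full-table order), the 70/30 split, the test-vs-training
#' similarity analysis, VIP descriptor selection (with the model-size sweep
#' unless disabled), map-size/epoch selection by venetian-blinds CV,
#' training of the final SKN or CPANN model, training/CV/test metrics,
#' y-randomization, the leverage applicability domain, and — when screening
#' tables are supplied — the spike-in screen. Every artifact is written as
#' CSV or JSON under `out_dir`, and `manifest.json` records all seeds and
#' settings; re-running the same configuration reproduces every artifact
#' byte-for-byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory results: `filter_report`,
#'   `scaler`, `split`, `similarity`, `sweep`, `selected_descriptors`,
#'   `tuning`, `model`, `metrics` (training/cv/test), `yrand`, `leverage`,
#'   `screening`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  table <- config$table %||%
    read_descriptor_table(config$input_csv, config$id_column,
                          config$label_column)
  if (is.null(table$labels)) stop("stage preprocess: table must be labelled")
  classes <- table$class_names
  positive <- config$positive_class %||% classes[1]

  # -- preprocessing ---------------------------------------------------
  zv <- drop_zero_variance(table)
  cf <- correlation_filter(zv$table, config$correlation_threshold)
  filter_report <- cf$report
  filter_report$removed_zero_variance <- zv$report$removed_zero_variance
  jsonlite::write_json(unclass(filter_report), out("filter_report.json"),
                       auto_unbox = TRUE, digits = NA)
  filtered <- cf$table

  # -- scaling + split -------------------------------------------------
  split_seed <- stage_seed(config$seed, "split")
  if (config$scaling == "scale-first") {
    scaler <- fit_scaler(filtered)
    scaled_all <- apply_scaler(filtered, scaler)
    sp <- split_train_test(scaled_all, config$train_fraction,
                           seed = split_seed)
  } else {
    sp_raw <- split_train_test(filtered, config$train_fraction,
                               seed = split_seed)
    scaler <- fit_scaler(sp_raw$train)
    sp <- sp_raw
    sp$train <- apply_scaler(sp_raw$train, scaler)
    sp$test <- apply_scaler(sp_raw$test, scaler)
  }
  jsonlite::write_json(unclass(scaler), out("scaler.json"),
                       auto_unbox = TRUE, digits = NA)
  sim <- similarity_analysis(sp$test, sp$train)
  write_similarity_report(sim, out("similarity.csv"))

  # -- descriptor selection --------------------------------------------
  sweep <- NULL
  if (!is.null(config$sweep_sizes)) {
    sizes <- config$sweep_sizes[config$sweep_sizes <=
                                  n_descriptors(sp$train)]
    if (!length(sizes))
      stop("stage select: no sweep size fits the ",
           n_descriptors(sp$train), " retained descriptors")
    sweep <- sweep_model_size(sp$train, sizes = sizes,
                              trainer = config$sweep_trainer,
                              cv_folds = config$cv_folds,
                              seed = stage_seed(config$seed, "sweep"))
    selected <- sweep$selected_descriptors
    write_vip_scores(sweep$vip, out("vip.csv"))
    utils::write.csv(
      data.frame(size = sweep$candidate_sizes,
                 cv_non_error_rate = sweep$cv_metric_per_size),
      out("sweep.csv"), row.names = FALSE, quote = FALSE)
  } else {
    selected <- config$fixed_descriptors %||% sp$train$descriptor_names
  }
  train_sel <- subset_descriptors(sp$train, selected)
  test_sel <- subset_descriptors(sp$test, selected)

  # -- hyperparameter tuning + final model -----------------------------
  trainer <- classifier_spec(config$model, class_weight = config$class_weight)
  tuning <- NULL
  if (length(config$sides) > 1 || length(config$epochs) > 1) {
    tuning <- select_hyperparameters(train_sel, trainer,
                                     sides = config$sides,
                                     epochs = config$epochs,
                                     k = config$cv_folds,
                                     seed = stage_seed(config$seed, "tune"))
    trainer$side <- tuning$side; trainer$epochs <- tuning$epochs
  } else {
    trainer$side <- config$sides[1]; trainer$epochs <- config$epochs[1]
  }
  jsonlite::write_json(list(side = trainer$side, epochs = trainer$epochs),
                       out("hyperparameters.json"), auto_unbox = TRUE)
  train_seed <- stage_seed(config$seed, "train")
  model <- fit_classifier(trainer, train_sel, seed = train_seed)
  model$scaler_ref <- scaler
  save_model(model, out("model.json"))

  # -- validation ------------------------------------------------------
  cv <- cross_validate(train_sel, trainer, k = config$cv_folds,
                       seed = stage_seed(config$seed, "cv"))
  pr_train <- stats::predict(model, train_sel)
  pr_test <- stats::predict(model, test_sel)
  metrics <- list(
    training = confusion_metrics(train_sel$labels,
                                 pr_train$predicted_class, classes),
    cv = cv$pooled,
    test = confusion_metrics(test_sel$labels, pr_test$predicted_class,
                             classes))
  for (stage in names(metrics))
    write_metrics(metrics[[stage]], out(sprintf("metrics_%s.csv", stage)),
                  stage = stage)
  roc <- NULL
  if (length(classes) == 2) {
    roc <- roc_curve(test_sel$labels, pr_test$scores[, positive], positive)
    utils::write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr),
                     out("roc_test.csv"), row.names = FALSE, quote = FALSE)
  }
  yrand <- NULL
  if (config$yrand_iterations > 0) {
    full_sel <- subset_descriptors(
      if (config$scaling == "scale-first") scaled_all else
        apply_scaler(filtered, scaler), selected)
    yrand <- y_randomization(full_sel, trainer,
                             n_iterations = config$yrand_iterations,
                             seed = stage_seed(config$seed, "yrand"),
                             train_fraction = config$train_fraction,
                             k = config$cv_folds)
    utils::write.csv(
      data.frame(iteration = seq_len(yrand$n_iterations),
                 train_error = yrand$train_error,
                 cv_error = yrand$cv_error,
                 test_error = yrand$test_error, auc = yrand$auc),
      out("yrand.csv"), row.names = FALSE, quote = FALSE)
  }

  # -- applicability domain + screening --------------------------------
  lev <- leverage(train_sel, test_sel)
  write_leverage_report(lev, out("leverage.csv"))
  screening <- NULL
  if (!is.null(config$screening)) {
    bg <- apply_scaler(config$screening$background, scaler)
    act <- apply_scaler(config$screening$actives, scaler)
    screening <- spike_in_screen(subset_descriptors(bg, selected),
                                 subset_descriptors(act, selected),
                                 model, positive,
                                 fractions = config$screening_fractions)
    write_screening_result(screening, out("screening.csv"))
  }

  manifest <- list(
    model = config$model, scaling = config$scaling,
    correlation_threshold = config$correlation_threshold,
    train_fraction = config$train_fraction,
    sweep = !is.null(config$sweep_sizes),
    sweep_sizes = config$sweep_sizes,
    selected_descriptors = selected,
    side = trainer$side, epochs = trainer$epochs,
    class_weight = config$class_weight, cv_folds = config$cv_folds,
    yrand_iterations = config$yrand_iterations,
    positive_class = positive, master_seed = config$seed,
    stage_seeds = as.list(vapply(c("split", "sweep", "tune", "train", "cv",
                                   "yrand"),
                                 function(s) stage_seed(config$seed, s),
                                 numeric(1))),
    n_molecules = n_molecules(table),
    n_descriptors_input = n_descriptors(table),
    n_descriptors_retained = n_descriptors(filtered))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(filter_report = filter_report, scaler = scaler, split = sp,
                 similarity = sim, sweep = sweep,
                 selected_descriptors = selected, tuning = tuning,
                 model = model, metrics = metrics, roc = roc,
                 yrand = yrand, leverage = lev, screening = screening,
                 manifest = manifest))
}
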