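#' Configuration of a full experiment
#'
#' Describes one end-to-end run: clean, optionally mask, split 8:1:1, build
#' the balanced partition plan, train the n x m classifier grid, reduce the
#' test votes hierarchically, and evaluate against the requested baselines.
#'
#' @param corpus A corpus tibble, or a path to a JSON Lines corpus file.
#' @param workdir Output directory; created if absent, with subdirectories
#'   `corpora/`, `plans/`, `models/`, `predictions/`, `reports/`.
#' @param split_ratios Train/val/test ratios (default 8:1:1).
#' @param n_subsets Number of balanced sub-datasets.
#' @param architectures Base architectures trained on every subset.
#' @param train_overrides Named list of [train_config()] overrides applied to
#'   every architecture (e.g. `list(epochs = 5)`).
#' @param clean Run [clean_corpus()] first?
#' @param cleaning A [cleaning_config()].
#' @param mask Apply the sentence-level mask after cleaning?
#' @param baselines Subset of `c("single", "oversample", "undersample",
#'   "dhe_sd")` to run and report.
#' @param strategy Majority-sampling strategy for [build_partition_plan()].
#' @param seed Master seed; the split, plan, resampling and every model seed
#'   derive from it.
#' @param tie_rule Ensemble tie rule.
#' @return An object of class `dhesd_experiment_config`.
#' @export
experiment_config <- function(corpus, workdir,
                              split_ratios = c(0.8, 0.1, 0.1),
                              n_subsets = 3L,
                              architectures = c("textcnn", "fasttext", "dpcnn"),
                              train_overrides = list(),
                              clean = TRUE, cleaning = cleaning_config(),
                              mask = FALSE,
                              baselines = c("single", "dhe_sd"),
                              strategy = "independent_sample",
                              seed = 1L, tie_rule = "positive") {
  known <- c("single", "oversample", "undersample", "dhe_sd")
  if (!all(baselines %in% known)) {
    stop("baselines must be a subset of: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  ok_arch <- c("textcnn", "fasttext", "dpcnn", "dummy")
  if (!length(architectures) || !all(architectures %in% ok_arch)) {
    stop("architectures must be a non-empty subset of: ",
         paste(ok_arch, collapse = ", "), call. = FALSE)
  }
  structure(
    list(corpus = corpus, workdir = workdir, split_ratios = split_ratios,
         n_subsets = as.integer(n_subsets), architectures = architectures,
         train_overrides = train_overrides, clean = clean,
         cleaning = cleaning, mask = mask, baselines = baselines,
         strategy = strategy, seed = as.integer(seed), tie_rule = tie_rule),
    class = "dhesd_experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror [experiment_config()] arguments; `corpus` must be a file path
#' (resolved relative to the YAML file). A `cleaning:` block is passed to
#' [cleaning_config()].
#'
#' @param path YAML file path.
#' @param overrides Named list taking precedence over the file (flags beat
#'   config beat defaults).
#' @return A `dhesd_experiment_config`.
#' @export
read_experiment_config <- function(path, overrides = list()) {
  raw <- yaml::yaml.load_file(path)
  if (!is.null(raw$corpus) && !grepl("^/", raw$corpus)) {
    raw$corpus <- file.path(dirname(path), raw$corpus)
  }
  if (!is.null(raw$cleaning)) {
    raw$cleaning <- do.call(cleaning_config, raw$cleaning)
  }
  raw[names(overrides)] <- overrides
  known <- names(formals(experiment_config))
  do.call(experiment_config, raw[intersect(names(raw), known)])
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %.2fs %s", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(sprintf("%s=%s", names(list(...)), list(...)),
                        collapse = " ")))
}

#' Run a full experiment
#'
#' Executes the pipeline described by the config and writes every
#' intermediate under `workdir` together with `manifest.json`; replaying the
#' same config reproduces every prediction file exactly. Model training seeds
#' derive deterministically from the master seed, the subset index and the
#' architecture position.
#'
#' For the `"single"` baseline each architecture is trained on the full
#' imbalanced training partition; the one with the best validation F1 is the
#' reported baseline (and is the architecture resampling baselines retrain).
#'
#' @param config A [experiment_config()].
#' @param quiet Suppress per-stage log lines?
#' @return An object of class `dhesd_experiment`: list with `comparison`
#'   (a [compare_methods()] table), `metrics` (per-method metric rows),
#'   `predictions` (named list of prediction tibbles), `classifier_grid`,
#'   `baseline_models`, `plan`, `split`, and `workdir`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "dhesd_experiment_config"))
  t0 <- as.numeric(Sys.time())
  log_ <- function(...) if (!quiet) stage_log(..., t0 = t0)
  wd <- config$workdir
  for (sub in c("corpora", "plans", "models", "predictions", "reports")) {
    dir.create(file.path(wd, sub), recursive = TRUE, showWarnings = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("experiment aborted at stage '%s': %s (partial outputs in %s)",
                   stage, conditionMessage(e), wd), call. = FALSE)
    })
  }

  corpus <- run_stage("load", {
    if (is.character(config$corpus)) read_corpus(config$corpus)
    else validate_corpus(config$corpus)
  })
  log_("load", n_posts = nrow(corpus))

  if (isTRUE(config$clean)) {
    corpus <- run_stage("clean", clean_corpus(corpus, config$cleaning))
    write_removal_tally(corpus, file.path(wd, "reports", "cleaning_tally.tsv"))
    write_corpus(corpus, file.path(wd, "corpora", "clean.jsonl"))
    log_("clean", n_posts = nrow(corpus))
  }
  if (isTRUE(config$mask)) {
    corpus <- run_stage("mask", apply_sentence_mask(corpus))
    write_removal_tally(corpus, file.path(wd, "reports", "mask_tally.tsv"))
    write_corpus(corpus, file.path(wd, "corpora", "masked.jsonl"))
    log_("mask", n_posts = nrow(corpus))
  }

  split <- run_stage("split",
    stratified_split(corpus, config$split_ratios, seed = config$seed))
  write_split(split, file.path(wd, "plans", "split.tsv"))
  train_c <- corpus_partition(corpus, split, "train")
  val_c <- corpus_partition(corpus, split, "val")
  test_c <- corpus_partition(corpus, split, "test")
  log_("split", train = length(unique(train_c$user_id)),
       val = length(unique(val_c$user_id)),
       test = length(unique(test_c$user_id)))

  predictions <- list()
  grid <- NULL
  plan <- NULL
  if ("dhe_sd" %in% config$baselines) {
    plan <- run_stage("partition",
      build_partition_plan(train_c, config$n_subsets, seed = config$seed,
                           strategy = config$strategy))
    write_partition_plan(plan, file.path(wd, "plans", "plan.json"))
    log_("partition", n_subsets = config$n_subsets)

    grid <- run_stage("train", {
      lapply(seq_len(config$n_subsets), function(p) {
        sub_train <- subset_corpus(train_c, plan, p)
        sub_val <- balanced_validation(val_c, plan, p)
        lapply(seq_along(config$architectures), function(q) {
          cfg <- make_train_config(config, config$architectures[[q]],
                                   offset = p * 131L + q)
          clf <- train_base_classifier(sub_train, sub_val, cfg)
          write_classifier(clf, file.path(
            wd, "models", sprintf("subset%d_%s.rds", p,
                                  config$architectures[[q]])))
          log_("train", subset = p, architecture = config$architectures[[q]],
               val_f1 = sprintf("%.4f", clf$validation_f1))
          clf
        })
      })
    })
    pred <- run_stage("predict", run_dhe_sd(grid, test_c, config$tie_rule))
    write_predictions(pred, file.path(wd, "predictions", "dhe_sd.tsv"))
    predictions$dhe_sd <- pred
  }

  baseline_models <- list()
  best_single <- NULL
  if (any(c("single", "oversample", "undersample") %in% config$baselines)) {
    baseline_models <- run_stage("baseline_single", {
      lapply(stats::setNames(config$architectures, config$architectures),
             function(a) {
        cfg <- make_train_config(config, a, offset = 7919L)
        clf <- train_base_classifier(train_c, val_c, cfg)
        log_("baseline_single", architecture = a,
             val_f1 = sprintf("%.4f", clf$validation_f1))
        clf
      })
    })
    f1s <- vapply(baseline_models, function(m) m$validation_f1, 0)
    best_single <- names(f1s)[which.max(f1s)]
    if ("single" %in% config$baselines) {
      pred <- predict_label(baseline_models[[best_single]], test_c)
      write_predictions(pred, file.path(wd, "predictions", "single.tsv"))
      predictions$single <- pred
    }
    if ("oversample" %in% config$baselines) {
      over_c <- oversample_minority(train_c, seed = derive_seed(config$seed, 11L))
      cfg <- make_train_config(config, best_single, offset = 17389L)
      clf <- train_base_classifier(over_c, val_c, cfg)
      pred <- predict_label(clf, test_c)
      write_predictions(pred, file.path(wd, "predictions", "oversample.tsv"))
      predictions$oversample <- pred
      baseline_models$oversample <- clf
      log_("baseline_oversample", architecture = best_single)
    }
    if ("undersample" %in% config$baselines) {
      under_c <- undersample_majority(train_c, seed = derive_seed(config$seed, 13L))
      cfg <- make_train_config(config, best_single, offset = 27449L)
      clf <- train_base_classifier(under_c, val_c, cfg)
      pred <- predict_label(clf, test_c)
      write_predictions(pred, file.path(wd, "predictions", "undersample.tsv"))
      predictions$undersample <- pred
      baseline_models$undersample <- clf
      log_("baseline_undersample", architecture = best_single)
    }
  }

  comparison <- run_stage("evaluate", {
    cmp_runs <- lapply(predictions, function(p)
      p[, c("user_id", "label", ".pred")])
    compare_methods(cmp_runs)
  })
  write_metrics(comparison, file.path(wd, "reports", "comparison.tsv"))
  metrics <- dplyr::bind_rows(lapply(predictions, compute_metrics),
                              .id = "method")
  write_metrics(metrics, file.path(wd, "reports", "metrics.tsv"))
  log_("evaluate", methods = paste(names(predictions), collapse = ","))

  manifest <- list(
    package_version = as.character(utils::packageVersion("dhesd")),
    seed = config$seed, split_ratios = config$split_ratios,
    n_subsets = config$n_subsets, architectures = config$architectures,
    train_overrides = config$train_overrides, clean = config$clean,
    mask = config$mask, baselines = config$baselines,
    strategy = config$strategy, tie_rule = config$tie_rule,
    best_single = best_single,
    outputs = as.list(output_checksums(wd))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(wd, "manifest.json"))

  structure(
    list(comparison = comparison, metrics = metrics,
         predictions = predictions, classifier_grid = grid,
         baseline_models = baseline_models, best_single = best_single,
         plan = plan, split = split, workdir = wd),
    class = "dhesd_experiment"
  )
}

make_train_config <- function(config, architecture, offset) {
  args <- c(list(architecture = architecture,
                 seed = derive_seed(config$seed, offset)),
            config$train_overrides)
  args <- args[!duplicated(names(args))] # overrides may not replace the seed
  do.call(train_config, args)
}

output_checksums <- function(wd) {
  files <- list.files(wd, recursive = TRUE, full.names = TRUE,
                      pattern = "\\.(tsv|jsonl|json)$")
  files <- files[basename(files) != "manifest.json"]
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", wd, "/?"), "", names(sums))
  sums
}

#' @export
print.dhesd_experiment <- function(x, ...) {
  cat("<dhesd_experiment>\n")
  print(as_tibble(x$comparison))
  invisible(x)
}

#' @describeIn run_experiment Per-method metric rows.
#' @param x A `dhesd_experiment`.
#' @param ... Unused.
#' @method tidy dhesd_experiment
#' @export
tidy.dhesd_experiment <- function(x, ...) {
  x$metrics
}

#' @describeIn run_experiment One-row summary of the winning method.
#' @method glance dhesd_experiment
#' @export
glance.dhesd_experiment <- function(x, ...) {
  top <- as_tibble(x$comparison)[1L, ]
  tibble(best_method = top$method, best_f1 = top$f1,
         best_accuracy = top$accuracy,
         n_methods = nrow(x$comparison),
         baseline = x$best_single %||% NA_character_)
}

#' @method autoplot dhesd_experiment
#' @export
autoplot.dhesd_experiment <- function(object, ...) {
  autoplot(object$comparison, ...)
}
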