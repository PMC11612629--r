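# End-to-end orchestration: data source -> filters -> segmentation ->
# split -> feature extraction -> selection (with ablation variants) ->
# classifier evaluation, with deterministic artifacts on disk.

#' Pipeline configuration
#'
#' A single master seed fans out to per-stage seeds by fixed offsets, so
#' one integer reproduces the whole run.
#'
#' @param source `"synthetic"`, `"bonn"`, or `"edf"`.
#' @param paths For `"bonn"`: list with `manifest`, a CSV of
#'   `path,label` rows; for `"edf"`: list with `edf`, `channels`, and
#'   optionally `annotations` (sidecar TSV of seizure intervals).
#' @param n_per_class Records per class for the synthetic source.
#' @param filter A [filter_spec].
#' @param window_len,overlap Segmentation geometry (standard protocol:
#'   1024-sample windows, 64 shared samples). `stride` may be given
#'   instead of `overlap` to interpret the overlap figure as a step size.
#' @param fractions Train/validation/test fractions.
#' @param extraction An [extraction_config].
#' @param swarm A [swarm_config] (its seed is overridden by the fan-out).
#' @param models Character vector of classifier kinds to evaluate.
#' @param ablation `"full_pmpso"`, `"mpso_only"`, `"pearson_only"`, or
#'   `"none"`.
#' @param cv_folds Folds for the cross-validated evaluation.
#' @param seed Master seed.
#' @param out_dir Output directory for artifacts (`NULL` = don't write).
#' @param save_segments Also write the segment table (large; off by
#'   default).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(source = c("synthetic", "bonn", "edf"),
                            paths = list(), n_per_class = 100,
                            filter = filter_spec(),
                            window_len = 1024, overlap = 64, stride = NULL,
                            fractions = c(0.9, 0.05, 0.05),
                            extraction = extraction_config(),
                            swarm = swarm_config(),
                            models = "rf",
                            ablation = c("full_pmpso", "mpso_only",
                                         "pearson_only", "none"),
                            cv_folds = 10, seed = 1L, out_dir = NULL,
                            save_segments = FALSE) {
  source <- match.arg(source)
  ablation <- match.arg(ablation)
  if (!is.null(stride)) overlap <- window_len - stride
  structure(list(source = source, paths = paths, n_per_class = n_per_class,
                 filter = filter, window_len = window_len, overlap = overlap,
                 fractions = fractions, extraction = extraction,
                 swarm = swarm, models = models, ablation = ablation,
                 cv_folds = cv_folds, seed = seed, out_dir = out_dir,
                 save_segments = save_segments),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config]; the
#' `filter`, `extraction`, and `pmpso` keys hold the arguments of
#' [filter_spec], [extraction_config], and [swarm_config].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("source", "paths", "n_per_class",
                                  "window_len", "overlap", "stride",
                                  "fractions", "models", "ablation",
                                  "cv_folds", "seed", "out_dir",
                                  "save_segments"))]
  if (!is.null(y$filter)) args$filter <- do.call(filter_spec, y$filter)
  if (!is.null(y$extraction)) args$extraction <- do.call(extraction_config, y$extraction)
  if (!is.null(y$pmpso)) args$swarm <- do.call(swarm_config, y$pmpso)
  do.call(pipeline_config, args)
}

# djb2 string hash of the serialised config (minus output locations, which
# do not affect the computation), for the run manifest.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$save_segments <- NULL
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE)
  h <- 5381
  for (v in utf8ToInt(as.character(s))) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

load_records <- function(config) {
  switch(config$source,
    synthetic = gen_eeg_dataset(config$n_per_class,
                                seed = derive_seed(config$seed, 4L)),
    bonn = {
      man <- read.csv(config$paths$manifest, stringsAsFactors = FALSE)
      lapply(seq_len(nrow(man)), function(i) {
        read_bonn_record(man$path[i], label = man$label[i])
      })
    },
    edf = read_edf_records(config$paths$edf,
                           channels = config$paths$channels %||% "all"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Univariate ANOVA-style feature ranking
#'
#' Between-class over within-class variance ratio (the one-way ANOVA F
#' statistic) per column; used by the `pearson_only` ablation, which
#' needs a ranking without the swarm stage.
#'
#' @param x Numeric feature matrix with named columns.
#' @param labels Class labels.
#' @return Named vector of F statistics, canonical column order.
#' @export
anova_rank <- function(x, labels) {
  f <- factor(labels)
  k <- nlevels(f)
  n <- length(f)
  vapply(colnames(x), function(j) {
    v <- x[, j]
    gm <- tapply(v, f, mean)
    gn <- tapply(v, f, length)
    ssb <- sum(gn * (gm - mean(v))^2)
    ssw <- sum((v - gm[f])^2)
    if (ssw == 0) return(Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }, numeric(1))
}

# Feature selection under one ablation mode; returns the selected names
# plus whatever stage objects were produced.
select_features <- function(features, cfg, mode) {
  x <- features$x
  labels <- features$labels
  switch(mode,
    none = list(subset = colnames(x), result = NULL),
    full_pmpso = {
      res <- pmpso(features, cfg = cfg)
      list(subset = res$final_subset, result = res)
    },
    mpso_only = {
      run <- run_mpso(x, labels, cfg)
      imp <- feature_importance(run$history, names = colnames(x))
      list(subset = top_k_features(imp, min(cfg$top_k, ncol(x))),
           importance = imp, result = NULL)
    },
    pearson_only = {
      scores <- anova_rank(x, labels)
      ranked <- top_k_features(scores, min(cfg$top_k, ncol(x)))
      filt <- redundancy_filter(x, ranked, cfg$delta)
      list(subset = filt$final_subset, r_table = filt$r_table, result = NULL)
    },
    stop("unknown ablation mode: ", mode))
}

subset_features <- function(fm, subset) {
  feature_matrix(fm$x[, subset, drop = FALSE], fm$labels)
}

#' Run the full pipeline
#'
#' Loads (or generates) records, filters and segments them, splits
#' stratified into train/validation/test, extracts the 35-feature
#' matrix, selects features on the training partition only under the
#' configured ablation mode, and evaluates each configured classifier:
#' cross-validated on the training partition and once on the held-out
#' test partition (trained on train + validation). The test partition is
#' never touched by selection or model fitting before that final step.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with `split` (segment sets), `features`
#'   (per-partition `feature_matrix`), `selection`, `subset`, `reports`
#'   (per classifier: `cv` report and `test` confusion/metrics), and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- load_records(config)
  segsets <- lapply(records, function(r) {
    segment_record(apply_filters(r, config$filter),
                   window_len = config$window_len, overlap = config$overlap)
  })
  segset <- bind_segment_sets(segsets)
  split <- split_segments(segset, config$fractions,
                          seed = derive_seed(config$seed, 1L))
  feats <- lapply(split, extract_feature_matrix, config = config$extraction)

  cfg <- config$swarm
  cfg$seed <- derive_seed(config$seed, 2L)
  selection <- select_features(feats$train, cfg, config$ablation)

  reports <- list()
  for (kind in config$models) {
    spec <- model_spec(kind)
    cv <- kfold_cv(subset_features(feats$train, selection$subset),
                   spec = spec, k = config$cv_folds,
                   seed = derive_seed(config$seed, 3L))
    test_report <- NULL
    if (nrow(feats$test$x) > 0) {
      trval <- feature_matrix(
        rbind(feats$train$x, feats$val$x)[, selection$subset, drop = FALSE],
        c(feats$train$labels, feats$val$labels))
      pred <- train_and_predict(spec, trval$x, trval$labels,
                                feats$test$x[, selection$subset, drop = FALSE])
      cm <- confusion_matrix(feats$test$labels, pred,
                             levels = sort(unique(segset$labels)))
      test_report <- list(confusion = cm,
                          metrics_macro = metrics_from_confusion(cm, "macro"),
                          accuracy = sum(diag(cm)) / sum(cm) * 100)
    }
    reports[[kind]] <- list(cv = cv, test = test_report)
  }

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   source = config$source, ablation = config$ablation,
                   n_segments = nrow(segset$segments),
                   n_features = ncol(feats$train$x),
                   subset = selection$subset,
                   package_version = as.character(utils::packageVersion("eegswarm")))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (config$save_segments) {
      write_segments(segset, file.path(config$out_dir, "segments.csv"))
    }
    write_feature_matrix(feats$train, file.path(config$out_dir, "features_train.csv"))
    if (!is.null(selection$result)) {
      write_selection_result(selection$result,
                             file.path(config$out_dir, "selection.json"))
    }
    for (kind in names(reports)) {
      write_eval_report(reports[[kind]]$cv,
                        file.path(config$out_dir, paste0("eval_", kind, ".json")))
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(split = split, features = feats, selection = selection,
                 subset = selection$subset, reports = reports,
                 manifest = manifest))
}

#' Ablation suite over the four selection variants
#'
#' Runs `none` (all features), `mpso_only`, `pearson_only`, and
#' `full_pmpso` on one feature matrix and cross-validates the same
#' classifier on each selected subset.
#'
#' @param features A `feature_matrix`.
#' @param cfg A [swarm_config].
#' @param spec Classifier to evaluate (default random forest, the
#'   standard ablation classifier).
#' @param k CV folds.
#' @param seed Seed for the evaluation folds.
#' @param modes Ablation modes to run.
#' @return Data frame with one row per mode: subset size and CV
#'   accuracy; the per-mode subsets are attached as the
#'   `"subsets"` attribute.
#' @export
run_ablation <- function(features, cfg = swarm_config(),
                         spec = model_spec("rf"), k = 5, seed = 0L,
                         modes = c("none", "mpso_only", "pearson_only",
                                   "full_pmpso")) {
  rows <- list()
  subsets <- list()
  for (mode in modes) {
    sel <- select_features(features, cfg, mode)
    rep <- kfold_cv(subset_features(features, sel$subset), spec = spec,
                    k = k, seed = seed)
    rows[[mode]] <- data.frame(mode = mode,
                               n_features = length(sel$subset),
                               cv_accuracy = rep$accuracy)
    subsets[[mode]] <- sel$subset
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "subsets") <- subsets
  out
}

#' Compare the constricted selector against a plain-PSO baseline
#'
#' Both selectors share seeds and swarm geometry; the baseline forces
#' the constriction factor to 1 and skips the Pearson stage (its subset
#' is the top-k ranking itself).
#'
#' @param features A `feature_matrix`.
#' @param cfg A [swarm_config].
#' @param selectors Subset of `c("pmpso", "pso_baseline")`.
#' @param k CV folds for evaluating each final subset.
#' @param seed Evaluation fold seed.
#' @return Data frame: selector, subset size, CV accuracy, iterations;
#'   subsets in the `"subsets"` attribute.
#' @export
compare_selectors <- function(features, cfg = swarm_config(),
                              selectors = c("pmpso", "pso_baseline"),
                              k = 5, seed = 0L) {
  rows <- list()
  subsets <- list()
  for (sel in selectors) {
    if (sel == "pmpso") {
      res <- pmpso(features, cfg = cfg)
      subset <- res$final_subset
      iters <- res$swarm$iterations
    } else if (sel == "pso_baseline") {
      cfg_b <- cfg
      cfg_b$constriction <- FALSE
      run <- run_mpso(features$x, features$labels, cfg_b)
      imp <- feature_importance(run$history, names = colnames(features$x))
      subset <- top_k_features(imp, min(cfg$top_k, ncol(features$x)))
      iters <- run$iterations
    } else stop("unknown selector: ", sel)
    rep <- kfold_cv(subset_features(features, subset), spec = model_spec("rf"),
                    k = k, seed = seed)
    rows[[sel]] <- data.frame(selector = sel, n_features = length(subset),
                              cv_accuracy = rep$accuracy, iterations = iters)
    subsets[[sel]] <- subset
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "subsets") <- subsets
  out
}
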