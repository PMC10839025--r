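#' End-to-end pipeline configuration
#'
#' Bundles the defaults of the reference experiment: 50 signals per class of
#' 20 s at 512 Hz, non-overlapping 256-sample epochs (40 images per signal,
#' 4,000 in total), symmetric GASF rescaling, SIFT and ORB extraction, a
#' 100-word vocabulary with frequency histograms, top-10 chi-square feature
#' selection, a stratified 90/10 image-level split, and SVM-RBF / RF / k-NN
#' classifiers.
#'
#' @param n_per_class,duration_s,fs,dataset_seed synthetic dataset settings
#'   (see [synthetic_config()]).
#' @param manifest optional path to a dataset manifest CSV (id, label, path,
#'   fs); when given, signals are read from disk instead of simulated.
#' @param epoch_len,overlap epoching (see [epoching_config()]).
#' @param rescale_mode GASF rescale mode.
#' @param methods feature extractors to run, subset of `c("sift", "orb")`.
#' @param extractor an [extractor_config()] template (method is set per run).
#' @param bow_k,bow_normalization vocabulary size and histogram normalisation.
#' @param k_select number of chi-square-selected features.
#' @param test_frac,stratified,group_by_signal split settings.
#' @param classifiers character vector of classifier kinds.
#' @param snr_grid SNR grid (dB) for the noise sweep.
#' @param noise_n_per_class signals per class for the noise sweep.
#' @param noise_snr_db optional SNR applied to the dataset itself
#'   (`Inf` = clean; used by the retraining variant of the sweep).
#' @param seed global seed; all stage seeds are derived from it.
#' @param out_dir optional artifact directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_class = 50L, duration_s = 20, fs = 512,
                            dataset_seed = NULL, manifest = NULL,
                            epoch_len = 256L, overlap = 0L,
                            rescale_mode = "symmetric",
                            methods = c("sift", "orb"),
                            extractor = extractor_config(),
                            bow_k = 100L,
                            bow_normalization = "frequency",
                            k_select = 10L,
                            test_frac = 0.1, stratified = TRUE,
                            group_by_signal = FALSE,
                            classifiers = c("svm_rbf", "rf", "knn"),
                            snr_grid = c(5, 10, 15, 20),
                            noise_n_per_class = 40L,
                            noise_snr_db = Inf,
                            seed = 1L, out_dir = NULL) {
  methods <- match.arg(methods, c("sift", "orb"), several.ok = TRUE)
  structure(list(
    n_per_class = as.integer(n_per_class), duration_s = duration_s, fs = fs,
    dataset_seed = dataset_seed, manifest = manifest,
    epoch_len = as.integer(epoch_len), overlap = as.integer(overlap),
    rescale_mode = rescale_mode, methods = methods, extractor = extractor,
    bow_k = as.integer(bow_k), bow_normalization = bow_normalization,
    k_select = as.integer(k_select),
    test_frac = test_frac, stratified = stratified,
    group_by_signal = group_by_signal,
    classifiers = classifiers, snr_grid = snr_grid,
    noise_n_per_class = as.integer(noise_n_per_class),
    noise_snr_db = noise_snr_db,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read or write a pipeline configuration as JSON
#'
#' The file representation round-trips losslessly through
#' [pipeline_config()].
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ex <- x$extractor
  x$extractor <- NULL
  if (!is.null(x$noise_snr_db) && is.character(x$noise_snr_db)) {
    x$noise_snr_db <- Inf
  }
  cfg <- do.call(pipeline_config, x)
  if (!is.null(ex)) cfg$extractor <- do.call(extractor_config, as.list(ex))
  cfg
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$extractor <- unclass(x$extractor)
  if (is.infinite(x$noise_snr_db)) x$noise_snr_db <- "Inf"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

load_manifest_signals <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    read_signal(man$path[i], fs = man$fs[i], label = man$label[i],
                id = man$id[i])
  })
}

pipeline_dataset <- function(cfg) {
  if (!is.null(cfg$manifest)) {
    signals <- load_manifest_signals(cfg$manifest)
  } else {
    scfg <- synthetic_config(n_per_class = cfg$n_per_class,
                             duration_s = cfg$duration_s, fs = cfg$fs,
                             seed = cfg$dataset_seed %||% child_seed(cfg$seed, 1L))
    signals <- generate_dataset(scfg)
  }
  if (is.finite(cfg$noise_snr_db)) {
    signals <- lapply(seq_along(signals), function(i) {
      add_noise(signals[[i]], cfg$noise_snr_db,
                seed = child_seed(cfg$seed, 7000L + i))
    })
  }
  signals
}

# GASF-encode a list of signals; returns images plus parallel label/id vectors.
pipeline_images <- function(signals, cfg) {
  ecfg <- epoching_config(cfg$epoch_len, cfg$overlap)
  imgs <- list(); labels <- character(0); ids <- character(0)
  for (s in signals) {
    im <- signal_to_images(s, ecfg, rescale_mode = cfg$rescale_mode)
    imgs <- c(imgs, im)
    labels <- c(labels, rep(s$label %||% NA_character_, length(im)))
    ids <- c(ids, vapply(im, function(g)
      sprintf("%s_e%d", attr(g, "source_id"), attr(g, "epoch_index")), ""))
  }
  list(images = imgs, labels = labels, image_id = ids)
}

apply_selection <- function(table, selected_idx) {
  out <- table
  out$rows <- table$rows[, selected_idx, drop = FALSE]
  out$selected_idx <- selected_idx
  out
}

#' Run the full experiment: simulate, encode, extract, select, classify
#'
#' Executes the complete chain — dataset (synthetic or from a manifest) →
#' epoching + GASF encoding → keypoint extraction per method → vocabulary
#' built on the training partition only → histograms → chi-square selection →
#' classifier training → held-out evaluation — and returns the fitted
#' artifacts plus a tidy summary (one row per method x classifier). Fully
#' reproducible under the global seed. When `cfg$out_dir` is set, reports,
#' the summary CSV and a run manifest (config hash, stage timings, seeds) are
#' written there; a rerun with an unchanged config hash reloads the finished
#' summary instead of recomputing.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage progress.
#' @return a `pipeline_fit` (invisibly reusable by [run_noise_sweep()]).
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  hash <- config_hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  if (!is.null(cfg$out_dir)) {
    mpath <- file.path(cfg$out_dir, "run_manifest.json")
    if (file.exists(mpath)) {
      man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
      spath <- file.path(cfg$out_dir, "summary.csv")
      if (identical(man$config_hash, hash) && file.exists(spath)) {
        if (verbose) message("config hash unchanged; reusing completed run")
        return(structure(list(config = cfg, config_hash = hash, cached = TRUE,
                              summary = utils::read.csv(spath)),
                         class = "pipeline_fit"))
      }
    }
  }
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c(); tick <- function() proc.time()[["elapsed"]]
  t0 <- tick()

  signals <- pipeline_dataset(cfg)
  timings["dataset"] <- tick() - t0; t0 <- tick()
  say("dataset: %d signals", length(signals))

  px <- pipeline_images(signals, cfg)
  timings["gasf"] <- tick() - t0; t0 <- tick()
  say("gasf: %d images of %d x %d", length(px$images),
      cfg$epoch_len, cfg$epoch_len)

  # image-level split, shared across methods
  placeholder <- new_feature_table(matrix(0, length(px$images), 1L),
                                   labels = px$labels, image_id = px$image_id)
  sp <- split_table(placeholder, test_frac = cfg$test_frac,
                    stratified = cfg$stratified,
                    group_by_signal = cfg$group_by_signal,
                    seed = child_seed(cfg$seed, 2L))
  train_ids <- sp$train$image_id
  is_train <- px$image_id %in% train_ids
  say("split: %d train / %d test images", sum(is_train), sum(!is_train))

  methods_out <- list()
  rows <- list()
  for (method in cfg$methods) {
    ecfg <- cfg$extractor; ecfg$method <- method
    dsets <- extract_batch(px$images, ecfg)
    nk <- vapply(dsets, n_descriptors, 0L)
    timings[paste0("extract_", method)] <- tick() - t0; t0 <- tick()
    say("%s: %d keypoints over %d images", method, sum(nk), length(dsets))
    pool_n <- sum(nk[is_train])
    if (pool_n < cfg$bow_k) {
      stop_gasfeeg("gasfeeg_vocab_error",
                   "[%s] training pool has %d descriptors < bow_k = %d",
                   method, pool_n, cfg$bow_k)
    }
    if (pool_n < 10L * cfg$bow_k) {
      warning(sprintf("[%s] small vocabulary pool (%d descriptors for k = %d)",
                      method, pool_n, cfg$bow_k), call. = FALSE)
    }
    vocab <- build_vocabulary(dsets[is_train], k = cfg$bow_k,
                              seed = child_seed(cfg$seed, 3L))
    full <- feature_table(dsets, vocab, px$labels,
                          normalization = cfg$bow_normalization)
    full$image_id <- px$image_id
    train_tab <- subset_table(full, which(is_train))
    test_tab <- subset_table(full, which(!is_train))
    chi2 <- chi2_score(train_tab)
    train_sel <- select_top_k(chi2, train_tab, cfg$k_select)
    test_sel <- apply_selection(test_tab, train_sel$selected_idx)
    timings[paste0("bow_", method)] <- tick() - t0; t0 <- tick()

    models <- list(); reports <- list()
    for (kind in cfg$classifiers) {
      spec <- classifier_spec(kind, seed = child_seed(cfg$seed, 4L))
      models[[kind]] <- train_classifier(spec, train_sel)
      reports[[kind]] <- evaluate_model(models[[kind]], test_sel)
      m <- reports[[kind]]$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, classifier = kind,
        accuracy = m[["acc"]], precision = m[["precision"]],
        recall = m[["recall"]], specificity = m[["specificity"]],
        f1 = m[["f1"]], auc = m[["auc"]], logloss = m[["logloss"]],
        n_test = reports[[kind]]$n_test)
      say("%s/%s: acc=%.3f auc=%.3f", method, kind, m[["acc"]], m[["auc"]])
    }
    timings[paste0("classify_", method)] <- tick() - t0; t0 <- tick()
    methods_out[[method]] <- list(
      vocab = vocab, chi2 = chi2, selected_idx = train_sel$selected_idx,
      models = models, reports = reports,
      frozen_hash = config_hash(list(vocab$centroids, train_sel$selected_idx)))
  }
  summary <- do.call(rbind, rows)

  fit <- structure(list(
    config = cfg, config_hash = hash, cached = FALSE,
    summary = summary, methods = methods_out,
    split = list(train_ids = train_ids, test_ids = sp$test$image_id),
    timings = timings), class = "pipeline_fit")

  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(fit)
  fit
}

write_pipeline_artifacts <- function(fit) {
  dir <- fit$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(summary = file.path(dir, "summary.csv"))
  utils::write.csv(fit$summary, paths["summary"], row.names = FALSE)
  for (method in names(fit$methods)) {
    mo <- fit$methods[[method]]
    vp <- file.path(dir, sprintf("vocabulary_%s.csv", method))
    utils::write.csv(mo$vocab$centroids, vp, row.names = FALSE)
    paths[paste0("vocab_", method)] <- vp
    for (kind in names(mo$reports)) {
      rp <- file.path(dir, sprintf("report_%s_%s.json", method, kind))
      report_to_json(mo$reports[[kind]], rp)
      paths[paste0("report_", method, "_", kind)] <- rp
    }
  }
  manifest <- list(config_hash = fit$config_hash,
                   package_version = as.character(utils::packageVersion("gasfeeg")),
                   seed = fit$config$seed,
                   timings_s = as.list(round(fit$timings, 3)),
                   artifacts = as.list(paths))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
print.pipeline_fit <- function(x, ...) {
  cat(sprintf("<pipeline_fit> hash=%s%s\n", x$config_hash,
              if (isTRUE(x$cached)) " (cached)" else ""))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Noise-robustness sweep over an SNR grid
#'
#' Generates a fresh balanced set of evaluation signals, corrupts them with
#' Gaussian noise at each SNR in the grid, pushes them through the frozen
#' pipeline (the vocabulary, the selected features and the trained
#' classifiers from `fit` are reused, never refit), and reports per-class
#' one-vs-rest accuracy and F1 for each method. `Inf` in the grid is the
#' no-noise sentinel. With `retrain = TRUE` the whole pipeline is instead
#' re-run per SNR on noise-corrupted training data.
#'
#' @param fit a non-cached [run_pipeline()] result.
#' @param snr_grid SNR values in dB (default from the fit's config:
#'   5, 10, 15, 20).
#' @param n_per_class evaluation signals per class (default from config: 40).
#' @param classifier which trained classifier to use (default `"rf"`).
#' @param seed seed for the evaluation signals and noise draws.
#' @param retrain refit the pipeline on corrupted data at each SNR.
#' @param verbose print progress.
#' @return a `noise_sweep` data.frame: method, positive_class, snr_db,
#'   accuracy, f1, n_images.
#' @export
run_noise_sweep <- function(fit, snr_grid = NULL, n_per_class = NULL,
                            classifier = "rf", seed = NULL, retrain = FALSE,
                            verbose = FALSE) {
  stopifnot(inherits(fit, "pipeline_fit"))
  if (isTRUE(fit$cached)) {
    stop_gasfeeg("gasfeeg_sweep_error",
                 "cached fit has no frozen model artifacts; rerun the pipeline")
  }
  cfg <- fit$config
  snr_grid <- snr_grid %||% cfg$snr_grid
  n_per_class <- n_per_class %||% cfg$noise_n_per_class
  seed <- seed %||% child_seed(cfg$seed, 5L)

  if (retrain) return(noise_sweep_retrain(cfg, snr_grid, classifier, verbose))

  # frozen-artifact contract: recompute and compare the fingerprints
  for (method in names(fit$methods)) {
    mo <- fit$methods[[method]]
    stopifnot(identical(mo$frozen_hash,
                        config_hash(list(mo$vocab$centroids, mo$selected_idx))))
    if (!classifier %in% names(mo$models)) {
      stop_gasfeeg("gasfeeg_sweep_error",
                   "classifier '%s' was not trained in the clean run", classifier)
    }
  }

  scfg <- synthetic_config(n_per_class = n_per_class,
                           duration_s = cfg$duration_s, fs = cfg$fs,
                           seed = child_seed(seed, 1L))
  eval_signals <- generate_dataset(scfg)
  ecfg <- epoching_config(cfg$epoch_len, cfg$overlap)

  rows <- list()
  for (snr in snr_grid) {
    noisy <- lapply(seq_along(eval_signals), function(i) {
      add_noise(eval_signals[[i]], snr, seed = child_seed(seed, 100L + i))
    })
    px <- pipeline_images(noisy, cfg)
    for (method in names(fit$methods)) {
      mo <- fit$methods[[method]]
      ecfg2 <- cfg$extractor; ecfg2$method <- method
      dsets <- extract_batch(px$images, ecfg2)
      tab <- feature_table(dsets, mo$vocab, px$labels,
                           normalization = cfg$bow_normalization)
      tab$image_id <- px$image_id
      tab <- apply_selection(tab, mo$selected_idx)
      for (pos in c("normal", "focal")) {
        rep <- evaluate_model(mo$models[[classifier]], tab,
                              positive_class = pos)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, positive_class = pos, snr_db = snr,
          accuracy = rep$metrics[["acc"]], f1 = rep$metrics[["f1"]],
          n_images = rep$n_test)
      }
      if (verbose) message(sprintf("snr=%s dB, %s done", format(snr), method))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "classifier") <- classifier
  attr(out, "interpretation") <-
    "per-class rows are one-vs-rest metrics with that class as positive"
  class(out) <- c("noise_sweep", class(out))
  out
}

noise_sweep_retrain <- function(cfg, snr_grid, classifier, verbose) {
  rows <- list()
  for (snr in snr_grid) {
    cfg2 <- cfg
    cfg2$noise_snr_db <- snr
    cfg2$out_dir <- NULL
    f <- run_pipeline(cfg2, verbose = verbose)
    sub <- f$summary[f$summary$classifier == classifier, ]
    for (i in seq_len(nrow(sub))) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = sub$method[i], positive_class = "focal", snr_db = snr,
        accuracy = sub$accuracy[i], f1 = sub$f1[i], n_images = sub$n_test[i])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "classifier") <- classifier
  attr(out, "interpretation") <- "pipeline refit per SNR (retrain = TRUE)"
  class(out) <- c("noise_sweep", class(out))
  out
}

#' Reshape a noise sweep into the metrics-by-SNR table layout
#'
#' One row per method x class x metric, one column per SNR.
#'
#' @param sweep a [run_noise_sweep()] result.
#' @return a data.frame with `method`, `positive_class`, `metric` and one
#'   `snr_<value>` column per grid point.
#' @export
noise_sweep_table <- function(sweep) {
  snrs <- sort(unique(sweep$snr_db))
  combos <- unique(sweep[, c("method", "positive_class")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    for (metric in c("accuracy", "f1")) {
      sub <- sweep[sweep$method == combos$method[i] &
                     sweep$positive_class == combos$positive_class[i], ]
      vals <- vapply(snrs, function(s) sub[[metric]][sub$snr_db == s][1], 0)
      row <- data.frame(method = combos$method[i],
                        positive_class = combos$positive_class[i],
                        metric = metric)
      for (j in seq_along(snrs)) {
        row[[sprintf("snr_%s", format(snrs[j]))]] <- vals[j]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
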