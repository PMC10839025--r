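#' Classifier specification
#'
#' Three classifier families are supported: RBF-kernel SVM, random forest,
#' and k-nearest neighbours. Hyperparameters default to the standard
#' settings: `knn_k = 5`; `rf_ntree = 100` with unlimited depth; SVM
#' `cost = 1` and `gamma = 1 / (n_features * var(X))` (the "scale" heuristic)
#' when `gamma = NULL`. Fits are deterministic under `seed`. k-NN is
#' implemented in-package with a tie-inclusive neighbourhood (all training
#' points within the k-th smallest distance vote), so duplicate feature rows
#' -- common in selected bag-of-words histograms -- never require random tie
#' breaking.
#'
#' @param kind `"svm_rbf"`, `"rf"`, or `"knn"`.
#' @param cost,gamma SVM hyperparameters.
#' @param rf_ntree,rf_maxnodes random-forest hyperparameters.
#' @param knn_k neighbour count.
#' @param seed integer seed.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "rf", "knn"),
                            cost = 1, gamma = NULL,
                            rf_ntree = 100L, rf_maxnodes = NULL,
                            knn_k = 5L, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, cost = cost, gamma = gamma,
                 rf_ntree = as.integer(rf_ntree), rf_maxnodes = rf_maxnodes,
                 knn_k = as.integer(knn_k), seed = as.integer(seed)),
            class = "classifier_spec")
}

table_group <- function(table) sub("_e[0-9]+$", "", table$image_id)

subset_table <- function(table, idx) {
  out <- table
  out$rows <- table$rows[idx, , drop = FALSE]
  out$labels <- table$labels[idx]
  out$image_id <- table$image_id[idx]
  out
}

#' Split a feature table into train and test partitions
#'
#' Stratified by label by default (the reference setting: 4,000 images split
#' 90/10 into 3,600 train and 400 test). With `group_by_signal`, whole
#' signals (all epochs sharing an image-id prefix before `_e<k>`) are
#' assigned to one partition, which avoids epoch-level leakage between the
#' partitions.
#'
#' @param table a `feature_table`.
#' @param test_frac test fraction in (0, 1); default 0.1.
#' @param stratified preserve class proportions.
#' @param group_by_signal keep all epochs of a signal together.
#' @param seed integer seed.
#' @return list with `train` and `test` feature tables.
#' @export
split_table <- function(table, test_frac = 0.1, stratified = TRUE,
                        group_by_signal = FALSE, seed = 1L) {
  if (test_frac <= 0 || test_frac >= 1) {
    stop_gasfeeg("gasfeeg_split_error", "test_frac must be in (0, 1)")
  }
  n <- nrow(table$rows)
  test_idx <- with_seed(seed, {
    if (group_by_signal) {
      grp <- table_group(table)
      glab <- tapply(table$labels, grp, function(l) l[1])
      picked <- character(0)
      units <- if (stratified) split(names(glab), unname(glab)) else list(names(glab))
      for (u in units) {
        m <- max(1L, round(length(u) * test_frac))
        picked <- c(picked, sample(u, m))
      }
      which(grp %in% picked)
    } else {
      units <- if (stratified) split(seq_len(n), table$labels) else list(seq_len(n))
      unlist(lapply(units, function(ii) {
        sample(ii, max(1L, round(length(ii) * test_frac)))
      }), use.names = FALSE)
    }
  })
  train <- subset_table(table, setdiff(seq_len(n), test_idx))
  test <- subset_table(table, sort(test_idx))
  cls <- unique(table$labels)
  if (!all(cls %in% train$labels) || !all(cls %in% test$labels)) {
    stop_gasfeeg("gasfeeg_split_error",
                 "a class is absent from one partition; adjust test_frac")
  }
  list(train = train, test = test)
}

#' Train a classifier on a feature table
#'
#' Returns an opaque fitted model plus training metadata; refitting with the
#' same seed reproduces predictions exactly. For the RBF SVM, a Platt
#' calibration (logistic fit of the training labels on the decision values)
#' is attached so probabilities and log-loss are available.
#'
#' @param spec a [classifier_spec()].
#' @param table a training `feature_table` with two classes.
#' @return a `gasfeeg_model`.
#' @export
train_classifier <- function(spec, table) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(table, "feature_table"))
  x <- table$rows
  lev <- sort(unique(table$labels))
  if (length(lev) < 2L) {
    stop_gasfeeg("gasfeeg_training_error", "training data has a single class")
  }
  y <- factor(table$labels, levels = lev)
  fit <- platt <- NULL
  if (spec$kind == "svm_rbf") {
    gamma <- spec$gamma
    if (is.null(gamma)) {
      v <- stats::var(as.vector(x))
      gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
    }
    fit <- with_seed(spec$seed,
      e1071::svm(x, y, kernel = "radial", cost = spec$cost, gamma = gamma,
                 scale = FALSE))
    d <- as.numeric(attr(stats::predict(fit, x, decision.values = TRUE),
                         "decision.values"))
    y01 <- as.integer(y == lev[2])
    platt <- suppressWarnings(
      stats::glm(y01 ~ d, family = stats::binomial(),
                 data = data.frame(d = d, y01 = y01)))
  } else if (spec$kind == "rf") {
    fit <- with_seed(spec$seed,
      randomForest::randomForest(x, y, ntree = spec$rf_ntree,
                                 maxnodes = spec$rf_maxnodes))
  } else { # knn stores its training data
    fit <- list(x = x, y = y)
  }
  structure(list(spec = spec, fit = fit, platt = platt, levels = lev,
                 features = colnames(x),
                 selected_idx = table$selected_idx),
            class = "gasfeeg_model")
}

#' @export
print.gasfeeg_model <- function(x, ...) {
  cat(sprintf("<gasfeeg_model> %s on %d feature(s), classes: %s\n",
              x$spec$kind, length(x$features), paste(x$levels, collapse = "/")))
  invisible(x)
}

#' Predicted probability of a class for each row of a feature table
#'
#' @param model a [train_classifier()] fit.
#' @param table a `feature_table` with matching feature columns.
#' @param positive_class the label whose probability is returned.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_scores <- function(model, table, positive_class = model$levels[2]) {
  stopifnot(inherits(model, "gasfeeg_model"))
  x <- table$rows
  if (!identical(colnames(x), model$features)) {
    stop_gasfeeg("gasfeeg_evaluation_error",
                 "feature columns do not match the model's training features")
  }
  if (!positive_class %in% model$levels) {
    stop_gasfeeg("gasfeeg_evaluation_error",
                 "positive_class '%s' was not in training labels", positive_class)
  }
  lev <- model$levels
  # models may arrive deserialized (readRDS) in a session where the fitting
  # package's namespace, and hence its S3 predict method, is not yet loaded
  ns <- c(svm_rbf = "e1071", rf = "randomForest")[model$spec$kind]
  if (!is.na(ns)) loadNamespace(ns)
  p2 <- switch(model$spec$kind,
    svm_rbf = {
      d <- as.numeric(attr(stats::predict(model$fit, x, decision.values = TRUE),
                           "decision.values"))
      as.numeric(stats::predict(model$platt, newdata = data.frame(d = d),
                                type = "response"))
    },
    rf = {
      pr <- stats::predict(model$fit, x, type = "prob")
      as.numeric(pr[, lev[2]])
    },
    knn = {
      # deterministic k-NN: the neighbourhood is every training point within
      # the k-th smallest distance (ties included), the score its class-2
      # vote fraction; distance ties therefore never need to be broken
      tx <- model$fit$x
      ty <- model$fit$y == lev[2]
      k <- min(model$spec$knn_k, nrow(tx))
      d2 <- outer(rowSums(x^2), rep(1, nrow(tx))) - 2 * x %*% t(tx) +
        outer(rep(1, nrow(x)), rowSums(tx^2))
      apply(d2, 1, function(dr) {
        kd <- sort(dr, partial = k)[k]
        mean(ty[dr <= kd + 1e-12])
      })
    })
  if (positive_class == lev[2]) p2 else 1 - p2
}

#' ROC curve points from scores and labels
#'
#' Thresholds sweep the distinct scores in descending order; duplicate points
#' are removed and the endpoints (0,0) and (1,1) are always present.
#'
#' @param scores numeric score per observation (higher = more positive).
#' @param labels class labels.
#' @param positive_class label treated as positive.
#' @return data.frame with columns `fpr`, `tpr`, nondecreasing in both.
#' @export
roc_curve <- function(scores, labels, positive_class) {
  y <- labels == positive_class
  np <- sum(y); nn <- sum(!y)
  if (np == 0 || nn == 0) {
    stop_gasfeeg("gasfeeg_roc_error",
                 "ROC needs at least one positive and one negative")
  }
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  keep <- c(diff(ss) != 0, TRUE) # last index of each distinct score
  pts <- data.frame(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
  pts <- unique(pts)
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  }
  pts
}

#' Trapezoidal area under an ROC curve
#'
#' @param roc_points data.frame from [roc_curve()], or `NULL` to build it
#'   from `scores`/`labels`/`positive_class`.
#' @param scores,labels,positive_class used when `roc_points` is `NULL`.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc_points = NULL, scores = NULL, labels = NULL,
                          positive_class = NULL) {
  if (is.null(roc_points)) {
    roc_points <- roc_curve(scores, labels, positive_class)
  }
  sum(diff(roc_points$fpr) *
        (utils::head(roc_points$tpr, -1) + utils::tail(roc_points$tpr, -1)) / 2)
}

#' Metric suite from confusion counts
#'
#' acc = (TP+TN)/N; precision = TP/(TP+FP); recall = TP/(TP+FN);
#' specificity = TN/(TN+FP); f1 = 2PR/(P+R). A zero denominator yields 0 and
#' sets the corresponding name in the `undefined` attribute.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return named numeric vector with an `undefined` character attribute.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  m <- c(acc = safe(tp + tn, tp + tn + fp + fn),
         precision = safe(tp, tp + fp),
         recall = safe(tp, tp + fn),
         specificity = safe(tn, tn + fp))
  pr <- m[["precision"]]; rc <- m[["recall"]]
  m[["f1"]] <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  und <- character(0)
  if (tp + fp == 0) und <- c(und, "precision")
  if (tp + fn == 0) und <- c(und, "recall")
  if (tn + fp == 0) und <- c(und, "specificity")
  if (m[["precision"]] + m[["recall"]] == 0) und <- c(und, "f1")
  attr(m, "undefined") <- und
  m
}

#' Evaluate a fitted model on a test feature table
#'
#' Predictions use the positive-class probability at threshold 0.5. The
#' report carries the confusion counts, accuracy / precision / recall /
#' specificity / F1, trapezoidal AUC over the score-swept ROC, log-loss with
#' probabilities clipped to `[1e-15, 1 - 1e-15]`, and the ROC points.
#'
#' @param model a `gasfeeg_model`.
#' @param table a test `feature_table`.
#' @param positive_class label treated as positive (default `"focal"` when
#'   present).
#' @return an `evaluation_report`.
#' @export
evaluate_model <- function(model, table,
                           positive_class = if ("focal" %in% model$levels)
                             "focal" else model$levels[2]) {
  if (nrow(table$rows) == 0L) {
    stop_gasfeeg("gasfeeg_evaluation_error", "empty test table")
  }
  p <- predict_scores(model, table, positive_class)
  y <- table$labels == positive_class
  pred <- p >= 0.5
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  metrics <- confusion_metrics(tp, fp, tn, fn)
  roc <- roc_curve(p, table$labels, positive_class)
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  logloss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  structure(list(
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    metrics = c(metrics, auc = auc_trapezoid(roc), logloss = logloss),
    undefined = attr(metrics, "undefined"),
    roc_points = roc,
    positive_class = positive_class,
    n_test = nrow(table$rows),
    classifier = model$spec$kind),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, n=%d, positive='%s'\n",
              x$classifier, x$n_test, x$positive_class))
  cm <- x$confusion
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", cm["tp"], cm["fp"], cm["tn"], cm["fn"]))
  print(round(x$metrics, 4))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path optional output file.
#' @return the JSON string, invisibly if written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(classifier = report$classifier,
              positive_class = report$positive_class,
              n_test = report$n_test,
              confusion = as.list(report$confusion),
              metrics = as.list(report$metrics),
              undefined = report$undefined,
              roc_points = report$roc_points)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
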