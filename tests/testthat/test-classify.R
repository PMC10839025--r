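# two separable Gaussian point clouds as a feature table
separable_table <- function(n_per_class = 50, p = 4, gap = 8, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, mean = gap), n_per_class))
  x <- x - min(x) # keep features nonnegative like BoW histograms
  make_table(x, rep(c("normal", "focal"), each = n_per_class),
             image_id = sprintf("sig%03d_e1", seq_len(2 * n_per_class)))
}

test_that("the 90/10 stratified split reproduces the reference partition sizes", {
  tab <- make_table(matrix(runif(4000 * 3), 4000),
                    labels = rep(c("normal", "focal"), each = 2000),
                    image_id = sprintf("%s_%03d_e%d",
                                       rep(c("normal", "focal"), each = 2000),
                                       rep(rep(1:50, each = 40), 2),
                                       rep(1:40, 100)))
  sp <- split_table(tab, test_frac = 0.1, seed = 3)
  expect_equal(nrow(sp$train$rows), 3600)
  expect_equal(nrow(sp$test$rows), 400)
  expect_equal(sum(sp$test$labels == "normal"), 200) # stratification
  expect_length(intersect(sp$train$image_id, sp$test$image_id), 0)
})

test_that("grouped splitting keeps all epochs of a signal together", {
  # 2 classes x 5 signals x 40 epochs = 400 rows
  ids <- sprintf("%s_%02d_e%d", rep(c("normal", "focal"), each = 200),
                 rep(rep(1:5, each = 40), 2), rep(1:40, 10))
  tab <- make_table(matrix(runif(400 * 2), 400),
                    labels = rep(c("normal", "focal"), each = 200),
                    image_id = ids)
  sp <- split_table(tab, 0.1, group_by_signal = TRUE, seed = 2)
  test_sigs <- unique(sub("_e[0-9]+$", "", sp$test$image_id))
  expect_equal(length(test_sigs), 2) # max(1, round(5 * 0.1)) signal per class
  expect_equal(nrow(sp$test$rows), 2 * 40) # all 40 epochs of each
  train_sigs <- unique(sub("_e[0-9]+$", "", sp$train$image_id))
  expect_length(intersect(train_sigs, test_sigs), 0)
})

test_that("splits are deterministic under seed and fail when a class vanishes", {
  tab <- separable_table(20)
  a <- split_table(tab, 0.2, seed = 5)
  b <- split_table(tab, 0.2, seed = 5)
  expect_identical(a$test$image_id, b$test$image_id)
  lop <- make_table(matrix(runif(8), 4), c("a", "a", "a", "b"))
  expect_error(split_table(lop, 0.25, seed = 1), class = "gasfeeg_split_error")
  expect_error(split_table(tab, 1.2), class = "gasfeeg_split_error")
})

test_that("all three classifiers separate linearly separable clouds perfectly", {
  tab <- separable_table(30)
  for (kind in c("svm_rbf", "rf", "knn")) {
    model <- train_classifier(classifier_spec(kind, seed = 7), tab)
    p <- predict_scores(model, tab, "focal")
    pred <- ifelse(p >= 0.5, "focal", "normal")
    expect_equal(mean(pred == tab$labels), 1.0)
  }
})

test_that("1-NN reproduces its own training labels", {
  tab <- separable_table(15, gap = 2, seed = 3)
  model <- train_classifier(classifier_spec("knn", knn_k = 1), tab)
  p <- predict_scores(model, tab, "focal")
  expect_equal(ifelse(p >= 0.5, "focal", "normal"), tab$labels)
})

test_that("random-forest fits are reproducible under a fixed seed", {
  tab <- separable_table(25, gap = 1.5, seed = 9)
  test <- separable_table(25, gap = 1.5, seed = 10)
  m1 <- train_classifier(classifier_spec("rf", seed = 11), tab)
  m2 <- train_classifier(classifier_spec("rf", seed = 11), tab)
  expect_identical(predict_scores(m1, test, "focal"),
                   predict_scores(m2, test, "focal"))
})

test_that("single-class training data is rejected", {
  tab <- make_table(matrix(runif(10), 5), rep("a", 5))
  expect_error(train_classifier(classifier_spec("rf"), tab),
               class = "gasfeeg_training_error")
})

test_that("the metric suite matches hand evaluation of the formulas", {
  m <- confusion_metrics(tp = 40, fp = 5, tn = 45, fn = 10)
  expect_equal(round(m[["acc"]], 4), 0.85)
  expect_equal(round(m[["precision"]], 4), 0.8889)
  expect_equal(round(m[["recall"]], 4), 0.80)
  expect_equal(round(m[["specificity"]], 4), 0.90)
  expect_equal(round(m[["f1"]], 4), 0.8421)
  perfect <- confusion_metrics(50, 0, 50, 0)
  expect_true(all(perfect[c("acc", "precision", "recall",
                            "specificity", "f1")] == 1))
})

test_that("zero denominators report 0 with an undefined flag", {
  m <- confusion_metrics(tp = 0, fp = 0, tn = 10, fn = 5)
  expect_equal(m[["precision"]], 0)
  expect_true("precision" %in% attr(m, "undefined"))
})

test_that("the 4-score concordance example gives AUC 0.75", {
  scores <- c(0.9, 0.4, 0.8, 0.2)
  labels <- c("pos", "pos", "neg", "neg")
  # oracle: pairwise concordance count — 3 of the 4 (pos, neg) pairs ordered
  pos <- scores[labels == "pos"]; neg <- scores[labels == "neg"]
  conc <- mean(outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`))
  expect_equal(conc, 0.75)
  expect_equal(auc_trapezoid(scores = scores, labels = labels,
                             positive_class = "pos"), 0.75)
})

test_that("ROC endpoints, degenerate ties, and perfect ranking behave", {
  r <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c("p", "p", "n", "n"), "p")
  expect_equal(r[1, ], data.frame(fpr = 0, tpr = 0), ignore_attr = TRUE)
  expect_equal(unlist(r[nrow(r), ]), c(fpr = 1, tpr = 1))
  expect_true(any(r$fpr == 0 & r$tpr == 1)) # passes through (0,1)
  expect_equal(auc_trapezoid(r), 1.0)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))

  tied <- roc_curve(c(0.5, 0.5, 0.5, 0.5), c("p", "p", "n", "n"), "p")
  expect_equal(tied, data.frame(fpr = c(0, 1), tpr = c(0, 1)),
               ignore_attr = TRUE)
  expect_equal(auc_trapezoid(tied), 0.5)
  expect_error(roc_curve(1:3, c("p", "p", "p"), "p"), class = "gasfeeg_roc_error")
})

test_that("AUC agrees with an independent implementation and is rank-invariant", {
  set.seed(13)
  scores <- runif(60)
  labels <- ifelse(runif(60) < plogis(6 * (scores - 0.5)), "p", "n")
  expect_setequal(unique(labels), c("p", "n")) # seed yields both classes
  ours <- auc_trapezoid(scores = scores, labels = labels, positive_class = "p")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
  # strictly monotone transform leaves AUC unchanged
  expect_equal(auc_trapezoid(scores = exp(3 * scores), labels = labels,
                             positive_class = "p"), ours, tolerance = 1e-12)
})

test_that("f1 is bracketed by precision and recall", {
  set.seed(4)
  for (i in 1:20) {
    cm <- rmultinom(1, 100, rep(0.25, 4))
    m <- confusion_metrics(cm[1], cm[2], cm[3], cm[4])
    pr <- m[["precision"]]; rc <- m[["recall"]]
    if (pr + rc > 0) {
      expect_gte(m[["f1"]], min(pr, rc) - 1e-12)
      expect_lte(m[["f1"]], max(pr, rc) + 1e-12)
    }
    if (pr == rc) expect_equal(m[["f1"]], pr)
  }
})

test_that("swapping the positive class swaps recall/specificity and TP/TN", {
  tab <- separable_table(20, gap = 1, seed = 21)
  model <- train_classifier(classifier_spec("rf", seed = 2), tab)
  test <- separable_table(20, gap = 1, seed = 22)
  rf <- evaluate_model(model, test, positive_class = "focal")
  rn <- evaluate_model(model, test, positive_class = "normal")
  expect_equal(rf$confusion[["tp"]], rn$confusion[["tn"]])
  expect_equal(rf$confusion[["fp"]], rn$confusion[["fn"]])
  expect_equal(rf$metrics[["recall"]], rn$metrics[["specificity"]])
  expect_equal(rf$metrics[["specificity"]], rn$metrics[["recall"]])
  expect_equal(rf$metrics[["acc"]], rn$metrics[["acc"]])
})

test_that("evaluation reports are complete and serialise to JSON", {
  tab <- separable_table(20)
  model <- train_classifier(classifier_spec("svm_rbf"), tab)
  rep <- evaluate_model(model, tab)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(sum(rep$confusion), nrow(tab$rows))
  expect_true(all(rep$metrics[c("acc", "precision", "recall", "specificity",
                                "f1", "auc")] >= 0 &
                  rep$metrics[c("acc", "precision", "recall", "specificity",
                                "f1", "auc")] <= 1))
  expect_gte(rep$metrics[["logloss"]], 0)
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(js$metrics$acc, rep$metrics[["acc"]])
  expect_equal(js$confusion$tp, unname(rep$confusion["tp"]))
})
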