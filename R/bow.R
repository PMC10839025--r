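#' Build a visual-word vocabulary by k-means over pooled descriptors
#'
#' Descriptors from all supplied sets are pooled (ORB bytes are unpacked to
#' 0/1 dimensions so centroids live in a real vector space), canonically
#' sorted so the result does not depend on the order of the sets, seeded with
#' k-means++ under `seed`, and clustered with Lloyd iterations via
#' [stats::kmeans()]. The vocabulary must be built from training-split
#' descriptors only; test images are encoded against the frozen centroids.
#'
#' @param descriptor_sets list of `descriptor_set`s (one method throughout).
#' @param k number of visual words (reference setting: 100).
#' @param seed integer seed; fixed seed gives a deterministic vocabulary.
#' @param iter_max Lloyd iteration cap.
#' @param max_pool cluster at most this many pooled descriptors; a larger
#'   pool is subsampled deterministically under `seed` (0 = no cap).
#' @return a `bow_vocabulary`: `centroids` (k x width), `method`, `k`,
#'   `seed`, `training_hash`.
#' @export
build_vocabulary <- function(descriptor_sets, k = 100L, seed = 1L,
                             iter_max = 20L, max_pool = 10000L) {
  methods <- unique(vapply(descriptor_sets, `[[`, "", "method"))
  if (length(methods) != 1L) {
    stop_gasfeeg("gasfeeg_vocab_error",
                 "descriptor sets mix methods: %s", paste(methods, collapse = ","))
  }
  mats <- lapply(descriptor_sets, descriptor_matrix)
  mats <- mats[vapply(mats, nrow, 0L) > 0L]
  if (length(mats) == 0L) {
    stop_gasfeeg("gasfeeg_vocab_error", "no descriptors in training pool")
  }
  pool <- do.call(rbind, mats)
  if (nrow(pool) < k) {
    stop_gasfeeg("gasfeeg_vocab_error",
                 "%d pooled descriptors < k = %d; use a smaller vocabulary",
                 nrow(pool), k)
  }
  # canonical row order: invariant to descriptor-set order
  pool <- pool[do.call(order, as.data.frame(pool)), , drop = FALSE]
  dimnames(pool) <- NULL
  if (max_pool > 0L && nrow(pool) > max_pool) {
    keep <- with_seed(child_seed(seed, 99L),
                      sort(sample.int(nrow(pool), max_pool)))
    pool <- pool[keep, , drop = FALSE]
  }

  fit <- NULL
  for (attempt in 1:5) {
    init <- with_seed(child_seed(seed, attempt), kmeanspp_init(pool, k))
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(pool, centers = init,
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop_gasfeeg("gasfeeg_vocab_error",
                 "k-means failed to produce %d non-empty clusters", k)
  }
  structure(list(centroids = unname(fit$centers), method = methods, k = as.integer(k),
                 seed = as.integer(seed), training_hash = config_hash(pool)),
            class = "bow_vocabulary")
}

# k-means++ seeding: first centre uniform, subsequent centres sampled with
# probability proportional to squared distance to the nearest chosen centre.
# Caller provides the RNG state.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  rs <- rowSums(x^2)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- pmax(0, rs - 2 * drop(x %*% centers[1L, ]) + sum(centers[1L, ]^2))
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1L) # all points coincide with a centre
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, pmax(0, rs - 2 * drop(x %*% centers[j, ]) +
                          sum(centers[j, ]^2)))
  }
  centers
}

#' @export
print.bow_vocabulary <- function(x, ...) {
  cat(sprintf("<bow_vocabulary> %s, k=%d, width=%d, seed=%d\n",
              toupper(x$method), x$k, ncol(x$centroids), x$seed))
  invisible(x)
}

#' Encode a descriptor set as a visual-word histogram
#'
#' Each descriptor is assigned to its nearest centroid (Euclidean distance;
#' ties go to the lowest word index). `"count"` rows sum to the descriptor
#' count; `"frequency"` rows are L1-normalised (an image with no keypoints
#' encodes as the all-zero row in either mode).
#'
#' @param dset a `descriptor_set`.
#' @param vocab a [build_vocabulary()] result of the same method.
#' @param normalization `"frequency"` (default) or `"count"`.
#' @return numeric vector of length `vocab$k`.
#' @export
bow_encode <- function(dset, vocab, normalization = c("frequency", "count")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(dset, "descriptor_set"), inherits(vocab, "bow_vocabulary"))
  d <- descriptor_matrix(dset)
  if (ncol(d) > 0 && ncol(d) != ncol(vocab$centroids)) {
    stop_gasfeeg("gasfeeg_encoding_error",
                 "descriptor width %d does not match vocabulary width %d",
                 ncol(d), ncol(vocab$centroids))
  }
  h <- numeric(vocab$k)
  if (nrow(d) > 0) {
    cc <- vocab$centroids
    d2 <- outer(rowSums(d^2), rep(1, vocab$k)) +
      outer(rep(1, nrow(d)), rowSums(cc^2)) - 2 * d %*% t(cc)
    assign <- max.col(-d2, ties.method = "first")
    tab <- tabulate(assign, nbins = vocab$k)
    h <- as.numeric(tab)
    if (normalization == "frequency") h <- h / sum(h)
  }
  h
}

#' Assemble a feature table of visual-word histograms
#'
#' @param descriptor_sets list of `descriptor_set`s.
#' @param vocab a `bow_vocabulary`.
#' @param labels class label per image (length matches the sets).
#' @param normalization passed to [bow_encode()].
#' @return a `feature_table`: `rows` (matrix, columns `word_000...`),
#'   `labels`, `image_id`, `normalization`, `selected_idx` (NULL until
#'   [select_top_k()]).
#' @export
feature_table <- function(descriptor_sets, vocab, labels,
                          normalization = c("frequency", "count")) {
  normalization <- match.arg(normalization)
  stopifnot(length(labels) == length(descriptor_sets))
  rows <- t(vapply(descriptor_sets, bow_encode, numeric(vocab$k),
                   vocab = vocab, normalization = normalization))
  colnames(rows) <- sprintf("word_%03d", seq_len(vocab$k) - 1L)
  structure(list(rows = rows, labels = as.character(labels),
                 image_id = vapply(descriptor_sets, `[[`, "", "image_id"),
                 normalization = normalization, selected_idx = NULL),
            class = "feature_table")
}

new_feature_table <- function(rows, labels, image_id = NULL,
                              normalization = "count", selected_idx = NULL) {
  rows <- as.matrix(rows)
  if (is.null(colnames(rows))) {
    colnames(rows) <- sprintf("word_%03d", seq_len(ncol(rows)) - 1L)
  }
  structure(list(rows = rows, labels = as.character(labels),
                 image_id = image_id %||% sprintf("img_%d", seq_len(nrow(rows))),
                 normalization = normalization, selected_idx = selected_idx),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d images x %d features (%s)%s\n",
              nrow(x$rows), ncol(x$rows), x$normalization,
              if (is.null(x$selected_idx)) "" else
                sprintf(", %d selected", length(x$selected_idx))))
  invisible(x)
}

#' Chi-square association score between each feature and the class labels
#'
#' For feature f with per-class mass `obs_c` (sum of the feature over rows of
#' class c) and class proportions `n_c / n`, the score is
#' `sum_c (obs_c - exp_c)^2 / exp_c` with `exp_c = sum_c(obs_c) * n_c / n` —
#' the standard feature-selection generalisation that treats nonnegative
#' feature values as weights. p-values use the chi-square distribution with
#' `classes - 1` degrees of freedom. A feature with zero total mass scores 0.
#'
#' @param table a `feature_table` with at least two classes.
#' @return a `chi2_result`: `scores`, `p_values`, `ranking` (1-based feature
#'   indices by descending score, ties to the lower index).
#' @export
chi2_score <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$rows < 0)) {
    stop_gasfeeg("gasfeeg_scoring_error", "feature values must be nonnegative")
  }
  cls <- unique(table$labels)
  if (length(cls) < 2L) {
    stop_gasfeeg("gasfeeg_scoring_error",
                 "chi-square scoring needs at least two classes")
  }
  n <- length(table$labels)
  prop <- vapply(cls, function(c) sum(table$labels == c) / n, 0)
  obs <- rowsum(table$rows, group = factor(table$labels, levels = cls))
  tot <- colSums(obs)
  expd <- outer(prop, tot) # classes x features
  dev <- (obs - expd)^2 / expd
  scores <- colSums(dev)
  scores[tot == 0] <- 0
  pv <- stats::pchisq(scores, df = length(cls) - 1L, lower.tail = FALSE)
  pv[tot == 0] <- 1
  structure(list(scores = unname(scores), p_values = unname(pv),
                 ranking = order(-scores, seq_along(scores))),
            class = "chi2_result")
}

#' Retain the top-scoring feature columns
#'
#' Keeps the `k_select` features with the highest chi-square scores (ties
#' broken toward the lower index), preserving their original column order,
#' and records them in `selected_idx`. The reference setting keeps the top
#' 10 of 100 visual words.
#'
#' @param result a [chi2_score()] result for `table`.
#' @param table the `feature_table` to reduce.
#' @param k_select number of features to retain (`1 <= k_select <= ncol`).
#' @return the reduced `feature_table`.
#' @export
select_top_k <- function(result, table, k_select = 10L) {
  stopifnot(inherits(result, "chi2_result"), inherits(table, "feature_table"))
  p <- ncol(table$rows)
  if (k_select < 1L || k_select > p) {
    stop_gasfeeg("gasfeeg_selection_error",
                 "k_select = %d out of range [1, %d]", k_select, p)
  }
  keep <- sort(result$ranking[seq_len(k_select)])
  out <- table
  out$rows <- table$rows[, keep, drop = FALSE]
  prev <- table$selected_idx %||% seq_len(p)
  out$selected_idx <- prev[keep]
  out
}
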