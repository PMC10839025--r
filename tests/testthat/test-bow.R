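test_that("identical descriptors collapse to a single-centroid vocabulary", {
  d <- matrix(rep(c(1, 0, 1, 1), each = 20), nrow = 20)
  v <- build_vocabulary(list(fake_dset(d)), k = 1, seed = 1)
  expect_equal(unname(v$centroids), matrix(c(1, 0, 1, 1), 1), tolerance = 1e-12)
})

test_that("two well-separated clusters are recovered at k = 2 (tiny-Lloyd oracle)", {
  set.seed(8)
  m1 <- c(0, 0); m2 <- c(20, 20)
  x1 <- sweep(matrix(rnorm(60), 30), 2, m1, `+`)
  x2 <- sweep(matrix(rnorm(60), 30), 2, m2, `+`)
  # oracle: exact Lloyd by hand from both possible seedings converges to the
  # same two centres
  lloyd <- function(init) {
    cen <- init
    for (i in 1:50) {
      d1 <- rowSums(sweep(rbind(x1, x2), 2, cen[1, ])^2)
      d2 <- rowSums(sweep(rbind(x1, x2), 2, cen[2, ])^2)
      g <- ifelse(d1 <= d2, 1, 2)
      cen <- rbind(colMeans(rbind(x1, x2)[g == 1, , drop = FALSE]),
                   colMeans(rbind(x1, x2)[g == 2, , drop = FALSE]))
    }
    cen
  }
  o1 <- lloyd(rbind(x1[1, ], x2[1, ]))
  o2 <- lloyd(rbind(x2[5, ], x1[5, ]))
  oracle <- o1[order(o1[, 1]), ]
  expect_equal(oracle, o2[order(o2[, 1]), ], tolerance = 1e-9)

  v <- build_vocabulary(list(fake_dset(x1), fake_dset(x2)), k = 2, seed = 4)
  cen <- v$centroids[order(v$centroids[, 1]), ]
  expect_lt(sqrt(sum((cen[1, ] - oracle[1, ])^2)), 1.0)
  expect_lt(sqrt(sum((cen[2, ] - oracle[2, ])^2)), 1.0)
})

test_that("vocabulary construction is deterministic and set-order invariant", {
  set.seed(5)
  sets <- lapply(1:6, function(i) fake_dset(matrix(rnorm(40), 10)))
  v1 <- build_vocabulary(sets, k = 3, seed = 9)
  v2 <- build_vocabulary(sets, k = 3, seed = 9)
  v3 <- build_vocabulary(rev(sets), k = 3, seed = 9)
  expect_identical(v1$centroids, v2$centroids)
  expect_identical(v1$centroids, v3$centroids)
})

test_that("too few pooled descriptors raises a vocabulary error", {
  expect_error(build_vocabulary(list(fake_dset(matrix(rnorm(8), 2))), k = 5),
               "smaller", class = "gasfeeg_vocab_error")
})

test_that("histograms assign to the nearest word with exhaustive-search agreement", {
  set.seed(6)
  cen <- matrix(rnorm(10 * 4), 10)
  vocab <- structure(list(centroids = cen, method = "sift", k = 10L,
                          seed = 1L, training_hash = "x"),
                     class = "bow_vocabulary")
  # three descriptors placed near words 3, 3 and 8 (1-based)
  d <- rbind(cen[3, ] + 0.01, cen[3, ] - 0.01, cen[8, ] + 0.01)
  # oracle: exhaustive nearest centroid
  nearest <- apply(d, 1, function(r) which.min(colSums((t(cen) - r)^2)))
  expect_equal(nearest, c(3, 3, 8))
  h <- bow_encode(fake_dset(d), vocab, "count")
  expect_equal(h[3], 2)
  expect_equal(h[8], 1)
  expect_equal(sum(h), 3)
  hf <- bow_encode(fake_dset(d), vocab, "frequency")
  expect_equal(hf[3], 2 / 3)
  expect_equal(hf[8], 1 / 3)
  expect_equal(sum(hf), 1)
})

test_that("an empty descriptor set encodes as the zero histogram", {
  vocab <- structure(list(centroids = matrix(rnorm(8), 2), method = "sift",
                          k = 2L, seed = 1L, training_hash = "x"),
                     class = "bow_vocabulary")
  empty <- fake_dset(matrix(numeric(0), 0, 4))
  expect_equal(bow_encode(empty, vocab, "count"), c(0, 0))
  expect_equal(bow_encode(empty, vocab, "frequency"), c(0, 0))
})

test_that("count histograms conserve the descriptor count", {
  set.seed(7)
  vocab <- structure(list(centroids = matrix(rnorm(5 * 6), 5), method = "sift",
                          k = 5L, seed = 1L, training_hash = "x"),
                     class = "bow_vocabulary")
  for (n in c(1, 17, 250)) {
    d <- fake_dset(matrix(rnorm(n * 6), n))
    expect_equal(sum(bow_encode(d, vocab, "count")), n)
  }
})

test_that("descriptor-width mismatches are rejected at encoding", {
  vocab <- structure(list(centroids = matrix(0, 2, 4), method = "sift",
                          k = 2L, seed = 1L, training_hash = "x"),
                     class = "bow_vocabulary")
  expect_error(bow_encode(fake_dset(matrix(0, 3, 5)), vocab),
               class = "gasfeeg_encoding_error")
})

test_that("chi-square scores match the hand-worked contingency example", {
  tab <- make_table(cbind(A = c(0, 0, 5, 5), B = c(3, 3, 3, 3)),
                    labels = c("0", "0", "1", "1"))
  res <- chi2_score(tab)
  # feature A: obs (0, 10), exp (5, 5) -> 5 + 5 = 10
  expect_equal(res$scores, c(10, 0))
  expect_equal(res$ranking[1], 1)
  expect_equal(res$p_values[1], pchisq(10, 1, lower.tail = FALSE))
  # permuting rows leaves scores unchanged (class sums only)
  perm <- make_table(cbind(A = c(5, 0, 5, 0), B = c(3, 3, 3, 3)),
                     labels = c("1", "0", "1", "0"))
  expect_equal(chi2_score(perm)$scores, res$scores)
})

test_that("chi-square scoring rejects single-class and negative tables", {
  expect_error(chi2_score(make_table(matrix(1, 3, 2), c("a", "a", "a"))),
               class = "gasfeeg_scoring_error")
  expect_error(chi2_score(make_table(matrix(-1, 4, 2), c("a", "a", "b", "b"))),
               class = "gasfeeg_scoring_error")
})

test_that("zero-mass features score zero and rank last", {
  tab <- make_table(cbind(c(1, 0, 3, 1), c(0, 0, 0, 0)),
                    labels = c("a", "a", "b", "b"))
  res <- chi2_score(tab)
  expect_equal(res$scores[2], 0)
  expect_equal(res$p_values[2], 1)
  expect_equal(res$ranking, c(1L, 2L))
})

test_that("top-k selection keeps the highest scorers and is idempotent", {
  tab <- make_table(cbind(A = c(0, 0, 5, 5), B = c(3, 3, 3, 3)),
                    labels = c("0", "0", "1", "1"))
  res <- chi2_score(tab)
  sel <- select_top_k(res, tab, 1)
  expect_equal(colnames(sel$rows), "A")
  expect_equal(sel$selected_idx, 1L)
  # identity selection keeps everything and records indices
  all2 <- select_top_k(res, tab, 2)
  expect_equal(all2$rows, tab$rows)
  expect_equal(all2$selected_idx, 1:2)
  # idempotence
  res2 <- chi2_score(sel)
  expect_equal(select_top_k(res2, sel, 1)$rows, sel$rows)
  expect_error(select_top_k(res, tab, 3), class = "gasfeeg_selection_error")
})

test_that("ties in chi-square scores break toward the lower feature index", {
  tab <- make_table(cbind(c(0, 0, 4, 4), c(0, 0, 4, 4), c(1, 1, 1, 1)),
                    labels = c("a", "a", "b", "b"))
  res <- chi2_score(tab)
  expect_equal(res$scores[1], res$scores[2])
  expect_equal(res$ranking[1:2], c(1L, 2L))
  expect_equal(select_top_k(res, tab, 1)$selected_idx, 1L)
})
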