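test_that("cosine matches the closed form and rejects zero vectors", {
  expect_equal(cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine(c(2, 2), c(1, 1)), 1)
  expect_equal(cosine(c(2, 0), c(1, 1)), 1 / sqrt(2), tolerance = 1e-8)
  expect_error(cosine(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine(c(1, 0), c(1, 1, 1)), "length")
})

test_that("neurocognitive projection equals the brute-force cosine oracle", {
  emb <- toy_embedding(n = 7L, d = 5L, seed = 3L)
  anchors <- list(alpha = c("w01", "w02"), beta = c("w03", "w04"))
  sp <- neurocognitive_space(emb, anchors)
  expect_setequal(rownames(sp$matrix), c("w05", "w06", "w07"))
  expect_identical(colnames(sp$matrix), c("alpha", "beta"))
  for (tg in rownames(sp$matrix)) for (d in names(anchors)) {
    oracle <- mean(vapply(anchors[[d]], function(a)
      cos_oracle(emb$vectors[tg, ], emb$vectors[a, ]), 0))
    expect_equal(sp$matrix[tg, d], oracle, tolerance = 1e-10)
  }
  # anchor-overlapping targets are dropped and reported
  expect_setequal(sp$anchor_metadata$dropped_targets,
                  c("w01", "w02", "w03", "w04"))
  # a dimension with no available anchors is an error naming it
  expect_error(neurocognitive_space(emb, list(alpha = "w01", ghost = "nope")),
               "ghost")
  # missing anchors are averaged over, not imputed
  sp2 <- neurocognitive_space(emb, list(alpha = c("w01", "absent"), beta = "w03"))
  expect_equal(sp2$anchor_metadata$n_available, c(alpha = 1L, beta = 1L))
})

test_that("13-dimension anchor specs give 13 columns", {
  emb <- toy_embedding(n = 40L, d = 6L, seed = 9L)
  anchors <- split(sprintf("w%02d", 1:26), rep(paste0("dim", 1:13), each = 2))
  sp <- neurocognitive_space(emb, anchors)
  expect_equal(ncol(sp$matrix), 13L)
})

test_that("global space is the all-pairs cosine matrix with self removed", {
  emb <- toy_embedding(n = 5L, d = 4L, seed = 11L)
  sp <- distributional_global_space(emb)
  oracle <- cos_mat_oracle(emb$vectors, emb$vectors)
  diag(oracle) <- NA_real_
  expect_equal(sp$matrix, oracle, tolerance = 1e-10)
  expect_equal(sp$matrix["w01", "w02"], sp$matrix["w02", "w01"])
  expect_equal(sum(!is.na(sp$matrix["w03", ])), 4L)
})

test_that("local model anchors are the exhaustive k-nearest neighbours", {
  emb <- toy_embedding(n = 6L, d = 4L, seed = 13L)
  nb <- local_anchor_sets(emb, k = 2L)
  cm <- cos_mat_oracle(emb$vectors, emb$vectors)
  for (w in rownames(cm)) {
    others <- setdiff(rownames(cm), w)
    oracle <- others[order(cm[w, others], decreasing = TRUE)][1:2]
    expect_setequal(nb[[w]], oracle)
  }
})

test_that("local model on identical embedding tables gives perfect correlation", {
  emb <- toy_embedding(n = 8L, d = 5L, seed = 17L)
  res <- distributional_local_ilc(emb, emb, k = 3L)
  expect_true(all(abs(tanh(res$per_concept_z) - 1) < 1e-6))
  expect_warning(distributional_local_ilc(emb, emb, k = 100L), "fewer than k")
})

test_that("feature space equals the brute-force cosine table", {
  emb <- toy_embedding(n = 7L, d = 4L, seed = 19L)
  feats <- c("w05", "w06", "w07")
  sp <- feature_space(emb, feats, n_features = 3L,
                      targets = c("w01", "w02", "w03", "w04"))
  oracle <- cos_mat_oracle(emb$vectors[sprintf("w%02d", 1:4), ],
                           emb$vectors[feats, ])
  expect_equal(unname(sp$matrix), unname(oracle), tolerance = 1e-10)
  # orthogonal features give a zero row
  m <- rbind(t1 = c(1, 0, 0, 0), f1 = c(0, 1, 0, 0), f2 = c(0, 0, 1, 0))
  sp0 <- feature_space(embedding_table(m), c("f1", "f2"), 2L, "t1")
  expect_equal(unname(sp0$matrix["t1", ]), c(0, 0))
})

test_that("random-word anchors are reproducible under a seed and uniform over concepts", {
  concepts <- sprintf("c%03d", 1:50)
  set.seed(5); a1 <- sample_random_anchors(concepts, 13)
  set.seed(5); a2 <- sample_random_anchors(concepts, 13)
  expect_identical(a1, a2)
  set.seed(6)
  counts <- table(factor(replicate(2000, sample_random_anchors(concepts, 13)),
                         levels = concepts))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("neurocognitive space with one anchor per dimension equals the random-word space", {
  emb <- toy_embedding(n = 20L, d = 5L, seed = 23L)
  anchors13 <- sprintf("w%02d", 1:13)
  neuro <- neurocognitive_space(
    emb, stats::setNames(as.list(anchors13), paste0("d", 1:13)))
  rand <- random_word_space(emb, anchors13)
  expect_equal(unname(neuro$matrix), unname(rand$matrix[rownames(neuro$matrix), ]),
               tolerance = 1e-12)
})

test_that("random-dimension model recovers planted blobs and degenerates to random-word", {
  # 10 anchor words in 2 well-separated blobs: K-means must recover them
  set.seed(31)
  blob <- rbind(matrix(stats::rnorm(5 * 4, 0, 0.05), 5, 4),
                matrix(stats::rnorm(5 * 4, 10, 0.05), 5, 4))
  rownames(blob) <- sprintf("w%02d", 1:10)
  extra <- matrix(stats::rnorm(4 * 4), 4, 4,
                  dimnames = list(sprintf("t%d", 1:4), NULL))
  emb <- embedding_table(rbind(blob, extra), "A")
  got <- NULL
  # force the sampler to pick exactly the 10 blob words by restricting the pool
  emb_set <- list(A = embedding_table(rbind(blob, extra), "A"),
                  B = embedding_table(rbind(blob, extra), "B"))
  set.seed(1)
  sp <- random_dimension_space(emb_set, targets = sprintf("t%d", 1:4),
                               n_words = 14L, n_clusters = 2L)
  groups <- sp$A$anchor_metadata$groups
  blob_groups <- groups[intersect(names(groups), rownames(blob))]
  # blob members must never straddle clusters when both blobs are sampled
  g1 <- blob_groups[names(blob_groups) %in% sprintf("w%02d", 1:5)]
  g2 <- blob_groups[names(blob_groups) %in% sprintf("w%02d", 6:10)]
  if (length(g1) && length(g2)) expect_true(all(g1 != g2[1]))

  # n_clusters == n_words: each pseudo-dimension is one word
  set.seed(2)
  sp1 <- random_dimension_space(emb_set, targets = sprintf("t%d", 1:4),
                                n_words = 5L, n_clusters = 5L)
  anchor_ids <- names(sp1$A$anchor_metadata$groups)
  rw <- random_word_space(emb_set$A, anchor_ids, targets = sprintf("t%d", 1:4))
  expect_equal(sort(as.vector(sp1$A$matrix)), sort(as.vector(rw$matrix)),
               tolerance = 1e-12)
})

test_that("projections are invariant to positive rescaling of embedding vectors", {
  emb <- toy_embedding(n = 8L, d = 4L, seed = 37L)
  scaled <- emb$vectors * stats::runif(8, 0.5, 3)
  anchors <- list(a = c("w01", "w02"), b = c("w03", "w04"))
  s1 <- neurocognitive_space(emb, anchors)
  s2 <- neurocognitive_space(embedding_table(scaled), anchors)
  expect_equal(s1$matrix, s2$matrix, tolerance = 1e-12)
  # anchor order within a dimension is irrelevant
  s3 <- neurocognitive_space(emb, list(a = c("w02", "w01"), b = c("w04", "w03")))
  expect_equal(s1$matrix, s3$matrix, tolerance = 1e-12)
})
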