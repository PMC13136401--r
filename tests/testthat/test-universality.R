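test_that("fisher_z is the clipped atanh and odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-7)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_error(fisher_z(NaN), "NA")
})

test_that("ilc equals a direct per-concept correlation oracle", {
  set.seed(41)
  a <- matrix(stats::rnorm(20), 4, 5, dimnames = list(paste0("c", 1:4), NULL))
  b <- matrix(stats::rnorm(20), 4, 5, dimnames = list(paste0("c", 1:4), NULL))
  res <- ilc(a, b)
  oracle <- mean(vapply(1:4, function(i)
    atanh(min(max(stats::cor(a[i, ], b[i, ]), -(1 - 1e-7)), 1 - 1e-7)), 0))
  expect_equal(res$mean_z, oracle, tolerance = 1e-10)

  # identical spaces hit the clipping bound; sign flip negates the mean
  expect_equal(ilc(a, a)$mean_z, atanh(1 - 1e-7))
  expect_equal(ilc(a, -a)$mean_z, -ilc(a, a)$mean_z)

  # zero-variance rows are skipped with a count
  a2 <- a; a2[2, ] <- 1
  res2 <- ilc(a2, b)
  expect_equal(res2$n_skipped, 1L)
  expect_equal(length(res2$per_concept_z), 3L)
})

test_that("ilc_matrix fast path agrees with the pairwise path", {
  set.seed(43)
  spaces <- lapply(1:4, function(i)
    matrix(stats::rnorm(30), 6, 5, dimnames = list(paste0("c", 1:6), NULL)))
  names(spaces) <- paste0("L", 1:4)
  fast <- ilc_matrix(spaces)
  slow <- vapply(1:3, function(i) ilc(spaces[[i]], spaces[[4]])$mean_z, 0)
  expect_equal(unname(fast$z[4, 1:3]), slow, tolerance = 1e-12)
  expect_equal(fast$z, t(fast$z))
})

test_that("paired Wilcoxon comparison matches an exhaustive signed-rank computation", {
  a <- c(0.9, 0.5, 0.8, 0.3, 0.7, 0.6, 0.45, 0.85)
  b <- c(0.4, 0.6, 0.2, 0.35, 0.3, 0.5, 0.40, 0.30)
  res <- compare_models(a, b)
  d <- a - b
  v_oracle <- sum(rank(abs(d))[d > 0])
  expect_equal(res$V, v_oracle)
  expect_equal(res$n, 8L)
  expect_true(res$ci[1] <= res$median_diff && res$median_diff <= res$ci[2])

  expect_warning(res0 <- compare_models(a, a), "zero")
  expect_equal(res0$p, 1)

  fam <- compare_model_family(list(x = list(a = a, b = b),
                                   y = list(a = a, b = a + 0.01)))
  expect_equal(fam$q, stats::p.adjust(fam$p, "BH"))
})

test_that("PCA universality: identity, isotropy limit, and eigen oracle", {
  set.seed(47)
  base <- matrix(stats::rnorm(60), 12, 5, dimnames = list(paste0("c", 1:12), NULL))
  identical_langs <- list(A = base, B = base, C = base)
  expect_equal(pca_universality(identical_langs)$pc1_share, 1, tolerance = 1e-10)

  # independent languages approach 1/L
  shares <- vapply(1:10, function(s) {
    set.seed(100 + s)
    spaces <- lapply(1:3, function(i)
      matrix(stats::rnorm(1000), 200, 5, dimnames = list(paste0("c", 1:200), NULL)))
    names(spaces) <- paste0("L", 1:3)
    pca_universality(spaces)$pc1_share
  }, 0)
  expect_lt(abs(mean(shares) - 1 / 3), 0.05)

  # eigen oracle on a small matrix
  spaces <- lapply(1:6, function(i)
    matrix(stats::rnorm(8), 4, 2, dimnames = list(paste0("c", 1:4), NULL)))
  names(spaces) <- paste0("L", 1:6)
  got <- pca_universality(spaces)
  X <- vapply(spaces, as.vector, numeric(8))
  ev <- eigen(stats::cor(X))$values
  expect_equal(got$pc1_share, ev[1] / sum(ev), tolerance = 1e-8)

  # invariance to relabeling languages
  expect_equal(pca_universality(rev(spaces))$pc1_share, got$pc1_share,
               tolerance = 1e-10)
})

test_that("null_benchmark uses the +1 permutation convention", {
  set.seed(53)
  nulls <- stats::rnorm(199)
  nb <- null_benchmark(max(nulls) + 1, function(i) nulls[i], n_iters = 199L)
  expect_equal(nb$one_tailed_p, 1 / 200)
  nb2 <- null_benchmark(min(nulls) - 1, function(i) nulls[i], n_iters = 199L)
  expect_equal(nb2$one_tailed_p, 1)
  expect_true(nb$one_tailed_p > 0)
})

test_that("inter-subject correlation matrix matches the direct oracle", {
  ratings <- toy_ratings(n_lang = 2L, n_part = 2L, noise = 0.5, seed = 59L)
  ism <- intersubject_matrix(ratings)
  m1 <- ratings$rating[ratings$participant == "p01"]
  m2 <- ratings$rating[ratings$participant == "p02"]
  expect_equal(ism$r["p01", "p02"], stats::cor(m1, m2), tolerance = 1e-10)
  # a duplicated participant correlates at 1
  dup <- ratings[ratings$participant == "p01", ]
  dup$participant <- "p99"
  ism2 <- intersubject_matrix(rbind(ratings, dup))
  expect_equal(ism2$r["p01", "p99"], 1)
  # constant raters are excluded with a warning
  flat <- dup; flat$participant <- "p98"; flat$rating <- 3
  expect_warning(ism3 <- intersubject_matrix(rbind(ratings, flat)), "constant")
  expect_false("p98" %in% rownames(ism3$r))
})

test_that("QC filter excludes a planted pure-noise rater at threshold 0.5", {
  ratings <- toy_ratings(n_lang = 2L, n_part = 5L, noise = 0.2, seed = 61L)
  noisy <- ratings[ratings$participant == "p01", ]
  set.seed(62)
  noisy$rating <- stats::runif(nrow(noisy), 0, 6)
  ratings <- rbind(ratings[ratings$participant != "p01", ], noisy)
  qc <- qc_filter(ratings, threshold = 0.5)
  expect_true("p01" %in% qc$excluded)
  expect_false(any(paste0("p0", 2:5) %in% qc$excluded))
  # identical raters are all retained
  same <- toy_ratings(n_lang = 2L, n_part = 3L, noise = 0, seed = 63L)
  expect_equal(length(qc_filter(same)$excluded), 0L)
})

test_that("variance components: shares sum to one, limits and ordering hold", {
  # noiseless, language-free: universal share -> 1
  r0 <- toy_ratings(n_lang = 3L, n_part = 3L, noise = 0, seed = 67L)
  mu <- tapply(r0$rating, paste(r0$concept_id, r0$dimension), mean)
  r0$rating <- mu[paste(r0$concept_id, r0$dimension)]
  vc0 <- variance_components(r0)
  expect_equal(vc0$universal_share, 1, tolerance = 1e-10)
  expect_equal(vc0$universal_share + vc0$language_share + vc0$residual_share, 1,
               tolerance = 1e-9)

  # language effect variance 4x rater variance: language share > residual share
  set.seed(68)
  rows <- expand.grid(l = 1:4, p = 1:4, c = 1:30, d = 1:3)
  cell_mu <- array(stats::runif(30 * 3, 1, 5), c(30, 3))
  lang_dev <- array(stats::rnorm(4 * 30 * 3, 0, 1), c(4, 30, 3))
  rat <- data.frame(
    participant = sprintf("p%d_%d", rows$l, rows$p),
    language_code = sprintf("L%d", rows$l),
    concept_id = sprintf("c%d", rows$c),
    dimension = sprintf("d%d", rows$d),
    rating = cell_mu[cbind(rows$c, rows$d)] +
      lang_dev[cbind(rows$l, rows$c, rows$d)] +
      stats::rnorm(nrow(rows), 0, 0.5))
  vc <- variance_components(rat)
  expect_gt(vc$language_share, vc$residual_share)
  expect_equal(vc$universal_share + vc$language_share + vc$residual_share, 1,
               tolerance = 1e-9)
})
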