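test_that("semantic RDM matches the 1 - fisher_z(r) oracle", {
  set.seed(109)
  base <- matrix(stats::rnorm(40), 8, 5, dimnames = list(paste0("c", 1:8), NULL))
  spaces <- list(A = base,
                 B = base + matrix(stats::rnorm(40, 0, 0.5), 8, 5),
                 C = matrix(stats::rnorm(40), 8, 5,
                            dimnames = list(paste0("c", 1:8), NULL)))
  d <- semantic_rdm(spaces)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    r <- stats::cor(as.vector(spaces[[pair[1]]]), as.vector(spaces[[pair[2]]]))
    expect_equal(d[pair[1], pair[2]], 1 - atanh(r), tolerance = 1e-10)
  }
  # identical languages sit at the matrix minimum; r = 0 maps to exactly 1
  d2 <- semantic_rdm(list(A = base, B = base))
  expect_equal(d2["A", "B"], 1 - atanh(1 - 1e-7))
  u <- matrix(c(1, -1, 1, -1), 2, 2, dimnames = list(c("c1", "c2"), NULL))
  v <- matrix(c(1, 1, -1, -1), 2, 2, dimnames = list(c("c1", "c2"), NULL))
  expect_equal(semantic_rdm(list(A = u, B = v), min_cells = 4)["A", "B"], 1)
})

test_that("neural RDM is 1 - Pearson between language-mean patterns", {
  set.seed(113)
  pat <- matrix(stats::rnorm(8 * 20), 8, 20)
  langs <- rep(c("A", "B", "C", "D"), each = 2)
  d <- neural_rdm(pat, langs)
  means <- rbind(colMeans(pat[1:2, ]), colMeans(pat[3:4, ]),
                 colMeans(pat[5:6, ]), colMeans(pat[7:8, ]))
  oracle <- 1 - stats::cor(t(means))
  expect_equal(unname(d), unname(oracle), tolerance = 1e-10)
  # identical mean patterns -> 0; anti-correlated -> 2
  d2 <- neural_rdm(rbind(means[1, ], means[1, ], -means[1, ]),
                   c("A", "A", "B"))
  expect_equal(d2["A", "B"], 2, tolerance = 1e-10)
  expect_equal(d2["A", "A"], 0)
})

test_that("pair tables standardize every column and keep the pair count", {
  w <- generate_world(seed = 29)
  pt <- make_pair_table(w$semantic_rdm_true,
                        list(climate = w$climate_rdm,
                             geography = geodesic_distance(w$coordinates)),
                        w$families)
  n <- length(w$languages)
  expect_equal(nrow(pt), n * (n - 1) / 2)
  for (col in c("y", "climate", "geography")) {
    expect_lt(abs(mean(pt[[col]])), 1e-10)
    expect_lt(abs(stats::sd(pt[[col]]) - 1), 1e-10)
  }
})

test_that("mixed-model betas are invariant to affine transforms of raw distances", {
  w <- generate_world(seed = 31)
  env1 <- list(climate = w$climate_rdm)
  env2 <- list(climate = 3.7 * w$climate_rdm + 11)
  f1 <- fit_env_model(make_pair_table(w$semantic_rdm_true, env1, w$families))
  f2 <- fit_env_model(make_pair_table(w$semantic_rdm_true, env2, w$families))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("an exact predictor copy yields beta 1 and a singular design errors", {
  w <- generate_world(seed = 37)
  pt <- make_pair_table(w$climate_rdm, list(climate = w$climate_rdm,
                                            geography = geodesic_distance(w$coordinates)),
                        w$families)
  fit <- fit_env_model(pt)
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "climate"], 1, tolerance = 1e-6)
  expect_lt(abs(est$estimate[est$term == "geography"]), 1e-6)

  pt$clim_copy <- pt$climate
  expect_error(fit_env_model(pt), "collinear")
})

test_that("hierarchical increments behave under orthogonality, construction, and nesting", {
  set.seed(128)
  n <- 400
  pt <- data.frame(lang_i = "x", lang_j = "y", family_i = "f", family_j = "g",
                   b1 = stats::rnorm(n), b2 = stats::rnorm(n),
                   b3 = stats::rnorm(n))
  # response orthogonal to block 2
  pt$y <- pt$b1 * 0.5 + stats::rnorm(n)
  h <- hierarchical_increment(pt, "b1", c("b2", "b3"))
  expect_lt(h$delta_r2, 0.02)
  expect_gte(h$r2_full, h$r2_block1)

  # planted block-2 share of 0.6 (in variance terms)
  reps <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    b2 <- stats::rnorm(n); b3 <- stats::rnorm(n)
    d <- data.frame(b1 = stats::rnorm(n), b2 = b2, b3 = b3,
                    y = sqrt(0.6) * (b2 + b3) / sqrt(2) + sqrt(0.4) * stats::rnorm(n))
    hierarchical_increment(d, "b1", c("b2", "b3"))$delta_r2
  }, 0)
  expect_lt(abs(mean(reps) - 0.6), 0.1)
  expect_error(hierarchical_increment(pt, "b1", c("b1", "b2")), "disjoint")
})

test_that("control and peak-distance covariates act as designed", {
  w <- generate_world(seed = 41)
  env <- list(climate = w$climate_rdm)
  base <- fit_env_model(make_pair_table(w$semantic_rdm_true, env, w$families))
  b0 <- base$coefficients$estimate[base$coefficients$term == "climate"]

  # control structure identical to the DV saturates the climate effect
  sat <- control_model(w$semantic_rdm_true, env, w$semantic_rdm_true,
                       w$families)
  bsat <- sat$coefficients$estimate[sat$coefficients$term == "climate"]
  expect_lt(abs(bsat), 0.05)

  # an orthogonal covariate leaves the climate beta essentially unchanged
  set.seed(131)
  n <- length(w$languages)
  rnd <- matrix(stats::runif(n^2), n, n,
                dimnames = list(w$languages, w$languages))
  rnd <- (rnd + t(rnd)) / 2; diag(rnd) <- 0
  ort <- control_model(w$semantic_rdm_true, env, rnd, w$families)
  bort <- ort$coefficients$estimate[ort$coefficients$term == "climate"]
  expect_lt(abs(bort - b0), 0.02)

  # peak centroids independent of the response barely move the estimate
  pt <- make_pair_table(w$semantic_rdm_true, env, w$families)
  cents <- matrix(stats::rnorm(n * 3), n, 3,
                  dimnames = list(w$languages, c("x", "y", "z")))
  pk <- peak_distance_control(pt, cents)
  bpk <- pk$coefficients$estimate[pk$coefficients$term == "climate"]
  expect_lt(abs(bpk - b0), 0.02)
  # constant centroids drop the covariate with a warning, beta unchanged
  cents0 <- cents; cents0[] <- 1
  expect_warning(pk0 <- peak_distance_control(pt, cents0), "constant")
  expect_equal(pk0$coefficients$estimate[pk0$coefficients$term == "climate"],
               b0, tolerance = 1e-10)
})

test_that("commonality partition satisfies its algebraic identity and limits", {
  set.seed(137)
  n <- 400
  pt <- data.frame(lang_i = rep(paste0("L", 1:25), 16)[1:n],
                   lang_j = rep(paste0("M", 1:16), each = 25)[1:n],
                   family_i = "f", family_j = "g",
                   sem = stats::rnorm(n), clim = stats::rnorm(n))
  pt$y <- 0.5 * pt$sem + 0.4 * pt$clim + stats::rnorm(n)
  cp <- commonality_partition(pt, "sem", "clim")
  expect_equal(cp$unique_semantic + cp$unique_climate + cp$common, 1,
               tolerance = 1e-10)
  # orthogonal predictors share (almost) nothing
  expect_lt(abs(cp$common), 0.05)

  # collinear limit: everything is common
  pt2 <- pt; pt2$clim <- pt2$sem + stats::rnorm(n, 0, 1e-4)
  pt2$y <- pt2$sem + stats::rnorm(n, 0, 0.5)
  cp2 <- commonality_partition(pt2, "sem", "clim")
  expect_gt(cp2$common, 0.95)
  expect_lt(abs(cp2$unique_semantic), 0.05)

  # cluster bootstrap produces coherent intervals
  w <- generate_world(seed = 43)
  rois <- emit_neural_rdms(w, lambda_sem = 1, lambda_clim = 1, noise_sd = 0.7)
  ptw <- make_pair_table(rois[[1]],
                         list(sem = w$semantic_rdm_true, clim = w$climate_rdm),
                         w$families)
  set.seed(7)
  cpw <- commonality_partition(ptw, "sem", "clim", n_boot = 50L)
  expect_true(all(cpw$ci[1, ] <= cpw$ci[2, ]))
})

test_that("per-dimension RDMs respond to planted per-dimension structure", {
  wd <- rep(0, 13); wd[5] <- 1
  w <- generate_world(seed = 47, climate_dim_weights = wd, scaling_beta = 0.8)
  sps <- emit_language_spaces(w)
  rdms <- per_dimension_rdms(sps, method = "euclidean")
  expect_equal(length(rdms), 13L)
  expect_equal(names(rdms)[5], "dim05")
  pd <- per_dimension_fits(sps, list(climate = w$climate_rdm), w$families,
                           method = "euclidean")
  expect_equal(which.min(pd$table$p), 5L)
})

test_that("per-dimension tests control false discoveries on null worlds under the language structure", {
  fd <- vapply(1:8, function(s) {
    w <- generate_world(seed = 9800 + s, scaling_beta = 0)
    sps <- emit_language_spaces(w)
    pd <- per_dimension_fits(sps, list(climate = w$climate_rdm), w$families,
                             method = "correlation",
                             random_structure = "language")
    sum(pd$table$significant)
  }, 0)
  expect_lte(mean(fd), 0.05 * 13)
})
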