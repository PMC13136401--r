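# synthetic-world generator
#
# Generates ground-truth "worlds" with the statistical structure every
# downstream stage assumes: a family tree over languages; a shared latent
# concept x 13-dimension loading matrix with per-dimension anchor concepts;
# per-language embeddings that are rotated, climate-modulated, noisy
# realizations of the latent structure; family-correlated climate profiles;
# colexification edges sampled from latent similarity; ratings with
# participant noise; and neural RDMs with planted semantic/climate signal.
# All generators are pure functions of (params, seed).
#
# Two planted climate effects coexist:
#  * the exp-link on the per-language dimension scalings s_l (drives the
#    structure seen by the embedding/projection chain), and
#  * a distance-level planted response RDM in which the standardized
#    climate coefficient equals `planted_beta_climate` exactly in
#    expectation (residual variance is derived as
#    1 - beta^2 - 2*family_variance), used by the mixed-model recovery and
#    calibration oracles.

#' Random family tree with languages at the leaves
#'
#' Root at depth 0, one node per family at depth 1, leaves below. With
#' `depth = 2` each family is a star; larger depths grow (approximately
#' balanced) binary subtrees inside each family, so within-family tree-step
#' distances always stay below between-family ones.
#'
#' @param n_families number of families (>= 2).
#' @param langs_per_family languages per family (>= 1).
#' @param depth leaf depth (>= 2).
#' @param seed RNG seed.
#' @return an `ape::phylo`; attribute `families` is a named vector
#'   language -> family.
#' @export
make_family_tree <- function(n_families, langs_per_family, depth = 2L, seed = 1L) {
  if (n_families < 2L) stop("need >= 2 families")
  if (langs_per_family < 1L) stop("need >= 1 language per family")
  if (depth < 2L) stop("depth must be >= 2")
  set.seed(seed)
  langs <- sprintf("lang%02d", seq_len(n_families * langs_per_family))
  fam_of <- rep(sprintf("fam%d", seq_len(n_families)), each = langs_per_family)
  names(fam_of) <- langs
  subtree <- function(ls, levels) {
    n <- length(ls)
    if (n == 1L) return(ls)
    if (levels <= 1L) return(paste0("(", paste(ls, collapse = ","), ")"))
    ls <- sample(ls)
    half <- ceiling(n / 2)
    paste0("(", subtree(ls[seq_len(half)], levels - 1L), ",",
           subtree(ls[-seq_len(half)], levels - 1L), ")")
  }
  fams <- vapply(sprintf("fam%d", seq_len(n_families)), function(f) {
    ls <- langs[fam_of == f]
    if (length(ls) == 1L) ls else subtree(ls, depth - 1L)
  }, "")
  nwk <- paste0("(", paste(fams, collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "families") <- fam_of
  tree
}

random_orthogonal <- function(d) {
  qrd <- qr(matrix(stats::rnorm(d * d), d, d))
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))), d)
}

#' Generate a synthetic cross-linguistic world
#'
#' @param n_families,langs_per_family,tree_depth family-tree shape
#'   (defaults 5 families x 6 languages).
#' @param n_concepts target concepts (default 60).
#' @param n_dims semantic dimensions (default 13).
#' @param n_anchors_per_dim anchor concepts generated per dimension, with
#'   loading concentrated on that dimension (default 4).
#' @param embedding_dim embedding dimensionality (default 50; >= n_dims).
#' @param planted_beta_climate standardized climate effect on the
#'   distance-level semantic response (default 0.5).
#' @param family_variance variance of each crossed family intercept on the
#'   standardized distance scale (default 0.05).
#' @param noise_sd embedding noise level (default 0.3), expressed relative to
#'   the per-coordinate standard deviation of the latent signal so the level
#'   is comparable across loading scales and embedding dimensionalities.
#' @param n_nuisance_dims shared non-neurocognitive latent dimensions
#'   (topical/distributional structure real embeddings carry; default 12).
#' @param nuisance_sd loading scale of the nuisance dimensions (default 0.3).
#' @param nuisance_stability cross-language correlation of nuisance loadings
#'   in \[0, 1\] (default 0.7): non-neurocognitive structure is shared but
#'   less stable across languages than the dimensional core.
#' @param climate_icc family-level intraclass correlation of the climate
#'   variables (default 0.5).
#' @param n_climate_vars bioclim-style variables (default 19).
#' @param scaling_beta strength of the exp-link from the climate first
#'   principal component to the per-language dimension scalings; defaults to
#'   `planted_beta_climate`.
#' @param climate_dim_weights length-`n_dims` non-negative sensitivity of
#'   each dimension's scaling to climate (default: random in \[0.2, 1\];
#'   pass a basis vector to make a single dimension climate-sensitive).
#' @param scaling_family_sd,scaling_noise_sd family and residual sd on the
#'   log scalings (defaults 0.1).
#' @param seed RNG seed; the whole world is a pure function of the
#'   parameters and this seed.
#' @return object of class `synth_world`.
#' @export
generate_world <- function(n_families = 5L, langs_per_family = 6L,
                           tree_depth = 2L, n_concepts = 60L, n_dims = 13L,
                           n_anchors_per_dim = 4L, embedding_dim = 50L,
                           planted_beta_climate = 0.5, family_variance = 0.05,
                           noise_sd = 0.3, climate_icc = 0.5,
                           n_climate_vars = 19L,
                           scaling_beta = planted_beta_climate,
                           climate_dim_weights = NULL,
                           scaling_family_sd = 0.1, scaling_noise_sd = 0.1,
                           n_nuisance_dims = 12L, nuisance_sd = 0.3,
                           nuisance_stability = 0.7, seed = 1L) {
  stopifnot(embedding_dim >= n_dims + n_nuisance_dims, noise_sd >= 0,
            family_variance >= 0, nuisance_stability >= 0,
            nuisance_stability <= 1)
  resid_var <- 1 - planted_beta_climate^2 - 2 * family_variance
  if (resid_var < 0)
    stop("planted_beta_climate^2 + 2*family_variance must be <= 1")
  tree <- make_family_tree(n_families, langs_per_family, tree_depth, seed)
  fam_of <- attr(tree, "families")
  langs <- names(fam_of)
  L_n <- length(langs)
  set.seed(seed + 1L)

  # latent loadings: sparse block structure for targets, concentrated for anchors
  concepts <- sprintf("c%03d", seq_len(n_concepts))
  dims <- sprintf("dim%02d", seq_len(n_dims))
  L <- matrix(stats::runif(n_concepts * n_dims, 0, 0.15), n_concepts, n_dims,
              dimnames = list(concepts, dims))
  for (i in seq_len(n_concepts)) {
    on <- sample(n_dims, sample(1:3, 1L))
    L[i, on] <- stats::runif(length(on), 0.6, 1)
  }
  anchor_spec <- list()
  A <- NULL
  for (d in seq_len(n_dims)) {
    ids <- sprintf("a_%s_%d", dims[d], seq_len(n_anchors_per_dim))
    anchor_spec[[dims[d]]] <- ids
    block <- matrix(stats::runif(n_anchors_per_dim * n_dims, 0, 0.05),
                    n_anchors_per_dim, n_dims, dimnames = list(ids, dims))
    block[, d] <- stats::runif(n_anchors_per_dim, 0.9, 1)
    A <- rbind(A, block)
  }
  loadings <- rbind(L, A)

  # family-correlated climate driven by two latent factors (temperature- and
  # precipitation-like), mirroring the strong low-rank structure of real
  # bioclim tables where the first two components dominate
  fams <- unique(fam_of)
  factor_scores <- vapply(1:2, function(k) {
    fe <- stats::setNames(stats::rnorm(length(fams), 0, sqrt(climate_icc)), fams)
    fe[fam_of] + stats::rnorm(L_n, 0, sqrt(1 - climate_icc))
  }, numeric(L_n))
  load1 <- stats::runif(n_climate_vars, -1, 1)
  load2 <- stats::runif(n_climate_vars, -1, 1)
  clim <- factor_scores[, 1L] %o% load1 + factor_scores[, 2L] %o% load2 +
    matrix(stats::rnorm(L_n * n_climate_vars, 0, 0.5), L_n, n_climate_vars)
  dimnames(clim) <- list(langs, sprintf("bio%02d", seq_len(n_climate_vars)))
  # give variables bioclim-like heterogeneous locations/scales (z-scored away
  # downstream; exercises the scaling invariances)
  clim <- sweep(sweep(clim, 2L, stats::runif(n_climate_vars, 1, 10), `*`),
                2L, stats::runif(n_climate_vars, -5, 25), `+`)
  pc1 <- zstd(stats::prcomp(scale(clim))$x[, 1L])
  names(pc1) <- langs

  # per-language dimension scalings via the exp link
  if (is.null(climate_dim_weights))
    climate_dim_weights <- stats::runif(n_dims, 0.2, 1)
  stopifnot(length(climate_dim_weights) == n_dims)
  s <- matrix(NA_real_, L_n, n_dims, dimnames = list(langs, dims))
  fam_eff <- matrix(stats::rnorm(length(fams) * n_dims, 0, scaling_family_sd),
                    length(fams), n_dims, dimnames = list(fams, dims))
  for (l in seq_len(L_n))
    s[l, ] <- exp(scaling_beta * climate_dim_weights * pc1[langs[l]] +
                    fam_eff[fam_of[langs[l]], ] +
                    stats::rnorm(n_dims, 0, scaling_noise_sd))

  # shared nuisance loadings (non-neurocognitive structure; all concepts,
  # anchors included, carry it)
  nuisance_shared <- matrix(stats::rnorm(nrow(loadings) * n_nuisance_dims,
                                         0, nuisance_sd),
                            nrow(loadings), n_nuisance_dims,
                            dimnames = list(rownames(loadings),
                                            sprintf("nuis%02d", seq_len(n_nuisance_dims))))

  # per-language orthogonal rotations of the embedding space
  rotations <- lapply(langs, function(l) random_orthogonal(embedding_dim))
  names(rotations) <- langs

  # geographic coordinates: family centres plus scatter
  fam_lat <- stats::setNames(stats::runif(length(fams), -55, 65), fams)
  fam_lon <- stats::setNames(stats::runif(length(fams), -170, 170), fams)
  coords <- data.frame(
    lat = pmin(pmax(fam_lat[fam_of] + stats::rnorm(L_n, 0, 5), -89), 89),
    lon = pmin(pmax(fam_lon[fam_of] + stats::rnorm(L_n, 0, 5), -179), 179),
    row.names = langs)

  # distance-level planted semantic response (standardized scale)
  clim_rdm <- climate_distance(clim)
  x <- zstd(lower_tri(clim_rdm))
  u <- stats::setNames(stats::rnorm(length(fams), 0, sqrt(family_variance)), fams)
  pairs <- lower_tri_pairs(langs)
  t_ij <- planted_beta_climate * x + u[fam_of[pairs$lang_i]] +
    u[fam_of[pairs$lang_j]] + stats::rnorm(nrow(pairs), 0, sqrt(resid_var))
  sem_true <- matrix(0, L_n, L_n, dimnames = list(langs, langs))
  sem_true[lower.tri(sem_true)] <- t_ij
  sem_true <- sem_true + t(sem_true)

  structure(list(
    languages = langs, families = fam_of, family_tree = tree,
    latent_loadings = loadings, target_concepts = concepts,
    anchor_spec = anchor_spec, dims = dims,
    climate = clim, climate_pc1 = pc1, climate_rdm = clim_rdm,
    coordinates = coords, scalings = s, rotations = rotations,
    nuisance_shared = nuisance_shared, semantic_rdm_true = sem_true,
    params = list(
      n_families = n_families, langs_per_family = langs_per_family,
      tree_depth = tree_depth, n_concepts = n_concepts, n_dims = n_dims,
      n_anchors_per_dim = n_anchors_per_dim, embedding_dim = embedding_dim,
      planted_beta_climate = planted_beta_climate,
      family_variance = family_variance, noise_sd = noise_sd,
      climate_icc = climate_icc, n_climate_vars = n_climate_vars,
      scaling_beta = scaling_beta,
      climate_dim_weights = climate_dim_weights,
      scaling_family_sd = scaling_family_sd,
      scaling_noise_sd = scaling_noise_sd,
      n_nuisance_dims = n_nuisance_dims, nuisance_sd = nuisance_sd,
      nuisance_stability = nuisance_stability, seed = seed)),
    class = "synth_world")
}

#' @exportS3Method base::print
print.synth_world <- function(x, ...) {
  p <- x$params
  cat(sprintf("<synth_world> %d languages in %d families; %d concepts x %d dims; planted beta %.2f; seed %d\n",
              length(x$languages), p$n_families, p$n_concepts, p$n_dims,
              p$planted_beta_climate, p$seed))
  invisible(x)
}

#' Emit per-language embedding tables from a world
#'
#' Language l's vector for concept c is the orthogonal rotation of the
#' zero-padded latent realization `[diag(s_l) L[c, ] | nuisance_l[c, ]]`
#' plus Gaussian noise in the latent subspace. The noise standard deviation
#' is `noise_sd` times the per-coordinate sd of the latent signal (a
#' relative, dimension-independent level). Nuisance loadings are a
#' `nuisance_stability`-weighted mixture of the world-shared component and a
#' language-specific draw. Anchor concepts (loading concentrated on one
#' dimension) are included, so the world's anchor specification is
#' recoverable by construction.
#'
#' @param world a `synth_world`.
#' @param noise_sd relative embedding noise level (default: the world's).
#' @param seed RNG seed (default: derived from the world's).
#' @return named list of `embedding_table`s.
#' @export
emit_embeddings <- function(world, noise_sd = world$params$noise_sd,
                            seed = world$params$seed + 2L) {
  set.seed(seed)
  p <- world$params
  d <- p$embedding_dim
  nn <- p$n_nuisance_dims
  st <- p$nuisance_stability
  out <- lapply(world$languages, function(l) {
    base <- sweep(world$latent_loadings, 2L, world$scalings[l, ], `*`)
    nuis <- sqrt(st) * world$nuisance_shared +
      sqrt(1 - st) * matrix(stats::rnorm(nrow(base) * nn, 0, p$nuisance_sd),
                            nrow(base), nn)
    signal <- cbind(base, nuis)
    sig_sd <- stats::sd(as.vector(signal))
    noisy <- signal + matrix(stats::rnorm(length(signal), 0, noise_sd * sig_sd),
                             nrow(signal), ncol(signal))
    vecs <- cbind(noisy, matrix(0, nrow(base), d - ncol(signal))) %*%
      t(world$rotations[[l]])
    rownames(vecs) <- rownames(world$latent_loadings)
    embedding_table(vecs, l)
  })
  names(out) <- world$languages
  out
}

#' Emit language-level semantic loading matrices (noisy diag(s_l) L)
#'
#' The language-level ground-truth spaces, analogous to language-mean rating
#' matrices: `diag over dims of s_l` applied to the target loadings plus a
#' small Gaussian perturbation.
#'
#' @param world a `synth_world`.
#' @param noise_sd perturbation sd (default 0.05).
#' @param seed RNG seed.
#' @return named list of concept x dimension matrices.
#' @export
emit_language_spaces <- function(world, noise_sd = 0.05,
                                 seed = world$params$seed + 3L) {
  set.seed(seed)
  Lt <- world$latent_loadings[world$target_concepts, , drop = FALSE]
  out <- lapply(world$languages, function(l)
    sweep(Lt, 2L, world$scalings[l, ], `*`) +
      matrix(stats::rnorm(length(Lt), 0, noise_sd), nrow(Lt), ncol(Lt)))
  names(out) <- world$languages
  out
}

#' Emit a colexification edge list from latent similarity
#'
#' The colexification probability of a concept pair is a logistic function
#' of the cosine similarity of their latent loading rows; edge weight is
#' Binomial(`n_pseudolanguages`, p). `density` sets the expected fraction of
#' pairs with elevated probability. An empty edge list or disconnected graph
#' is flagged.
#'
#' @param world a `synth_world`.
#' @param density target edge density in (0, 1) (default 0.2).
#' @param n_pseudolanguages colexifying language pool size (default 50).
#' @param slope logistic steepness (default 10).
#' @param seed RNG seed.
#' @return data.frame(concept_a, concept_b, n_languages) with attribute
#'   `connected` (logical).
#' @export
emit_colex_edges <- function(world, density = 0.2, n_pseudolanguages = 50L,
                             slope = 10, seed = world$params$seed + 4L) {
  stopifnot(density > 0, density < 1)
  set.seed(seed)
  Lt <- world$latent_loadings[world$target_concepts, , drop = FALSE]
  sim <- cosine_matrix(Lt, Lt)
  lt <- lower.tri(sim)
  thr <- stats::quantile(sim[lt], 1 - density)
  p <- stats::plogis(slope * (sim - thr)) * density * 2
  p <- pmin(p, 0.95)
  w <- matrix(0L, nrow(sim), ncol(sim), dimnames = dimnames(sim))
  w[lt] <- stats::rbinom(sum(lt), n_pseudolanguages, p[lt])
  idx <- which(lt & w > 0, arr.ind = TRUE)
  edges <- data.frame(concept_a = rownames(sim)[idx[, "col"]],
                      concept_b = rownames(sim)[idx[, "row"]],
                      n_languages = w[idx])
  connected <- FALSE
  if (nrow(edges) == 0L) {
    warning("empty colexification edge list at this density")
  } else {
    g <- build_graph(edges, concepts = world$target_concepts)
    connected <- igraph::is_connected(g)
    if (!connected) warning("colexification graph not connected")
  }
  structure(edges, connected = connected)
}

#' Emit a participant rating table from a world
#'
#' The true rating of concept c on dimension d in language l is an affine
#' map of `s_l[d] * L[c, d]` into the 1-5 range, computed per language
#' (raters anchor the response scale within their own language, and
#' correlation-based downstream analyses are invariant to per-language
#' affine maps); participants add Gaussian noise and ratings are clipped to
#' the 0-6 scale. Optional "careless" participants rate pure uniform noise.
#' Demographic covariates are attached.
#'
#' @param world a `synth_world`.
#' @param participants_per_language >= 2 (default 8).
#' @param rater_noise_sd participant noise sd (default 1.0).
#' @param n_careless careless (pure-noise) participants planted per world,
#'   assigned to the first language(s) (default 0).
#' @param seed RNG seed.
#' @return data.frame(participant, language_code, concept_id, dimension,
#'   rating, age, gender, education, ses).
#' @export
emit_ratings <- function(world, participants_per_language = 8L,
                         rater_noise_sd = 1.0, n_careless = 0L,
                         seed = world$params$seed + 5L) {
  stopifnot(participants_per_language >= 2L)
  set.seed(seed)
  Lt <- world$latent_loadings[world$target_concepts, , drop = FALSE]
  truth <- lapply(world$languages, function(l)
    sweep(Lt, 2L, world$scalings[l, ], `*`))
  affine <- function(v) 1 + 4 * (v - min(v)) / (max(v) - min(v))
  rows <- list()
  pid <- 0L
  careless_left <- n_careless
  for (l in world$languages) {
    mu <- affine(truth[[which(world$languages == l)]])
    for (p in seq_len(participants_per_language)) {
      pid <- pid + 1L
      id <- sprintf("p%03d", pid)
      if (careless_left > 0L && p == 1L) {
        vals <- stats::runif(length(mu), 0, 6)
        careless_left <- careless_left - 1L
      } else {
        vals <- pmin(pmax(mu + stats::rnorm(length(mu), 0, rater_noise_sd), 0), 6)
      }
      rows[[pid]] <- data.frame(
        participant = id, language_code = l,
        concept_id = rep(rownames(mu), ncol(mu)),
        dimension = rep(colnames(mu), each = nrow(mu)),
        rating = as.vector(vals),
        age = round(stats::runif(1, 18, 70)),
        gender = sample(c("f", "m"), 1L),
        education = sample(1:5, 1L),
        ses = sample(1:10, 1L))
    }
  }
  do.call(rbind, rows)
}

#' Emit per-ROI neural RDMs from a world
#'
#' One planted "r-ATL-like" ROI mixes the world's semantic response RDM and
#' climate RDM with noise; all other ROIs are pure noise.
#'
#' @param world a `synth_world`.
#' @param lambda_sem,lambda_clim planted mixing weights (>= 0).
#' @param noise_sd pair-level noise sd (default 1).
#' @param n_rois number of ROIs (default 12, the language-network count).
#' @param seed RNG seed.
#' @return named list of labelled RDMs; attribute `planted_roi` names the
#'   signal-carrying ROI.
#' @export
emit_neural_rdms <- function(world, lambda_sem = 1, lambda_clim = 1,
                             noise_sd = 1, n_rois = 12L,
                             seed = world$params$seed + 6L) {
  stopifnot(lambda_sem >= 0, lambda_clim >= 0)
  set.seed(seed)
  langs <- world$languages
  n <- length(langs)
  sem <- zstd(lower_tri(world$semantic_rdm_true))
  clim <- zstd(lower_tri(world$climate_rdm))
  sym <- function(v) {
    m <- matrix(0, n, n, dimnames = list(langs, langs))
    m[lower.tri(m)] <- v
    m + t(m)
  }
  rois <- stats::setNames(vector("list", n_rois),
                          sprintf("ROI%02d", seq_len(n_rois)))
  rois[[1L]] <- sym(lambda_sem * sem + lambda_clim * clim +
                      stats::rnorm(length(sem), 0, noise_sd))
  for (k in seq(2L, n_rois))
    rois[[k]] <- sym(stats::rnorm(length(sem), 0, noise_sd))
  structure(rois, planted_roi = names(rois)[1L])
}
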