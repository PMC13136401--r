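# end-to-end pipeline over a synthetic world: generate fixtures, project
# semantic spaces, benchmark universality, relate topology and environment,
# fit the mixed models, and write a deterministic manifest.

#' Build a run configuration
#'
#' @param out_dir artifact directory.
#' @param seed master seed, recorded in every output artifact.
#' @param world named list of [generate_world()] overrides.
#' @param k_neighbors local-model neighbours (default 100).
#' @param n_feature_words feature-model anchors (default 100).
#' @param n_random_anchor_words random-word-model anchors (default 13).
#' @param n_null_iters permutation iterations for the pipeline run
#'   (default 50; the reference analysis used 10,000).
#' @param fdr_level FDR level (default 0.05).
#' @return a validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, world = list(), k_neighbors = 100L,
                       n_feature_words = 100L, n_random_anchor_words = 13L,
                       n_null_iters = 50L, fdr_level = 0.05) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), world = world,
              k_neighbors = k_neighbors, n_feature_words = n_feature_words,
              n_random_anchor_words = n_random_anchor_words,
              n_null_iters = n_null_iters, fdr_level = fdr_level)
  num <- c(cfg$k_neighbors, cfg$n_feature_words, cfg$n_random_anchor_words,
           cfg$n_null_iters, cfg$fdr_level)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("configuration error: all numeric parameters must be positive")
  if (is.null(cfg$out_dir)) stop("configuration error: out_dir missing")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

write_csv10 <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Run the full synthetic-world pipeline
#'
#' Generates a world from the config, writes all fixture files in the
#' package's text dialects, runs every analysis stage (projection,
#' inter-language correlation with random-word and random-dimension nulls,
#' PCA universality, colexification topology, environmental RDMs, crossed
#' family mixed models, commonality partition, climate-PC projection), and
#' writes a manifest with the seed, parameter hash, and the md5 of every
#' artifact. Identical config + seed gives byte-identical artifacts.
#'
#' @param config a `run_config` (or list coercible to one).
#' @return the manifest (named list), invisibly; artifacts in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- synth ---------------------------------------------------------------
  world <- run_stage("synth", do.call(
    generate_world, c(config$world, list(seed = config$seed))))
  stage_log("synth", "world: %d languages, %d concepts, seed %d",
            length(world$languages), world$params$n_concepts, config$seed)
  embs <- run_stage("synth", emit_embeddings(world))
  for (l in world$languages)
    write_embeddings(embs[[l]], file.path(out, paste0("emb_", l, ".vec")))
  write_anchor_spec(world$anchor_spec, file.path(out, "anchors.tsv"))
  edges <- run_stage("synth", emit_colex_edges(world))
  write_colex_edges(edges, file.path(out, "colex_edges.tsv"))
  write_csv10(as.data.frame(world$climate), file.path(out, "climate.csv"))
  jsonlite::write_json(
    list(seed = config$seed,
         planted_beta_climate = world$params$planted_beta_climate,
         family_variance = world$params$family_variance,
         noise_sd = world$params$noise_sd,
         climate_dim_weights = world$params$climate_dim_weights),
    file.path(out, "world_truth.json"), auto_unbox = TRUE, digits = NA)

  # --- project -------------------------------------------------------------
  spaces <- run_stage("project", lapply(embs, neurocognitive_space,
                                        anchors = world$anchor_spec))
  stage_log("project", "neurocognitive spaces: %d x %d per language",
            nrow(spaces[[1]]$matrix), ncol(spaces[[1]]$matrix))
  for (l in world$languages)
    write_csv10(as.data.frame(spaces[[l]]$matrix),
                file.path(out, paste0("space_neuro_", l, ".csv")))

  # --- universality --------------------------------------------------------
  run_stage("universality", {
    ilcm <- ilc_matrix(spaces)
    write_rdm(ifelse(is.na(ilcm$z), 0, ilcm$z), file.path(out, "ilc_matrix.csv"))
    concepts <- rownames(spaces[[1]]$matrix)
    set.seed(config$seed + 10L)
    null_rw <- null_benchmark(
      ilcm$mean_ilc,
      function(i) {
        a <- sample_random_anchors(concepts, config$n_random_anchor_words)
        ilc_matrix(lapply(embs, random_word_space, anchor_ids = a,
                          targets = concepts))$mean_ilc
      }, n_iters = config$n_null_iters, statistic = "mean_ILC")
    set.seed(config$seed + 11L)
    null_rd <- null_benchmark(
      ilcm$mean_ilc,
      function(i) ilc_matrix(random_dimension_space(
        embs, targets = concepts,
        n_words = min(100L, floor(length(concepts) / 2))))$mean_ilc,
      n_iters = config$n_null_iters, statistic = "mean_ILC")
    pca <- pca_universality(spaces)
    jsonlite::write_json(list(
      seed = config$seed, mean_ilc_neurocognitive = ilcm$mean_ilc,
      p_vs_random_word = null_rw$one_tailed_p,
      p_vs_random_dimension = null_rd$one_tailed_p,
      null_random_word = null_rw$samples, null_random_dimension = null_rd$samples,
      pc1_share = pca$pc1_share),
      file.path(out, "universality.json"), auto_unbox = TRUE, digits = NA)
    stage_log("universality", "mean ILC %.3f; p(randword) %.3g; p(randdim) %.3g; PC1 %.3f",
              ilcm$mean_ilc, null_rw$one_tailed_p, null_rd$one_tailed_p,
              pca$pc1_share)
  })

  # --- colex ---------------------------------------------------------------
  run_stage("colex", {
    if (nrow(edges) > 0L) {
      g <- build_graph(edges, concepts = world$target_concepts)
      set.seed(config$seed + 12L)
      topo <- combined_similarity(g)
      write_csv10(topo$pairs, file.path(out, "topology_similarity.csv"))
      rho <- correlate_semantic_vs_topology(spaces, topo)
      jsonlite::write_json(list(seed = config$seed, mean_rho = rho$mean_rho,
                                per_language_rho = rho$per_language_rho),
                           file.path(out, "colex_rho.json"),
                           auto_unbox = TRUE, digits = NA)
      stage_log("colex", "mean Spearman rho %.3f over %d languages",
                rho$mean_rho, length(rho$per_language_rho))
    }
  })

  # --- envdist -------------------------------------------------------------
  env <- run_stage("envdist", {
    geo <- geodesic_distance(world$coordinates)
    tre <- tree_distance_matrix(world$family_tree)
    write_rdm(world$climate_rdm, file.path(out, "rdm_climate.csv"))
    write_rdm(geo, file.path(out, "rdm_geography.csv"))
    write_rdm(tre, file.path(out, "rdm_linghist.csv"))
    stage_log("envdist", "climate/geography/tree RDMs over %d languages",
              nrow(geo))
    list(climate = world$climate_rdm, geography = geo, linguistic_history = tre)
  })

  # --- rsa -----------------------------------------------------------------
  run_stage("rsa", {
    sem <- semantic_rdm(spaces)
    write_rdm(sem, file.path(out, "rdm_semantic.csv"))
    pt <- make_pair_table(sem, env, world$families)
    fit <- fit_env_model(pt)
    write_csv10(fit$coefficients, file.path(out, "fit_semantic_env.csv"))
    pt_true <- make_pair_table(world$semantic_rdm_true, env, world$families)
    fit_true <- fit_env_model(pt_true)
    write_csv10(fit_true$coefficients, file.path(out, "fit_planted_env.csv"))
    stage_log("rsa", "climate beta %.3f (pipeline), %.3f (planted response)",
              fit$coefficients$estimate[fit$coefficients$term == "climate"],
              fit_true$coefficients$estimate[fit_true$coefficients$term == "climate"])
  })

  # --- commonality ---------------------------------------------------------
  run_stage("commonality", {
    rois <- emit_neural_rdms(world)
    pt <- make_pair_table(rois[[attr(rois, "planted_roi")]],
                          list(semantic = world$semantic_rdm_true,
                               climate = env$climate), world$families)
    cp <- commonality_partition(pt, "semantic", "climate")
    jsonlite::write_json(cp[c("r2_full", "unique_semantic", "unique_climate",
                              "common")],
                         file.path(out, "commonality.json"),
                         auto_unbox = TRUE, digits = NA)
    stage_log("commonality", "common share %.3f of R2 %.3f", cp$common, cp$r2_full)
  })

  # --- climatepc -----------------------------------------------------------
  run_stage("climatepc", {
    pca <- climate_pca(world$climate)
    proj <- project_semantic(spaces, pca, pc_index = 1L)
    write_csv10(as.data.frame(proj$map), file.path(out, "climate_pc1_map.csv"))
    jsonlite::write_json(list(
      seed = config$seed,
      var_ratios = pca$var_ratios[1:2],
      association_ratio_positive = association_ratio(proj, "positive")),
      file.path(out, "climate_pca.json"), auto_unbox = TRUE, digits = NA)
    stage_log("climatepc", "PC1+PC2 capture %.1f%% of climate variance",
              100 * sum(pca$var_ratios[1:2]))
  })

  # --- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(out), "manifest.json"))
  md5 <- tools::md5sum(file.path(out, files))
  names(md5) <- files
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  manifest <- list(seed = config$seed,
                   parameters = unclass(cfg_for_hash),
                   files = as.list(md5))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
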