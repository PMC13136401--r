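# representational similarity regression with crossed family random
# intercepts, hierarchical increments, per-dimension and per-ROI fits,
# control models, and commonality variance partitioning
#
# The core model regresses the lower triangle of a response RDM (semantic,
# behavioural, or neural distance between languages i and j) on the lower
# triangles of environmental RDMs, with random intercepts for the language
# family of i and the language family of j:
#   y_ij = b0 + b1*Climate_ij + ... + (1|Family_i) + (1|Family_j) + e_ij
# All columns are standardized before fitting so the b's are standardized
# coefficients.

#' Semantic RDM across languages
#'
#' Distance between two languages = 1 - fisher_z(r), where r is the Pearson
#' correlation between their flattened concept x dimension matrices over
#' cells finite in both. (An affine variant of "1 - correlation with
#' Fisher's r-to-Z": it preserves ordering, can go negative for strong
#' correlations, and is harmless because all RDM columns are standardized
#' before any model fit.)
#'
#' @param spaces named list of `semantic_space`s (or matrices), one per
#'   language, column-aligned.
#' @param min_cells minimum shared finite cells per pair (default 10).
#' @return labelled RDM (entries 1 - atanh(clipped r)).
#' @export
semantic_rdm <- function(spaces, min_cells = 10L) {
  mats <- lapply(spaces, function(s)
    if (inherits(s, "semantic_space")) s$matrix else s)
  labs <- names(spaces)
  shared <- Reduce(intersect, lapply(mats, rownames))
  vecs <- lapply(mats, function(m) as.vector(m[shared, , drop = FALSE]))
  n <- length(vecs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- is.finite(vecs[[i]]) & is.finite(vecs[[j]])
    if (sum(ok) < min_cells) stop("pair (", labs[i], ",", labs[j],
                                  ") has fewer than ", min_cells, " shared cells")
    r <- stats::cor(vecs[[i]][ok], vecs[[j]][ok])
    d[i, j] <- d[j, i] <- 1 - fisher_z(r)
  }
  d
}

#' Language-level neural RDM from participant pattern vectors
#'
#' Averages each language's participants' ROI pattern vectors (e.g. t-maps
#' for intact vs degraded speech) and takes 1 - Pearson correlation between
#' language-mean patterns.
#'
#' @param patterns numeric matrix, participants x voxels/vertices.
#' @param language_of_participant character vector (length = participants).
#' @return labelled RDM over the languages present.
#' @export
neural_rdm <- function(patterns, language_of_participant) {
  stopifnot(nrow(patterns) == length(language_of_participant))
  langs <- unique(language_of_participant)
  means <- t(vapply(langs, function(lg)
    colMeans(patterns[language_of_participant == lg, , drop = FALSE]),
    numeric(ncol(patterns))))
  d <- 1 - stats::cor(t(means))
  dimnames(d) <- list(langs, langs)
  diag(d) <- 0
  d
}

#' Build a standardized language-pair table from RDMs
#'
#' One row per unordered language pair (lower triangle); the response and
#' every predictor are standardized to mean 0, sd 1; family labels of both
#' pair members are attached for the crossed random intercepts.
#'
#' @param response_rdm labelled RDM (the dependent distances).
#' @param predictor_rdms named list of labelled RDMs.
#' @param families named character vector language -> family.
#' @param languages optional language subset; default labels common to the
#'   response and all predictors.
#' @return data.frame with columns lang_i, lang_j, family_i, family_j, y,
#'   and one standardized column per predictor.
#' @export
make_pair_table <- function(response_rdm, predictor_rdms, families,
                            languages = NULL) {
  if (is.null(languages))
    languages <- Reduce(intersect, c(list(rownames(response_rdm)),
                                     lapply(predictor_rdms, rownames)))
  if (length(languages) < 3L) stop("fewer than 3 shared languages")
  if (!all(languages %in% names(families)))
    stop("missing family labels for: ",
         paste(setdiff(languages, names(families)), collapse = ", "))
  pairs <- lower_tri_pairs(languages)
  tab <- data.frame(
    lang_i = pairs$lang_i, lang_j = pairs$lang_j,
    family_i = unname(families[pairs$lang_i]),
    family_j = unname(families[pairs$lang_j]),
    y = zstd(lower_tri(response_rdm[languages, languages])),
    stringsAsFactors = FALSE)
  for (nm in names(predictor_rdms))
    tab[[nm]] <- zstd(lower_tri(predictor_rdms[[nm]][languages, languages]))
  tab
}

predictor_cols <- function(pair_table) {
  setdiff(names(pair_table), c("lang_i", "lang_j", "family_i", "family_j", "y"))
}

#' Crossed family random-intercept regression of a pair table
#'
#' Fits `y ~ predictors + (1|family_i) + (1|family_j)` by REML (lme4), with
#' Wald 95% confidence intervals and two-sided normal-approximation
#' p-values on the fixed effects. Variances estimated at the zero boundary
#' are permitted and flagged. A rank-deficient fixed-effects design is an
#' error naming the collinear columns.
#'
#' @param pair_table a table from [make_pair_table()].
#' @param predictors predictor column names; default all.
#' @param random_structure crossed random intercepts to include: `"family"`
#'   (the primary model), `"language"` (absorbs language-level
#'   non-independence of pairs), or `"both"`.
#' @return object of class `mixed_fit`: list with `coefficients` data.frame
#'   (estimate, se, ci_lo, ci_hi, p), `ranef_variance`, `residual_variance`,
#'   `boundary` flag, `marginal_r2`, `n_pairs`, and the `model`.
#' @export
fit_env_model <- function(pair_table, predictors = NULL,
                          random_structure = c("family", "language", "both")) {
  random_structure <- match.arg(random_structure)
  if (is.null(predictors)) predictors <- predictor_cols(pair_table)
  if (length(unique(c(pair_table$family_i, pair_table$family_j))) < 2L)
    stop("need >= 2 language families")
  X <- as.matrix(pair_table[, predictors, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- c("(intercept)", predictors)[-seq_len(qrX$rank)]
    stop("singular fixed-effects design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  re <- switch(random_structure,
    family = "(1 | family_i) + (1 | family_j)",
    language = "(1 | lang_i) + (1 | lang_j)",
    both = "(1 | family_i) + (1 | family_j) + (1 | lang_i) + (1 | lang_j)")
  fml <- stats::as.formula(paste(
    "y ~", paste(predictors, collapse = " + "), "+", re))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = pair_table, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  beta <- lme4::fixef(fit)
  se <- tryCatch(sqrt(diag(as.matrix(suppressWarnings(stats::vcov(fit))))),
                 error = function(e) NA)
  if (anyNA(se)) {
    # saturated/degenerate fits can defeat vcov.merMod; fall back to the
    # fixed-effects information with the (possibly ~0) residual variance
    vc0 <- as.data.frame(lme4::VarCorr(fit))
    rv0 <- vc0$vcov[vc0$grp == "Residual"]
    se <- sqrt(pmax(diag(solve(crossprod(cbind(1, X)))) * rv0, 0))
  }
  zval <- beta / se
  p <- 2 * stats::pnorm(-abs(zval))
  p[p == 0] <- .Machine$double.xmin
  vc <- as.data.frame(lme4::VarCorr(fit))
  grp <- setdiff(vc$grp, "Residual")
  rv <- stats::setNames(vc$vcov[match(grp, vc$grp)], grp)
  resid_var <- vc$vcov[vc$grp == "Residual"]
  yhat_fixed <- drop(cbind(1, X) %*% beta)
  marg_r2 <- stats::var(yhat_fixed) /
    (stats::var(yhat_fixed) + sum(rv) + resid_var)
  structure(list(
    coefficients = data.frame(
      term = names(beta), estimate = unname(beta), se = unname(se),
      ci_lo = unname(beta - stats::qnorm(0.975) * se),
      ci_hi = unname(beta + stats::qnorm(0.975) * se),
      p = unname(p)),
    ranef_variance = rv, residual_variance = resid_var,
    boundary = any(rv < 1e-10), marginal_r2 = marg_r2,
    n_pairs = nrow(pair_table), model = fit),
    class = "mixed_fit")
}

#' @exportS3Method base::print
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %d pairs; family variances %.4g / %.4g; marginal R2 %.3f\n",
              x$n_pairs, x$ranef_variance[1], x$ranef_variance[2], x$marginal_r2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Per-ROI semantic-to-neural fits with FDR across ROIs
#'
#' For each ROI, regresses the neural RDM's pairs on the semantic RDM with
#' crossed family intercepts; Benjamini-Hochberg q-values are computed
#' across the ROI family (the reference analysis used 12 language-network
#' regions).
#'
#' @param neural_rdms named list of labelled RDMs, one per ROI.
#' @param semantic_rdm labelled RDM.
#' @param families named family vector.
#' @param fdr_level significance level on q (default 0.05).
#' @return list with `table` (roi, beta, se, ci, p, q, significant) and
#'   `fits`.
#' @export
fit_semantic_to_neural <- function(neural_rdms, semantic_rdm, families,
                                   fdr_level = 0.05) {
  fits <- lapply(neural_rdms, function(nr) {
    pt <- make_pair_table(nr, list(semantic = semantic_rdm), families)
    fit_env_model(pt, "semantic")
  })
  tab <- do.call(rbind, lapply(names(fits), function(roi) {
    co <- fits[[roi]]$coefficients
    co <- co[co$term == "semantic", ]
    data.frame(roi = roi, beta = co$estimate, se = co$se,
               ci_lo = co$ci_lo, ci_hi = co$ci_hi, p = co$p)
  }))
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < fdr_level
  list(table = tab, fits = fits)
}

#' Hierarchical regression increment
#'
#' OLS fit of block 1, then blocks 1 + 2: reports R-squared of block 1, the
#' increment from adding block 2, and the Spearman correlation between the
#' full model's fitted and observed distances.
#'
#' @param pair_table pair table.
#' @param block1_cols,block2_cols disjoint predictor column sets.
#' @return list with `r2_block1`, `r2_full`, `delta_r2`, `spearman_fit`.
#' @export
hierarchical_increment <- function(pair_table, block1_cols, block2_cols) {
  if (length(intersect(block1_cols, block2_cols)))
    stop("blocks must be disjoint")
  f1 <- stats::lm(stats::reformulate(block1_cols, "y"), data = pair_table)
  f2 <- stats::lm(stats::reformulate(c(block1_cols, block2_cols), "y"),
                  data = pair_table)
  r2_1 <- summary(f1)$r.squared
  r2_2 <- summary(f2)$r.squared
  list(r2_block1 = r2_1, r2_full = r2_2, delta_r2 = r2_2 - r2_1,
       spearman_fit = stats::cor(stats::fitted(f2), pair_table$y,
                                 method = "spearman"))
}

#' Per-dimension semantic RDMs
#'
#' One RDM per anchor dimension. By default the distance between two
#' languages on dimension d is 1 - fisher_z(Pearson r) over the concept
#' vector of that dimension; `method = "euclidean"` instead uses plain
#' Euclidean distance on the dimension's values, which is sensitive to pure
#' per-dimension rescaling that a correlation cannot see.
#'
#' @param spaces named list of column-aligned `semantic_space`s/matrices.
#' @param method "correlation" (default) or "euclidean".
#' @return named list of labelled RDMs, one per column.
#' @export
per_dimension_rdms <- function(spaces, method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  mats <- lapply(spaces, function(s)
    if (inherits(s, "semantic_space")) s$matrix else s)
  shared <- Reduce(intersect, lapply(mats, rownames))
  labs <- names(spaces)
  dims <- colnames(mats[[1L]])
  if (is.null(dims)) dims <- paste0("dim", seq_len(ncol(mats[[1L]])))
  out <- lapply(seq_along(dims), function(d) {
    V <- vapply(mats, function(m) m[shared, d], numeric(length(shared)))
    if (method == "correlation") {
      r <- stats::cor(V)
      dd <- 1 - fisher_z(r)
      # fisher_z vectorizes; restore matrix shape and zero the diagonal
      dd <- matrix(dd, length(labs), length(labs), dimnames = list(labs, labs))
    } else {
      dd <- as.matrix(stats::dist(t(V)))
      dimnames(dd) <- list(labs, labs)
    }
    diag(dd) <- 0
    (dd + t(dd)) / 2
  })
  names(out) <- dims
  out
}

#' Per-dimension environmental fits with FDR across dimensions
#'
#' Fits the crossed-family mixed model once per anchor dimension and
#' adjusts the p-values of a chosen predictor across the 13-dimension
#' family by Benjamini-Hochberg.
#'
#' @param spaces named list of `semantic_space`s.
#' @param predictor_rdms named list of environmental RDMs.
#' @param families named family vector.
#' @param target_predictor predictor whose per-dimension q-values are
#'   reported (default first predictor).
#' @param method per-dimension distance method (see [per_dimension_rdms()]).
#' @param fdr_level q cutoff.
#' @param random_structure passed to [fit_env_model()]; the default
#'   `"family"` is the primary model, `"language"` additionally absorbs
#'   language-level non-independence of pairs (more conservative).
#' @return list with `table` (dimension, beta, p, q, significant) and `fits`.
#' @export
per_dimension_fits <- function(spaces, predictor_rdms, families,
                               target_predictor = NULL,
                               method = "correlation", fdr_level = 0.05,
                               random_structure = "family") {
  if (is.null(target_predictor)) target_predictor <- names(predictor_rdms)[1L]
  rdms <- per_dimension_rdms(spaces, method = method)
  fits <- lapply(rdms, function(rd) {
    pt <- make_pair_table(rd, predictor_rdms, families)
    fit_env_model(pt, random_structure = random_structure)
  })
  tab <- do.call(rbind, lapply(names(fits), function(d) {
    co <- fits[[d]]$coefficients
    co <- co[co$term == target_predictor, ]
    data.frame(dimension = d, beta = co$estimate, p = co$p)
  }))
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < fdr_level
  list(table = tab, fits = fits)
}

#' Competing-structure control model
#'
#' Re-estimates the climate (or any focal) effect on a response RDM with a
#' competing structure's distance added as covariate; both directions
#' (either structure as response) are obtained by swapping arguments.
#'
#' @param response_rdm response RDM.
#' @param focal_rdms named list of focal predictor RDMs (e.g. climate).
#' @param control_rdm competing-structure RDM entered as covariate.
#' @param families named family vector.
#' @param control_name covariate column name.
#' @return a `mixed_fit`.
#' @export
control_model <- function(response_rdm, focal_rdms, control_rdm, families,
                          control_name = "control_structure") {
  preds <- c(focal_rdms, stats::setNames(list(control_rdm), control_name))
  pt <- make_pair_table(response_rdm, preds, families)
  fit_env_model(pt)
}

#' Peak-centroid distance control
#'
#' Adds the Euclidean distance between per-language activation peak
#' centroids as a covariate and re-estimates the environmental effects. A
#' constant covariate is dropped with a warning and the fit re-run without
#' it.
#'
#' @param pair_table pair table.
#' @param peak_centroids numeric matrix, languages x 3 (x, y, z),
#'   language codes as rownames; pairs missing a centroid are dropped with
#'   a report.
#' @return a `mixed_fit`; attribute `n_dropped` counts dropped pairs.
#' @export
peak_distance_control <- function(pair_table, peak_centroids) {
  have <- pair_table$lang_i %in% rownames(peak_centroids) &
    pair_table$lang_j %in% rownames(peak_centroids)
  n_dropped <- sum(!have)
  if (n_dropped) message(n_dropped, " pair(s) dropped for missing centroids")
  pt <- pair_table[have, , drop = FALSE]
  pd <- sqrt(rowSums((peak_centroids[pt$lang_i, , drop = FALSE] -
                        peak_centroids[pt$lang_j, , drop = FALSE])^2))
  if (stats::sd(pd) == 0) {
    warning("constant peak-distance covariate dropped")
    fit <- fit_env_model(pt)
  } else {
    pt$peak_distance <- zstd(pd)
    fit <- fit_env_model(pt)
  }
  structure(fit, n_dropped = n_dropped)
}

#' Commonality partition of explained variance
#'
#' From the OLS R-squared of the full model and each single-predictor model:
#' unique_sem = R2_full - R2_clim; unique_clim = R2_full - R2_sem;
#' common = R2_sem + R2_clim - R2_full. Shares divide by R2_full and sum to
#' 1 by construction; negative components (suppression) are flagged.
#' Bootstrap confidence intervals resample languages (cluster bootstrap)
#' and rebuild the pair table.
#'
#' @param pair_table pair table containing the two predictor columns.
#' @param semantic_col,climate_col predictor column names.
#' @param n_boot bootstrap replicates (0 to skip).
#' @return list with r2 values, `unique_semantic`, `unique_climate`,
#'   `common` (shares of R2_full), `negative_flag`, and `ci` (2 x 3 matrix
#'   of 95% percentile bounds) when bootstrapped.
#' @export
commonality_partition <- function(pair_table, semantic_col, climate_col,
                                  n_boot = 0L) {
  part <- function(pt) {
    r2 <- function(cols) summary(
      stats::lm(stats::reformulate(cols, "y"), data = pt))$r.squared
    r2_full <- r2(c(semantic_col, climate_col))
    if (r2_full <= 0) stop("R2_full <= 0: partition undefined")
    u_sem <- r2_full - r2(climate_col)
    u_clim <- r2_full - r2(semantic_col)
    common <- r2(semantic_col) + r2(climate_col) - r2_full
    c(r2_full = r2_full, unique_semantic = u_sem / r2_full,
      unique_climate = u_clim / r2_full, common = common / r2_full)
  }
  est <- part(pair_table)
  ci <- NULL
  if (n_boot > 0L) {
    langs <- unique(c(pair_table$lang_i, pair_table$lang_j))
    key <- paste(pair_table$lang_i, pair_table$lang_j, sep = "\r")
    boot <- matrix(NA_real_, n_boot, 3L,
                   dimnames = list(NULL, c("unique_semantic", "unique_climate",
                                           "common")))
    b <- 0L; tries <- 0L
    while (b < n_boot && tries < 20L * n_boot) {
      tries <- tries + 1L
      samp <- sample(langs, length(langs), replace = TRUE)
      idx <- unlist(lapply(seq_along(samp), function(i) {
        js <- seq_len(i - 1L)
        k1 <- paste(samp[i], samp[js], sep = "\r")
        k2 <- paste(samp[js], samp[i], sep = "\r")
        m <- match(k1, key); m[is.na(m)] <- match(k2, key)[is.na(m)]
        m[!is.na(m)]
      }))
      pt <- pair_table[idx, , drop = FALSE]
      res <- tryCatch(part(pt), error = function(e) NULL)
      if (is.null(res)) next
      b <- b + 1L
      boot[b, ] <- res[c("unique_semantic", "unique_climate", "common")]
    }
    ci <- apply(boot[seq_len(b), , drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975), na.rm = TRUE)
  }
  list(r2_full = unname(est["r2_full"]),
       unique_semantic = unname(est["unique_semantic"]),
       unique_climate = unname(est["unique_climate"]),
       common = unname(est["common"]),
       negative_flag = any(est[-1L] < 0),
       ci = ci)
}
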