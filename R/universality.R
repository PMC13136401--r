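# cross-language / cross-subject commonality metrics and permutation nulls

#' Inter-language correlation (ILC) between two semantic spaces
#'
#' For every concept shared by the two spaces, the Pearson correlation
#' between the two languages' anchor-projection rows is computed over the
#' columns finite in both (for global spaces this drops the self cells
#' consistently), Fisher z-transformed, and averaged across concepts.
#'
#' @param space_a,space_b `semantic_space`s (or plain concept x dim matrices).
#' @param min_cols minimum aligned columns per concept (default 3).
#' @return list with `mean_z`, `per_concept_z` (named vector), and
#'   `n_skipped` (zero-variance or under-covered concepts dropped).
#' @export
ilc <- function(space_a, space_b, min_cols = 3L) {
  a <- if (inherits(space_a, "semantic_space")) space_a$matrix else space_a
  b <- if (inherits(space_b, "semantic_space")) space_b$matrix else space_b
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 2L) stop("fewer than 2 shared concepts")
  a <- a[shared, , drop = FALSE]; b <- b[shared, , drop = FALSE]
  if (ncol(a) != ncol(b)) stop("column counts differ between spaces")
  r <- rowwise_pearson(a, b, min_cols = min_cols)
  keep <- !is.na(r)
  z <- fisher_z(r[keep])
  names(z) <- shared[keep]
  list(mean_z = mean(z), per_concept_z = z, n_skipped = sum(!keep))
}

#' Pairwise mean-ILC matrix over a set of spaces
#'
#' @param spaces named list of `semantic_space`s (languages or participants).
#' @return object of class `ilc_matrix`: list with `z` (symmetric matrix of
#'   pairwise mean Fisher-z, `NA` diagonal), `n_concepts_used`, and
#'   `mean_ilc` (mean of the lower triangle).
#' @export
ilc_matrix <- function(spaces) {
  labs <- names(spaces)
  n <- length(spaces)
  z <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  nc <- matrix(NA_integer_, n, n, dimnames = list(labs, labs))
  mats <- lapply(spaces, function(s)
    if (inherits(s, "semantic_space")) s$matrix else s)
  rows_list <- lapply(mats, rownames)
  aligned <- length(unique(vapply(mats, ncol, 0L))) == 1L &&
    all(vapply(rows_list, identical, TRUE, rows_list[[1L]])) &&
    !any(vapply(mats, anyNA, TRUE))
  if (aligned) {
    # fast path: pre-standardize rows once per space
    d <- ncol(mats[[1L]])
    std <- lapply(mats, function(m) {
      c_ <- m - rowMeans(m)
      sd_ <- sqrt(rowSums(c_^2) / (d - 1L))
      list(m = c_ / sd_, ok = sd_ > 0)
    })
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      ok <- std[[i]]$ok & std[[j]]$ok
      r <- rowSums(std[[i]]$m[ok, , drop = FALSE] *
                     std[[j]]$m[ok, , drop = FALSE]) / (d - 1L)
      z[i, j] <- z[j, i] <- mean(fisher_z(r))
      nc[i, j] <- nc[j, i] <- sum(ok)
    }
  } else {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      res <- ilc(spaces[[i]], spaces[[j]])
      z[i, j] <- z[j, i] <- res$mean_z
      nc[i, j] <- nc[j, i] <- length(res$per_concept_z)
    }
  }
  structure(list(z = z, n_concepts_used = nc,
                 mean_ilc = mean(z[lower.tri(z)])),
            class = "ilc_matrix")
}

#' Paired comparison of two models' ILC values
#'
#' Two-sided Wilcoxon signed-rank test on paired per-language-pair ILC
#' vectors (exact distribution below n = 25, normal approximation above),
#' with the pseudomedian difference and its 95% confidence interval.
#'
#' @param ilc_pairs_a,ilc_pairs_b equal-length numeric vectors over the same
#'   language pairs.
#' @return list with `V`, `p`, `median_diff`, `ci` (length 2), `n`.
#' @export
compare_models <- function(ilc_pairs_a, ilc_pairs_b) {
  stopifnot(length(ilc_pairs_a) == length(ilc_pairs_b))
  d <- ilc_pairs_a - ilc_pairs_b
  if (all(d == 0)) {
    warning("all paired differences are zero")
    return(list(V = 0, p = 1, median_diff = 0, ci = c(0, 0), n = length(d)))
  }
  n <- length(d)
  wt <- suppressWarnings(stats::wilcox.test(
    ilc_pairs_a, ilc_pairs_b, paired = TRUE, exact = n < 25L,
    conf.int = TRUE, conf.level = 0.95))
  list(V = unname(wt$statistic), p = wt$p.value,
       median_diff = unname(wt$estimate), ci = unname(wt$conf.int), n = n)
}

#' Family of paired model comparisons with BH-FDR
#'
#' @param comparisons named list; each element a list(a =, b =) of paired
#'   ILC vectors.
#' @return data.frame with V, p, q (Benjamini-Hochberg), median_diff, ci.
#' @export
compare_model_family <- function(comparisons) {
  res <- lapply(comparisons, function(cmp) compare_models(cmp$a, cmp$b))
  df <- data.frame(
    comparison = names(comparisons),
    V = vapply(res, `[[`, 0, "V"),
    p = vapply(res, `[[`, 0, "p"),
    median_diff = vapply(res, `[[`, 0, "median_diff"),
    ci_lo = vapply(res, function(r) r$ci[1], 0),
    ci_hi = vapply(res, function(r) r$ci[2], 0),
    n = vapply(res, `[[`, 0L, "n"))
  df$q <- stats::p.adjust(df$p, method = "BH")
  df
}

#' PCA universality: PC1 explained-variance share across languages
#'
#' Reshapes each language's concept x dimension matrix (restricted to
#' concepts shared by all languages) into a vector, treats languages as
#' features and cells as samples, and performs correlation PCA (columns
#' centred and unit-scaled). A universal structure shows up as a high PC1
#' share; independent languages approach 1/L.
#'
#' @param spaces named list of `semantic_space`s.
#' @param shared_concepts optional concept subset; default all-language
#'   intersection.
#' @return list with `pc1_share`, `var_ratios`, `n_samples`.
#' @export
pca_universality <- function(spaces, shared_concepts = NULL) {
  if (length(spaces) < 2L) stop("need >= 2 languages")
  mats <- lapply(spaces, function(s)
    if (inherits(s, "semantic_space")) s$matrix else s)
  if (is.null(shared_concepts))
    shared_concepts <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared_concepts) < 2L) stop("fewer than 2 shared concepts")
  cols <- vapply(mats, ncol, 0L)
  if (length(unique(cols)) != 1L) stop("column counts differ across languages")
  X <- vapply(mats, function(m) as.vector(m[shared_concepts, , drop = FALSE]),
              numeric(length(shared_concepts) * cols[1L]))
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 2L) stop("fewer than 2 complete samples")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  list(pc1_share = ratios[1L], var_ratios = ratios, n_samples = nrow(X))
}

#' Permutation-null benchmark for an observed statistic
#'
#' Draws `n_iters` samples from a null generator and computes the one-tailed
#' permutation p-value with the +1 convention,
#' p = (1 + #\{null >= observed\}) / (n_iters + 1), which is never exactly 0.
#'
#' @param observed observed statistic.
#' @param null_generator function(i) -> one null statistic (deterministic
#'   given the session RNG state; seed before calling for reproducibility).
#' @param n_iters number of null iterations (the reference analysis used
#'   10,000 for embedding nulls and 1,000 for colexification nulls).
#' @param statistic label for the statistic.
#' @return object of class `null_distribution`: list with `samples`,
#'   `observed`, `one_tailed_p`, `statistic`, `n_iters`.
#' @export
null_benchmark <- function(observed, null_generator, n_iters = 1000L,
                           statistic = "statistic") {
  stopifnot(n_iters >= 1L)
  samples <- vapply(seq_len(n_iters), null_generator, 0)
  p <- (1 + sum(samples >= observed)) / (n_iters + 1)
  structure(list(statistic = statistic, samples = samples,
                 observed = observed, one_tailed_p = p, n_iters = n_iters),
            class = "null_distribution")
}

#' @exportS3Method base::print
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: observed %.4f vs %d nulls (95th pct %.4f), one-tailed p = %.4g\n",
              x$statistic, x$observed, x$n_iters,
              stats::quantile(x$samples, 0.95), x$one_tailed_p))
  invisible(x)
}

# ---- behavioural ratings -------------------------------------------------

# ratings: data.frame(participant, language_code, concept_id, dimension, rating)
ratings_to_matrix <- function(ratings) {
  cell <- paste(ratings$concept_id, ratings$dimension, sep = "|")
  cells <- sort(unique(cell))
  parts <- unique(ratings$participant)
  m <- matrix(NA_real_, length(parts), length(cells),
              dimnames = list(parts, cells))
  m[cbind(match(ratings$participant, parts), match(cell, cells))] <- ratings$rating
  lang <- ratings$language_code[match(parts, ratings$participant)]
  names(lang) <- parts
  list(m = m, language = lang)
}

#' Inter-subject correlation matrix from rating data
#'
#' Pearson correlation (raw r, not Fisher-z) between every participant
#' pair's full concept-by-dimension rating vectors (e.g. 207 concepts x 13
#' dimensions = 2691 ratings per participant), missing cells handled
#' pairwise. Constant raters are excluded with a warning.
#'
#' @param ratings data.frame with columns participant, language_code,
#'   concept_id, dimension, rating.
#' @return list with `r` (participants x participants correlation matrix),
#'   `language` (named vector), `excluded` (constant raters).
#' @export
intersubject_matrix <- function(ratings) {
  rm_ <- ratings_to_matrix(ratings)
  sds <- apply(rm_$m, 1L, stats::sd, na.rm = TRUE)
  bad <- rownames(rm_$m)[!is.finite(sds) | sds == 0]
  if (length(bad)) warning("excluding constant rater(s): ",
                           paste(bad, collapse = ", "))
  keep <- setdiff(rownames(rm_$m), bad)
  r <- stats::cor(t(rm_$m[keep, , drop = FALSE]), use = "pairwise.complete.obs")
  list(r = r, language = rm_$language[keep], excluded = bad)
}

#' Quality-control filter on raters
#'
#' Single pass: within each language, each participant's rating vector is
#' correlated with the group-average vector (computed over all participants,
#' including the candidate); participants with r below `threshold` are
#' excluded.
#'
#' @param ratings rating data.frame (see [intersubject_matrix()]).
#' @param threshold exclusion cutoff on r (default 0.5, the reference value).
#' @return list with `retained`, `excluded`, and `r` (named correlation with
#'   group mean).
#' @export
qc_filter <- function(ratings, threshold = 0.5) {
  rm_ <- ratings_to_matrix(ratings)
  r <- stats::setNames(rep(NA_real_, nrow(rm_$m)), rownames(rm_$m))
  for (lg in unique(rm_$language)) {
    ids <- names(rm_$language)[rm_$language == lg]
    if (length(ids) < 2L) stop("language ", lg, " has fewer than 2 participants")
    sub <- rm_$m[ids, , drop = FALSE]
    grp <- colMeans(sub, na.rm = TRUE)
    for (id in ids)
      r[id] <- stats::cor(sub[id, ], grp, use = "pairwise.complete.obs")
  }
  retained <- names(r)[r >= threshold]
  excluded <- names(r)[r < threshold]
  for (lg in unique(rm_$language))
    if (sum(rm_$language[retained] == lg) < 2L)
      warning("language ", lg, " reduced below 2 participants by QC")
  list(retained = retained, excluded = excluded, r = r)
}

#' Variance components of rating data
#'
#' Random-effects decomposition of rating cells into a universal component
#' (the grand concept-by-dimension pattern shared by all participants), a
#' language-specific component (per-language deviation of the cell pattern),
#' and participant residual. Estimated by expected mean squares with the
#' harmonic mean of per-language participant counts for unbalanced designs;
#' negative variance estimates are truncated at zero and flagged.
#'
#' @param ratings rating data.frame (see [intersubject_matrix()]).
#' @return list with `universal_share`, `language_share`, `residual_share`
#'   (summing to 1), raw `components`, and `truncated` flag.
#' @export
variance_components <- function(ratings) {
  rm_ <- ratings_to_matrix(ratings)
  langs <- unique(rm_$language)
  if (length(langs) < 2L) stop("need >= 2 languages")
  n_l <- table(rm_$language)
  if (any(n_l < 2L)) stop("need >= 2 participants per language")
  L <- length(langs)
  n_h <- 1 / mean(1 / as.numeric(n_l))          # harmonic mean group size
  lang_means <- t(vapply(langs, function(lg)
    colMeans(rm_$m[names(rm_$language)[rm_$language == lg], , drop = FALSE],
             na.rm = TRUE), numeric(ncol(rm_$m))))
  grand <- colMeans(lang_means)                  # unweighted grand pattern
  # residual: participant deviation from own language-cell mean
  dev <- rm_$m - lang_means[match(rm_$language, langs), , drop = FALSE]
  cnt <- colSums(!is.na(dev))
  sigma2_res <- sum(dev^2, na.rm = TRUE) /
    max(1L, sum(!is.na(dev)) - L * ncol(rm_$m))
  # language: per-cell variance of language means, EMS-corrected
  v_lang_cells <- apply(lang_means, 2L, stats::var)
  sigma2_lang <- mean(v_lang_cells) - sigma2_res / n_h
  # universal: variance of the grand cell pattern, EMS-corrected
  sigma2_univ <- stats::var(grand) - sigma2_lang / L - sigma2_res / (n_h * L)
  truncated <- sigma2_lang < 0 || sigma2_univ < 0
  sigma2_lang <- max(0, sigma2_lang)
  sigma2_univ <- max(0, sigma2_univ)
  tot <- sigma2_univ + sigma2_lang + sigma2_res
  list(universal_share = sigma2_univ / tot,
       language_share = sigma2_lang / tot,
       residual_share = sigma2_res / tot,
       components = c(universal = sigma2_univ, language = sigma2_lang,
                      residual = sigma2_res),
       truncated = truncated)
}
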