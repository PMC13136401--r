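# climate PCA and projection of semantic spaces onto climate principal
# components

#' PCA of bioclim climate profiles
#'
#' Variables are z-scored, constant variables dropped with a warning, and an
#' SVD-based PCA performed. Sign convention: each component is oriented so
#' that its largest-|loading| variable loads positively (PCA signs are
#' otherwise arbitrary).
#'
#' @param profiles languages x bioclim variables matrix, rownames = language
#'   codes.
#' @param n_pcs components to keep (default 2; in the reference analysis the
#'   first two captured most climate variation).
#' @return object of class `climate_pca`: list with `loadings` (vars x PCs),
#'   `scores` (languages x PCs), `var_ratios` (all components),
#'   `dropped_vars`.
#' @export
climate_pca <- function(profiles, n_pcs = 2L) {
  m <- as.matrix(profiles)
  if (nrow(m) < 3L) stop("need >= 3 languages")
  if (anyNA(m)) stop("incomplete climate profiles")
  sds <- apply(m, 2L, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped)) {
    warning("constant variable(s) dropped: ", paste(dropped, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_pcs, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(load[, j]))
    if (load[lead, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = load, scores = scores, var_ratios = ratios,
                 dropped_vars = dropped), class = "climate_pca")
}

#' Project semantic spaces onto a climate principal component
#'
#' Each language's concept x dimension matrix is scaled as a whole (divided
#' by its standard deviation, without centering, so both the sign structure
#' of the cosine associations and the relative differences between
#' dimensions survive), multiplied by the language's score on the chosen
#' climate PC, and the results averaged across languages: a signed concept
#' x dimension map in which positive values mark associations stronger
#' toward the positive pole of the PC.
#'
#' @param spaces named list of `semantic_space`s.
#' @param pca_scores languages x PCs score matrix (from [climate_pca()]`$scores`)
#'   or a `climate_pca`.
#' @param pc_index which PC to project onto.
#' @return object of class `projected_space`: list with `map` (concepts x
#'   dimensions), `pc_index`, `languages_used`, `excluded`.
#' @export
project_semantic <- function(spaces, pca_scores, pc_index = 1L) {
  if (inherits(pca_scores, "climate_pca")) pca_scores <- pca_scores$scores
  use <- intersect(names(spaces), rownames(pca_scores))
  excluded <- union(setdiff(names(spaces), use), setdiff(rownames(pca_scores), use))
  if (!length(use)) stop("no language present in both spaces and PC scores")
  mats <- lapply(spaces[use], function(s)
    if (inherits(s, "semantic_space")) s$matrix else s)
  shared <- Reduce(intersect, lapply(mats, rownames))
  acc <- 0
  for (lg in use) {
    m <- mats[[lg]][shared, , drop = FALSE]
    acc <- acc + (m / stats::sd(m)) * pca_scores[lg, pc_index]
  }
  map <- acc / length(use)
  structure(list(map = map, pc_index = pc_index, languages_used = use,
                 excluded = excluded), class = "projected_space")
}

#' Semantic association ratio along one PC direction
#'
#' Summed |values| in the chosen direction divided by the total summed
#' |values| in both directions; the two directions' ratios sum to 1.
#'
#' @param projected a `projected_space` (or its map matrix).
#' @param direction "positive" or "negative".
#' @param subset optional dimension (column) subset.
#' @return ratio in \[0, 1\].
#' @export
association_ratio <- function(projected, direction = c("positive", "negative"),
                              subset = NULL) {
  direction <- match.arg(direction)
  m <- if (inherits(projected, "projected_space")) projected$map else projected
  if (!is.null(subset)) m <- m[, subset, drop = FALSE]
  pos <- sum(m[m > 0])
  neg <- sum(-m[m < 0])
  if (pos + neg == 0) stop("all-zero projected map: ratio undefined")
  if (direction == "positive") pos / (pos + neg) else neg / (pos + neg)
}

#' Per-domain, per-dimension summary of a projected map
#'
#' @param projected a `projected_space` (or map matrix).
#' @param concept_to_domain named character vector concept -> domain;
#'   unmapped concepts are excluded with a report.
#' @return list with `summary` (domains x dimensions mean matrix),
#'   `unmapped` concepts.
#' @export
domain_summary <- function(projected, concept_to_domain) {
  m <- if (inherits(projected, "projected_space")) projected$map else projected
  mapped <- intersect(rownames(m), names(concept_to_domain))
  unmapped <- setdiff(rownames(m), names(concept_to_domain))
  if (!length(mapped)) stop("no concept maps to a domain")
  dom <- concept_to_domain[mapped]
  doms <- unique(dom)
  out <- t(vapply(doms, function(d)
    colMeans(m[mapped[dom == d], , drop = FALSE]), numeric(ncol(m))))
  rownames(out) <- doms
  list(summary = out, unmapped = unmapped)
}
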