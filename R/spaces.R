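# anchor-word projection semantic models
#
# A semantic space represents every target concept by its cosine
# similarities to a set of anchor vectors, making embedding spaces that
# live in different coordinate systems (one per language) comparable:
# cosine similarity is invariant to the arbitrary rotation of each
# language's embedding space.

new_semantic_space <- function(matrix, language_code, model_name, anchor_metadata = NULL) {
  structure(list(language_code = language_code, model_name = model_name,
                 matrix = matrix, anchor_metadata = anchor_metadata),
            class = "semantic_space")
}

#' @exportS3Method base::print
print.semantic_space <- function(x, ...) {
  cat(sprintf("<semantic_space> %s model, language %s: %d concepts x %d dims\n",
              x$model_name, x$language_code, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

emb_matrix <- function(emb) {
  if (inherits(emb, "embedding_table")) emb$vectors else emb
}

#' Neurocognitive anchor-dimension semantic space
#'
#' Projects each target concept onto named anchor dimensions: entry (c, d)
#' is the mean cosine similarity between concept c's vector and the vectors
#' of dimension d's anchor words. The default reference configuration uses
#' 13 dimensions (seven sensory-motor: color, shape, taste, smell, sound,
#' touch, motor; six cognitive: time, space, number, cognition, emotion,
#' social). Targets that appear inside any anchor list are dropped from the
#' rows, so no concept is scored against itself.
#'
#' @param emb an `embedding_table`.
#' @param anchors named list: dimension name -> character vector of anchor
#'   concept ids. Anchors missing a vector are averaged over (never imputed);
#'   a dimension with no available anchor is an error.
#' @param targets character vector of target concept ids (default: all
#'   concepts in `emb` not used as anchors).
#' @return a `semantic_space` with one column per dimension;
#'   `anchor_metadata$n_available` reports per-dimension available-anchor
#'   counts, `anchor_metadata$dropped_targets` the anchor-overlapping targets.
#' @export
neurocognitive_space <- function(emb, anchors, targets = NULL) {
  m <- emb_matrix(emb)
  all_anchor_ids <- unique(unlist(anchors, use.names = FALSE))
  if (is.null(targets)) targets <- rownames(m)
  dropped <- intersect(targets, all_anchor_ids)
  targets <- setdiff(targets, all_anchor_ids)
  targets <- intersect(targets, rownames(m))
  if (length(targets) == 0L) stop("no targets left after anchor exclusion")
  avail <- lapply(anchors, function(a) intersect(a, rownames(m)))
  n_avail <- lengths(avail)
  if (any(n_avail == 0L))
    stop("dimension(s) with zero available anchors: ",
         paste(names(anchors)[n_avail == 0L], collapse = ", "))
  tn <- row_normalize(m[targets, , drop = FALSE])
  out <- matrix(NA_real_, length(targets), length(anchors),
                dimnames = list(targets, names(anchors)))
  for (d in seq_along(anchors)) {
    an <- row_normalize(m[avail[[d]], , drop = FALSE])
    out[, d] <- rowMeans(tn %*% t(an))
  }
  new_semantic_space(out, emb$language_code, "neurocognitive",
                     list(anchors = avail, n_available = n_avail,
                          dropped_targets = dropped))
}

#' Distributional global semantic space
#'
#' Represents each concept by its cosine similarities to all other target
#' concepts in the same language. Returned as a full concepts x concepts
#' matrix in master-list order with `NA` on the diagonal (self excluded),
#' so that rows stay column-aligned across languages; comparison code drops
#' `NA` cells pairwise.
#'
#' @param emb an `embedding_table`.
#' @param targets concept ids (>= 2 with vectors); default all in `emb`.
#' @return a `semantic_space` with a square similarity matrix, diagonal `NA`.
#' @export
distributional_global_space <- function(emb, targets = NULL) {
  m <- emb_matrix(emb)
  if (is.null(targets)) targets <- rownames(m)
  targets <- intersect(targets, rownames(m))
  if (length(targets) < 2L) stop("need >= 2 targets with vectors")
  cm <- cosine_matrix(m[targets, , drop = FALSE], m[targets, , drop = FALSE])
  diag(cm) <- NA_real_
  new_semantic_space(cm, emb$language_code, "global")
}

#' Top-k nearest-neighbour anchor sets for the local model
#'
#' @param emb an `embedding_table`.
#' @param targets concept ids; default all.
#' @param k number of nearest neighbours (by cosine) per concept.
#' @return named list concept -> character vector of its k nearest concepts.
#' @export
local_anchor_sets <- function(emb, targets = NULL, k = 100L) {
  m <- emb_matrix(emb)
  if (is.null(targets)) targets <- rownames(m)
  targets <- intersect(targets, rownames(m))
  cm <- cosine_matrix(m[targets, , drop = FALSE], m[targets, , drop = FALSE])
  diag(cm) <- -Inf
  k_use <- min(k, length(targets) - 1L)
  out <- lapply(seq_along(targets), function(i)
    targets[order(cm[i, ], decreasing = TRUE)[seq_len(k_use)]])
  names(out) <- targets
  out
}

#' Distributional local model: pairwise comparable representations
#'
#' For an ordered language pair (A, B) and each shared concept c, the anchor
#' set is the top-k nearest concepts to c in A's space, transferred to B by
#' translation-equivalent concept identity; both languages' cosine vectors
#' to that anchor set are correlated per concept. The pair-level score
#' symmetrizes by averaging the (A->B) and (B->A) directions.
#'
#' @param emb_a,emb_b `embedding_table`s for the two languages.
#' @param targets shared target concept ids; default the intersection.
#' @param k neighbours per concept (default 100, the reference setting).
#' @return list with `mean_z` (symmetrized mean Fisher-z), `per_concept_z`
#'   (matrix: concepts x 2 directions), `n_skipped` zero-variance skips.
#' @export
distributional_local_ilc <- function(emb_a, emb_b, targets = NULL, k = 100L) {
  ma <- emb_matrix(emb_a); mb <- emb_matrix(emb_b)
  if (is.null(targets)) targets <- intersect(rownames(ma), rownames(mb))
  targets <- intersect(intersect(targets, rownames(ma)), rownames(mb))
  if (length(targets) < 2L) stop("need >= 2 shared target concepts")
  if (k > length(targets) - 1L)
    warning("fewer than k mappable neighbours; using all available")
  dir_z <- function(src, dst) {
    nb <- local_anchor_sets(embedding_table(src[targets, , drop = FALSE]),
                            targets, k)
    z <- rep(NA_real_, length(targets))
    sn <- row_normalize(src); dn <- row_normalize(dst)
    for (i in seq_along(targets)) {
      a <- nb[[targets[i]]]
      x <- drop(sn[targets[i], , drop = FALSE] %*% t(sn[a, , drop = FALSE]))
      y <- drop(dn[targets[i], , drop = FALSE] %*% t(dn[a, , drop = FALSE]))
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      z[i] <- fisher_z(stats::cor(x, y))
    }
    z
  }
  zab <- dir_z(ma, mb)
  zba <- dir_z(mb, ma)
  per <- cbind(a_to_b = zab, b_to_a = zba)
  rownames(per) <- targets
  list(mean_z = mean(rowMeans(per), na.rm = TRUE), per_concept_z = per,
       n_skipped = sum(!stats::complete.cases(per)))
}

#' Feature-word semantic space
#'
#' Projects targets onto the `n_features` top-ranked feature words that have
#' vectors; feature words that are themselves targets are excluded from the
#' anchor set so no concept is scored against itself.
#'
#' @param emb an `embedding_table`.
#' @param feature_words character vector of feature words, ranked by
#'   nomination frequency (most frequent first).
#' @param n_features number of features to use (default 100, the reference
#'   setting); features without vectors are skipped with a warning.
#' @param targets target concept ids; default all non-feature concepts.
#' @return a `semantic_space`; `anchor_metadata$n_skipped` counts features
#'   lacking vectors.
#' @export
feature_space <- function(emb, feature_words, n_features = 100L, targets = NULL) {
  m <- emb_matrix(emb)
  if (is.null(targets)) targets <- setdiff(rownames(m), feature_words)
  targets <- intersect(targets, rownames(m))
  pool <- setdiff(feature_words, targets)
  have <- pool[pool %in% rownames(m)]
  n_skipped <- sum(!(pool %in% rownames(m)) & seq_along(pool) <= n_features)
  if (length(have) < n_features) {
    warning(sprintf("only %d of %d requested feature words have vectors",
                    length(have), n_features))
    n_features <- length(have)
  }
  if (n_features == 0L) stop("no feature words with vectors")
  feats <- have[seq_len(n_features)]
  cm <- cosine_matrix(m[targets, , drop = FALSE], m[feats, , drop = FALSE])
  new_semantic_space(cm, emb$language_code, "feature",
                     list(features = feats, n_skipped = n_skipped))
}

#' Random-word control space
#'
#' Anchors are words sampled without replacement from the master concept
#' list; within one null iteration the same anchor identities are reused in
#' every language, so sample the anchors once (with `sample_random_anchors`)
#' and apply to each table.
#'
#' @param emb an `embedding_table`.
#' @param anchor_ids character vector of sampled anchor concept ids.
#' @param targets target ids; default all concepts excluding anchors.
#' @return a `semantic_space` with one column per anchor.
#' @export
random_word_space <- function(emb, anchor_ids, targets = NULL) {
  m <- emb_matrix(emb)
  if (is.null(targets)) targets <- rownames(m)
  targets <- setdiff(intersect(targets, rownames(m)), anchor_ids)
  have <- intersect(anchor_ids, rownames(m))
  if (length(have) == 0L) stop("no anchor with a vector")
  cm <- cosine_matrix(m[targets, , drop = FALSE], m[have, , drop = FALSE])
  new_semantic_space(cm, emb$language_code, "random_word",
                     list(anchors = have))
}

#' Sample anchor identities for the random-word control
#'
#' @param concepts master concept list.
#' @param n_anchors number of anchors (default 13, matching the dimension
#'   count of the neurocognitive model).
#' @return character vector of anchor ids.
#' @export
sample_random_anchors <- function(concepts, n_anchors = 13L) {
  if (n_anchors > length(concepts)) stop("n_anchors exceeds concept pool")
  sample(concepts, n_anchors)
}

#' Random-dimension (dimensionality-matched) control space
#'
#' Samples `n_words` concepts, groups them into `n_clusters` pseudo
#' dimensions by K-means on the anchor vectors of a designated reference
#' language, then applies the same grouping (by concept identity) in every
#' language: entry (c, g) is the mean cosine of concept c to group g's
#' anchors. This matches the dimensionality of the neurocognitive model
#' while destroying its content.
#'
#' @param emb_set named list of `embedding_table`s, one per language.
#' @param targets target ids; default concepts shared by all languages,
#'   excluding the sampled anchors.
#' @param n_words anchor words sampled per iteration (default 100).
#' @param n_clusters pseudo dimensions (default 13).
#' @param reference language code whose vectors are clustered (default the
#'   first table).
#' @param max_retries K-means retries on an empty-cluster failure.
#' @return named list of `semantic_space`s (one per language) sharing the
#'   same anchor grouping, stored in `anchor_metadata$groups`.
#' @export
random_dimension_space <- function(emb_set, targets = NULL, n_words = 100L,
                                   n_clusters = 13L, reference = NULL,
                                   max_retries = 10L) {
  stopifnot(n_words >= n_clusters)
  if (is.null(reference)) reference <- names(emb_set)[1L]
  shared <- Reduce(intersect, lapply(emb_set, function(e) rownames(emb_matrix(e))))
  if (n_words > length(shared)) stop("n_words exceeds shared concept pool")
  anchor_ids <- sample(shared, n_words)
  refm <- emb_matrix(emb_set[[reference]])[anchor_ids, , drop = FALSE]
  groups <- NULL
  if (n_clusters == n_words) {
    groups <- seq_len(n_words)
  } else {
    for (try in seq_len(max_retries)) {
      km <- tryCatch(stats::kmeans(refm, centers = n_clusters, nstart = 1L),
                     error = function(e) NULL)
      if (!is.null(km) && length(unique(km$cluster)) == n_clusters) {
        groups <- km$cluster; break
      }
    }
    if (is.null(groups)) stop("K-means failed to produce ", n_clusters,
                              " non-empty clusters after ", max_retries, " retries")
  }
  names(groups) <- anchor_ids
  if (is.null(targets)) targets <- shared
  targets <- setdiff(targets, anchor_ids)
  lapply(emb_set, function(e) {
    m <- emb_matrix(e)
    tg <- intersect(targets, rownames(m))
    cm <- cosine_matrix(m[tg, , drop = FALSE], m[anchor_ids, , drop = FALSE])
    out <- matrix(NA_real_, length(tg), n_clusters,
                  dimnames = list(tg, paste0("g", seq_len(n_clusters))))
    for (g in seq_len(n_clusters))
      out[, g] <- rowMeans(cm[, groups == g, drop = FALSE])
    new_semantic_space(out, e$language_code, "random_dimension",
                       list(groups = groups))
  })
}
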