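# colexification network topology and the composite concept-pair distance
#
# A colexification graph has concepts as nodes and an edge weighted by the
# number of languages in which one wordform expresses both concepts. Four
# topology metrics (edge weight; weighted common neighbours; Louvain and
# Infomap community co-membership) capture first-order, second-order, and
# global network information; their normalized average gives a composite
# similarity, and 1 - similarity a topology distance.

#' Build a colexification graph from an edge list
#'
#' Duplicate rows are summed; self-loops dropped with a warning; negative
#' weights are an error.
#'
#' @param edges data.frame with columns concept_a, concept_b, n_languages.
#' @param concepts optional master concept list; edges referencing unknown
#'   concepts are an error, isolated known concepts become nodes.
#' @return an undirected `igraph` graph with integer `weight` edge attribute.
#' @export
build_graph <- function(edges, concepts = NULL) {
  stopifnot(all(c("concept_a", "concept_b", "n_languages") %in% names(edges)))
  if (any(edges$n_languages < 0)) stop("negative edge weight")
  if (!is.null(concepts)) {
    unknown <- setdiff(c(edges$concept_a, edges$concept_b), concepts)
    if (length(unknown)) stop("edges reference unknown concepts: ",
                              paste(utils::head(unknown, 5L), collapse = ", "))
  }
  self <- edges$concept_a == edges$concept_b
  if (any(self)) {
    warning(sum(self), " self-loop row(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  key <- ifelse(edges$concept_a < edges$concept_b,
                paste(edges$concept_a, edges$concept_b, sep = "\r"),
                paste(edges$concept_b, edges$concept_a, sep = "\r"))
  w <- tapply(edges$n_languages, key, sum)
  ab <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ab[, 1L], to = ab[, 2L], weight = as.numeric(w)),
    directed = FALSE,
    vertices = if (is.null(concepts)) NULL else data.frame(name = concepts))
  g
}

#' Weighted common neighbours of two concepts
#'
#' Sum over shared neighbours z of min(w(a,z), w(b,z)) — a bounded,
#' symmetric convention; the product convention sum of w(a,z)*w(b,z) is
#' available via `convention = "product"`.
#'
#' @param g colexification graph.
#' @param a,b node names.
#' @param convention "min" (default) or "product".
#' @return non-negative real.
#' @export
common_neighbors <- function(g, a, b, convention = c("min", "product")) {
  convention <- match.arg(convention)
  wa <- weights_to_neighbors(g, a)
  wb <- weights_to_neighbors(g, b)
  z <- setdiff(intersect(names(wa), names(wb)), c(a, b))
  if (!length(z)) return(0)
  if (convention == "min") sum(pmin(wa[z], wb[z])) else sum(wa[z] * wb[z])
}

weights_to_neighbors <- function(g, v) {
  es <- igraph::incident(g, v)
  if (length(es) == 0L) return(stats::setNames(numeric(0), character(0)))
  ends <- igraph::ends(g, es)
  other <- ifelse(ends[, 1L] == v, ends[, 2L], ends[, 1L])
  stats::setNames(igraph::edge_attr(g, "weight", es), other)
}

#' Community co-membership fractions
#'
#' Runs a seeded community detection algorithm `n_runs` times and reports,
#' for every node pair, the fraction of runs in which the two nodes fall in
#' the same community. Connected components are handled by the algorithms
#' natively; nodes in different components never co-occur.
#'
#' @param g colexification graph.
#' @param algorithm "louvain" or "infomap".
#' @param n_runs number of seeded runs (default 10).
#' @return symmetric numeric matrix in \[0, 1\] with node-name dimnames.
#' @export
community_comembership <- function(g, algorithm = c("louvain", "infomap"),
                                   n_runs = 10L) {
  algorithm <- match.arg(algorithm)
  n <- igraph::vcount(g)
  labs <- igraph::V(g)$name
  acc <- matrix(0, n, n, dimnames = list(labs, labs))
  for (run in seq_len(n_runs)) {
    memb <- switch(algorithm,
      louvain = igraph::membership(igraph::cluster_louvain(g)),
      infomap = igraph::membership(igraph::cluster_infomap(g)))
    same <- outer(memb, memb, `==`) * 1
    acc <- acc + same
  }
  cm <- acc / n_runs
  diag(cm) <- 1
  cm
}

#' Composite topology similarity and distance over all concept pairs
#'
#' Computes edge weight (0 where no edge), weighted common neighbours, and
#' Louvain/Infomap co-membership for every node pair; min-max normalizes
#' each metric to \[0, 1\] over all pairs (a constant metric contributes 0.5
#' uniformly and is flagged); the combined similarity is the mean of the
#' four and the distance is 1 - combined.
#'
#' @param g colexification graph with >= 3 nodes.
#' @param n_runs community-detection runs per algorithm.
#' @param cn_convention common-neighbour convention (see
#'   [common_neighbors()]).
#' @return object of class `topology_similarity`: list of symmetric matrices
#'   `edge_weight`, `common_neighbors`, `louvain`, `infomap`, `combined`,
#'   `distance`, plus `constant_metrics` (character vector of flagged
#'   metrics) and `pairs` (long-format data.frame).
#' @export
combined_similarity <- function(g, n_runs = 10L, cn_convention = "min") {
  n <- igraph::vcount(g)
  if (n < 3L) stop("graph has fewer than 3 nodes")
  labs <- igraph::V(g)$name
  ew <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  dimnames(ew) <- list(labs, labs)
  # dense weighted-common-neighbour computation; zero self-weights make the
  # z = i, j terms vanish, matching common_neighbors()
  cn <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    cn[i, j] <- cn[j, i] <- if (cn_convention == "min")
      sum(pmin(ew[i, ], ew[j, ])) else sum(ew[i, ] * ew[j, ])
  lv <- community_comembership(g, "louvain", n_runs)[labs, labs]
  im <- community_comembership(g, "infomap", n_runs)[labs, labs]
  mats <- list(edge_weight = ew, common_neighbors = cn, louvain = lv, infomap = im)
  lt <- lower.tri(ew)
  constant <- character(0)
  norm <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    rng <- range(m[lt])
    if (diff(rng) == 0) {
      constant <<- c(constant, nm)
      out <- matrix(0.5, n, n, dimnames = dimnames(m))
      return(out)
    }
    (m - rng[1L]) / diff(rng)
  })
  if (length(constant)) warning("constant metric(s) contribute 0.5 uniformly: ",
                                paste(constant, collapse = ", "))
  combined <- Reduce(`+`, norm) / length(norm)
  combined <- (combined + t(combined)) / 2
  distance <- 1 - combined
  diag(distance) <- 0
  idx <- which(lt, arr.ind = TRUE)
  pairs <- data.frame(
    concept_a = labs[idx[, 2L]], concept_b = labs[idx[, 1L]],
    edge_weight = ew[lt], common_neighbors = cn[lt],
    louvain_comembership = lv[lt], infomap_comembership = im[lt],
    combined = combined[lt])
  structure(c(mats, list(combined = combined, distance = distance,
                         constant_metrics = constant, pairs = pairs)),
            class = "topology_similarity")
}

#' Correlate semantic-space distances with colexification topology distance
#'
#' Per language: Spearman correlation (average ranks on ties) between the
#' pairwise semantic distance of shared concepts (1 - Pearson between the
#' two concepts' anchor-projection rows) and the topology distance; the mean
#' across languages is the generalization statistic fed to
#' [null_benchmark()].
#'
#' @param spaces named list of `semantic_space`s.
#' @param topo a `topology_similarity` (or a labelled distance matrix).
#' @param shared_concepts optional concept subset.
#' @return list with `per_language_rho` (named) and `mean_rho`.
#' @export
correlate_semantic_vs_topology <- function(spaces, topo, shared_concepts = NULL) {
  dist_topo <- if (inherits(topo, "topology_similarity")) topo$distance else topo
  rho <- vapply(spaces, function(s) {
    m <- if (inherits(s, "semantic_space")) s$matrix else s
    cps <- intersect(rownames(m), rownames(dist_topo))
    if (!is.null(shared_concepts)) cps <- intersect(cps, shared_concepts)
    if (choose(length(cps), 2L) < 10L) stop("fewer than 10 shared concept pairs")
    sem <- 1 - suppressWarnings(stats::cor(t(m[cps, , drop = FALSE]),
                                           use = "pairwise.complete.obs"))
    td <- dist_topo[cps, cps]
    lt <- lower.tri(sem)
    ok <- is.finite(sem[lt])
    stats::cor(sem[lt][ok], td[lt][ok], method = "spearman")
  }, 0)
  list(per_language_rho = rho, mean_rho = mean(rho))
}
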