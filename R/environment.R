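# environmental distance matrices: climate, geography, family tree,
# demographics, and site-coordinate aggregation

#' Climate distance from bioclim profiles
#'
#' Scaled Euclidean distance: every bioclim variable is z-scored across the
#' included languages, then pairwise Euclidean distance is taken. Languages
#' with any missing variable are excluded (no imputation) and reported.
#'
#' @param profiles numeric matrix or data.frame, languages x bioclim
#'   variables (the standard schema has 19), language codes as rownames.
#' @return labelled RDM; attribute `excluded` lists dropped languages.
#' @export
climate_distance <- function(profiles) {
  m <- as.matrix(profiles)
  complete <- stats::complete.cases(m) & apply(is.finite(m), 1L, all)
  excluded <- rownames(m)[!complete]
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 complete climate profiles")
  sds <- apply(m, 2L, stats::sd)
  if (all(sds == 0)) stop("all bioclim variables constant")
  if (any(sds == 0)) {
    warning("constant bioclim variable(s) dropped: ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  d <- as.matrix(stats::dist(z))
  structure(d, excluded = excluded)
}

#' Great-circle geographic distance matrix (km)
#'
#' Haversine distance on a sphere of radius 6371.0088 km; the WGS84
#' ellipsoidal distance is available with `method = "ellipsoid"` (differences
#' are below 0.6% and vanish after standardization).
#'
#' @param points data.frame or matrix with columns `lat`, `lon` in degrees,
#'   language codes as rownames.
#' @param method "haversine" (default) or "ellipsoid".
#' @return labelled RDM in kilometres.
#' @export
geodesic_distance <- function(points, method = c("haversine", "ellipsoid")) {
  method <- match.arg(method)
  pts <- as.data.frame(points)
  if (!all(c("lat", "lon") %in% names(pts))) stop("need columns lat, lon")
  if (any(pts$lat < -90 | pts$lat > 90)) stop("latitude out of [-90, 90]")
  if (any(pts$lon < -180 | pts$lon > 180)) stop("longitude out of [-180, 180]")
  xy <- cbind(pts$lon, pts$lat)
  d <- switch(method,
    haversine = geosphere::distm(
      xy, fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000,
    ellipsoid = geosphere::distm(xy, fun = geosphere::distGeo) / 1000)
  dimnames(d) <- list(rownames(points), rownames(points))
  diag(d) <- 0
  d
}

#' Tree-step distance between two leaves of a family tree
#'
#' Counts the edges from each leaf up to their lowest common ancestor and
#' sums the two step counts (a metric, symmetric); the max-steps alternative
#' is available via `convention = "max"`. Zero iff the leaves coincide.
#'
#' @param family_tree an `ape::phylo` tree with languages at the leaves.
#' @param a,b leaf labels.
#' @param convention "sum" (default) or "max".
#' @return non-negative integer.
#' @export
tree_distance <- function(family_tree, a, b, convention = c("sum", "max")) {
  convention <- match.arg(convention)
  tips <- family_tree$tip.label
  if (!(a %in% tips) || !(b %in% tips)) stop("leaf not in tree: ",
                                             setdiff(c(a, b), tips)[1L])
  if (a == b) return(0L)
  ia <- match(a, tips); ib <- match(b, tips)
  up_a <- steps_to_root(family_tree, ia)
  up_b <- steps_to_root(family_tree, ib)
  common <- intersect(names(up_a), names(up_b))
  lca <- common[which.min(up_a[common])]
  if (convention == "sum") up_a[[lca]] + up_b[[lca]]
  else max(up_a[[lca]], up_b[[lca]])
}

# named vector: ancestor node id -> steps from `node` up to it
steps_to_root <- function(phy, node) {
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  steps <- integer(0)
  cur <- node; k <- 0L
  while (parent[cur] != 0L) {
    cur <- parent[cur]; k <- k + 1L
    steps[as.character(cur)] <- k
  }
  steps
}

#' Tree-step distance matrix over all leaves
#' @param family_tree an `ape::phylo` tree.
#' @param convention see [tree_distance()].
#' @return labelled integer RDM.
#' @export
tree_distance_matrix <- function(family_tree, convention = "sum") {
  tips <- family_tree$tip.label
  n <- length(tips)
  d <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    d[i, j] <- d[j, i] <- tree_distance(family_tree, tips[i], tips[j],
                                        convention = convention)
  d
}

#' Demographic distance between language samples
#'
#' Language-level means of age, gender (proportion-coded within language),
#' education level, and socioeconomic status are z-scored across languages
#' and compared by Euclidean distance. Participants missing a covariate are
#' dropped from that covariate's mean and reported.
#'
#' @param participants data.frame with columns language_code, age, gender
#'   (character/factor; the first level's proportion is used), education,
#'   ses.
#' @return labelled RDM; attribute `n_dropped` counts per-covariate drops.
#' @export
demographic_distance <- function(participants) {
  need <- c("language_code", "age", "gender", "education", "ses")
  if (!all(need %in% names(participants)))
    stop("need columns: ", paste(need, collapse = ", "))
  ref_gender <- sort(unique(stats::na.omit(as.character(participants$gender))))[1L]
  gnum <- as.numeric(as.character(participants$gender) == ref_gender)
  raw <- data.frame(age = participants$age, gender = gnum,
                    education = participants$education, ses = participants$ses)
  n_dropped <- colSums(is.na(raw))
  langs <- unique(participants$language_code)
  mm <- t(vapply(langs, function(lg)
    colMeans(raw[participants$language_code == lg, , drop = FALSE], na.rm = TRUE),
    numeric(4L)))
  rownames(mm) <- langs
  sds <- apply(mm, 2L, stats::sd)
  if (all(sds == 0)) {
    d <- matrix(0, nrow(mm), nrow(mm), dimnames = list(langs, langs))
    return(structure(d, n_dropped = n_dropped))
  }
  z <- scale(mm[, sds > 0, drop = FALSE])
  d <- as.matrix(stats::dist(z))
  structure(d, n_dropped = n_dropped)
}

#' Aggregate site coordinates to one geographic centre per language
#'
#' Arithmetic mean of latitude and longitude across a language's sites; a
#' warning is emitted when a language's sites span more than 180 degrees of
#' longitude (antimeridian wraparound makes the plain mean questionable).
#'
#' @param sites data.frame with columns language_code, lat, lon.
#' @return data.frame with rownames = language codes and columns lat, lon.
#' @export
aggregate_coordinates <- function(sites) {
  stopifnot(all(c("language_code", "lat", "lon") %in% names(sites)))
  langs <- unique(sites$language_code)
  out <- t(vapply(langs, function(lg) {
    s <- sites[sites$language_code == lg, , drop = FALSE]
    if (nrow(s) == 0L) stop("no sites for language ", lg)
    if (diff(range(s$lon)) > 180)
      warning("sites of ", lg, " span the antimeridian; mean longitude unreliable")
    c(lat = mean(s$lat), lon = mean(s$lon))
  }, c(lat = 0, lon = 0)))
  as.data.frame(out)
}
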