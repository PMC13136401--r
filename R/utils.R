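# shared numeric helpers

#' Fisher r-to-z transform
#'
#' atanh of a correlation, with the argument clipped to +/- (1 - 1e-7) so a
#' perfect correlation maps to a large finite value rather than Inf.
#'
#' @param r numeric vector of correlations in \[-1, 1\].
#' @return numeric vector of z values.
#' @examples
#' fisher_z(0)      # 0
#' fisher_z(0.5)    # atanh(0.5)
#' @export
fisher_z <- function(r) {
  if (any(is.na(r))) stop("fisher_z: NA/NaN correlation input")
  atanh(clip_r(r))
}

clip_r <- function(r, bound = 1 - 1e-7) pmin(pmax(r, -bound), bound)

#' Cosine similarity of two vectors
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return cosine similarity in \[-1, 1\].
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("cosine: vectors of unequal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine: zero vector")
  s <- sum(u * v) / (nu * nv)
  min(max(s, -1), 1)
}

# rows of `m` L2-normalized; zero rows rejected
row_normalize <- function(m) {
  n <- sqrt(rowSums(m^2))
  if (any(n == 0)) stop("all-zero vector not admitted to similarity computations")
  m / n
}

# cosine matrix between rows of a (targets) and rows of b (anchors)
cosine_matrix <- function(a, b) {
  row_normalize(a) %*% t(row_normalize(b))
}

# Pearson r between corresponding rows of two matrices (pairwise over
# columns where both are finite); rows with < min_cols usable columns or
# zero variance give NA
rowwise_pearson <- function(a, b, min_cols = 3L) {
  stopifnot(all(dim(a) == dim(b)))
  out <- rep(NA_real_, nrow(a))
  for (i in seq_len(nrow(a))) {
    x <- a[i, ]; y <- b[i, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_cols) next
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    out[i] <- stats::cor(x, y)
  }
  out
}

# standardize a numeric vector to mean 0, sd 1
zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant column")
  (x - mean(x)) / s
}

lower_tri <- function(m) m[lower.tri(m)]

# labels of the lower-triangle pairs of a labelled square matrix, i > j
lower_tri_pairs <- function(labels) {
  n <- length(labels)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(lang_i = labels[idx[, 1]], lang_j = labels[idx[, 2]],
             stringsAsFactors = FALSE)
}
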