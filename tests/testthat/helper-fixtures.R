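# small fixtures built in code

# deterministic toy embedding table: n concepts x d dims
toy_embedding <- function(n = 6L, d = 4L, seed = 1L, language = "toy") {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * d), n, d,
              dimnames = list(sprintf("w%02d", seq_len(n)), NULL))
  embedding_table(m, language)
}

# brute-force cosine: independent of the package's linear-algebra path
cos_oracle <- function(u, v) sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))

# brute-force cosine matrix between row sets
cos_mat_oracle <- function(a, b) {
  out <- matrix(NA_real_, nrow(a), nrow(b),
                dimnames = list(rownames(a), rownames(b)))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    out[i, j] <- cos_oracle(a[i, ], b[j, ])
  out
}

# a tiny rating table with known structure
toy_ratings <- function(n_lang = 2L, n_part = 3L, n_concept = 4L, n_dim = 3L,
                        noise = 0, seed = 1L) {
  set.seed(seed)
  mu <- array(stats::runif(n_lang * n_concept * n_dim, 1, 5),
              c(n_lang, n_concept, n_dim))
  rows <- list()
  pid <- 0L
  for (l in seq_len(n_lang)) for (p in seq_len(n_part)) {
    pid <- pid + 1L
    vals <- mu[l, , ] + matrix(stats::rnorm(n_concept * n_dim, 0, noise),
                               n_concept, n_dim)
    rows[[pid]] <- data.frame(
      participant = sprintf("p%02d", pid),
      language_code = sprintf("L%d", l),
      concept_id = rep(sprintf("c%d", seq_len(n_concept)), n_dim),
      dimension = rep(sprintf("d%d", seq_len(n_dim)), each = n_concept),
      rating = as.vector(vals))
  }
  do.call(rbind, rows)
}
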