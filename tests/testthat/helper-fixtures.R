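# Small in-code fixtures shared across test files.

# deterministic little community: 4 years x 5 taxa, all taxa seen
toy_matrix <- function(site = "brook") {
  counts <- rbind(c(10, 2, 0, 1, 3),
                  c(8, 0, 1, 2, 3),
                  c(12, 1, 2, 0, 4),
                  c(9, 3, 1, 1, 2))
  community_matrix(counts, site_id = site, years = 2001:2004,
                   taxa = paste0("t", 1:5))
}

# long-format tibble matching toy_matrix()
toy_long <- function(site = "brook") {
  community_to_long(toy_matrix(site))
}

# a random valid community matrix
random_matrix <- function(n_years = 6, n_taxa = 12, site = "rnd",
                          lambda = 3) {
  repeat {
    counts <- matrix(stats::rpois(n_years * n_taxa, lambda), n_years, n_taxa)
    if (all(rowSums(counts) > 0) && all(colSums(counts) > 0)) break
  }
  community_matrix(counts, site_id = site, years = 2000 + seq_len(n_years) - 1,
                   taxa = sprintf("t%02d", seq_len(n_taxa)))
}

# environment table consistent with a list of matrices (jittered so the
# predictors are never collinear)
toy_environment <- function(matrices, seed = 404) {
  sites <- vapply(matrices, site_id, character(1))
  n <- length(sites)
  withr::with_seed(seed, tibble::tibble(
    site = sites,
    bmi = pmax(0, 20 + 8 * stats::rnorm(n)),
    bryophytes = pmin(100, pmax(0, 45 + 18 * stats::rnorm(n))),
    simpson = 1 + stats::rgamma(n, shape = 4, rate = 2),
    temperature = 9 + 1.5 * stats::rnorm(n),
    connectivity = stats::rlnorm(n, log(800), 0.5)))
}

# enumerate all binary matrices with the margins of `m` (tiny inputs only)
enumerate_fixed_margins <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr * nc <= 16)
  rs <- rowSums(m); cs <- colSums(m)
  grid <- as.matrix(expand.grid(rep(list(0:1), nr * nc)))
  keep <- apply(grid, 1, function(v) {
    cand <- matrix(v, nr, nc)
    all(rowSums(cand) == rs) && all(colSums(cand) == cs)
  })
  lapply(which(keep), function(i) matrix(grid[i, ], nr, nc))
}

# stable key for a binary matrix, for counting ensemble members
matrix_key <- function(m) paste(as.integer(m), collapse = "")
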