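test_that("curveball randomization conserves all margins", {
  set.seed(31)
  for (i in 1:10) {
    m <- (matrix(stats::runif(8 * 15), 8, 15) < 0.4) * 1L
    m[rowSums(m) == 0, 1] <- 1L
    r <- binary_randomize(m, trades = 200)
    expect_identical(rowSums(r), rowSums(m))
    expect_identical(colSums(r), colSums(m))
    expect_identical(sum(r), sum(m))
    expect_true(all(r %in% c(0L, 1L)))
  }
})

test_that("ensembles of size one pass through unchanged", {
  ones <- matrix(1L, 3, 4)
  expect_identical(binary_randomize(ones, 100), ones)
  expect_error(binary_randomize(ones, -1), "non-negative")
  zero_row <- rbind(c(1L, 0L), c(0L, 0L))
  expect_error(binary_randomize(zero_row, 10), "all-zero")
})

test_that("the 2x2 checkerboard flips to each configuration about half the time", {
  m <- diag(1L, 2)
  set.seed(77)
  draws <- replicate(1000, binary_randomize(m, trades = 5)[1, 1])
  p <- mean(draws == 1L)
  # ensemble has exactly two members; binomial 99.9% band around 0.5
  expect_gt(p, 0.45)
  expect_lt(p, 0.55)
})

test_that("min-1 multinomial allocation honours totals and forced cases", {
  one_cell <- matrix(c(1L, 1L), 2, 1)
  out <- allocate_abundances(c(5L, 7L), one_cell)
  expect_identical(out[, 1], c(5L, 7L))

  forced <- matrix(1L, 2, 3)
  expect_identical(allocate_abundances(c(3L, 3L), forced),
                   matrix(1L, 2, 3))
  expect_error(allocate_abundances(c(2L, 3L), forced), "smaller than")
})

test_that("surplus individuals spread as an equal-probability multinomial", {
  # total 4 over 2 presence cells: (1,3),(2,2),(3,1) with prob 1/4,1/2,1/4
  pres <- matrix(c(1L, 1L), 1, 2)
  set.seed(123)
  draws <- replicate(4000, allocate_abundances(4L, pres)[1, 1])
  expect_true(all(draws %in% 1:3))
  freq <- table(factor(draws, levels = 1:3)) / 4000
  expect_equal(as.numeric(freq), c(0.25, 0.5, 0.25), tolerance = 0.035)
})

test_that("value-shuffling allocation preserves the abundance multiset", {
  m <- toy_matrix()
  pres <- (unclass(m) > 0) * 1L
  vals <- as.integer(m)[m > 0]
  suppressWarnings(
    out <- allocate_abundances(rowSums(m), pres, scheme = "shuffle_nonzero",
                               values = vals))
  expect_identical(sort(as.integer(out)[out > 0]), sort(vals))
  expect_identical((out > 0) * 1L, pres)
  expect_warning(
    allocate_abundances(rowSums(m), pres, scheme = "shuffle_nonzero",
                        values = vals),
    "totals")
})

test_that("null distribution conserves margins every iteration and is seeded", {
  m <- random_matrix(n_years = 6, n_taxa = 20)
  nd1 <- null_distribution(m, n_iter = 40, seed = 11,
                           check_conservation = TRUE, keep_iterations = TRUE)
  nd2 <- null_distribution(m, n_iter = 40, seed = 11, keep_iterations = TRUE)
  expect_identical(nd1$beta_dep, nd2$beta_dep)
  expect_identical(attr(nd1, "per_iteration_means"),
                   attr(nd2, "per_iteration_means"))
  its <- attr(nd1, "per_iteration_means")
  expect_true(all(its >= 0 & its <= 1))
  nd3 <- null_distribution(m, n_iter = 40, seed = 12)
  expect_false(identical(nd1$beta_exp_mean, nd3$beta_exp_mean))
})

test_that("per-site RNG streams make results order-independent", {
  mats <- list(random_matrix(site = "a"), random_matrix(site = "b"))
  fwd <- null_beta(mats, n_iter = 25, seed = 3)
  rev <- null_beta(rev(mats), n_iter = 25, seed = 3)
  expect_equal(dplyr::arrange(fwd, site), dplyr::arrange(rev, site))
})

test_that("departure statistic arithmetic and degenerate nulls", {
  expect_equal(beta_departure(0.30, 0.30, 0.05), 0)
  expect_equal(beta_departure(0.25, 0.30, 0.025), -2)
  expect_equal(beta_departure(0.35, 0.30, 0.025), 2)
  expect_identical(beta_departure(0.4, 0.3, 0), 0)
  expect_error(beta_departure(0.3, 0.3, -0.1), ">= 0")

  # a constant community under a forced single-member ensemble:
  # sd of iteration means is 0 -> flagged degenerate, beta_dep 0
  m <- community_matrix(rbind(c(2, 1), c(2, 1)), "deg", years = 2000:2001,
                        taxa = c("a", "b"))
  nd <- null_distribution(m, n_iter = 5, seed = 1,
                          allocation_scheme = "shuffle_nonzero")
  expect_true(nd$degenerate_null)
  expect_identical(nd$beta_dep, 0)
})

test_that("stability classification uses a strict threshold", {
  got <- classify_stability(c(-2.5, -1.0, -2.0, -8.9))
  expect_identical(as.character(got),
                   c("more_stable_than_chance", "indistinguishable",
                     "indistinguishable", "more_stable_than_chance"))
  expect_error(classify_stability(NaN), "finite")
})

test_that("a persistent, abundance-stable community departs negatively", {
  # strong year-to-year persistence with frozen abundances: beta_obs
  # far below the null expectation
  set.seed(8)
  base <- stats::rpois(25, 4) + 1
  counts <- t(replicate(10, base))
  # sprinkle a little occupancy turnover so the ensemble is non-trivial
  for (y in 1:10) {
    off <- sample.int(25, 6)
    counts[y, off] <- 0
  }
  stopifnot(all(rowSums(counts) > 0))
  keep <- colSums(counts) > 0
  m <- community_matrix(counts[, keep, drop = FALSE], "pers",
                        years = 2000:2009,
                        taxa = sprintf("t%02d", seq_len(sum(keep))))
  nd <- null_distribution(m, n_iter = 200, seed = 21)
  expect_lt(nd$beta_obs, nd$beta_exp_mean)
  expect_lt(nd$beta_dep, -2)
})

test_that("observed vs vegan curveball: same fixed-margins ensemble", {
  skip_if_not_installed("vegan")
  set.seed(55)
  m <- (matrix(stats::runif(5 * 8), 5, 8) < 0.45) * 1L
  m[rowSums(m) == 0, 1] <- 1L
  ours <- binary_randomize(m, trades = 300)
  nm <- vegan::nullmodel(m, "curveball")
  theirs <- simulate(nm, nsim = 1, burnin = 300)[, , 1]
  expect_identical(rowSums(ours), rowSums(theirs))
  expect_identical(colSums(ours), unname(colSums(theirs)))
})
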