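test_that("long reader pivots to per-site matrices with implicit zeros", {
  df <- tibble::tibble(site = c("A", "A", "A"),
                       year = c(2000L, 2000L, 2001L),
                       taxon = c("t1", "t2", "t1"),
                       count = c(2, 1, 4))
  mats <- community_from_long(df)
  expect_named(mats, "A")
  m <- mats$A
  expect_identical(community_years(m), 2000:2001)
  expect_identical(as.integer(m), c(2L, 4L, 1L, 0L))  # column-major
  expect_identical(colnames(m), c("t1", "t2"))
  expect_identical(unname(alpha_richness(m)), c(2L, 1L))
  expect_identical(gamma_richness(m), 2L)
})

test_that("14 contiguous years yield 13 consecutive pairs downstream", {
  set.seed(71)
  df <- tidyr::expand_grid(site = "S", year = 2000:2013,
                           taxon = sprintf("t%02d", 1:20)) |>
    dplyr::mutate(count = stats::rpois(dplyr::n(), 2)) |>
    dplyr::filter(count > 0)
  m <- community_from_long(df)$S
  expect_identical(nrow(m), 14L)
  expect_identical(nrow(consecutive_dissimilarities(m)), 13L)
})

test_that("reader rejects invalid counts, duplicates and year gaps", {
  base <- toy_long()
  neg <- dplyr::mutate(base, count = replace(count, 1, -1))
  expect_error(community_from_long(neg), "non-negative integers")
  frac <- dplyr::mutate(base, count = replace(count, 2, 1.5))
  expect_error(community_from_long(frac), "non-negative integers")
  dup <- dplyr::bind_rows(base, base[3, ])
  expect_error(community_from_long(dup), "duplicate")
  gap <- dplyr::filter(base, year != 2002)
  expect_error(community_from_long(gap), "consecutive")
})

test_that("community matrix validation enforces its invariants", {
  expect_error(community_matrix(matrix(1:2, 1, 2), "s", years = 2000,
                                taxa = c("a", "b")), "at least 2 years")
  expect_error(community_matrix(rbind(1:2, 3:4), "s", years = c(2001, 2000),
                                taxa = c("a", "b")), "strictly increasing")
  expect_error(community_matrix(rbind(1:2, 3:4), "s", years = c(2000, 2000),
                                taxa = c("a", "b")), "strictly increasing")
  expect_error(community_matrix(rbind(1:2, 3:4), "s", years = c(2000, 2001),
                                taxa = c("a", "a")), "duplicated taxon")
  expect_warning(
    m <- community_matrix(rbind(c(1, 0), c(2, 0)), "s", years = 2000:2001,
                          taxa = c("a", "zero")),
    "all-zero")
  expect_identical(colnames(m), "a")
})

test_that("row order of the long file never changes the matrix", {
  df <- toy_long()
  set.seed(9)
  shuffled <- df[sample.int(nrow(df)), ]
  expect_identical(community_from_long(df), community_from_long(shuffled))
})

test_that("long and wide readers round-trip through files", {
  dir <- withr::local_tempdir()
  mats <- list(toy_matrix("a1"), toy_matrix("b2"))
  path <- file.path(dir, "comm.tsv")
  readr::write_tsv(community_to_long(mats), path)
  back <- read_community_long(path)
  expect_identical(back, stats::setNames(mats, c("a1", "b2")))

  wide <- file.path(dir, "wide.csv")
  m <- toy_matrix("w")
  df <- tibble::as_tibble(unclass(m)) |>
    dplyr::mutate(year = community_years(m), .before = 1)
  readr::write_csv(df, wide)
  expect_identical(read_community_wide(wide, site_id = "w"), m)
})

test_that("taxon exclusion removes groups not counted every year", {
  df <- toy_long()
  mats <- community_from_long(df, exclude_taxa = "t1")
  expect_false("t1" %in% colnames(mats[[1]]))
  expect_identical(gamma_richness(mats[[1]]), 4L)
})

test_that("environment reader validates shape, ranges and duplicates", {
  dir <- withr::local_tempdir()
  env <- toy_environment(list(toy_matrix("x"), toy_matrix("y"), toy_matrix("z")))
  path <- file.path(dir, "env.tsv")
  readr::write_tsv(env, path)
  got <- read_environment(path)
  expect_equal(got$connectivity, env$connectivity, tolerance = 1e-12)

  writeLines(character(), file.path(dir, "empty.tsv"))
  expect_error(read_environment(file.path(dir, "empty.tsv")), "empty")

  readr::write_tsv(dplyr::bind_rows(env, env[1, ]), path)
  expect_error(read_environment(path), "duplicated site")

  env_na <- env
  env_na$bmi[2] <- NA
  readr::write_tsv(env_na, path)
  expect_error(read_environment(path), "missing values.*bmi")
})

test_that("environment/community assembly aligns sites and computes gamma", {
  mats <- list(toy_matrix("x"), toy_matrix("y"))
  env <- toy_environment(mats)
  full <- assemble_environment(env, mats)
  expect_identical(full$gamma, c(5L, 5L))
  expect_identical(names(full),
                   c("site", "bmi", "bryophytes", "simpson", "temperature",
                     "connectivity", "gamma"))
  expect_error(assemble_environment(env[1, ], mats), "site sets differ")
})

test_that("numeric round-trip through TSV holds to 12 significant digits", {
  dir <- withr::local_tempdir()
  env <- toy_environment(list(toy_matrix("q"))) |>
    dplyr::mutate(simpson = 1 + pi, temperature = exp(1) * 3)
  path <- file.path(dir, "env.tsv")
  readr::write_tsv(env, path)
  back <- read_environment(path)
  expect_equal(back$simpson, env$simpson, tolerance = 1e-12)
  expect_equal(back$temperature, env$temperature, tolerance = 1e-12)
})

test_that("result writer emits the expected tables and refuses empties", {
  dir <- withr::local_tempdir()
  mats <- lapply(1:12, function(i) {
    random_matrix(n_taxa = 8 + i, site = sprintf("s%02d", i))
  })
  names(mats) <- vapply(mats, site_id, character(1))
  env <- toy_environment(mats)
  set.seed(1)
  env$bryophytes <- env$bryophytes + rnorm(12)   # avoid exact collinearity
  env$bmi <- env$bmi + rnorm(12)
  env$simpson <- env$simpson + abs(rnorm(12, 0, 0.2))
  env$temperature <- env$temperature + rnorm(12)
  an <- temporal_beta_analysis(mats, env, n_iter = 30, seed = 4)
  paths <- write_results(an, dir)
  expect_true(all(file.exists(paths)))
  beta <- readr::read_tsv(paths[["beta_by_site.tsv"]],
                          show_col_types = FALSE)
  expect_identical(nrow(beta), 12L)
  imp <- readr::read_tsv(paths[["importance.tsv"]], show_col_types = FALSE)
  expect_identical(nrow(imp), 12L)  # 6 predictors x 2 responses
  expect_error(write_results(list(beta = tibble::tibble()), dir), "empty")
})
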