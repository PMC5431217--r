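stones <- function(percs, site = "s1") {
  tibble::tibble(site = site, period = sprintf("p%d", seq_along(percs)),
                 n_stones = 100L, n_moved = as.integer(percs))
}

test_that("bed movement indices: intensity, strict frequency, maximum", {
  rec <- stones(c(30, 10))
  expect_equal(bed_movement_intensity(rec)$bmi, 20)
  expect_equal(bed_movement_intensity(stones(c(100, 100)))$bmi, 100)
  expect_equal(bed_movement_intensity(stones(c(0, 0, 0)))$bmi, 0)

  expect_equal(bed_movement_frequency(stones(c(25, 15, 30)))$bed_movement_freq,
               2 / 3)
  # boundary: exactly at the threshold never counts
  expect_equal(bed_movement_frequency(stones(c(20, 20)))$bed_movement_freq, 0)
  expect_equal(bed_movement_frequency(stones(100))$bed_movement_freq, 1)

  expect_equal(bed_movement_maximum(stones(c(10, 35, 20)))$bed_movement_max, 35)
  expect_equal(bed_movement_maximum(stones(12))$bed_movement_max, 12)
})

test_that("period percentages pool stones across size classes", {
  rec <- tibble::tibble(site = "s1", period = "p1",
                        size_class = c("p50", "p75", "p90"),
                        n_stones = c(10L, 20L, 30L),
                        n_moved = c(10L, 2L, 0L))
  expect_equal(bed_movement_intensity(rec)$bmi, 100 * 12 / 60)
})

test_that("stone record validation", {
  bad <- tibble::tibble(site = "s", period = "p", n_stones = 10L, n_moved = 11L)
  expect_error(bed_movement_intensity(bad), "n_moved")
  bad2 <- tibble::tibble(site = "s", period = "p", n_stones = 0L, n_moved = 0L)
  expect_error(bed_movement_intensity(bad2), "n_stones")
})

test_that("substrate Simpson diversity (1/D) on pooled quadrats", {
  q <- function(counts, site = "s1", quadrat = 1) {
    out <- tibble::as_tibble(as.list(stats::setNames(counts, paste0("class_", 0:9))))
    dplyr::mutate(out, site = site, quadrat = quadrat, .before = 1)
  }
  one_class <- q(c(50, rep(0, 9)))
  expect_equal(simpson_substrate_diversity(one_class)$simpson, 1)
  four_equal <- q(c(rep(10, 4), rep(0, 6)))
  expect_equal(simpson_substrate_diversity(four_equal)$simpson, 4)
  prop <- q(c(75, 25, rep(0, 8)))
  expect_equal(simpson_substrate_diversity(prop)$simpson, 1.6)

  # pooling two quadrats equals one quadrat with summed counts
  two <- dplyr::bind_rows(q(c(30, 10, rep(0, 8)), quadrat = 1),
                          q(c(45, 15, rep(0, 8)), quadrat = 2))
  expect_equal(simpson_substrate_diversity(two)$simpson, 1.6)
  # averaged variant averages per-quadrat indices instead
  mixed <- dplyr::bind_rows(q(c(10, 10, rep(0, 8)), quadrat = 1),
                            q(c(20, 0, rep(0, 8)), quadrat = 2))
  expect_equal(simpson_substrate_diversity(mixed, method = "averaged")$simpson,
               1.5)
  bad <- dplyr::mutate(one_class, class_11 = 3)
  expect_error(simpson_substrate_diversity(bad), "outside 0-9")
})

test_that("cover and temperature means", {
  cv <- tibble::tibble(site = "s1", cover = c(40, 60))
  expect_equal(mean_cover(cv)$bryophytes, 50)
  expect_equal(mean_cover(tibble::tibble(site = "s", cover = rep(0, 20)))$bryophytes, 0)
  expect_error(mean_cover(tibble::tibble(site = "s", cover = 105)), "0, 100")

  # year means first, then across years: unbalanced days don't bias
  tm <- tibble::tibble(site = "s1",
                       year = c(2009L, 2009L, 2009L, 2010L),
                       daily_mean = c(8, 8, 8, 12))
  expect_equal(mean_temperature(tm)$temperature, 10)
  tm_date <- tibble::tibble(site = "s1", date = c("2009-06-01", "2010-06-01"),
                            daily_mean = c(9, 11))
  expect_equal(mean_temperature(tm_date)$temperature, 10)
})

test_that("riffle connectivity sums length x width over both directions", {
  seg <- tibble::tibble(site = "s1", direction = c("upstream", "downstream"),
                        length_m = c(50, 50), width_m = c(4, 4))
  expect_equal(connectivity_riffle_area(seg)$connectivity, 400)
  expect_equal(connectivity_riffle_area(seg[0, ], all_sites = "s1")$connectivity, 0)
  widths1 <- tibble::tibble(site = "s", direction = "upstream",
                            length_m = c(10, 20), width_m = 1)
  expect_equal(connectivity_riffle_area(widths1)$connectivity, 30)
  expect_error(connectivity_riffle_area(dplyr::mutate(seg, width_m = -1)),
               "positive")
})

test_that("rank consistency across repeat surveys", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(10, 20, 30, 40))
  expect_equal(as.numeric(rank_consistency(m)), 1)
  rev2 <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(as.numeric(rank_consistency(rev2)), -1)
  hand <- cbind(a = c(1, 2, 3), b = c(2, 1, 3))
  expect_equal(as.numeric(rank_consistency(hand)), 0.5)
  # invariant to monotone transforms
  m2 <- cbind(exp(m[, 1]), m[, 2]^3)
  expect_equal(as.numeric(rank_consistency(m2)), 1)
  # constant column skipped with a warning
  const <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(1, 3, 2))
  expect_warning(r <- rank_consistency(const), "constant")
  expect_equal(as.numeric(r), 0.5)
  # tidy input
  long <- tibble::tibble(site = rep(c("x", "y", "z"), 2),
                         time = rep(c("t1", "t2"), each = 3),
                         value = c(1, 2, 3, 2, 1, 3))
  expect_equal(as.numeric(rank_consistency(long)), 0.5)
})

test_that("build_environment assembles and validates the predictor table", {
  sites <- c("s1", "s2", "s3")
  st <- dplyr::bind_rows(lapply(sites, function(s) stones(c(10, 30), site = s)))
  qd <- purrr::map_dfr(sites, function(s) {
    tibble::tibble(site = s, quadrat = 1,
                   class_0 = 5, class_1 = 5, class_2 = 0, class_3 = 0,
                   class_4 = 0, class_5 = 0, class_6 = 0, class_7 = 0,
                   class_8 = 0, class_9 = 0)
  })
  br <- tidyr::expand_grid(site = sites, quadrat = 1:3) |>
    dplyr::mutate(cover = 30)
  tm <- tidyr::expand_grid(site = sites, year = 2009:2010) |>
    dplyr::mutate(daily_mean = 9)
  rf <- tibble::tibble(site = sites, direction = "upstream",
                       length_m = 40, width_m = 5)
  env <- build_environment(st, qd, br, tm, rf)
  expect_identical(nrow(env), 3L)
  expect_equal(env$bmi, rep(20, 3))
  expect_equal(env$simpson, rep(2, 3))
  expect_equal(env$bryophytes, rep(30, 3))
  expect_equal(env$temperature, rep(9, 3))
  expect_equal(env$connectivity, rep(200, 3))
})
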