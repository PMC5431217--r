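# Explanatory variables derived from field-style records: streambed
# disturbance from marked-stone monitoring, substrate heterogeneity,
# vegetation cover, water temperature and riffle-network connectivity.

check_stone_records <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("site", "period", "n_stones", "n_moved")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("stone records lack column(s): %s",
                         paste(miss, collapse = ", ")))
  }
  if (any(records$n_stones <= 0)) rlang::abort("`n_stones` must be > 0")
  if (any(records$n_moved < 0 | records$n_moved > records$n_stones)) {
    rlang::abort("`n_moved` must lie in [0, n_stones]")
  }
  records
}

# percent of stones moved per (site, period), pooled over size classes
period_percent_moved <- function(records) {
  check_stone_records(records) |>
    dplyr::group_by(.data$site, .data$period) |>
    dplyr::summarise(percent_moved = 100 * sum(.data$n_moved) / sum(.data$n_stones),
                     .groups = "drop")
}

#' Streambed disturbance indices from marked-stone monitoring
#'
#' Stones spanning the site's substrate size distribution are marked and
#' checked after each monitoring period; the fraction moved (or turned)
#' indexes bed disturbance.  Stone counts are pooled over size classes
#' within a period.  Three summaries per site:
#' `bed_movement_intensity()` (BMI) is the mean percentage of stones
#' moved across periods; `bed_movement_frequency()` is the proportion of
#' periods with strictly more than `threshold` percent moved;
#' `bed_movement_maximum()` is the largest period percentage.
#'
#' @param records tibble of stone-monitoring records with columns
#'   `site`, `period`, `n_stones`, `n_moved` (extra columns such as
#'   `season` or `size_class` are allowed and pooled over).
#' @param threshold percent cut-off for a period to count as a
#'   high-movement period (strict `>`; default 20).
#' @return tibble with one row per site: `site` and the index column
#'   (`bmi`, `bed_movement_freq` or `bed_movement_max`, all on the
#'   percent or proportion scale).
#' @examples
#' rec <- tibble::tibble(site = "s1", period = c("p1", "p2"),
#'                       n_stones = c(30, 30), n_moved = c(9, 3))
#' bed_movement_intensity(rec)  # (30% + 10%) / 2 = 20
#' @export
bed_movement_intensity <- function(records) {
  period_percent_moved(records) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(bmi = mean(.data$percent_moved), .groups = "drop")
}

#' @rdname bed_movement_intensity
#' @export
bed_movement_frequency <- function(records, threshold = 20) {
  period_percent_moved(records) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(bed_movement_freq = mean(.data$percent_moved > threshold),
                     .groups = "drop")
}

#' @rdname bed_movement_intensity
#' @export
bed_movement_maximum <- function(records) {
  period_percent_moved(records) |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(bed_movement_max = max(.data$percent_moved),
                     .groups = "drop")
}

#' Substrate heterogeneity as inverse Simpson diversity of size classes
#'
#' Particle counts per quadrat are recorded in modified Wentworth
#' classes 0 (silt) to 9 (large boulder/bedrock).  With class
#' proportions `p_c`, the index is `1 / sum(p_c^2)` (inverse Simpson,
#' 1/D): 1 when a single class dominates completely, k for k equally
#' frequent classes.  Quadrats are pooled per site before computing the
#' index (default); `method = "averaged"` instead averages per-quadrat
#' indices.
#'
#' @param quadrats tibble with columns `site`, `quadrat` and
#'   `class_0` .. `class_9` particle counts.
#' @param method `"pooled"` (default) or `"averaged"`.
#' @return tibble with columns `site`, `simpson`.
#' @export
simpson_substrate_diversity <- function(quadrats, method = c("pooled", "averaged")) {
  method <- match.arg(method)
  quadrats <- tibble::as_tibble(quadrats)
  class_cols <- grep("^class_[0-9]$", names(quadrats), value = TRUE)
  if (length(class_cols) == 0L) {
    rlang::abort("substrate quadrats need count columns class_0 .. class_9")
  }
  extra <- grep("^class_", names(quadrats), value = TRUE)
  if (length(setdiff(extra, class_cols)) > 0L) {
    rlang::abort(sprintf("substrate classes outside 0-9 are not valid: %s",
                         paste(setdiff(extra, class_cols), collapse = ", ")))
  }
  counts <- as.matrix(quadrats[class_cols])
  if (anyNA(counts) || any(counts < 0)) {
    rlang::abort("substrate class counts must be non-negative")
  }
  inv_simpson <- function(x) {
    tot <- sum(x)
    if (tot <= 0) rlang::abort("substrate counts sum to zero")
    1 / sum((x / tot)^2)
  }
  if (method == "pooled") {
    tibble::tibble(site = quadrats$site) |>
      dplyr::bind_cols(tibble::as_tibble(counts)) |>
      dplyr::group_by(.data$site) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(class_cols), sum),
                       .groups = "drop") |>
      dplyr::rowwise() |>
      dplyr::mutate(simpson = inv_simpson(dplyr::c_across(dplyr::all_of(class_cols)))) |>
      dplyr::ungroup() |>
      dplyr::select("site", "simpson")
  } else {
    tibble::tibble(site = quadrats$site,
                   simpson_q = apply(counts, 1L, inv_simpson)) |>
      dplyr::group_by(.data$site) |>
      dplyr::summarise(simpson = mean(.data$simpson_q), .groups = "drop")
  }
}

#' Mean percentage cover over replicate quadrats
#'
#' Visual cover estimates (e.g. bryophytes in twenty 50 x 50 cm
#' quadrats) are averaged to one value per site.
#'
#' @param covers tibble with columns `site`, `cover` (percent, 0-100).
#' @return tibble with columns `site`, `bryophytes`.
#' @export
mean_cover <- function(covers) {
  covers <- tibble::as_tibble(covers)
  if (!all(c("site", "cover") %in% names(covers))) {
    rlang::abort("cover table needs columns `site`, `cover`")
  }
  if (anyNA(covers$cover) || any(covers$cover < 0 | covers$cover > 100)) {
    rlang::abort("cover values must lie in [0, 100] percent")
  }
  covers |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(bryophytes = mean(.data$cover), .groups = "drop")
}

#' Mean water temperature from daily logger means
#'
#' Daily mean temperatures are first averaged within each site-year,
#' then those annual means are averaged over the monitoring years, so
#' years with unequal logging coverage carry equal weight.
#'
#' @param daily tibble with columns `site`, `daily_mean` (degrees C)
#'   and either `year` or a `date` from which the year is extracted.
#' @return tibble with columns `site`, `temperature`.
#' @export
mean_temperature <- function(daily) {
  daily <- tibble::as_tibble(daily)
  if (!all(c("site", "daily_mean") %in% names(daily))) {
    rlang::abort("temperature table needs columns `site`, `daily_mean`")
  }
  if (!"year" %in% names(daily)) {
    if (!"date" %in% names(daily)) {
      rlang::abort("temperature table needs a `year` or `date` column")
    }
    daily$year <- as.integer(format(as.Date(daily$date), "%Y"))
  }
  if (nrow(daily) == 0L || anyNA(daily$daily_mean)) {
    rlang::abort("temperature records must be non-empty and complete")
  }
  daily |>
    dplyr::group_by(.data$site, .data$year) |>
    dplyr::summarise(annual = mean(.data$daily_mean), .groups = "drop") |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(temperature = mean(.data$annual), .groups = "drop")
}

#' Connectivity as riffle habitat area near the study reach
#'
#' Riffle segments surveyed within a 500-m buffer up- and downstream
#' are summed as length x width (m2); larger values mean more nearby
#' colonization sources.
#'
#' @param segments tibble with columns `site`, `length_m`, `width_m`
#'   (and optionally `direction`); sites present with zero segments can
#'   be supplied via `all_sites`.
#' @param all_sites optional character vector of site ids that must
#'   appear in the output (with 0 m2 if they have no segments).
#' @return tibble with columns `site`, `connectivity` (m2).
#' @export
connectivity_riffle_area <- function(segments, all_sites = NULL) {
  segments <- tibble::as_tibble(segments)
  if (!all(c("site", "length_m", "width_m") %in% names(segments))) {
    rlang::abort("riffle table needs columns `site`, `length_m`, `width_m`")
  }
  if (nrow(segments) > 0L &&
      (any(segments$length_m <= 0) || any(segments$width_m <= 0))) {
    rlang::abort("riffle segment dimensions must be positive")
  }
  out <- segments |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(connectivity = sum(.data$length_m * .data$width_m),
                     .groups = "drop")
  if (!is.null(all_sites)) {
    out <- tibble::tibble(site = all_sites) |>
      dplyr::left_join(out, by = "site") |>
      dplyr::mutate(connectivity = dplyr::coalesce(.data$connectivity, 0))
  }
  out
}

#' Rank consistency of a covariate across repeat surveys
#'
#' How stable is the ranking of sites in a covariate measured at several
#' time points?  Computes the Spearman rank correlation (average-rank
#' tie handling) between every pair of time points and returns the mean.
#' A time point where all sites are tied carries no ranking information;
#' pairs involving it are skipped with a warning.
#'
#' @param values tibble with columns `site`, `time`, `value`, or a
#'   sites-by-times numeric matrix.
#' @return the mean pairwise Spearman correlation, with the per-pair
#'   correlations as attribute `"pairs"`.
#' @export
rank_consistency <- function(values) {
  if (is.matrix(values)) {
    m <- values
  } else {
    values <- tibble::as_tibble(values)
    if (!all(c("site", "time", "value") %in% names(values))) {
      rlang::abort("rank consistency needs columns `site`, `time`, `value`")
    }
    wide <- tidyr::pivot_wider(values, id_cols = "site",
                               names_from = "time", values_from = "value")
    m <- as.matrix(wide[-1L])
    rownames(m) <- wide$site
  }
  if (ncol(m) < 2L || nrow(m) < 3L) {
    rlang::abort("rank consistency needs >= 2 time points and >= 3 sites")
  }
  constant <- apply(m, 2L, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    rlang::warn(sprintf("skipping constant time point(s): %s",
                        paste(colnames(m)[constant], collapse = ", ")))
  }
  keep <- which(!constant)
  if (length(keep) < 2L) rlang::abort("fewer than 2 usable time points")
  prs <- utils::combn(keep, 2L)
  rs <- apply(prs, 2L, function(ij) {
    stats::cor(m[, ij[1L]], m[, ij[2L]], method = "spearman")
  })
  structure(mean(rs),
            pairs = tibble::tibble(time_a = colnames(m)[prs[1L, ]],
                                   time_b = colnames(m)[prs[2L, ]],
                                   spearman = rs))
}

#' Assemble the environment table from raw field records
#'
#' Convenience wrapper joining [bed_movement_intensity()],
#' [mean_cover()], [simpson_substrate_diversity()],
#' [mean_temperature()] and [connectivity_riffle_area()] into the
#' per-site predictor table consumed by [fit_all_subsets()] (gamma is
#' added later from the community matrices by [assemble_environment()]).
#'
#' @param stones,quadrats,bryophytes,temperature,riffles record tables
#'   as documented in the respective metric functions.
#' @return tibble with columns `site`, `bmi`, `bryophytes`, `simpson`,
#'   `temperature`, `connectivity`.
#' @export
build_environment <- function(stones, quadrats, bryophytes, temperature,
                              riffles) {
  tabs <- list(bed_movement_intensity(stones),
               mean_cover(bryophytes),
               simpson_substrate_diversity(quadrats),
               mean_temperature(temperature))
  out <- Reduce(function(a, b) dplyr::full_join(a, b, by = "site"), tabs)
  out <- dplyr::full_join(out,
                          connectivity_riffle_area(riffles, all_sites = out$site),
                          by = "site")
  validate_environment(out)
}
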