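#' Read a long-format community file
#'
#' The canonical input is tidy/long: one row per (site, year, taxon)
#' observation with columns `site`, `year`, `taxon`, `count`.  Absent
#' (year, taxon) combinations are implicit zeros.  One
#' [community_matrix()] is built per site; taxa never observed at a site
#' are not part of that site's matrix.
#'
#' @param path delimited text file (TSV or CSV; the delimiter is sniffed
#'   from the header line unless given).
#' @param delim field delimiter, `"\t"` or `","`; `NULL` (default) sniffs.
#' @param exclude_taxa character vector of taxon identifiers to drop
#'   before matrices are built (e.g. groups not counted in every year).
#' @return named list of [community_matrix()] objects, one per site,
#'   ordered by site identifier.
#' @seealso [read_community_wide()] for per-site years-by-taxa tables,
#'   [read_environment()] for the covariate table.
#' @export
read_community_long <- function(path, delim = NULL, exclude_taxa = character()) {
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    site = readr::col_character(), year = readr::col_integer(),
    taxon = readr::col_character(), count = readr::col_double()),
    progress = FALSE)
  required <- c("site", "year", "taxon", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf("community file lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  community_from_long(df, exclude_taxa = exclude_taxa)
}

#' Build community matrices from a long data frame
#'
#' @param df data frame with columns `site`, `year`, `taxon`, `count`.
#' @inheritParams read_community_long
#' @return named list of [community_matrix()] objects.
#' @export
community_from_long <- function(df, exclude_taxa = character()) {
  df <- tibble::as_tibble(df)
  if (length(exclude_taxa) > 0L) {
    df <- dplyr::filter(df, !.data$taxon %in% exclude_taxa)
  }
  if (nrow(df) == 0L) rlang::abort("community table has no rows")
  bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "counts must be non-negative integers; first offending row: site '%s', year %s, taxon '%s', count %s",
      df$site[bad[1L]], df$year[bad[1L]], df$taxon[bad[1L]], df$count[bad[1L]]))
  }
  dup <- duplicated(df[c("site", "year", "taxon")])
  if (any(dup)) {
    i <- which(dup)[1L]
    rlang::abort(sprintf(
      "duplicate (site, year, taxon) row: ('%s', %s, '%s')",
      df$site[i], df$year[i], df$taxon[i]))
  }
  sites <- sort(unique(df$site), method = "radix")
  out <- lapply(sites, function(s) {
    sub <- df[df$site == s, , drop = FALSE]
    years <- sort(unique(sub$year))
    taxa <- sort(unique(sub$taxon), method = "radix")
    counts <- matrix(0L, length(years), length(taxa),
                     dimnames = list(as.character(years), taxa))
    counts[cbind(match(sub$year, years), match(sub$taxon, taxa))] <-
      as.integer(sub$count)
    community_matrix(counts, site_id = s, years = years, taxa = taxa)
  })
  stats::setNames(out, sites)
}

#' Read a wide (years-by-taxa) community file for one site
#'
#' Secondary reader for archives that ship one matrix per site: first
#' column `year`, remaining columns one per taxon.
#'
#' @inheritParams read_community_long
#' @param site_id site identifier to attach to the matrix.
#' @return a [community_matrix()].
#' @export
read_community_wide <- function(path, site_id, delim = NULL) {
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, progress = FALSE,
                          col_types = readr::cols(year = readr::col_integer(),
                                                  .default = readr::col_double()))
  if (!"year" %in% names(df)) rlang::abort("wide community file needs a `year` column")
  m <- as.matrix(df[setdiff(names(df), "year")])
  community_matrix(m, site_id = site_id, years = df$year,
                   taxa = colnames(m))
}

#' Convert community matrices back to long format
#'
#' Zero cells are omitted, so `community_from_long()` round-trips.
#'
#' @param matrices list of [community_matrix()] objects (or one).
#' @return tibble with columns `site`, `year`, `taxon`, `count`.
#' @export
community_to_long <- function(matrices) {
  if (inherits(matrices, "community_matrix")) matrices <- list(matrices)
  purrr::map_dfr(matrices, function(m) {
    tibble::tibble(site = site_id(m),
                   year = rep(community_years(m), times = ncol(m)),
                   taxon = rep(colnames(m), each = nrow(m)),
                   count = as.integer(m)) |>
      dplyr::filter(.data$count > 0L) |>
      dplyr::arrange(.data$year, .data$taxon)
  })
}

# the six predictors used in model selection, in canonical order
env_predictors <- function() {
  c("bmi", "bryophytes", "simpson", "temperature", "connectivity", "gamma")
}

#' Read a per-site environment table
#'
#' One row per site with the five measured predictors: `bmi` (bed
#' movement intensity, percent of stones moved), `bryophytes` (percent
#' cover), `simpson` (substrate Simpson diversity 1/D, dimensionless,
#' at least 1), `temperature` (mean water temperature, degrees C) and
#' `connectivity` (riffle area in m2 within a 500-m buffer).  Temporal
#' gamma diversity is computed from the community matrices, not read.
#'
#' @inheritParams read_community_long
#' @return validated tibble, one row per site.
#' @export
read_environment <- function(path, delim = NULL) {
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, progress = FALSE,
                          col_types = readr::cols(site = readr::col_character(),
                                                  .default = readr::col_double()))
  validate_environment(df)
}

#' Validate an environment table
#'
#' @param df data frame with columns `site`, `bmi`, `bryophytes`,
#'   `simpson`, `temperature`, `connectivity` (and optionally `gamma`).
#' @return the table as a tibble, invisibly checked: exactly one row per
#'   site, no missing values, percents in 0-100, simpson >= 1.
#' @export
validate_environment <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("site", "bmi", "bryophytes", "simpson", "temperature",
              "connectivity")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf("environment table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) rlang::abort("environment table is empty")
  if (anyDuplicated(df$site)) {
    rlang::abort(sprintf("duplicated site row(s): %s",
                         paste(unique(df$site[duplicated(df$site)]), collapse = ", ")))
  }
  num_cols <- setdiff(intersect(c(needed, "gamma"), names(df)), "site")
  na_cells <- which(is.na(as.matrix(df[num_cols])), arr.ind = TRUE)
  if (nrow(na_cells) > 0L) {
    cells <- apply(na_cells, 1L, function(ix) {
      sprintf("(site '%s', %s)", df$site[ix[1L]], num_cols[ix[2L]])
    })
    rlang::abort(sprintf("missing values in environment table: %s",
                         paste(cells, collapse = ", ")))
  }
  for (col in intersect(c("bmi", "bryophytes"), names(df))) {
    if (any(df[[col]] < 0 | df[[col]] > 100)) {
      rlang::abort(sprintf("`%s` must lie in [0, 100] percent", col))
    }
  }
  if (any(df$simpson < 1)) {
    rlang::abort("`simpson` (inverse Simpson index) must be >= 1")
  }
  if (any(df$connectivity < 0)) {
    rlang::abort("`connectivity` (riffle area, m2) must be >= 0")
  }
  df
}

#' Attach gamma diversity and align environment with community data
#'
#' Joins the per-site gamma richness computed from `matrices` onto the
#' environment table and checks the two site sets match one-to-one.
#'
#' @param env environment tibble as from [read_environment()].
#' @param matrices list of [community_matrix()] objects.
#' @return environment tibble with a `gamma` column, rows ordered as
#'   `matrices`.
#' @export
assemble_environment <- function(env, matrices) {
  env <- validate_environment(env)
  cs <- community_summary(matrices)
  if (!setequal(env$site, cs$site)) {
    rlang::abort(sprintf(
      "site sets differ between community and environment data; only in community: %s; only in environment: %s",
      paste(setdiff(cs$site, env$site), collapse = ", ") %|e|% "none",
      paste(setdiff(env$site, cs$site), collapse = ", ") %|e|% "none"))
  }
  if ("gamma" %in% names(env)) {
    chk <- dplyr::inner_join(env["site"], cs[c("site", "gamma")], by = "site")
    if (any(env$gamma[match(chk$site, env$site)] != chk$gamma)) {
      rlang::abort("`gamma` column disagrees with gamma computed from the community matrices")
    }
    env$gamma <- NULL
  }
  dplyr::inner_join(cs[c("site", "gamma")], env, by = "site") |>
    dplyr::select("site", dplyr::all_of(setdiff(env_predictors(), "gamma")),
                  "gamma")
}

`%|e|%` <- function(x, alt) if (nzchar(x)) x else alt

#' Write pipeline result tables
#'
#' Writes tab-separated tables and a JSON run manifest to `out_dir`:
#' `beta_by_site.tsv` (observed and null-expected dissimilarity and
#' beta_dep per site), `model_selection_obs.tsv` and
#' `model_selection_dep.tsv` (best models with standardized coefficients,
#' adjusted R-squared and delta AICc), `importance.tsv` (per-variable
#' summed Akaike weights for both responses) and `manifest.json`.
#'
#' @param results list as produced by [temporal_beta_analysis()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, out_dir) {
  if (is.null(results$beta) || nrow(results$beta) == 0L) {
    rlang::abort("empty result set: nothing to write")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  paths <- character()
  wr <- function(df, file) {
    p <- file.path(out_dir, file)
    readr::write_tsv(df, p)
    paths[[file]] <<- p
  }
  wr(results$beta, "beta_by_site.tsv")
  imp <- dplyr::bind_rows(
    dplyr::mutate(variable_importance(results$models_obs), response = "beta_obs"),
    dplyr::mutate(variable_importance(results$models_dep), response = "beta_dep"))
  wr(dplyr::select(imp, "response", dplyr::everything()), "importance.tsv")
  wr(best_models(results$models_obs), "model_selection_obs.tsv")
  wr(best_models(results$models_dep), "model_selection_dep.tsv")
  manifest <- list(
    package = "betadep",
    version = as.character(utils::packageVersion("betadep")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_sites = nrow(results$beta),
    null = results$null_config,
    log_base = results$log_base)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths[["manifest.json"]] <- file.path(out_dir, "manifest.json")
  invisible(paths)
}
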