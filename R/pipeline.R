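#' Run the full risk-assessment and classification pipeline
#'
#' Parses raw sampling rows (if needed), computes the three risk
#' indices per (unit, product), standardizes them, fits k-means++ for
#' every candidate cluster number, selects K by the validity-index
#' vote, orders the clusters into risk levels and tabulates the
#' high-risk composition.
#'
#' @param samples either a raw sampling table (columns `province`,
#'   `city`, `product`, `raw_value`) or already-parsed records.
#' @param consumption consumption table (`province`, `product`, `fc`).
#' @param csf carcinogenic slope factor, (mg/(kg.d))^-1; required
#'   unless `params` is given.
#' @param limits limit standard, see [limit_standard()].
#' @param level `"city"` or `"province"` granularity.
#' @param products optional subset of product categories to cluster
#'   (indices are still computed for all products).
#' @param k_range candidate cluster numbers.
#' @param seed integer seed for the clustering restarts.
#' @param restarts k-means restarts per candidate K.
#' @param high_threshold level at or above which a combination counts
#'   as high risk.
#' @param nd_tokens non-detect tokens for parsing.
#' @param params optional pre-built [exposure_params()]; overrides
#'   `csf` / `consumption`.
#' @return object of class `cd_risk_run`: list with `records`,
#'   `indices`, `features`, `scores`, `votes`, `fit`, `k`, `levels`,
#'   `summary`, `level`, `seed`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_provinces = 4, cities_per_province = 5,
#'                         samples_per_cell = 20, seed = 3)
#' run <- run_risk_pipeline(generate_samples(cfg), generate_consumption(cfg),
#'                          csf = 6.1, k_range = 2:6, seed = 3)
#' run$k
#' run$summary
run_risk_pipeline <- function(samples, consumption = NULL, csf = NULL,
                              limits = limit_standard(),
                              level = c("city", "province"),
                              products = NULL, k_range = 2:8, seed = 1L,
                              restarts = 10, high_threshold = 4,
                              nd_tokens = default_nd_tokens(),
                              params = NULL) {
  level <- match.arg(level)
  records <- if ("raw_value" %in% names(samples)) {
    parse_records(samples, nd_tokens = nd_tokens)
  } else {
    samples
  }
  if (is.null(params)) {
    .assert(!is.null(csf), "supply csf (and consumption) or a params object")
    params <- exposure_params(csf = csf, consumption = consumption)
  }
  idx <- unit_indices(records, params, limits, level)
  sub <- if (is.null(products)) idx else {
    .assert(all(products %in% .products), "unknown product in 'products'")
    idx[idx$product %in% products, , drop = FALSE]
  }
  feats <- feature_matrix(sub)
  sel <- select_and_fit(feats, k_range = k_range, seed = seed,
                        restarts = restarts)
  lvls <- assign_levels(sel$fit, feats)
  structure(list(records = records, indices = idx, features = feats,
                 scores = sel$scores, votes = sel$votes, fit = sel$fit,
                 k = sel$k, levels = lvls,
                 summary = tabulate_levels(lvls, high_threshold),
                 level = level, seed = seed),
            class = "cd_risk_run")
}

#' @export
print.cd_risk_run <- function(x, ...) {
  cat(sprintf("cadmium risk classification run (%s level, seed %s)\n",
              x$level, format(x$seed)))
  cat(sprintf("  %d records -> %d (unit, product) observations\n",
              nrow(x$records), nrow(x$levels)))
  cat(sprintf("  selected K = %d by validity-index vote\n", x$k))
  print(x$summary)
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Emits plain-text deliverables into `dir`: descriptive statistics,
#' the unit-index table, risk levels, the high-risk subset, the level
#' summary, the vote tally, and a JSON run manifest (selected K, seed,
#' versions).
#'
#' @param run a `cd_risk_run` from [run_risk_pipeline()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_risk_report <- function(run, dir) {
  .assert(inherits(run, "cd_risk_run"), "run must be a cd_risk_run")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    descriptive = file.path(dir, "descriptive_stats.csv"),
    indices = file.path(dir, "unit_indices.csv"),
    levels = file.path(dir, "risk_levels.csv"),
    high = file.path(dir, "high_risk.csv"),
    summary = file.path(dir, "level_summary.csv"),
    votes = file.path(dir, "vote_tally.csv"),
    manifest = file.path(dir, "manifest.json"))
  utils::write.csv(summarize_concentrations(run$records, run$level),
                   paths[["descriptive"]], row.names = FALSE)
  utils::write.csv(run$indices, paths[["indices"]], row.names = FALSE)
  utils::write.csv(as.data.frame(run$levels), paths[["levels"]],
                   row.names = FALSE)
  high <- as.data.frame(run$levels)
  high <- high[high$level >= run$summary$high_threshold, , drop = FALSE]
  utils::write.csv(high, paths[["high"]], row.names = FALSE)
  utils::write.csv(run$summary$by_level, paths[["summary"]], row.names = FALSE)
  utils::write.csv(as.data.frame(run$votes), paths[["votes"]],
                   row.names = FALSE)
  jsonlite::write_json(
    list(k = run$k, seed = run$seed, level = run$level,
         n_records = nrow(run$records), n_observations = nrow(run$levels),
         high_threshold = run$summary$high_threshold,
         package = "cdrisk",
         package_version = as.character(utils::packageVersion("cdrisk")),
         r_version = R.version.string),
    paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
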