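#' Configuration for the synthetic surveillance-data generator
#'
#' Describes a simulated national sampling campaign: a
#' province -> city -> product hierarchy, a per-tier log-normal
#' concentration model with left-censoring at the detection limit, and
#' the reporting dialects ("ND" tokens, values written as `"<value"`)
#' seen in real laboratory exports.
#'
#' Each city carries a latent risk tier; all samples drawn in that city
#' (any product) follow a log-normal distribution with the tier's median
#' and the common geometric standard deviation. Draws below `lod` are
#' reported as `nd_token`; detects below `lt_threshold` are reported as
#' `"<value"` with probability `lt_dialect`.
#'
#' The defaults emulate a national campaign of the scale of the 2023-2024
#' cadmium surveillance of processed grain products: 20 provinces,
#' about 180 cities, strongly right-skewed concentrations with
#' coefficients of variation of order 1-4, and a detection limit of
#' 0.002 mg/kg.
#'
#' @param n_provinces number of provinces (>= 1).
#' @param cities_per_province cities per province (>= 1).
#' @param samples_per_cell samples drawn per city x product cell (>= 1).
#' @param tier_medians strictly increasing vector of log-normal medians
#'   (mg/kg), one per latent risk tier.
#' @param gsd geometric standard deviation shared by all tiers (>= 1).
#' @param lod detection limit (mg/kg, >= 0); draws below it are reported
#'   as `nd_token`.
#' @param nd_token string used for non-detects.
#' @param lt_dialect probability that a detect below `lt_threshold` is
#'   written as `"<value"`.
#' @param lt_threshold reporting threshold for the `"<"` dialect;
#'   defaults to `2 * lod`.
#' @param tier_assignment optional named integer vector mapping every
#'   city name to a tier index; defaults to a round-robin assignment.
#' @param seed integer seed; drives per-province RNG substreams so a
#'   province's block is reproducible on its own.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_samples()], [generate_consumption()], [tier_table()]
#' @export
#' @examples
#' cfg <- synthetic_config(n_provinces = 2, cities_per_province = 2,
#'                         samples_per_cell = 5, seed = 7)
#' head(generate_samples(cfg))
synthetic_config <- function(n_provinces = 20,
                             cities_per_province = 9,
                             samples_per_cell = 50,
                             tier_medians = c(0.002, 0.006, 0.02, 0.06, 0.18),
                             gsd = 3,
                             lod = 0.002,
                             nd_token = "ND",
                             lt_dialect = 0.05,
                             lt_threshold = NULL,
                             tier_assignment = NULL,
                             seed = 1L) {
  .assert_scalar(n_provinces, "n_provinces", lower = 1)
  .assert_scalar(cities_per_province, "cities_per_province", lower = 1)
  .assert_scalar(samples_per_cell, "samples_per_cell", lower = 1)
  .assert(is.numeric(tier_medians) && length(tier_medians) >= 1 &&
            all(is.finite(tier_medians)) && all(tier_medians > 0),
          "tier_medians must be positive")
  .assert(!is.unsorted(tier_medians, strictly = TRUE),
          "tier_medians must be strictly increasing")
  .assert_scalar(gsd, "gsd", lower = 1)
  .assert_scalar(lod, "lod", lower = 0)
  .assert(is.character(nd_token) && length(nd_token) == 1L && nzchar(nd_token),
          "nd_token must be a non-empty string")
  .assert_scalar(lt_dialect, "lt_dialect", lower = 0)
  .assert(lt_dialect <= 1, "lt_dialect must be a probability in [0, 1]")
  lt_threshold <- lt_threshold %||% (2 * lod)
  .assert_scalar(lt_threshold, "lt_threshold", lower = 0)
  .assert_scalar(seed, "seed")

  n_provinces <- as.integer(n_provinces)
  cities_per_province <- as.integer(cities_per_province)
  provinces <- sprintf("P%02d", seq_len(n_provinces))
  cities <- as.vector(vapply(
    seq_len(n_provinces),
    function(p) sprintf("P%02d_C%02d", p, seq_len(cities_per_province)),
    character(cities_per_province)
  ))
  if (is.null(tier_assignment)) {
    tier_assignment <- stats::setNames(
      rep_len(seq_along(tier_medians), length(cities)), cities)
  } else {
    .assert(!is.null(names(tier_assignment)) &&
              setequal(names(tier_assignment), cities),
            "tier_assignment must name every city of the design")
    .assert(all(tier_assignment %in% seq_along(tier_medians)),
            "tier_assignment values must index tier_medians")
    tier_assignment <- tier_assignment[cities]
  }

  structure(
    list(n_provinces = n_provinces,
         cities_per_province = cities_per_province,
         samples_per_cell = as.integer(samples_per_cell),
         tier_medians = as.numeric(tier_medians),
         gsd = gsd,
         lod = lod,
         nd_token = nd_token,
         lt_dialect = lt_dialect,
         lt_threshold = lt_threshold,
         tier_assignment = as.integer(tier_assignment),
         provinces = provinces,
         cities = cities,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic surveillance design: %d provinces x %d cities x 3 products x %d samples\n",
    x$n_provinces, x$cities_per_province, x$samples_per_cell))
  cat(sprintf("  tiers: %d (medians %s mg/kg, gsd %.3g), lod %.4g mg/kg, seed %d\n",
              length(x$tier_medians),
              paste(signif(x$tier_medians, 3), collapse = ", "),
              x$gsd, x$lod, x$seed))
  invisible(x)
}

## per-province RNG substream seed derived from the global seed, so a
## single province block can be regenerated without the others
.substream <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 1009 + index * 9973) %% 2147483629)
}

#' Latent risk tier of every simulated city
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns `city`, `province`, `tier` — the
#'   ground truth against which recovered risk levels can be scored.
#' @export
tier_table <- function(config) {
  .assert(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  data.frame(
    city = config$cities,
    province = rep(config$provinces, each = config$cities_per_province),
    tier = config$tier_assignment,
    stringsAsFactors = FALSE
  )
}

#' Generate raw surveillance sampling records
#'
#' Draws `samples_per_cell` cadmium concentrations for every
#' city x product cell from the city's tier log-normal, then renders
#' them in the raw reporting dialect: draws below the detection limit
#' become the non-detect token, detects below the reporting threshold
#' are written as `"<value"` with probability `lt_dialect`, everything
#' else as a plain 5-decimal numeral. Censoring is reported, not
#' truncated: below-LOD draws keep their row.
#'
#' The same configuration (including seed) yields byte-identical output.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with character columns `province`, `city`,
#'   `product`, `raw_value`; exactly
#'   `n_provinces * cities_per_province * 3 * samples_per_cell` rows.
#' @seealso [parse_records()] to turn the raw rows back into numbers.
#' @export
generate_samples <- function(config) {
  .assert(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  m <- config$samples_per_cell
  sdlog <- log(config$gsd)
  tier_of <- stats::setNames(config$tier_assignment, config$cities)

  out <- vector("list", config$n_provinces)
  for (p in seq_len(config$n_provinces)) {
    set.seed(.substream(config$seed, p))
    cities <- sprintf("P%02d_C%02d", p, seq_len(config$cities_per_province))
    blocks <- vector("list", length(cities) * length(.products))
    bi <- 1L
    for (city in cities) {
      med <- config$tier_medians[tier_of[[city]]]
      for (prod in .products) {
        x <- stats::rlnorm(m, meanlog = log(med), sdlog = sdlog)
        u <- stats::runif(m)
        nd <- x < config$lod
        lt <- !nd & x < config$lt_threshold & u < config$lt_dialect
        val <- sprintf("%.5f", x)
        raw <- ifelse(nd, config$nd_token, ifelse(lt, paste0("<", val), val))
        blocks[[bi]] <- data.frame(
          province = sprintf("P%02d", p), city = city, product = prod,
          raw_value = raw, stringsAsFactors = FALSE)
        bi <- bi + 1L
      }
    }
    out[[p]] <- do.call(rbind, blocks)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a per-province consumption table
#'
#' Stands in for a national total-diet-study table: one daily-intake
#' value (kg/d) per (province, product). With `jitter_sd = 0` every
#' province receives `base_fc` unchanged; otherwise intakes are
#' perturbed by a log-normal factor, deterministically under the
#' configuration seed.
#'
#' @param config a [synthetic_config()].
#' @param base_fc named numeric vector of national per-capita daily
#'   intakes (kg/d) for `rice`, `wheat_flour`, `other`.
#' @param jitter_sd log-scale SD of the per-province perturbation.
#' @param provinces optional character vector of provinces; defaults to
#'   the configuration's provinces. An empty vector yields an empty table.
#' @return data.frame with columns `province`, `product`, `fc` (kg/d).
#' @export
generate_consumption <- function(config,
                                 base_fc = c(rice = 0.24, wheat_flour = 0.14,
                                             other = 0.05),
                                 jitter_sd = 0,
                                 provinces = NULL) {
  .assert(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  .assert(is.numeric(base_fc) && setequal(names(base_fc), .products),
          "base_fc must be a numeric vector named rice, wheat_flour, other")
  .assert(all(is.finite(base_fc)) && all(base_fc >= 0),
          "base_fc values must be >= 0")
  .assert_scalar(jitter_sd, "jitter_sd", lower = 0)
  provinces <- provinces %||% config$provinces
  if (length(provinces) == 0L) {
    return(data.frame(province = character(), product = character(),
                      fc = numeric(), stringsAsFactors = FALSE))
  }
  set.seed(.substream(config$seed, 999983L))
  grid <- expand.grid(product = .products, province = provinces,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fc <- unname(base_fc[grid$product]) * exp(stats::rnorm(nrow(grid), 0, jitter_sd))
  data.frame(province = grid$province, product = grid$product, fc = fc,
             stringsAsFactors = FALSE)
}
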