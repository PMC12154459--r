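#' National limit standard for cadmium per product
#'
#' Regulatory maximum levels (mg/kg) used as the denominator of the
#' pollution index: 0.2 for rice, 0.1 for wheat flour and 0.2 for other
#' processed grain products (GB 2762 convention).
#'
#' @param rice,wheat_flour,other limits in mg/kg, all > 0.
#' @return named numeric vector of limits.
#' @export
limit_standard <- function(rice = 0.2, wheat_flour = 0.1, other = 0.2) {
  s <- c(rice = rice, wheat_flour = wheat_flour, other = other)
  .assert(is.numeric(s) && all(is.finite(s)) && all(s > 0),
          "all limits must be finite and > 0")
  s
}

#' Pollution index
#'
#' Ratio of a detected concentration to the product's regulatory limit,
#' `P = X / S`.
#'
#' @param x detected concentration (mg/kg, >= 0); vectorised.
#' @param s limit standard (mg/kg, > 0).
#' @return dimensionless pollution index.
#' @export
#' @examples
#' pollution_index(0.9, 0.2)  # 4.5
pollution_index <- function(x, s) {
  .assert(is.numeric(s) && all(is.finite(s)) && all(s > 0),
          "limit standard must be > 0")
  .assert(is.numeric(x) && all(is.finite(x)) && all(x >= 0),
          "concentration must be >= 0")
  x / s
}

#' Nemerow integrated pollution index
#'
#' Root-mean-square of the maximum and average pollution indices within
#' a unit: `sqrt((p_max^2 + p_avg^2) / 2)`. Weighting the maximum this
#' way makes the index sensitive to worst-case contamination.
#'
#' @param p_max maximum pollution index of the unit (>= `p_avg`).
#' @param p_avg average pollution index of the unit (>= 0).
#' @return dimensionless NIPI; always within `[p_max / sqrt(2), p_max]`.
#' @export
#' @examples
#' nipi(4.5, 0.5493)
nipi <- function(p_max, p_avg) {
  .assert(is.numeric(p_max) && is.numeric(p_avg) &&
            all(is.finite(p_max)) && all(is.finite(p_avg)),
          "pollution indices must be finite numbers")
  .assert(all(p_avg >= 0) && all(p_max >= 0), "pollution indices must be >= 0")
  .assert(all(p_avg <= p_max),
          "p_avg exceeds p_max: inconsistent aggregation")
  sqrt((p_max^2 + p_avg^2) / 2)
}

#' Estimated daily intake
#'
#' `EDI = FC * Xq / W`: daily consumption times a concentration
#' quantile, per kilogram of body mass.
#'
#' @param fc daily consumption of the product (kg/d, >= 0).
#' @param xq concentration quantile (mg/kg, >= 0).
#' @param w body mass (kg, > 0).
#' @return intake in mg/(kg.d).
#' @export
edi <- function(fc, xq, w) {
  .assert(is.numeric(w) && all(is.finite(w)) && all(w > 0),
          "body mass w must be > 0")
  .assert(is.numeric(fc) && all(fc >= 0) && is.numeric(xq) && all(xq >= 0),
          "fc and xq must be >= 0")
  fc * xq / w
}

#' Exposure-assessment parameters
#'
#' Bundles every constant of the TCR/THQ formulas together with the
#' consumption table. There is no default carcinogenic slope factor:
#' `csf` must be supplied explicitly, because silently assuming one
#' would fabricate cancer-risk numbers.
#'
#' `rfd` defaults to 0.001 mg/(kg.d) (1 ug/kg/d), the JECFA-derived
#' convention for cadmium.
#'
#' @param csf carcinogenic slope factor, (mg/(kg.d))^-1; required, > 0.
#' @param consumption optional data.frame with columns `province`,
#'   `product`, `fc` (kg/d); required by [unit_indices()].
#' @param ef exposure frequency, days/year.
#' @param ed exposure duration, years.
#' @param atc averaging time for the carcinogenic effect, days;
#'   defaults to `ef * ed`.
#' @param w body mass, kg.
#' @param rfd oral reference dose, mg/(kg.d).
#' @return an object of class `exposure_params`.
#' @export
exposure_params <- function(csf, consumption = NULL, ef = 365, ed = 70,
                            atc = ef * ed, w = 60, rfd = 0.001) {
  .assert(!missing(csf),
          "csf (carcinogenic slope factor) must be supplied explicitly")
  .assert_scalar(csf, "csf", lower = 0, strict = TRUE)
  .assert_scalar(ef, "ef", lower = 0, strict = TRUE)
  .assert_scalar(ed, "ed", lower = 0, strict = TRUE)
  .assert_scalar(atc, "atc", lower = 0, strict = TRUE)
  .assert_scalar(w, "w", lower = 0, strict = TRUE)
  .assert_scalar(rfd, "rfd", lower = 0, strict = TRUE)
  if (!is.null(consumption)) {
    need <- c("province", "product", "fc")
    .assert(is.data.frame(consumption) && all(need %in% names(consumption)),
            "consumption must have columns %s", paste(need, collapse = ", "))
    .assert(all(is.finite(consumption$fc)) && all(consumption$fc >= 0),
            "consumption fc values must be >= 0")
    .assert(!anyDuplicated(.pair_key(consumption$province, consumption$product)),
            "consumption must have one row per (province, product)")
  }
  structure(list(csf = csf, ef = ef, ed = ed, atc = atc, w = w, rfd = rfd,
                 consumption = consumption),
            class = "exposure_params")
}

#' @export
print.exposure_params <- function(x, ...) {
  cat(sprintf(
    "exposure parameters: EF %g d/y, ED %g y, ATC %g d, W %g kg, RfD %g mg/(kg.d), CSF %g (mg/(kg.d))^-1\n",
    x$ef, x$ed, x$atc, x$w, x$rfd, x$csf))
  if (!is.null(x$consumption))
    cat(sprintf("  consumption table: %d (province, product) rows\n",
                nrow(x$consumption)))
  invisible(x)
}

#' Target cancer risk
#'
#' `TCR = EF * ED * CSF * EDI50 / ATC`. With the default EF, ED and
#' ATC = EF * ED this reduces to `CSF * EDI50`; the full formula is kept
#' so non-default exposure constants work.
#'
#' @param params an [exposure_params()] object.
#' @param edi50 estimated daily intake at the median concentration,
#'   mg/(kg.d).
#' @return dimensionless lifetime cancer-risk proxy.
#' @export
tcr <- function(params, edi50) {
  .assert(inherits(params, "exposure_params"), "params must be exposure_params")
  .assert(is.numeric(edi50) && all(edi50 >= 0), "edi50 must be >= 0")
  params$ef * params$ed * params$csf * edi50 / params$atc
}

#' Target hazard quotient
#'
#' `THQ = EF * ED * EDI95 / (ATC * RfD)`; at the defaults this is
#' `EDI95 / RfD`. Values above 1 flag non-carcinogenic concern.
#'
#' @param params an [exposure_params()] object (with `rfd > 0`).
#' @param edi95 estimated daily intake at the 95th-percentile
#'   concentration, mg/(kg.d).
#' @return dimensionless hazard quotient.
#' @export
thq <- function(params, edi95) {
  .assert(inherits(params, "exposure_params"), "params must be exposure_params")
  .assert(params$rfd > 0, "rfd must be > 0")
  .assert(is.numeric(edi95) && all(edi95 >= 0), "edi95 must be >= 0")
  params$ef * params$ed * edi95 / (params$atc * params$rfd)
}

#' Risk indices per (geographic unit, product)
#'
#' For every (unit, product) group: pollution indices of all samples
#' (censored values enter as 0), the Nemerow index from their maximum
#' and mean, median and 95th-percentile concentrations by linear
#' interpolation between order statistics, TCR from the median and THQ
#' from the 95th percentile. The resulting three-index vector per group
#' is the observation clustered by [select_and_fit()].
#'
#' @param records parsed sampling records.
#' @param params an [exposure_params()] carrying a consumption table.
#' @param limits named limit vector, see [limit_standard()].
#' @param level `"city"` or `"province"` granularity.
#' @return data.frame with one row per group: `unit`, `province`,
#'   `product`, `n_samples`, `p_max`, `p_avg`, `nipi`, `x50`, `x95`,
#'   `tcr`, `thq`.
#' @export
unit_indices <- function(records, params, limits = limit_standard(),
                         level = c("city", "province")) {
  level <- match.arg(level)
  .assert(inherits(params, "exposure_params"), "params must be exposure_params")
  .assert(!is.null(params$consumption),
          "unit_indices needs a consumption table inside exposure_params")
  .assert(all(.products %in% names(limits)),
          "limits must name rice, wheat_flour, other")
  g <- group_records(records, level)
  keys <- attr(g, "keys")
  cons_key <- .pair_key(params$consumption$province, params$consumption$product)

  n_g <- length(g)
  p_max <- p_avg <- x50 <- x95 <- tcr_v <- thq_v <- numeric(n_g)
  n_samples <- integer(n_g)
  for (i in seq_len(n_g)) {
    x <- g[[i]]
    prod <- keys$product[i]
    prov <- keys$province[i]
    p <- pollution_index(x, limits[[prod]])
    p_max[i] <- max(p)
    p_avg[i] <- mean(p)
    fc <- params$consumption$fc[match(.pair_key(prov, prod), cons_key)]
    if (is.na(fc)) {
      stop(sprintf("no consumption entry for province '%s', product '%s'",
                   prov, prod), call. = FALSE)
    }
    q <- stats::quantile(x, c(0.5, 0.95), type = 7, names = FALSE)
    x50[i] <- q[1]
    x95[i] <- q[2]
    tcr_v[i] <- tcr(params, edi(fc, q[1], params$w))
    thq_v[i] <- thq(params, edi(fc, q[2], params$w))
    n_samples[i] <- length(x)
  }
  data.frame(unit = keys$unit, province = keys$province,
             product = keys$product, n_samples = n_samples,
             p_max = p_max, p_avg = p_avg,
             nipi = nipi(p_max, p_avg),
             x50 = x50, x95 = x95, tcr = tcr_v, thq = thq_v,
             stringsAsFactors = FALSE)
}

#' Nemerow index from published summary statistics
#'
#' Reconstructs the NIPI of a (province, product) cell from its printed
#' range and mean: with non-detects coded as 0 the minimum is 0, so the
#' maximum equals `range + minimum`.
#'
#' @param stats data.frame with columns `province`, `product`, `range`,
#'   `mean` (mg/kg).
#' @param limits named limit vector, see [limit_standard()].
#' @param minimum the minimum concentration assumed when recovering the
#'   maximum from the range; 0 under non-detect zero-coding.
#' @return `stats` with added columns `p_max`, `p_avg`, `nipi`.
#' @export
#' @examples
#' nipi_from_stats(data.frame(province = "Hunan", product = "rice",
#'                            range = 0.9, mean = 0.10986))
nipi_from_stats <- function(stats, limits = limit_standard(), minimum = 0) {
  need <- c("province", "product", "range", "mean")
  .assert(is.data.frame(stats) && all(need %in% names(stats)),
          "stats must have columns %s", paste(need, collapse = ", "))
  .assert(all(stats$product %in% names(limits)),
          "unknown product category in stats")
  s <- unname(limits[stats$product])
  p_max <- (stats$range + minimum) / s
  p_avg <- stats$mean / s
  out <- stats
  out$p_max <- p_max
  out$p_avg <- p_avg
  out$nipi <- nipi(p_max, p_avg)
  out
}

#' Published provincial cadmium summary statistics (2023-2024)
#'
#' The published per-province descriptive statistics (range, mean, SD,
#' CV in mg/kg) of cadmium in rice, wheat flour and other processed
#' grain products from the 2023-2024 national surveillance of China,
#' shipped as a plain-text table. These printed summaries are the only
#' publicly available part of the restricted raw dataset and are the
#' inputs of the worked NIPI examples.
#'
#' @return data.frame with columns `province`, `product`, `range`,
#'   `mean`, `sd`, `cv`.
#' @export
cd_surveillance_stats <- function() {
  utils::read.csv(system.file("extdata", "provincial_cd_stats_2023_2024.csv",
                              package = "cdrisk"),
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Published high-risk (product, city) combinations
#'
#' The 22 published (product, city) combinations classified at risk
#' level 4 or 5 in the 2023-2024 national analysis, used to reproduce
#' the published high-risk composition shares.
#'
#' @return data.frame with columns `product`, `city`, `level`, `province`.
#' @export
cd_high_risk_table <- function() {
  utils::read.csv(system.file("extdata", "high_risk_combinations.csv",
                              package = "cdrisk"),
                  stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
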