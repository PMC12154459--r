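#' Default non-detect tokens
#'
#' Reporting dialects used by laboratories for results below the
#' detection limit. Matching is case-insensitive.
#'
#' @return character vector of tokens.
#' @export
default_nd_tokens <- function() {
  c("ND", "N.D.", "not detected", "未检出")
}

## vectorised raw-value parser; returns concentration/censored plus a
## `bad` flag instead of stopping, so callers can choose strict/lenient
.parse_raw <- function(raw, nd_tokens) {
  trimmed <- trimws(as.character(raw))
  censored <- tolower(trimmed) %in% tolower(nd_tokens)
  stripped <- sub("^<[[:space:]]*", "", trimmed)
  conc <- suppressWarnings(as.numeric(stripped))
  conc[censored] <- 0
  bad <- !nzchar(trimmed) | (!censored & (is.na(conc) | conc < 0))
  list(concentration = conc, censored = censored, bad = bad)
}

#' Parse raw detection-value strings
#'
#' Applies the preprocessing rules used for national surveillance
#' exports: non-detect tokens are assigned a concentration of 0 mg/kg
#' and flagged as censored; a leading `"<"` is deleted and the numeric
#' value retained (uncensored); plain numerals parse directly.
#'
#' @param raw character vector of raw values.
#' @param nd_tokens tokens treated as non-detects (case-insensitive).
#' @return data.frame with numeric `concentration` (mg/kg) and logical
#'   `censored`, one row per input.
#' @export
#' @examples
#' parse_detection_value(c("not detected", "<0.01", "0.16"))
parse_detection_value <- function(raw, nd_tokens = default_nd_tokens()) {
  p <- .parse_raw(raw, nd_tokens)
  if (any(p$bad)) {
    idx <- which(p$bad)
    shown <- utils::head(idx, 5)
    stop(sprintf(
      "cannot parse detection value%s: %s",
      if (length(idx) > 1) "s" else "",
      paste0("'", trimws(as.character(raw))[shown], "' (row ", shown, ")",
             collapse = ", ")), call. = FALSE)
  }
  data.frame(concentration = p$concentration, censored = p$censored)
}

#' Parse a raw sampling table into records
#'
#' @param x data.frame with character columns `province`, `city`,
#'   `product`, `raw_value` (as produced by [generate_samples()] or read
#'   from a surveillance export).
#' @param nd_tokens tokens treated as non-detects.
#' @param strict if `TRUE` (default) any malformed value or unknown
#'   product aborts with row context; if `FALSE` offending rows are
#'   dropped with a warning listing their row numbers.
#' @return data.frame of sampling records: `province`, `city`, `product`,
#'   `concentration` (mg/kg), `censored`.
#' @export
parse_records <- function(x, nd_tokens = default_nd_tokens(), strict = TRUE) {
  need <- c("province", "city", "product", "raw_value")
  .assert(is.data.frame(x) && all(need %in% names(x)),
          "input must have columns %s", paste(need, collapse = ", "))
  bad_prod <- !(x$product %in% .products)
  p <- .parse_raw(x$raw_value, nd_tokens)
  bad <- bad_prod | p$bad
  if (any(bad)) {
    idx <- which(bad)
    if (strict) {
      shown <- utils::head(idx, 5)
      stop(sprintf("malformed record%s at row%s %s%s",
                   if (length(idx) > 1) "s" else "",
                   if (length(idx) > 1) "s" else "",
                   paste(shown, collapse = ", "),
                   if (length(idx) > 5) sprintf(" (and %d more)", length(idx) - 5) else ""),
           call. = FALSE)
    }
    warning(sprintf("skipped %d malformed record(s) at rows %s",
                    length(idx), paste(utils::head(idx, 10), collapse = ", ")),
            call. = FALSE)
  }
  keep <- !bad
  data.frame(province = x$province[keep], city = x$city[keep],
             product = x$product[keep],
             concentration = p$concentration[keep],
             censored = p$censored[keep],
             stringsAsFactors = FALSE)
}

#' Read sampling records from a delimited text file
#'
#' Expects a UTF-8 CSV with a header row and columns
#' `province,city,product,raw_value`.
#'
#' @param path file path.
#' @inheritParams parse_records
#' @return parsed records, see [parse_records()].
#' @export
read_samples <- function(path, nd_tokens = default_nd_tokens(), strict = TRUE) {
  x <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                       fileEncoding = "UTF-8")
  parse_records(x, nd_tokens = nd_tokens, strict = strict)
}

#' Descriptive statistics of a concentration sample
#'
#' The four indicators used for surveillance summaries: range
#' (max - min), arithmetic mean, sample standard deviation (n - 1
#' denominator; defined as 0 for a single value) and coefficient of
#' variation (sd / mean; `NA` marker when the mean is 0).
#'
#' @param values numeric vector of concentrations (mg/kg), length >= 1.
#' @return one-row data.frame with columns `n`, `range`, `mean`, `sd`, `cv`.
#' @export
#' @examples
#' descriptive_stats(c(0.1, 0.2, 0.3))
descriptive_stats <- function(values) {
  .assert(is.numeric(values) && length(values) >= 1 && all(is.finite(values)),
          "at least one finite numeric value is required")
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else 0
  cv <- if (m > 0) s / m else NA_real_
  data.frame(n = n, range = max(values) - min(values), mean = m, sd = s, cv = cv)
}

#' Group records by geographic unit and product
#'
#' @param records parsed sampling records ([parse_records()]).
#' @param level `"city"` or `"province"`; at province level city
#'   identity is ignored.
#' @return named list of concentration vectors, one per
#'   (unit, product) group, with a `keys` attribute data.frame
#'   (`unit`, `province`, `product`) aligned with the list.
#' @export
group_records <- function(records, level = c("city", "province")) {
  level <- match.arg(level)
  need <- c("province", "city", "product", "concentration")
  .assert(is.data.frame(records) && all(need %in% names(records)),
          "records must have columns %s", paste(need, collapse = ", "))
  .assert(all(records$product %in% .products),
          "unknown product category in records")
  unit <- records[[level]]
  key <- .pair_key(unit, records$product)
  f <- factor(key, levels = unique(key))
  groups <- split(records$concentration, f)
  first <- match(levels(f), key)
  attr(groups, "keys") <- data.frame(
    unit = unit[first],
    province = records$province[first],
    product = records$product[first],
    stringsAsFactors = FALSE)
  groups
}

#' Descriptive-statistics table per (unit, product)
#'
#' @inheritParams group_records
#' @return data.frame with `unit`, `province`, `product` plus the
#'   columns of [descriptive_stats()], one row per group.
#' @export
summarize_concentrations <- function(records, level = c("province", "city")) {
  level <- match.arg(level)
  g <- group_records(records, level)
  keys <- attr(g, "keys")
  stats <- do.call(rbind, lapply(g, descriptive_stats))
  out <- cbind(keys, stats)
  rownames(out) <- NULL
  out
}

#' Overall per-product statistics under two weightings
#'
#' National summary rows can be computed by pooling all samples
#' ("pooled") or by averaging the per-unit statistics ("unit_mean");
#' surveillance reports do not always say which convention they use, so
#' both are returned, labelled.
#'
#' @inheritParams group_records
#' @return data.frame with columns `product`, `weighting`, `n`, `range`,
#'   `mean`, `sd`, `cv`.
#' @export
overall_stats <- function(records, level = c("province", "city")) {
  level <- match.arg(level)
  per_unit <- summarize_concentrations(records, level)
  rows <- lapply(.products[.products %in% records$product], function(prod) {
    vals <- records$concentration[records$product == prod]
    pooled <- cbind(product = prod, weighting = "pooled",
                    descriptive_stats(vals), stringsAsFactors = FALSE)
    u <- per_unit[per_unit$product == prod, , drop = FALSE]
    unit_mean <- data.frame(
      product = prod, weighting = "unit_mean", n = sum(u$n),
      range = mean(u$range), mean = mean(u$mean), sd = mean(u$sd),
      cv = mean(u$cv, na.rm = TRUE), stringsAsFactors = FALSE)
    rbind(pooled, unit_mean)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
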