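#' Order clusters into risk levels
#'
#' Clusters are ordered by the mean of their standardized centroid
#' coordinates — an equal-weight NIPI + TCR + THQ severity score — and
#' numbered 1 (lowest risk) to K (highest). Score ties are broken by
#' the unstandardized THQ centroid, then by stable cluster id, so the
#' mapping is deterministic and invariant to relabelling of clusters.
#'
#' @param fit a `cd_kmeans` object ([kmeans_fit()], [select_and_fit()]).
#' @param features the `cd_features` object the fit was computed on
#'   (provides the standardization record and observation metadata).
#' @return a `risk_level_table`: data.frame with the observation
#'   metadata plus `cluster` and `level` columns, and attribute `k`.
#' @export
assign_levels <- function(fit, features) {
  .assert(inherits(fit, "cd_kmeans"), "fit must be a cd_kmeans object")
  .assert(inherits(features, "cd_features"), "features must be cd_features")
  z_cent <- fit$centroids
  k <- nrow(z_cent)
  score <- rowMeans(z_cent)
  raw_cent <- sweep(sweep(z_cent, 2, features$scale, "*"), 2,
                    features$center, "+")
  thq_col <- match("thq", colnames(z_cent))
  if (is.na(thq_col)) thq_col <- ncol(z_cent)
  ord <- order(score, raw_cent[, thq_col], seq_len(k))
  lvl <- integer(k)
  lvl[ord] <- seq_len(k)
  meta <- features$meta
  out <- if (is.null(meta)) {
    data.frame(cluster = fit$assignments, level = lvl[fit$assignments])
  } else {
    data.frame(meta, cluster = fit$assignments,
               level = lvl[fit$assignments], stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "k") <- k
  class(out) <- c("risk_level_table", "data.frame")
  out
}

#' Tabulate risk levels and high-risk composition
#'
#' Counts and percentage shares per level, and — among combinations at
#' or above the high-risk threshold — the composition by product and by
#' province. Percentages are truncated (not rounded) at the second
#' decimal, matching the convention of published shares such as
#' 16/22 = 72.72.
#'
#' @param levels a `risk_level_table` ([assign_levels()]) or any
#'   data.frame with a `level` column (plus `product` / `province` for
#'   the composition tables).
#' @param high_threshold levels `>= high_threshold` count as high risk.
#' @return object of class `risk_level_summary`: list with `n`, `k`,
#'   `by_level` (level, count, percent), `n_high`, `high_by_product`
#'   and `high_by_province` composition tables.
#' @export
tabulate_levels <- function(levels, high_threshold = 4) {
  .assert(is.data.frame(levels) && "level" %in% names(levels),
          "levels must be a data.frame with a 'level' column")
  .assert(nrow(levels) >= 1, "empty risk-level table")
  .assert_scalar(high_threshold, "high_threshold", lower = 1)
  k <- attr(levels, "k") %||% max(levels$level)
  n <- nrow(levels)
  cnt <- tabulate(levels$level, nbins = k)
  by_level <- data.frame(level = seq_len(k), count = cnt,
                         percent = .trunc_percent(100 * cnt / n))
  high <- levels[levels$level >= high_threshold, , drop = FALSE]
  comp <- function(var) {
    if (!nrow(high) || !var %in% names(high)) {
      out <- data.frame(x = character(), count = integer(),
                        percent = numeric(), stringsAsFactors = FALSE)
      names(out)[1] <- var
      return(out)
    }
    t <- sort(table(high[[var]]), decreasing = TRUE)
    out <- data.frame(x = names(t), count = as.integer(t),
                      percent = .trunc_percent(100 * as.integer(t) / nrow(high)),
                      stringsAsFactors = FALSE)
    names(out)[1] <- var
    out
  }
  structure(list(n = n, k = k, high_threshold = high_threshold,
                 by_level = by_level, n_high = nrow(high),
                 high_by_product = comp("product"),
                 high_by_province = comp("province")),
            class = "risk_level_summary")
}

#' @export
print.risk_level_summary <- function(x, ...) {
  cat(sprintf("risk levels over %d (unit, product) combinations (K = %d):\n",
              x$n, x$k))
  print.data.frame(x$by_level, row.names = FALSE)
  cat(sprintf("high risk (level >= %d): %d combination%s\n",
              x$high_threshold, x$n_high, if (x$n_high == 1) "" else "s"))
  if (x$n_high > 0) {
    cat("  by product:\n")
    print.data.frame(x$high_by_product, row.names = FALSE)
    if (nrow(x$high_by_province)) {
      cat("  by province:\n")
      print.data.frame(x$high_by_province, row.names = FALSE)
    }
  }
  invisible(x)
}
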