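#' Column-standardize a feature matrix
#'
#' z-scores each column (n - 1 standard deviation). Constant columns
#' cannot be scaled; they are set to 0 and flagged. Standardization
#' matters here because the three risk indices live on wildly different
#' scales (TCR ~ 1e-3, THQ ~ 1); without it Euclidean clustering would
#' see only the largest-scale index.
#'
#' @param x numeric matrix (or data.frame of numeric columns), >= 2 rows.
#' @return an object of class `cd_features`: list with the standardized
#'   matrix `z`, the `center` and `scale` applied per column, a logical
#'   `constant` flag per column, and (optionally) observation metadata
#'   in `meta`.
#' @export
standardize <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  .assert(nrow(m) >= 2, "at least two observations are required")
  .assert(all(is.finite(m)), "non-finite feature values")
  center <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  constant <- s < 1e-12
  scale_used <- ifelse(constant, 1, s)
  z <- sweep(sweep(m, 2, center), 2, scale_used, "/")
  z[, constant] <- 0
  structure(list(z = z, center = center, scale = scale_used,
                 constant = constant, meta = NULL),
            class = "cd_features")
}

#' Build the clustering feature matrix from a unit-index table
#'
#' @param indices output of [unit_indices()] (or any data.frame with the
#'   requested columns).
#' @param columns index columns to use as features.
#' @param standardize z-score the columns (recommended and default).
#' @return a `cd_features` object carrying `unit` / `province` /
#'   `product` metadata for each row.
#' @export
feature_matrix <- function(indices, columns = c("nipi", "tcr", "thq"),
                           standardize = TRUE) {
  .assert(is.data.frame(indices) && all(columns %in% names(indices)),
          "indices must contain columns %s", paste(columns, collapse = ", "))
  m <- as.matrix(indices[columns])
  f <- if (standardize) {
    standardize(m)
  } else {
    structure(list(z = m, center = stats::setNames(rep(0, ncol(m)), columns),
                   scale = stats::setNames(rep(1, ncol(m)), columns),
                   constant = stats::setNames(rep(FALSE, ncol(m)), columns),
                   meta = NULL),
              class = "cd_features")
  }
  meta_cols <- intersect(c("unit", "province", "product"), names(indices))
  f$meta <- indices[meta_cols]
  f
}

## N x K matrix of squared Euclidean distances to centers
.sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

#' k-means++ centroid initialization
#'
#' The first centroid is chosen uniformly at random from the points;
#' each subsequent centroid is drawn with probability proportional to
#' the squared minimum distance to the centroids already chosen, so
#' already-picked (or coincident) points have probability 0 unless all
#' remaining distances are 0. Uses the current RNG state; seed via
#' `set.seed()` or through [kmeans_fit()].
#'
#' @param points numeric matrix of observations (rows).
#' @param k number of centroids, `1 <= k <= nrow(points)`.
#' @return `k x d` matrix of centroids with an `indices` attribute
#'   giving the chosen row indices.
#' @export
kmeanspp_init <- function(points, k) {
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  n <- nrow(m)
  .assert(all(is.finite(m)), "non-finite coordinates")
  .assert(is.numeric(k) && length(k) == 1L && k >= 1 && k <= n,
          "k must satisfy 1 <= k <= number of points")
  k <- as.integer(k)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(m, 2, m[idx[1], ], "-")^2)
    for (j in 2:k) {
      idx[j] <- if (sum(d2) <= 0) sample.int(n, 1L)
                else sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, rowSums(sweep(m, 2, m[idx[j], ], "-")^2))
    }
  }
  structure(m[idx, , drop = FALSE], indices = idx)
}

## Lloyd iterations from a given set of centers; empty clusters are
## repaired by re-seeding with the point farthest from its centroid
## (repair stops if every point sits on a centroid)
.lloyd <- function(m, centers, max_iter, tol) {
  n <- nrow(m)
  k <- nrow(centers)
  shift <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    d2 <- .sq_dist(m, centers)
    assign <- max.col(-d2, ties.method = "first")
    repeat {
      empty <- which(tabulate(assign, k) == 0L)
      if (!length(empty)) break
      mind2 <- d2[cbind(seq_len(n), assign)]
      far <- which.max(mind2)
      if (mind2[far] <= 0) break
      centers[empty[1L], ] <- m[far, ]
      d2 <- .sq_dist(m, centers)
      assign <- max.col(-d2, ties.method = "first")
    }
    grp <- sort(unique(assign))
    new_centers <- centers
    new_centers[grp, ] <- rowsum(m, assign) / tabulate(assign, k)[grp]
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- .sq_dist(m, centers)
  assign <- max.col(-d2, ties.method = "first")
  list(centers = centers, assignments = assign,
       sse = sum(d2[cbind(seq_len(n), assign)]),
       iterations = it, converged = shift < tol)
}

#' Fit k-means with k-means++ seeding and restarts
#'
#' Runs Lloyd iterations from [kmeanspp_init()] starts, keeping the
#' solution with the smallest within-cluster sum of squared distances
#' over `restarts` independent starts. Iteration stops when the largest
#' centroid displacement drops below `tol` or `max_iter` is reached.
#'
#' @param points numeric matrix of observations (rows); all finite.
#' @param k number of clusters, `1 <= k <= nrow(points)`.
#' @param restarts independent k-means++ starts; best SSE wins.
#' @param max_iter Lloyd iteration cap per start.
#' @param tol convergence threshold on the maximum centroid displacement.
#' @param seed optional integer; if supplied, `set.seed(seed)` is called
#'   so the fit is reproducible in isolation. Leave `NULL` to use the
#'   ambient RNG stream (as [select_and_fit()] does).
#' @return object of class `cd_kmeans`: `k`, `centroids`, `assignments`,
#'   `sse`, `iterations`, `converged`, `restarts`, `seed`.
#' @export
kmeans_fit <- function(points, k, restarts = 10, max_iter = 300, tol = 1e-8,
                       seed = NULL) {
  m <- as.matrix(points)
  storage.mode(m) <- "double"
  .assert(all(is.finite(m)), "non-finite coordinates")
  .assert(is.numeric(k) && length(k) == 1L && k >= 1 && k <= nrow(m),
          "k must satisfy 1 <= k <= number of points")
  .assert_scalar(restarts, "restarts", lower = 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- .lloyd(m, kmeanspp_init(m, k), max_iter, tol)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  structure(list(k = as.integer(k), centroids = best$centers,
                 assignments = best$assignments, sse = best$sse,
                 iterations = best$iterations, converged = best$converged,
                 restarts = as.integer(restarts), seed = seed),
            class = "cd_kmeans")
}

#' @export
print.cd_kmeans <- function(x, ...) {
  cat(sprintf("k-means++ fit: k = %d, n = %d, sse = %.6g (%d restart%s)\n",
              x$k, length(x$assignments), x$sse, x$restarts,
              if (x$restarts > 1) "s" else ""))
  cat(sprintf("  cluster sizes: %s\n",
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}
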