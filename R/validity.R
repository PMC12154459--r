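#' Silhouette coefficient of a partition
#'
#' For each point, `a(i)` is the mean distance to the other members of
#' its own cluster and `b(i)` the smallest mean distance to the members
#' of another cluster; the silhouette width is
#' `(b(i) - a(i)) / max(a(i), b(i))`. Points in singleton clusters
#' contribute 0 (the common convention). The score is the average width
#' over all points and lies in `[-1, 1]`; larger is better.
#'
#' @param points numeric matrix of observations.
#' @param assignments cluster label per row; at least 2 distinct labels.
#' @return mean silhouette width.
#' @export
silhouette_score <- function(points, assignments) {
  m <- as.matrix(points)
  n <- nrow(m)
  .assert(length(assignments) == n, "one assignment per point is required")
  ids <- unique(assignments)
  .assert(length(ids) >= 2, "silhouette is undefined for a single cluster")
  D <- as.matrix(stats::dist(m))
  sp <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignments == assignments[i]
    n_own <- sum(own)
    if (n_own == 1L) next  # singleton: sp = 0
    a <- sum(D[i, own]) / (n_own - 1)
    b <- min(vapply(ids[ids != assignments[i]],
                    function(cid) mean(D[i, assignments == cid]),
                    numeric(1)))
    denom <- max(a, b)
    sp[i] <- if (denom > 0) (b - a) / denom else 0
  }
  mean(sp)
}

#' Dunn index of a partition
#'
#' Minimum single-linkage distance between any two clusters divided by
#' the maximum cluster diameter; Euclidean distances throughout. Larger
#' is better. An all-singleton partition (every diameter 0) returns
#' `Inf`.
#'
#' @inheritParams silhouette_score
#' @return Dunn index in `[0, Inf]`.
#' @export
dunn_index <- function(points, assignments) {
  m <- as.matrix(points)
  .assert(length(assignments) == nrow(m), "one assignment per point is required")
  ids <- unique(assignments)
  .assert(length(ids) >= 2, "Dunn index is undefined for a single cluster")
  D <- as.matrix(stats::dist(m))
  members <- lapply(ids, function(cid) which(assignments == cid))
  diam <- vapply(members, function(w) {
    if (length(w) < 2) 0 else max(D[w, w])
  }, numeric(1))
  max_diam <- max(diam)
  inter <- Inf
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      inter <- min(inter, min(D[members[[i]], members[[j]]]))
    }
  }
  if (max_diam <= 0) return(Inf)
  inter / max_diam
}

#' Davies-Bouldin index of a partition
#'
#' Standard definition: with `s_i` the mean distance of cluster `i`'s
#' members to their centroid and `d_ij` the distance between centroids,
#' `DBI = mean_i max_{j != i} (s_i + s_j) / d_ij`. Smaller is better.
#' Coincident centroids with nonzero scatter give `Inf`; coincident
#' zero-scatter clusters contribute 0.
#'
#' @inheritParams silhouette_score
#' @return Davies-Bouldin index, >= 0.
#' @export
davies_bouldin <- function(points, assignments) {
  m <- as.matrix(points)
  .assert(length(assignments) == nrow(m), "one assignment per point is required")
  ids <- unique(assignments)
  k <- length(ids)
  .assert(k >= 2, "Davies-Bouldin index is undefined for a single cluster")
  members <- lapply(ids, function(cid) which(assignments == cid))
  cent <- do.call(rbind, lapply(members, function(w)
    colMeans(m[w, , drop = FALSE])))
  s <- vapply(seq_len(k), function(i) {
    w <- members[[i]]
    mean(sqrt(rowSums(sweep(m[w, , drop = FALSE], 2, cent[i, ], "-")^2)))
  }, numeric(1))
  Dc <- as.matrix(stats::dist(cent))
  worst <- vapply(seq_len(k), function(i) {
    r <- vapply(setdiff(seq_len(k), i), function(j) {
      num <- s[i] + s[j]
      if (Dc[i, j] > 0) num / Dc[i, j] else if (num > 0) Inf else 0
    }, numeric(1))
    max(r)
  }, numeric(1))
  mean(worst)
}

#' Rank-voting selection of the number of clusters
#'
#' Each validity index ranks the candidate cluster numbers (silhouette
#' and Dunn: larger is better; Davies-Bouldin: smaller is better). With
#' `C` candidates the best receives `C` points, the second `C - 1`, the
#' worst 1; tied candidates share the mean of the points they span, so
#' each index always distributes `C (C + 1) / 2` points. Totals are
#' summed across the three indices; the candidate with the highest
#' total wins, ties broken toward the smaller K (parsimony).
#'
#' @param scores data.frame with one row per candidate and columns `sc`,
#'   `di`, `dbi` (and optionally `k`).
#' @param candidates candidate cluster numbers; defaults to `scores$k`.
#' @return object of class `cd_votes`: a data.frame with per-index and
#'   total points, with the winning K in attribute `selected_k`.
#' @export
vote_select_k <- function(scores, candidates = scores$k) {
  .assert(is.data.frame(scores) && all(c("sc", "di", "dbi") %in% names(scores)),
          "scores must have columns sc, di, dbi")
  .assert(!is.null(candidates) && length(candidates) == nrow(scores),
          "one candidate K per score row is required")
  C <- nrow(scores)
  .assert(C >= 2, "at least two candidate cluster numbers are required")
  .assert(!anyNA(scores$sc) && !anyNA(scores$di) && !anyNA(scores$dbi),
          "missing validity scores")
  pts <- function(values, larger_better) {
    r <- rank(if (larger_better) -values else values, ties.method = "average")
    C - r + 1
  }
  sc_p <- pts(scores$sc, TRUE)
  di_p <- pts(scores$di, TRUE)
  dbi_p <- pts(scores$dbi, FALSE)
  total <- sc_p + di_p + dbi_p
  sel <- candidates[order(-total, candidates)][1]
  structure(
    data.frame(k = candidates, sc_points = sc_p, di_points = di_p,
               dbi_points = dbi_p, total = total),
    selected_k = sel,
    class = c("cd_votes", "data.frame"))
}

#' @export
print.cd_votes <- function(x, ...) {
  cat("validity-index vote tally:\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("selected number of clusters: %d\n", attr(x, "selected_k")))
  invisible(x)
}

#' Fit candidate cluster numbers, score them and vote
#'
#' Fits every K in `k_range` with a shared restart policy, scores each
#' fit with the silhouette coefficient, Dunn index and Davies-Bouldin
#' index, tallies the rank vote and returns the winning fit. Fully
#' reproducible for a given (data, seed, config).
#'
#' @param features a `cd_features` object ([feature_matrix()]) or a
#'   numeric matrix.
#' @param k_range candidate cluster numbers (all >= 2,
#'   max <= number of observations).
#' @param seed integer seed driving all restarts.
#' @param restarts,max_iter,tol passed to [kmeans_fit()].
#' @return list with elements `fit` (the winning [kmeans_fit()] result),
#'   `scores` (data.frame of `k`, `sc`, `di`, `dbi`), `votes`
#'   ([vote_select_k()] tally) and `k` (selected number of clusters).
#' @export
select_and_fit <- function(features, k_range = 2:8, seed = 1L, restarts = 10,
                           max_iter = 300, tol = 1e-8) {
  z <- if (inherits(features, "cd_features")) features$z else as.matrix(features)
  k_range <- as.integer(k_range)
  .assert(length(k_range) >= 2, "at least two candidate cluster numbers are required")
  .assert(all(k_range >= 2), "candidate cluster numbers must be >= 2")
  .assert(max(k_range) <= nrow(z),
          "largest candidate K exceeds the number of observations")
  set.seed(as.integer(seed))
  fits <- lapply(k_range, function(k)
    kmeans_fit(z, k, restarts = restarts, max_iter = max_iter, tol = tol))
  scores <- data.frame(
    k = k_range,
    sc = vapply(fits, function(f) silhouette_score(z, f$assignments), numeric(1)),
    di = vapply(fits, function(f) dunn_index(z, f$assignments), numeric(1)),
    dbi = vapply(fits, function(f) davies_bouldin(z, f$assignments), numeric(1)))
  votes <- vote_select_k(scores, k_range)
  sel <- attr(votes, "selected_k")
  list(fit = fits[[match(sel, k_range)]], scores = scores, votes = votes,
       k = sel)
}
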