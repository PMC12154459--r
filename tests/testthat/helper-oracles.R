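# Independent brute-force oracles for the cluster-validity indices and
# the k-means objective. Deliberately written as plain loops over
# pairwise Euclidean distances, sharing no code with the package.

euclid <- function(a, b) sqrt(sum((a - b)^2))

brute_silhouette <- function(points, cl) {
  points <- as.matrix(points)
  n <- nrow(points)
  sp <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0) {
      sp[i] <- 0
      next
    }
    a <- mean(vapply(own, function(j) euclid(points[i, ], points[j, ]), 0))
    b <- Inf
    for (cid in setdiff(unique(cl), cl[i])) {
      mem <- which(cl == cid)
      b <- min(b, mean(vapply(mem, function(j) euclid(points[i, ], points[j, ]), 0)))
    }
    sp[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(sp)
}

brute_dunn <- function(points, cl) {
  points <- as.matrix(points)
  ids <- unique(cl)
  diam <- 0
  for (cid in ids) {
    mem <- which(cl == cid)
    if (length(mem) > 1) {
      for (i in mem) for (j in mem) if (i < j)
        diam <- max(diam, euclid(points[i, ], points[j, ]))
    }
  }
  inter <- Inf
  for (a in seq_along(ids)) for (b in seq_along(ids)) if (a < b) {
    for (i in which(cl == ids[a])) for (j in which(cl == ids[b]))
      inter <- min(inter, euclid(points[i, ], points[j, ]))
  }
  if (diam <= 0) Inf else inter / diam
}

brute_dbi <- function(points, cl) {
  points <- as.matrix(points)
  ids <- unique(cl)
  k <- length(ids)
  cent <- lapply(ids, function(cid) colMeans(points[cl == cid, , drop = FALSE]))
  s <- vapply(seq_len(k), function(i) {
    mem <- which(cl == ids[i])
    mean(vapply(mem, function(j) euclid(points[j, ], cent[[i]]), 0))
  }, 0)
  worst <- numeric(k)
  for (i in seq_len(k)) {
    r <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      d <- euclid(cent[[i]], cent[[j]])
      rij <- if (d > 0) (s[i] + s[j]) / d else if (s[i] + s[j] > 0) Inf else 0
      r <- max(r, rij)
    }
    worst[i] <- r
  }
  mean(worst)
}

# exhaustive global optimum of the 2-cluster k-means objective
best_two_partition_sse <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    inA <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sse <- 0
    for (side in list(which(inA), which(!inA))) {
      sub <- points[side, , drop = FALSE]
      ctr <- colMeans(sub)
      sse <- sse + sum(sweep(sub, 2, ctr, "-")^2)
    }
    best <- min(best, sse)
  }
  best
}

# random labelled fixture with at least two non-trivial clusters
random_fixture <- function(n = NULL, k = NULL, d = 2) {
  n <- n %||% sample(6:30, 1)
  k <- k %||% sample(2:4, 1)
  repeat {
    cl <- sample.int(k, n, replace = TRUE)
    if (length(unique(cl)) >= 2) break
  }
  list(points = matrix(rnorm(n * d), ncol = d), cl = cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
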