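fake_fit <- function(centroids, assignments) {
  structure(list(k = nrow(centroids), centroids = centroids,
                 assignments = assignments, sse = 0, iterations = 1L,
                 converged = TRUE, restarts = 1L, seed = NULL),
            class = "cd_kmeans")
}

fake_features <- function(n_obs, meta = NULL, d = 3) {
  structure(list(z = matrix(0, n_obs, d,
                            dimnames = list(NULL, c("nipi", "tcr", "thq"))),
                 center = rep(0, d), scale = rep(1, d),
                 constant = rep(FALSE, d), meta = meta),
            class = "cd_features")
}

test_that("clusters are ordered into levels by standardized centroid score", {
  cent <- matrix(c(+1, +1, +1,
                   -1, -1, -1), ncol = 3, byrow = TRUE,
                 dimnames = list(NULL, c("nipi", "tcr", "thq")))
  lv <- assign_levels(fake_fit(cent, c(1, 2, 2)), fake_features(3))
  # cluster 2 (low centroid) -> level 1; cluster 1 (high) -> level 2
  expect_equal(lv$level, c(2, 1, 1))
  expect_equal(attr(lv, "k"), 2)
})

test_that("level assignment is invariant to cluster relabelling", {
  set.seed(30)
  pts <- rbind(matrix(rnorm(30, 0, 0.3), ncol = 3),
               matrix(rnorm(30, 3, 0.3), ncol = 3),
               matrix(rnorm(30, 6, 0.3), ncol = 3))
  colnames(pts) <- c("nipi", "tcr", "thq")
  feats <- standardize(pts)
  fit <- kmeans_fit(feats$z, 3, restarts = 5, seed = 1)
  lv <- assign_levels(fit, feats)
  # permute cluster ids
  perm <- c(3, 1, 2)
  fit2 <- fit
  fit2$assignments <- perm[fit$assignments]
  fit2$centroids <- fit$centroids[order(perm), ]
  lv2 <- assign_levels(fit2, feats)
  expect_equal(lv2$level, lv$level)
})

test_that("identical centroids fall back to a stable documented tie order", {
  cent <- matrix(0, 2, 3, dimnames = list(NULL, c("nipi", "tcr", "thq")))
  lv <- assign_levels(fake_fit(cent, c(1, 2)), fake_features(2))
  expect_equal(sort(unique(lv$level)), 1:2)
  lv_again <- assign_levels(fake_fit(cent, c(1, 2)), fake_features(2))
  expect_identical(lv$level, lv_again$level)
})

test_that("tabulation counts, truncated percents and partition sums behave", {
  tab <- data.frame(
    product = c("rice", "rice", "other", "rice", "wheat_flour", "rice"),
    province = c("A", "A", "B", "B", "C", "A"),
    level = c(5, 4, 4, 2, 1, 3))
  s <- tabulate_levels(tab)
  expect_equal(sum(s$by_level$count), nrow(tab))
  expect_equal(s$n_high, 3)
  expect_equal(s$high_by_product$count[s$high_by_product$product == "rice"], 2)
  # truncation, not rounding: 2/3 -> 66.66, 1/3 -> 33.33
  expect_equal(sort(s$high_by_product$percent), c(33.33, 66.66))
  expect_gte(sum(s$by_level$percent), 99.9)  # truncation loses < 0.01 per level

  single <- tabulate_levels(data.frame(product = "rice", province = "A", level = 4))
  expect_equal(single$high_by_product$percent, 100)

  none <- tabulate_levels(data.frame(product = "rice", province = "A",
                                     level = c(1, 2)))
  expect_equal(none$n_high, 0)
  expect_equal(nrow(none$high_by_product), 0)
  expect_equal(sum(none$by_level$percent), 100)

  expect_error(tabulate_levels(tab[0, ]), "empty")
})

test_that("the full pipeline returns a coherent, reproducible run object", {
  cfg <- synthetic_config(n_provinces = 3, cities_per_province = 4,
                          samples_per_cell = 15, seed = 21,
                          tier_medians = c(0.01, 0.08, 0.3), gsd = 1.3)
  raw <- generate_samples(cfg)
  cons <- generate_consumption(cfg)
  run <- run_risk_pipeline(raw, cons, csf = 6.1, k_range = 2:5, seed = 21)
  expect_s3_class(run, "cd_risk_run")
  expect_equal(nrow(run$levels), 3 * 4 * 3)
  expect_true(all(run$levels$level %in% seq_len(run$k)))
  expect_equal(run$summary$n, nrow(run$levels))
  run2 <- run_risk_pipeline(raw, cons, csf = 6.1, k_range = 2:5, seed = 21)
  expect_identical(run$levels$level, run2$levels$level)
  expect_identical(run$k, run2$k)
})

test_that("report writing emits the delimited tables and a manifest", {
  cfg <- synthetic_config(n_provinces = 2, cities_per_province = 3,
                          samples_per_cell = 10, seed = 8)
  run <- run_risk_pipeline(generate_samples(cfg), generate_consumption(cfg),
                           csf = 6.1, k_range = 2:4, seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_risk_report(run, dir)
  expect_true(all(file.exists(paths)))
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$k, run$k)
  expect_equal(manifest$package, "cdrisk")
  lv <- utils::read.csv(paths[["levels"]])
  expect_equal(nrow(lv), nrow(run$levels))
})
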