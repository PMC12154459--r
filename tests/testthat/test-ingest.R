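test_that("raw detection values parse per the surveillance dialect rules", {
  p <- parse_detection_value(c("not detected", "<0.01", "0.16", "ND", " < 0.02 "))
  expect_equal(p$concentration, c(0, 0.01, 0.16, 0, 0.02))
  expect_equal(p$censored, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("unparsable values raise errors carrying row context", {
  expect_error(parse_detection_value(c("0.1", "oops", "0.2")), "row 2")
  expect_error(parse_detection_value("-0.5"))
  expect_error(parse_detection_value("  "))
})

test_that("descriptive statistics use range, mean, n-1 SD and CV", {
  s <- descriptive_stats(c(0.1, 0.2, 0.3))
  expect_equal(s$mean, 0.2)
  expect_equal(s$range, 0.2)
  expect_equal(s$sd, 0.1)
  expect_equal(s$cv, 0.5)

  const <- descriptive_stats(c(0.05, 0.05, 0.05))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)

  zero <- descriptive_stats(c(0, 0))
  expect_true(is.na(zero$cv))  # undefined marker, not a crash

  expect_equal(descriptive_stats(c(0, 0.9))$range, 0.9)
  expect_error(descriptive_stats(numeric(0)))
})

test_that("grouping conserves records and projects city identity at province level", {
  rec <- data.frame(
    province = c("A", "A", "A", "B", "B", "B"),
    city = c("A1", "A2", "A1", "B1", "B1", "B2"),
    product = c("rice", "rice", "wheat_flour", "rice", "other", "other"),
    concentration = seq(0.01, 0.06, by = 0.01),
    censored = FALSE, stringsAsFactors = FALSE)

  g_city <- group_records(rec, "city")
  expect_equal(sum(lengths(g_city)), nrow(rec))

  g_prov <- group_records(rec, "province")
  keys <- attr(g_prov, "keys")
  expect_equal(sum(lengths(g_prov)), nrow(rec))
  expect_true(all(keys$unit %in% c("A", "B")))
  # cities A1 and A2 collapse into one provincial rice group
  expect_equal(length(g_prov[[which(keys$unit == "A" & keys$product == "rice")]]), 2)

  one <- rec[rec$city == "B1" & rec$product == "rice", , drop = FALSE]
  g_one <- group_records(one, "city")
  expect_equal(length(g_one), 1)
  expect_equal(lengths(g_one)[[1]], nrow(one))
})

test_that("parsing is idempotent through a serialize/re-parse round trip", {
  cfg <- synthetic_config(n_provinces = 2, cities_per_province = 2,
                          samples_per_cell = 25, seed = 9)
  rec <- parse_records(generate_samples(cfg))
  reserialized <- data.frame(
    province = rec$province, city = rec$city, product = rec$product,
    raw_value = ifelse(rec$censored, "ND",
                       format(rec$concentration, trim = TRUE, scientific = FALSE)),
    stringsAsFactors = FALSE)
  rec2 <- parse_records(reserialized)
  expect_equal(rec2$concentration, rec$concentration)
  expect_identical(rec2$censored, rec$censored)
})

test_that("file ingest supports strict and lenient modes", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("province,city,product,raw_value",
               "A,A1,rice,0.10",
               "A,A1,rice,not detected",
               "A,A1,noodle,0.20",
               "A,A2,rice,garbage",
               "A,A2,wheat_flour,<0.05"), tmp)
  expect_error(read_samples(tmp), "row")
  expect_warning(rec <- read_samples(tmp, strict = FALSE), "skipped 2")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$concentration, c(0.10, 0, 0.05))
  expect_equal(rec$censored, c(FALSE, TRUE, FALSE))
})

test_that("overall statistics report both pooled and unit-mean weightings", {
  rec <- data.frame(
    province = rep(c("A", "B"), each = 4),
    city = rep(c("A1", "B1"), each = 4),
    product = "rice",
    concentration = c(0.1, 0.2, 0.3, 0.4, 0.01, 0.02, 0.03, 0.04),
    censored = FALSE, stringsAsFactors = FALSE)
  ov <- overall_stats(rec)
  pooled <- ov[ov$weighting == "pooled", ]
  um <- ov[ov$weighting == "unit_mean", ]
  expect_equal(pooled$mean, mean(rec$concentration))
  expect_equal(um$mean, mean(c(0.25, 0.025)))
  expect_equal(pooled$n, 8)
})
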