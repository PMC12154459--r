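params_with <- function(fc_rice = 0.3, csf = 6.1, ...) {
  cons <- data.frame(province = "A", product = c("rice", "wheat_flour", "other"),
                     fc = c(fc_rice, 0.14, 0.05), stringsAsFactors = FALSE)
  exposure_params(csf = csf, consumption = cons, ...)
}

test_that("pollution index is concentration over limit", {
  expect_equal(pollution_index(0.9, 0.2), 4.5)
  expect_equal(pollution_index(0.2, 0.2), 1)
  expect_equal(pollution_index(0, 0.1), 0)
  expect_error(pollution_index(0.1, 0), "> 0")
  expect_error(pollution_index(-0.1, 0.2), ">= 0")
})

test_that("NIPI reproduces the published provincial worked examples", {
  expect_equal(nipi(4.5, 0.5493), 3.2056, tolerance = 5e-5)
  expect_equal(nipi(1.0, 0.1387), 0.71388, tolerance = 5e-5)
  expect_equal(nipi(1, 1), 1)
  expect_error(nipi(0.5, 0.6), "inconsistent")
})

test_that("NIPI is bounded between p_max/sqrt(2) and p_max", {
  set.seed(1)
  for (i in 1:200) {
    p <- runif(10, 0, 5)
    v <- nipi(max(p), mean(p))
    expect_gte(v, max(p) / sqrt(2) - 1e-12)
    expect_lte(v, max(p) + 1e-12)
  }
})

test_that("EDI is consumption times quantile per body mass", {
  expect_equal(edi(0.3, 0.1, 60), 5e-4)
  expect_equal(edi(0, 0.7, 60), 0)
  expect_equal(edi(0.2, 0.2, 60), 6.6667e-4, tolerance = 1e-4)
  expect_error(edi(0.3, 0.1, 0), "> 0")
})

test_that("TCR and THQ reduce to CSF*EDI50 and EDI95/RfD at the defaults", {
  p <- params_with(csf = 6.1)
  expect_equal(tcr(p, 5e-4), 6.1 * 5e-4)
  expect_equal(thq(p, 4.83029e-3), 4.83029)
  expect_equal(thq(p, p$rfd), 1)
  expect_equal(tcr(p, 0), 0)
  expect_equal(thq(p, 0), 0)
  p1 <- params_with(csf = 1)
  expect_equal(tcr(p1, 0.001), 0.001)
  # full formula honours non-default exposure constants
  p2 <- params_with(csf = 2, ef = 200, ed = 30, atc = 365 * 70)
  expect_equal(tcr(p2, 0.001), 200 * 30 * 2 * 0.001 / (365 * 70))
})

test_that("the slope factor has no silent default", {
  expect_error(exposure_params(), "csf")
})

test_that("unit indices compose the three indices per (unit, product) group", {
  rec <- data.frame(province = "A", city = "A1", product = "rice",
                    concentration = c(0, 0.1, 0.2, 0.3, 0.9),
                    censored = c(TRUE, rep(FALSE, 4)), stringsAsFactors = FALSE)
  p <- params_with(fc_rice = 0.3, csf = 6.1)
  idx <- unit_indices(rec, p, limit_standard(), level = "city")
  expect_equal(nrow(idx), 1)
  expect_equal(idx$p_max, 4.5)
  expect_equal(idx$p_avg, 1.5)
  expect_equal(idx$nipi, sqrt((20.25 + 2.25) / 2))
  # type-7 quantiles of {0,.1,.2,.3,.9}
  expect_equal(idx$x50, 0.2)
  expect_equal(idx$x95, 0.78)
  expect_equal(idx$tcr, 6.1 * 0.3 * 0.2 / 60)
  expect_equal(idx$thq, (0.3 * 0.78 / 60) / 0.001)
  expect_equal(idx$n_samples, 5)
})

test_that("all-zero concentrations give zero indices", {
  rec <- data.frame(province = "A", city = "A1", product = "rice",
                    concentration = c(0, 0, 0), censored = TRUE,
                    stringsAsFactors = FALSE)
  idx <- unit_indices(rec, params_with(), level = "city")
  expect_equal(unlist(idx[c("nipi", "tcr", "thq")]), c(nipi = 0, tcr = 0, thq = 0))
})

test_that("a missing consumption row is reported by province and product", {
  rec <- data.frame(province = "ZZ", city = "Z1", product = "rice",
                    concentration = 0.1, censored = FALSE,
                    stringsAsFactors = FALSE)
  expect_error(unit_indices(rec, params_with(), level = "city"),
               "province 'ZZ'.*product 'rice'")
})

test_that("indices are linear in their drivers and monotone under scaling", {
  set.seed(2)
  p <- params_with(fc_rice = 0.3, csf = 6.1)
  p_double_fc <- params_with(fc_rice = 0.6, csf = 6.1)
  for (i in 1:20) {
    x <- rlnorm(15, log(0.02), 1)
    rec <- data.frame(province = "A", city = "A1", product = "rice",
                      concentration = x, censored = FALSE,
                      stringsAsFactors = FALSE)
    rec2 <- rec; rec2$concentration <- 2.5 * x
    i1 <- unit_indices(rec, p, level = "city")
    i2 <- unit_indices(rec2, p, level = "city")
    # scaling every concentration by c >= 1 does not decrease any index
    expect_true(all(unlist(i2[c("nipi", "tcr", "thq")]) >=
                      unlist(i1[c("nipi", "tcr", "thq")])))
    # TCR linear in X50; doubling FC doubles TCR and THQ
    expect_equal(i2$tcr, 2.5 * i1$tcr)
    expect_equal(i2$thq, 2.5 * i1$thq)
    i3 <- unit_indices(rec, p_double_fc, level = "city")
    expect_equal(i3$tcr, 2 * i1$tcr)
    expect_equal(i3$thq, 2 * i1$thq)
  }
})

test_that("provincial and municipal granularity share one code path", {
  cfg <- synthetic_config(n_provinces = 2, cities_per_province = 3,
                          samples_per_cell = 12, seed = 5)
  rec <- parse_records(generate_samples(cfg))
  cons <- generate_consumption(cfg)
  p <- exposure_params(csf = 6.1, consumption = cons)
  city <- unit_indices(rec, p, level = "city")
  prov <- unit_indices(rec, p, level = "province")
  expect_equal(nrow(city), 2 * 3 * 3)
  expect_equal(nrow(prov), 2 * 3)
  expect_true(all(prov$unit %in% c("P01", "P02")))
  # provincial group pools the province's city samples
  expect_equal(sum(prov$n_samples), sum(city$n_samples))
})

test_that("NIPI from published summary statistics recovers the max from the range", {
  st <- data.frame(province = "Hunan", product = "rice",
                   range = 0.9, mean = 0.10986, stringsAsFactors = FALSE)
  out <- nipi_from_stats(st)
  expect_equal(out$p_max, 4.5)
  expect_equal(out$p_avg, 0.5493)
  expect_equal(out$nipi, 3.2056, tolerance = 5e-5)
})
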