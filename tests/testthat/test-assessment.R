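test_that("quota allocation reproduces the published split and sums exactly", {
  expect_equal(allocate_quota(6700), c(Norway = 2000, Denmark = 4700))
  expect_equal(allocate_quota(0), c(Norway = 0, Denmark = 0))
  expect_equal(allocate_quota(15000), c(Norway = 4500, Denmark = 10500))
})

test_that("largest-remainder allocation sums to the total for any shares", {
  set.seed(8)
  for (k in 1:40) {
    n_countries <- sample(2:4, 1)
    shares <- runif(n_countries)
    shares <- shares / sum(shares)
    names(shares) <- paste0("C", seq_len(n_countries))
    total <- sample(0:300, 1) * 100
    parts <- allocate_quota(total, shares, 100)
    expect_equal(sum(parts), round(total / 100) * 100)
    expect_true(all(parts >= 0))
    expect_true(all(parts %% 100 == 0))
  }
  # deterministic tie-break by country name
  a <- allocate_quota(300, c(B = 0.5, A = 0.5), 100)
  b <- allocate_quota(300, c(B = 0.5, A = 0.5), 100)
  expect_identical(a, b)
  expect_equal(unname(a["A"]), 200)
})

test_that("the emergency closure fires exactly when the prediction drops below target", {
  p <- default_params()
  w <- uniform_weights()
  # no harvest can never trigger a closure
  expect_false(emergency_closure_check(59, 10, w, 0, the_specs, p, the_clim))
  # a healthy state under a modest quota stays open
  expect_false(emergency_closure_check(80, 10, w, 5, the_specs, p, the_clim))
  # the 2015 situation: 59 thousand counted, 15 thousand standing quota
  expect_true(emergency_closure_check(59, 10, w, 15, the_specs, p, the_clim))
  # monotone in the quota: once closed, larger quotas stay closed
  quotas <- seq(0, 30, by = 2.5)
  fired <- vapply(quotas, function(q) {
    emergency_closure_check(59, 10, w, q, the_specs, p, the_clim)
  }, logical(1))
  expect_true(all(diff(fired) >= 0))
})

test_that("a 2015-like assessment closes under the block quota but stays open one-year", {
  p <- default_params()
  rec <- monitoring_record(2015, spring_count = 59000, days = 10)
  d3 <- annual_assessment(rec, uniform_weights(), the_specs, p,
                          strategy_config("THREE_YEAR"), block_quota = 15)
  expect_true(d3$closure)
  expect_identical(d3$total_quota, 0)
  expect_true(all(d3$allocation == 0))
  d1 <- annual_assessment(rec, uniform_weights(), the_specs, p,
                          strategy_config("ONE_YEAR"))
  expect_false(d1$closure)
  expect_gt(d1$total_quota, 0)
  expect_lt(d1$total_quota, 15000)
})

test_that("an overabundant population draws the top of the action grid in both modes", {
  p <- default_params()
  rec <- monitoring_record(2020, spring_count = 120000, days = 10)
  d1 <- annual_assessment(rec, uniform_weights(), the_specs, p,
                          strategy_config("ONE_YEAR"))
  expect_identical(d1$total_quota, 30000)
  expect_false(d1$closure)
  d3 <- annual_assessment(rec, uniform_weights(), the_specs, p,
                          strategy_config("THREE_YEAR"), block_quota = 30)
  expect_identical(d3$total_quota, 30000)
  expect_false(d3$closure)
})

test_that("assessments are reproducible and require a spring count", {
  p <- default_params()
  rec <- monitoring_record(2015, spring_count = 59000, days = 12)
  prev <- list(N = 74.8, days = 9, harvest = 14.8)
  d_a <- annual_assessment(rec, uniform_weights(), the_specs, p,
                          strategy_config("THREE_YEAR"), block_quota = 15,
                          prev = prev)
  d_b <- annual_assessment(rec, uniform_weights(), the_specs, p,
                          strategy_config("THREE_YEAR"), block_quota = 15,
                          prev = prev)
  expect_identical(d_a[names(d_a) != "weights"], d_b[names(d_b) != "weights"])
  expect_identical(unclass(d_a$weights), unclass(d_b$weights))
  # the observation updated the weights away from the uniform prior
  expect_gt(max(abs(unclass(d_a$weights) - 1 / 9)), 1e-6)
  bad <- monitoring_record(2015, spring_count = NA, days = 12)
  expect_error(
    annual_assessment(bad, uniform_weights(), the_specs, p,
                      strategy_config("THREE_YEAR"), block_quota = 15),
    "spring count"
  )
  # THREE_YEAR mode without a standing quota is an error
  expect_error(
    annual_assessment(rec, uniform_weights(), the_specs, p,
                      strategy_config("THREE_YEAR")),
    "block quota"
  )
})

test_that("the decision log is append-only and keeps issued decisions intact", {
  p <- default_params()
  log <- withr::local_tempfile(fileext = ".tsv")
  rec15 <- monitoring_record(2015, spring_count = 59000, days = 10)
  d15 <- annual_assessment(rec15, uniform_weights(), the_specs, p,
                           strategy_config("THREE_YEAR"), block_quota = 15)
  append_decision(d15, log)
  first <- read.delim(log)
  # the November revision (74,800) arrives: the issued decision is untouched,
  # the revised count simply informs the next cycle's record
  rec16 <- monitoring_record(2016, spring_count = 74800, days = 8)
  d16 <- annual_assessment(rec16, uniform_weights(), the_specs, p,
                           strategy_config("ONE_YEAR"))
  append_decision(d16, log)
  both <- read.delim(log)
  expect_identical(nrow(both), 2L)
  expect_identical(both[1, ], first[1, ])
  expect_identical(both$year, c(2015L, 2016L))
})

test_that("the Chapman estimator matches worked values and handles edge cases", {
  est <- cmr_estimate(100, 50, 10)
  expect_equal(est$estimate, 101 * 51 / 11 - 1, tolerance = 1e-12)
  expect_equal(est$estimate, 467.2727, tolerance = 1e-6)
  expect_gt(est$se, 0)
  # complete overlap recovers the marked total
  expect_equal(cmr_estimate(40, 40, 40)$estimate, 40)
  # zero recaptures stay finite
  z <- cmr_estimate(100, 50, 0)
  expect_equal(z$estimate, 101 * 51 - 1)
  expect_true(is.finite(z$se))
  expect_error(cmr_estimate(100, 50, 60), "exceed")
  expect_error(cmr_estimate(5, 50, 10), "exceed")
})

test_that("monitoring files round-trip and reject malformed headers", {
  recs <- rbind(
    monitoring_record(2013, 81600, 79000, 0.12, 2800, 8500, 11),
    monitoring_record(2014, 76000, NA, NA, 3200, 11600, 9)
  )
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_monitoring(recs, tmp)
  re <- read_monitoring(tmp)
  expect_equal(re$spring_count, c(81600, 76000))
  expect_true(is.na(re$autumn_count[2]))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("year\tcount\n2013\t81600", bad)
  expect_error(read_monitoring(bad), "lacks columns")
})
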