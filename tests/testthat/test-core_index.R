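test_that("normalization maps the calibration range onto [0, 1]", {
  spec <- default_ehsra_spec()
  base <- data.frame(t_dry = 21.97, t_wet = 12.10, t_globe = 23.40,
                     v_air = 0, metabolism = 130, clo = 0.50)
  z <- normalize_thermal(base, spec)
  expect_equal(unname(unlist(z)), rep(0, 6))

  top <- data.frame(t_dry = 48.20, t_wet = 37.57, t_globe = 62.70,
                    v_air = 4.20, metabolism = 490, clo = 1.35)
  expect_equal(unname(unlist(normalize_thermal(top, spec))), rep(1, 6))

  g <- normalize_thermal(transform(base, t_globe = 40), spec)
  expect_equal(g$t_globe, 16.60 / 39.30, tolerance = 1e-12)
})

test_that("out-of-calibration input is flagged, not clipped", {
  spec <- default_ehsra_spec()
  hot <- data.frame(t_dry = 55, t_wet = 20, t_globe = 60, v_air = 1,
                    metabolism = 300, clo = 0.8)
  expect_warning(z <- normalize_thermal(hot, spec), "t_dry")
  expect_gt(z$t_dry, 1)  # not clipped
  expect_silent(normalize_thermal(hot, spec, warn_out_of_range = FALSE))
})

test_that("input validation names the offending field", {
  ok <- data.frame(t_dry = 30, t_wet = 20, t_globe = 40, v_air = 1,
                   metabolism = 300, clo = 0.8)
  expect_error(ehsra_score(ok[-3]), "t_globe")
  bad <- ok; bad$t_wet <- NA_real_
  expect_error(ehsra_score(bad), "t_wet")
  bad <- ok; bad$v_air <- -0.1
  expect_error(ehsra_score(bad), "v_air")
  bad <- ok; bad$t_dry <- 45  # dry above globe: warn, accept
  expect_warning(s <- ehsra_score(bad), "t_globe")
  expect_true(is.finite(s))
})

test_that("worked score values match hand evaluation", {
  spec <- default_ehsra_spec()
  lo <- data.frame(t_dry = 21.97, t_wet = 12.10, t_globe = 23.40,
                   v_air = 0, metabolism = 130, clo = 0.50)
  expect_identical(ehsra_score(lo, spec), 0)
  hi <- data.frame(t_dry = 48.20, t_wet = 37.57, t_globe = 62.70,
                   v_air = 4.20, metabolism = 490, clo = 1.35)
  expect_equal(ehsra_score(hi, spec),
               10 * sum(0.752, 0.686, 0.774, 0.244, 0.491, 0.387),
               tolerance = 1e-12)
  mid <- data.frame(t_dry = 30, t_wet = 20, t_globe = 40, v_air = 1.0,
                    metabolism = 300, clo = 0.8)
  s <- ehsra_score(mid, spec)
  expect_equal(s, 10.80, tolerance = 0.01)
  expect_equal(s, oracle_score(mid), tolerance = 1e-12)
})

test_that("score equals the term-by-term oracle on 1000 random samples", {
  set.seed(401)
  d <- random_thermal(1000)
  got <- ehsra_score(d, warn_out_of_range = FALSE)
  want <- vapply(seq_len(nrow(d)), function(i) oracle_score(d[i, ]),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("score is monotone in each variable with the air-velocity switch", {
  set.seed(402)
  d <- random_thermal(300)
  s0 <- ehsra_score(d, warn_out_of_range = FALSE)
  eps <- 1e-4
  for (v in c("t_wet", "t_globe", "metabolism", "clo")) {
    d2 <- d; d2[[v]] <- d2[[v]] + eps * diff(range(d[[v]]))
    expect_true(all(ehsra_score(d2, warn_out_of_range = FALSE) > s0),
                label = paste("increasing in", v))
  }
  # air velocity: direction set by dry temperature vs the 35 degC threshold
  d2 <- d; d2$v_air <- d2$v_air + 0.01
  delta <- ehsra_score(d2, warn_out_of_range = FALSE) - s0
  expect_true(all(delta[d$t_dry >= 35] > 0))
  expect_true(all(delta[d$t_dry < 35] < 0))
  # dry temperature, away from the switch point
  away <- abs(d$t_dry - 35) > 1
  d2 <- d; d2$t_dry <- d2$t_dry + 0.5
  still_same_side <- away & (d$t_dry < 35) == (d2$t_dry < 35)
  delta <- ehsra_score(d2, warn_out_of_range = FALSE) - s0
  expect_true(all(delta[still_same_side] > 0))
})

test_that("risk classification reproduces the published band table", {
  expect_identical(as.character(classify_risk(c(10.0, 12.02, 16.0, 18.0))),
                   c("Low", "Moderate", "High", "Very high"))
  # edge conventions: lower bounds closed, top band strictly open
  expect_identical(as.character(classify_risk(c(12.02 - 1e-9, 15.88, 17.56,
                                                17.56 + 1e-9))),
                   c("Low", "High", "High", "Very high"))
  # scores rounded to 2 dp reproduce the printed table, gap row included
  expect_identical(as.character(classify_risk(c(15.87, 15.88))),
                   c("Moderate", "High"))
})

test_that("classification is a total order-preserving step function", {
  set.seed(403)
  s <- sort(runif(500, -5, 40))
  bands <- classify_risk(s)
  expect_true(all(diff(as.integer(bands)) >= 0))
  expect_false(anyNA(bands))
  expect_error(classify_risk(NaN), "finite")
})

test_that("HRmax screening follows the age equation", {
  expect_equal(hrmax(0), 208)
  expect_equal(hrmax(40), 180)
  sc <- hrmax_screen(c(40, 20), c(180, 195))
  expect_equal(sc$hrmax, c(180, 194))
  expect_identical(sc$pass, c(TRUE, FALSE))  # equality passes, excess fails
  sc2 <- hrmax_screen(30, 120, tympanic = c(39.2))
  expect_false(sc2$pass)
  expect_true(sc2$pass_hr)
})

test_that("repeat aggregation: mean for thermal, max for physiological", {
  reps <- data.frame(
    subject_id = "a", time = c(30, 60, 90),
    t_dry = c(30, 32, 34), t_wet = c(20, 21, 22), t_globe = c(40, 41, 42),
    v_air = c(0.5, 0.6, 0.7), metabolism = c(280, 300, 320),
    clo = c(0.8, 0.8, 0.8),
    tympanic = c(37.2, 37.6, 37.5), heart_rate = c(110, 140, 130)
  )
  one <- aggregate_repeats(reps)
  expect_equal(one$t_dry, 32)
  expect_equal(one$tympanic, 37.6)
  expect_equal(one$heart_rate, 140)
  expect_null(one$time)
  # single repeat: identity under both rules
  single <- aggregate_repeats(reps[2, ])
  expect_equal(single$t_dry, 32)
  expect_equal(single$tympanic, 37.6)
  expect_error(aggregate_repeats(reps[0, ]), "no repeats")
})

test_that("long-format cohorts aggregate by subject", {
  reps <- expand.grid(subject_id = c("a", "b"), time = c(30, 60, 90),
                      stringsAsFactors = FALSE)
  reps$t_dry <- ifelse(reps$subject_id == "a", 30, 40) + reps$time / 90
  reps$tympanic <- ifelse(reps$subject_id == "a", 37, 38) + reps$time / 900
  out <- aggregate_cohort(reps)
  expect_equal(nrow(out), 2)
  a <- out[out$subject_id == "a", ]
  expect_equal(a$t_dry, 30 + mean(c(30, 60, 90)) / 90)
  expect_equal(a$tympanic, 37 + 0.1)
  expect_error(aggregate_cohort(reps, by = "worker"), "worker")
})
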