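test_that("maneuver subtypes collapse to reversal vs curve, idempotently", {
  ev <- data.frame(
    maneuver = c("long_reversal", "short_reversal", "gradual_curve"),
    angle_deg = c(10, 20, 30), distance_mm = c(0, 0, 0)
  )
  out <- collapse_maneuvers(ev)
  expect_equal(out$maneuver, c("reversal", "reversal", "curve"))
  expect_equal(collapse_maneuvers(out), out) # idempotent
  empty <- ev[0, ]
  expect_equal(nrow(collapse_maneuvers(empty)), 0L)
  bad <- data.frame(maneuver = c("curve", "pirouette"), angle_deg = 1:2,
    distance_mm = 0)
  expect_error(collapse_maneuvers(bad), "pirouette")
  expect_error(collapse_maneuvers(bad), "row")
})

test_that("only the first event of a serial avoidance run is kept", {
  ev <- data.frame(
    maneuver = "curve", angle_deg = 10, distance_mm = 0,
    sequence_index = c(1, 2, 3, 1, 2)
  )
  out <- first_occurrence_filter(ev)
  expect_equal(rownames(out), c("1", "4"))
  all_first <- data.frame(maneuver = "curve", angle_deg = 1,
    distance_mm = 0, sequence_index = c(1, 1))
  expect_equal(first_occurrence_filter(all_first), all_first)
  expect_equal(nrow(first_occurrence_filter(ev[0, ])), 0L)
  expect_equal(
    first_occurrence_filter(first_occurrence_filter(ev)),
    first_occurrence_filter(ev)
  ) # idempotent
  expect_error(first_occurrence_filter(demo_events()), "sequence_index")
})

test_that("choice ratios are binned every 10 degrees with count conservation", {
  # perfectly linear ratios across bins -> r = 1
  mids <- seq(5, 85, by = 10)
  ev <- do.call(rbind, lapply(seq_along(mids), function(i) {
    n_rev <- 2 * i # ratio i/10 of 20 events per bin
    data.frame(
      maneuver = rep(c("reversal", "curve"), c(n_rev, 20 - n_rev)),
      angle_deg = mids[i], distance_mm = 0
    )
  }))
  cs <- bin_choice_ratio(ev, min_count = 15)
  expect_equal(cs$pearson_r, 1.0)
  expect_lt(cs$p_value, 0.01)
  expect_equal(sum(cs$bins$n), nrow(ev)) # counts conserved
  expect_equal(cs$bins$reversal_ratio, seq(0.1, 0.9, by = 0.1))

  # hand count: 20 reversals at 85, 20 curves at 5, nothing else
  ev2 <- data.frame(
    maneuver = rep(c("reversal", "curve"), each = 20),
    angle_deg = rep(c(85, 5), each = 20), distance_mm = 0
  )
  cs2 <- suppressWarnings(bin_choice_ratio(ev2, min_count = 15))
  expect_equal(cs2$bins$reversal_ratio[1], 0.0)
  expect_equal(cs2$bins$reversal_ratio[9], 1.0)
  expect_true(all(cs2$bins$flagged[2:8]))
  expect_false(any(cs2$bins$flagged[c(1, 9)]))
  # only 2 unflagged bins: correlation undefined, with a warning
  expect_warning(bin_choice_ratio(ev2, min_count = 15), "correlation")
  expect_true(is.na(cs2$pearson_r))
})

test_that("bin edges are half-open with the last bin closed at 90", {
  ev <- data.frame(
    maneuver = c("reversal", "curve", "reversal"),
    angle_deg = c(10, 9.999, 90), distance_mm = 0
  )
  cs <- suppressWarnings(bin_choice_ratio(ev, min_count = 1))
  expect_equal(cs$bins$n[1], 1L) # 9.999 in [0, 10)
  expect_equal(cs$bins$n[2], 1L) # 10 in [10, 20)
  expect_equal(cs$bins$n[9], 1L) # 90 in the closed last bin
  expect_error(
    bin_choice_ratio(data.frame(
      maneuver = "curve", angle_deg = 120, distance_mm = 0
    )),
    "\\[0, 90\\]"
  )
  expect_error(
    bin_choice_ratio(data.frame(
      maneuver = "gradual_curve", angle_deg = 10, distance_mm = 0
    )),
    "collapse"
  )
})

test_that("distance summaries report aligned histograms, mean, SD, quartiles", {
  ev <- data.frame(
    maneuver = "curve", angle_deg = 10, distance_mm = c(0.1, 0.3)
  )
  ds <- distance_summary(ev)
  expect_equal(ds$curve$n, 2L)
  expect_equal(ds$curve$mean, 0.2)
  expect_equal(ds$curve$sd, sqrt(0.02)) # ~0.1414, n - 1 denominator
  expect_equal(ds$curve$histogram$lo, c(0.0, 0.2)) # two adjacent 0.2 mm bins
  expect_equal(ds$curve$histogram$count, c(1L, 1L))
  expect_equal(sum(ds$curve$histogram$count), ds$curve$n)
  # absent class and degenerate single event
  expect_equal(ds$reversal$n, 0L)
  expect_true(is.na(ds$reversal$mean))
  one <- distance_summary(data.frame(
    maneuver = "reversal", angle_deg = 1, distance_mm = 0.5
  ))
  expect_equal(one$reversal$n, 1L)
  expect_true(is.na(one$reversal$sd))
})

test_that("distance summaries agree with a naive two-pass oracle", {
  set.seed(99)
  ev <- data.frame(
    maneuver = sample(c("curve", "reversal"), 500, replace = TRUE),
    angle_deg = runif(500, 0, 90),
    distance_mm = rnorm(500, -0.5, 0.8)
  )
  ds <- distance_summary(ev)
  for (cls in c("curve", "reversal")) {
    d <- ev$distance_mm[ev$maneuver == cls]
    # two-pass oracle: accumulate the sum, then squared deviations
    s <- 0
    for (v in d) s <- s + v
    mu <- s / length(d)
    ss <- 0
    for (v in d) ss <- ss + (v - mu)^2
    sd_oracle <- sqrt(ss / (length(d) - 1))
    expect_equal(ds[[cls]]$mean, mu, tolerance = 1e-12)
    expect_equal(ds[[cls]]$sd, sd_oracle, tolerance = 1e-12)
    expect_equal(sum(ds[[cls]]$histogram$count), length(d))
  }
})

test_that("Pearson r is affine-invariant and bounded", {
  set.seed(3)
  ev <- generate_event_table(synthetic_event_model(400), seed = 3)
  cs <- suppressWarnings(bin_choice_ratio(ev, min_count = 5))
  expect_lte(abs(cs$pearson_r), 1)
  b <- cs$bins[!cs$bins$flagged, ]
  r_scaled <- cor(10 + 2 * b$mid, 3 - 0 * b$reversal_ratio + 5 * b$reversal_ratio)
  expect_equal(r_scaled, cs$pearson_r, tolerance = 1e-12)
})

test_that("the F test compares variances two-sidedly", {
  a <- c(1, 2, 3, 4, 5)
  fv <- compare_variances(a, a)
  expect_equal(fv$F, 1)
  expect_equal(fv$p_value, 1)
  # variance exactly 4x: F = 4 regardless of argument order
  set.seed(12)
  b <- rnorm(50)
  fv4 <- compare_variances(2 * b, b)
  expect_equal(fv4$F, 4, tolerance = 1e-12)
  expect_lt(fv4$p_value, 0.01)
  expect_equal(compare_variances(b, 2 * b)$F, fv4$F)
  expect_error(compare_variances(1, b), "at least 2")
})

test_that("Student's t uses pooled variance and is two-sided", {
  a <- c(1, 2, 3)
  tt <- compare_means(a, a)
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)
  # exact construction: mean 0 vs 1, SD 1, n = 100 -> |t| = 1/sqrt(2/100)
  set.seed(13)
  x <- as.numeric(scale(rnorm(100)))
  y <- x + 1
  tt2 <- compare_means(x, y)
  expect_equal(abs(tt2$t), sqrt(100 / 2), tolerance = 1e-9)
  expect_equal(tt2$df, 198)
  expect_lt(tt2$p_value, 1e-9)
  # permutation invariance of the mean
  expect_equal(compare_means(x, sample(x))$t, 0, tolerance = 1e-12)
  expect_error(compare_means(a, 1), "at least 2")
})

test_that("step-capped simulator rows are excluded from statistics by default", {
  ev <- data.frame(
    maneuver = c("curve", NA, "reversal"),
    angle_deg = c(10, 50, 80),
    distance_mm = c(-0.5, -3, 0.2),
    terminated = c("escaped", "step_cap", "escaped")
  )
  cs <- suppressWarnings(bin_choice_ratio(ev, min_count = 1))
  expect_equal(cs$n_events, 2L)
  ds <- distance_summary(ev)
  expect_equal(ds$curve$n + ds$reversal$n, 2L)
})
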