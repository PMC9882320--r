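test_that("whole-residence, split, and partner-free cases partition correctly", {
  ## partner precedes target: entire residence is ternary
  r1 <- classify_ternary(data.frame(spot_id = 1, onset = 100, end = 300),
                         data.frame(spot_id = 1, onset = 0, end = 500))
  expect_equal(r1$ternary_time, 200)
  expect_equal(r1$nonternary_time, 0)
  expect_equal(r1$event_pool, "ternary")
  ## partner arrives mid-residence: head is non-ternary, tail ternary
  r2 <- classify_ternary(data.frame(spot_id = 1, onset = 100, end = 300),
                         data.frame(spot_id = 1, onset = 200, end = 260),
                         simultaneity_tol = 5)
  expect_equal(r2$nonternary_time, 100)
  expect_equal(r2$ternary_time, 100)    # tail counted past partner departure
  expect_equal(r2$event_pool, "ternary")
  expect_equal(r2$first_overlap, 200)
  ## no partner at all
  r3 <- classify_ternary(data.frame(spot_id = 1, onset = 100, end = 300),
                         data.frame(spot_id = integer(0), onset = numeric(0),
                                    end = numeric(0)))
  expect_false(r3$ternary)
  expect_equal(r3$nonternary_time, 200)
  expect_equal(r3$event_pool, "nonternary")
})

test_that("simultaneity tolerance admits near-simultaneous partner arrival", {
  ## partner 3 s after target onset, within the 5-s tolerance: whole-residence
  r <- classify_ternary(data.frame(spot_id = 1, onset = 100, end = 300),
                        data.frame(spot_id = 1, onset = 103, end = 400))
  expect_equal(r$ternary_time, 200)
  ## beyond the tolerance: split
  r2 <- classify_ternary(data.frame(spot_id = 1, onset = 100, end = 300),
                         data.frame(spot_id = 1, onset = 106, end = 400))
  expect_equal(r2$nonternary_time, 6)
})

test_that("censored residences contribute time but no event", {
  r <- classify_ternary(
    data.frame(spot_id = 1:2, onset = c(0, 0), end = c(100, 100),
               censored = c(TRUE, FALSE)),
    data.frame(spot_id = 1:2, onset = c(0, 0), end = c(100, 100)))
  expect_equal(r$event_pool, c("censored", "ternary"))
  rates <- estimate_off_rates(r)
  expect_equal(rates$kt$n_events, 1)
  expect_equal(rates$kt$total_time, 200)
})

test_that("pool accounting closes exactly", {
  set.seed(1)
  for (i in 1:50) {
    ps <- random_pulse_set()
    if (!nrow(ps$target)) next
    r <- classify_ternary(ps$target, ps$partner)
    expect_equal(r$ternary_time + r$nonternary_time, r$duration)
  }
})

test_that("classification matches the exhaustive grid oracle exactly", {
  set.seed(2)
  for (i in 1:200) {
    ps <- random_pulse_set()
    if (!nrow(ps$target)) next
    got <- classify_ternary(ps$target, ps$partner, simultaneity_tol = 5)
    want <- oracle_classify(ps$target, ps$partner, tol = 5)
    expect_equal(got$ternary_time, want$ternary_time)
    expect_equal(got$nonternary_time, want$nonternary_time)
    expect_equal(got$first_overlap, want$first_overlap)
  }
})

test_that("overlapping target pulses on one spot are rejected", {
  expect_error(classify_ternary(
    data.frame(spot_id = c(1, 1), onset = c(0, 50), end = c(100, 150)),
    data.frame(spot_id = 1, onset = 0, end = 10)), "overlapping")
})

test_that("off-rate formulas reproduce a hand-computed example", {
  recs <- data.frame(
    spot_id = 1:5,
    onset = 0, end = 1,
    duration = c(100, 200, 300, 50, 50),
    censored = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    ternary = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    first_overlap = c(0, 0, 0, NA, NA),
    ternary_time = c(100, 200, 300, 0, 0),
    nonternary_time = c(0, 0, 0, 50, 50),
    overlap_time = 0,
    event_pool = c("ternary", "ternary", "censored", "nonternary", "censored"))
  r <- estimate_off_rates(recs)
  expect_equal(r$kt$k, 2 / (600 / 3600))    # 12 / hr
  expect_equal(r$kn$k, 1 / (100 / 3600))    # 36 / hr
  expect_equal(r$kt$se, r$kt$k / sqrt(2))
})

test_that("a single never-ternary residence gives kn = 1/hr, kt undefined", {
  r <- classify_ternary(data.frame(spot_id = 1, onset = 0, end = 3600),
                        data.frame(spot_id = integer(0), onset = numeric(0),
                                   end = numeric(0)))
  est <- estimate_off_rates(r)
  expect_equal(est$kn$k, 1)
  expect_false(est$kt$defined)
  expect_true(is.na(est$kt$k))
})

test_that("off-rate recovery from simulated uncoupled kinetics", {
  ## coupling 1: both pools should recover k_off within 2 standard errors
  p <- kinetic_params(k_on_A = 1.4, k_off_A = 25, coupling_factor = 1)
  gt <- simulate_pulse_trains(p, 1000, seed = 5)
  tg <- subset(gt$pulses, channel == "target")
  tg$censored <- tg$truncated
  recs <- classify_ternary(tg, subset(gt$pulses, channel == "partner"))
  est <- estimate_off_rates(recs)
  expect_lt(abs(est$kt$k - 25), 2 * est$kt$se)
  expect_lt(abs(est$kn$k - 25), 2 * est$kn$se)
})

test_that("arrival order classification follows the 5-s convention", {
  recs <- classify_ternary(
    data.frame(spot_id = 1:3, onset = c(103, 150, 100),
               end = c(300, 400, 300)),
    data.frame(spot_id = 1:3, onset = c(100, 100, 120),
               end = c(400, 400, 400)))
  ao <- arrival_order(recs, simultaneity_tol = 5)
  expect_equal(ao$n_ternary, 3L)
  expect_equal(ao$n_simultaneous, 1L)     # |103 - 100| <= 5
  expect_equal(ao$partner_first, 0.5)     # among the 2 non-simultaneous
  expect_equal(ao$target_first, 0.5)
  ## all simultaneous
  recs2 <- classify_ternary(
    data.frame(spot_id = 1:2, onset = c(100, 200), end = c(300, 400)),
    data.frame(spot_id = 1:2, onset = c(100, 202), end = c(400, 500)))
  expect_equal(arrival_order(recs2)$simultaneous, 1)
})

test_that("residence summaries compute counts, fractions and co-occupancy", {
  pulses <- data.frame(duration = c(60, 100, 400), censored = FALSE)
  s <- residence_summaries(pulses, n_spots = 3)
  expect_equal(s$fraction_short, 2 / 3)
  expect_equal(s$fraction_long, 1 / 3)
  expect_equal(residence_summaries(
    data.frame(duration = rep(100, 1049), censored = FALSE),
    n_spots = 1000)$mean_residences_per_spot, 1.049)
  expect_error(residence_summaries(pulses, n_spots = 0), "n_spots")
  ## exponential tail: fraction of dwells beyond 300 s at k = 25/hr
  p <- kinetic_params(k_on_A = 20, k_off_A = 25, k_on_B = 0,
                      duration = 36000)
  gt <- simulate_pulse_trains(p, 30, seed = 6)
  tg <- subset(gt$pulses, channel == "target" & !truncated)
  tg$duration <- tg$end - tg$onset
  tg$censored <- FALSE
  s2 <- residence_summaries(tg, n_spots = 30)
  p_long <- exp(-25 * 300 / 3600)
  se <- sqrt(p_long * (1 - p_long) / nrow(tg))
  expect_lt(abs(s2$fraction_long - p_long), 2 * se)
})

test_that("coupled kinetics drop the ternary off-rate below the non-ternary one", {
  ## pooled over three simulated fields (~3000 residences) so the ratio test
  ## reflects the coupling rather than single-field sampling noise
  p <- kinetic_params(coupling_factor = 0.5)
  recs <- do.call(rbind, lapply(8:10, function(s) {
    gt <- simulate_pulse_trains(p, 1000, seed = s)
    tg <- subset(gt$pulses, channel == "target")
    tg$censored <- tg$truncated
    classify_ternary(tg, subset(gt$pulses, channel == "partner"))
  }))
  est <- estimate_off_rates(recs)
  expect_lt(est$kt$k, est$kn$k)
  expect_gt(est$kt$k / est$kn$k, 0.4)
  expect_lt(est$kt$k / est$kn$k, 0.65)
})
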