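test_that("heart periods are first differences attached to the ending beat", {
  expect_equal(compute_hp(c(0, 1, 2))$hp, c(NA, 1, 1))
  expect_equal(compute_hp(c(0, 0.8, 1.7))$hp, c(NA, 0.8, 0.9))
  expect_error(compute_hp(c(1, 0.5)), "increasing")
  expect_error(compute_hp(1.0), "two events")
})

test_that("beat detection recovers synthetic pulse trains to sub-sample accuracy", {
  centers <- 1:60
  ev0 <- event_series(centers)
  x <- synth_ppg(ev0, fs = 400, pulse_width = 0.05)
  ev <- detect_beats(x, fs = 400)
  expect_equal(length(ev$u), 60)
  expect_lt(max(abs(ev$u - centers)), 1 / 400)

  # 75 bpm spacing
  ev2 <- detect_beats(synth_ppg(event_series(seq(0.5, by = 0.8,
                                                 length.out = 50)),
                                fs = 400), fs = 400)
  expect_equal(mean(ev2$hp, na.rm = TRUE), 0.8, tolerance = 2.5e-3 / 0.8)
})

test_that("beat detection rejects flat and too-short signals", {
  expect_error(detect_beats(rep(1, 4000), fs = 400), "no pulse peaks")
  expect_error(detect_beats(rnorm(100), fs = 400), "too short")
  expect_error(detect_beats(rnorm(4000), fs = 400, min_rate = 10),
               "min_rate")
})

test_that("artifact correction merges spurious beats and splits missed ones", {
  # extra event at 10.5 splits one 1-s interval into two 0.5-s ones
  ev_extra <- regular_events(n = 30, extra_at = 10.5)
  fixed <- correct_artifacts(ev_extra)
  expect_equal(length(fixed$u), 30)
  expect_lt(max(abs(fixed$hp[-1] - 1)), 1e-9)
  expect_true("corrected" %in% fixed$flags)

  # deleting the event at 10 s leaves a 2-s gap that gets one insertion
  ev_miss <- regular_events(n = 30, drop_at = 10)
  fixed2 <- correct_artifacts(ev_miss)
  expect_lt(max(fixed2$hp, na.rm = TRUE), 1.3)
  expect_true("interpolated" %in% fixed2$flags)
  expect_equal(sum(fixed2$flags == "interpolated"), 1)

  # clean input is untouched
  clean <- regular_events(n = 30)
  out <- correct_artifacts(clean)
  expect_identical(out$u, clean$u)
  expect_true(all(out$flags == "original"))

  expect_error(correct_artifacts(regular_events(n = 8)), "11 beats")
})

test_that("artifact correction is idempotent and span-preserving on random inputs", {
  set.seed(9)
  for (rep in 1:5) {
    hp <- runif(60, 0.7, 1.0)
    u <- cumsum(c(0, hp))
    # corrupt: one doubled gap and one split beat
    u <- setdiff(u, u[20])
    u <- sort(c(u, u[40] + 0.3 * hp[40]))
    ev <- event_series(u)
    once <- correct_artifacts(ev)
    twice <- correct_artifacts(once)
    expect_equal(twice$u, once$u, tolerance = 1e-12)
    # event-series invariants
    expect_true(all(diff(once$u) > 0))
    expect_true(all(once$hp[-1] > 0))
    # total span preserved within one local median
    expect_lt(abs((max(once$u) - min(once$u)) - (max(u) - min(u))),
              median(diff(u)) + 1e-9)
  }
})
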