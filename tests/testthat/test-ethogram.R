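ev_row <- function(behaviour, start, end, idx = NA_integer_) {
  data.frame(behaviour = behaviour, start_s = start, end_s = end,
             repeat_index = idx)
}

test_that("bout classification applies the 3-second / three-repetition rules", {
  # bar-mouthing must last at least 3 s
  expect_equal(nrow(classify_stereotypic(ev_row("bar_mouthing", 0, 2.5))), 0)
  b <- classify_stereotypic(ev_row("bar_mouthing", 0, 3))
  expect_equal(nrow(b), 1)
  expect_equal(b$end_s - b$start_s, 3)

  # three back-flips with 2-s gaps merge into one bout
  flips <- ev_row("back_flipping", c(0, 3, 6), c(1, 4, 7), 1:3)
  b <- classify_stereotypic(flips)
  expect_equal(nrow(b), 1)
  expect_equal(b$start_s, 0)
  expect_equal(b$end_s, 7)
  expect_equal(b$n_reps, 3)

  # two twirls, a 4-s pause, two twirls: neither run reaches three
  tw <- ev_row("cage_top_twirling", c(0, 1.5, 7, 8.5), c(1, 2.5, 8, 9.5), 1:4)
  expect_equal(nrow(classify_stereotypic(tw)), 0)

  # a pause of exactly 3 s keeps the run; strictly more breaks it
  keep <- ev_row("circling", c(0, 4, 8), c(1, 5, 9))
  expect_equal(nrow(classify_stereotypic(keep)), 1)
  broken <- ev_row("circling", c(0, 4.01, 8.02), c(1, 5.01, 9.02))
  expect_equal(nrow(classify_stereotypic(broken)), 0)

  expect_error(classify_stereotypic(ev_row("grooming", 0, 5)),
               "unknown behaviour")
})

test_that("bout classification is idempotent on its own output spans", {
  ev <- rbind(ev_row("bar_mouthing", 10, 20),
              ev_row("back_flipping", c(30, 32, 34), c(31, 33, 35), 1:3))
  bouts <- classify_stereotypic(ev)
  again <- classify_stereotypic(bouts)
  expect_equal(again, bouts)
})

test_that("the default observation scheme yields 480 intervals", {
  sc <- observation_scheme()
  expect_equal(sc$n_intervals, 480)
  expect_equal(nrow(sc$intervals), 480)
  # 2 days x 4 blocks x 60 intervals of 15 s
  expect_equal(sc$block_length_s / sc$interval_s, 60)
  expect_error(observation_scheme(interval_s = 14), "divide")
  expect_error(observation_scheme(block_starts_s = c(0, 100)), "overlap")
})

test_that("one-zero sampling flags intervals touched by qualifying bouts", {
  sc <- observation_scheme()
  t0 <- sc$intervals$start_s[1]
  # a 30-s bar-mouthing bout at a block start flags exactly two intervals
  ev <- ev_row("bar_mouthing", t0, t0 + 30)
  m <- one_zero_sample(ev, sc)
  expect_equal(sum(m$bar_mouthing), 2)
  expect_equal(which(m$bar_mouthing == 1), 1:2)
  # ... and those intervals are active
  expect_true(all(m$active[1:2] == 1))

  # empty stream: everything inactive
  m0 <- one_zero_sample(ev_row("active", 0, 0)[0, ], sc)
  expect_true(all(m0$inactive == 1))
  expect_equal(sum(m0$active), 0)

  # boundary: a bout starting exactly at an interval boundary belongs to the
  # later interval (half-open intervals)
  t1 <- sc$intervals$start_s[2]
  mb <- one_zero_sample(ev_row("bar_mouthing", t1, t1 + 3), sc)
  expect_equal(which(mb$bar_mouthing == 1), 2)
})

test_that("brief twitches do not break inactivity; longer movement does", {
  sc <- observation_scheme()
  t0 <- sc$intervals$start_s[1]
  twitch <- ev_row("active", t0 + 1, t0 + 5)      # 4 s <= 5 s
  m <- one_zero_sample(twitch, sc)
  expect_equal(m$active[1], 0L)
  move <- ev_row("active", t0 + 1, t0 + 7)        # 6 s > 5 s
  m2 <- one_zero_sample(move, sc)
  expect_equal(m2$active[1], 1L)
})

test_that("events outside all observation blocks are ignored but counted", {
  sc <- observation_scheme()
  ev <- ev_row("active", 0, 10)  # before the first block at 3600 s
  m <- one_zero_sample(ev, sc)
  expect_equal(sum(m$active), 0)
  expect_equal(attr(m, "n_events_outside"), 1L)
})

test_that("one-zero sampling is monotone in the event stream", {
  sc <- observation_scheme()
  set.seed(71)
  base <- simulate_ethogram(etho_profile(
    levels = c(bar_mouthing = 0.1, circling = 0.05), activity = 0.5), sc)
  extra <- rbind(base,
                 ev_row("bar_mouthing", sc$intervals$start_s[10] + 1,
                        sc$intervals$start_s[10] + 6))
  m1 <- one_zero_sample(base, sc)
  m2 <- one_zero_sample(extra, sc)
  for (col in c("bar_mouthing", "circling", "active"))
    expect_true(all(m2[[col]] >= m1[[col]]))
})

test_that("stereotypy levels are proportions of active intervals with union semantics", {
  sc <- observation_scheme()
  starts <- sc$intervals$start_s
  # 200 active intervals, the first 50 flagged for bar-mouthing
  ev <- do.call(rbind, c(
    lapply(starts[1:200], function(t) ev_row("active", t, t + 15)),
    lapply(starts[1:50], function(t) ev_row("bar_mouthing", t + 1, t + 6))))
  m <- one_zero_sample(ev, sc)
  expect_equal(sum(m$active), 200)
  expect_equal(stereotypy_level(m, "bar_mouthing"), 0.25)
  expect_equal(stereotypy_level(m, "circling"), 0)

  # intervals flagged for two forms count once in "all"
  ev2 <- rbind(ev, do.call(rbind, lapply(starts[1:50], function(t)
    ev_row("circling", t + c(7, 9, 11), t + c(8, 10, 12), 1:3))))
  m2 <- one_zero_sample(ev2, sc)
  expect_equal(stereotypy_level(m2, "circling"), 0.25)
  expect_equal(stereotypy_level(m2, "all"), 0.25)  # same 50 intervals

  # degenerate: no active intervals
  m0 <- one_zero_sample(ev_row("active", 0, 1)[0, ], sc)
  expect_warning(lv <- stereotypy_level(m0), "undefined")
  expect_true(is.na(lv))
})

test_that("per-form levels never exceed the overall level, which is at most 1", {
  sc <- observation_scheme()
  set.seed(81)
  for (i in 1:5) {
    ev <- simulate_ethogram(etho_profile(
      levels = c(bar_mouthing = runif(1, 0, 0.4),
                 back_flipping = runif(1, 0, 0.4),
                 route_tracing = runif(1, 0, 0.2)),
      activity = runif(1, 0.3, 0.9)), sc)
    m <- one_zero_sample(ev, sc)
    all_lv <- stereotypy_level(m, "all")
    expect_lte(all_lv, 1)
    for (f in c("bar_mouthing", "back_flipping", "route_tracing"))
      expect_lte(stereotypy_level(m, f), all_lv)
  }
})

test_that("ethogram_levels reports levels with their square-root transforms", {
  sc <- observation_scheme()
  set.seed(91)
  ev <- simulate_ethogram(etho_profile(levels = c(bar_mouthing = 0.2)), sc)
  out <- ethogram_levels(one_zero_sample(ev, sc), "m7")
  expect_equal(out$subject_id, "m7")
  expect_equal(out$n_intervals, 480)
  expect_equal(out$sqrt_level_bar_mouthing, sqrt(out$level_bar_mouthing))
  expect_equal(out$level_all, out$level_bar_mouthing)
})
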