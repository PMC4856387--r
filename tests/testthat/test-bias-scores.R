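make_log <- function(times, duration = 600) {
  # times: named seconds per role; one visit per role, laid end to end
  roles <- default_role_map()
  arm_for <- function(r) as.integer(names(roles)[roles == r][1])
  v <- data.frame(arm_id = integer(0), entry_s = numeric(0),
                  exit_s = numeric(0))
  t <- 0
  for (r in names(times)) {
    v <- rbind(v, data.frame(arm_id = arm_for(r), entry_s = t,
                             exit_s = t + times[[r]]))
    t <- t + times[[r]]
  }
  arm_visit_log("m1", v, duration_s = duration)
}

test_that("time_in_roles sums visit time by role and assigns the rest to centre", {
  roles <- default_role_map()
  log <- make_log(c(positive = 30))
  tt <- time_in_roles(log, roles)
  expect_equal(tt[["positive"]], 30)
  expect_equal(tt[["negative"]], 0)
  expect_equal(tt[["centre"]], 570)

  none <- arm_visit_log("m1", data.frame(arm_id = integer(0),
                                         entry_s = numeric(0),
                                         exit_s = numeric(0)))
  tt0 <- time_in_roles(none, roles)
  expect_true(all(tt0[setdiff(names(tt0), "centre")] == 0))
  expect_equal(tt0[["centre"]], 600)

  # conservation: role time + centre = session duration
  log2 <- make_log(c(positive = 100, negative = 50, near_positive = 120,
                     near_negative = 150))
  expect_equal(sum(time_in_roles(log2, roles)), 600)
})

test_that("visits to closed or unmapped arms are rejected", {
  roles <- arm_role_map(c(`1` = "positive", `2` = "positive",
                          `3` = "closed", `4` = "closed",
                          `5` = "negative", `6` = "negative",
                          `7` = "closed", `8` = "closed"))
  log <- arm_visit_log("m1", data.frame(arm_id = 3, entry_s = 0, exit_s = 10))
  expect_error(time_in_roles(log, roles), "closed")
  log9 <- arm_visit_log("m1", data.frame(arm_id = 9, entry_s = 0, exit_s = 10))
  expect_error(time_in_roles(log9, roles), "no assigned role")
})

test_that("the three bias scores implement their defining ratios", {
  roles <- default_role_map()
  expect_equal(positive_arm_score(make_log(c(positive = 300, negative = 100)),
                                  roles), 0.5)
  expect_equal(positive_arm_score(make_log(c(positive = 80, negative = 80)),
                                  roles), 0)
  expect_equal(positive_arm_score(make_log(c(positive = 50)), roles), 1)

  expect_equal(reference_arm_score(
    make_log(c(positive = 100, negative = 100)), roles), 1)
  expect_equal(reference_arm_score(
    make_log(c(positive = 100, negative = 50, near_positive = 75,
               near_negative = 75)), roles), 0)
  expect_equal(reference_arm_score(
    make_log(c(positive = 100, negative = 50, near_positive = 200,
               near_negative = 250)), roles), -0.5)

  expect_equal(ambiguous_arm_score(
    make_log(c(near_positive = 120, near_negative = 40)), roles), 0.5)
  expect_equal(ambiguous_arm_score(
    make_log(c(near_positive = 60, near_negative = 60)), roles), 0)
  expect_equal(ambiguous_arm_score(
    make_log(c(near_positive = 60)), roles), 1)
})

test_that("zero-denominator scores are missing, never zero", {
  roles <- default_role_map()
  amb_only <- make_log(c(near_positive = 60, near_negative = 60))
  expect_warning(res <- positive_arm_score(amb_only, roles), "undefined")
  expect_true(is.na(res))
  ref_only <- make_log(c(positive = 100))
  expect_warning(res2 <- ambiguous_arm_score(ref_only, roles), "undefined")
  expect_true(is.na(res2))
  empty <- arm_visit_log("m1", data.frame(arm_id = integer(0),
                                          entry_s = numeric(0),
                                          exit_s = numeric(0)))
  expect_warning(res3 <- reference_arm_score(empty, roles), "undefined")
  expect_true(is.na(res3))
})

test_that("scores are antisymmetric under swapping the paired roles", {
  roles <- default_role_map()
  swap <- function(x, a, b) {
    y <- x
    names(y)[names(y) == a] <- "tmp"
    names(y)[names(y) == b] <- a
    names(y)[names(y) == "tmp"] <- b
    y
  }
  set.seed(61)
  for (i in 1:10) {
    tms <- setNames(runif(4, 10, 150),
                    c("positive", "negative", "near_positive",
                      "near_negative"))
    log <- make_log(tms)
    expect_equal(positive_arm_score(make_log(swap(tms, "positive",
                                                  "negative")), roles),
                 -positive_arm_score(log, roles))
    expect_equal(ambiguous_arm_score(make_log(swap(tms, "near_positive",
                                                   "near_negative")), roles),
                 -ambiguous_arm_score(log, roles))
    # reference score flips when reference and ambiguous budgets swap
    swapped <- swap(swap(tms, "positive", "near_positive"),
                    "negative", "near_negative")
    expect_equal(reference_arm_score(make_log(swapped), roles),
                 -reference_arm_score(log, roles))
  }
})

test_that("scores are invariant to uniform time rescaling", {
  roles <- default_role_map()
  tms <- c(positive = 120, negative = 40, near_positive = 90,
           near_negative = 30)
  a <- make_log(tms, duration = 600)
  b <- make_log(tms / 2, duration = 300)
  for (f in list(positive_arm_score, reference_arm_score,
                 ambiguous_arm_score))
    expect_equal(f(a, roles), f(b, roles))
})

test_that("entry summaries count entries per role", {
  roles <- default_role_map()
  v <- data.frame(arm_id = c(1, 2, 1, 5, 7, 4, 1, 2, 8, 3),
                  entry_s = seq(0, 540, by = 60),
                  exit_s = seq(30, 570, by = 60))
  log <- arm_visit_log("m1", v)
  es <- entry_summary(log, roles)
  expect_equal(es$total_entries, 10)
  expect_equal(es$rel_entries[["positive"]], 0.5)  # arms 1, 2
  expect_equal(sum(es$rel_entries), 1)

  empty <- arm_visit_log("m1", data.frame(arm_id = integer(0),
                                          entry_s = numeric(0),
                                          exit_s = numeric(0)))
  es0 <- entry_summary(empty, roles)
  expect_equal(es0$total_entries, 0L)
  expect_true(all(is.na(es0$rel_entries)))
})

test_that("arm_visit_log validates time structure", {
  expect_error(arm_visit_log("m", data.frame(arm_id = 1, entry_s = 10,
                                             exit_s = 5)),
               "entry_s < exit_s")
  expect_error(arm_visit_log("m", data.frame(arm_id = c(1, 2),
                                             entry_s = c(0, 20),
                                             exit_s = c(30, 40))),
               "overlap")
  expect_error(arm_visit_log("m", data.frame(arm_id = 1, entry_s = 0,
                                             exit_s = 700)),
               "outside")
  # open visit at session end is truncated
  log <- arm_visit_log("m", data.frame(arm_id = 1, entry_s = 580,
                                       exit_s = NA))
  expect_equal(log$visits$exit_s, 600)
})
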