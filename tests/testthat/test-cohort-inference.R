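test_that("round assignment follows the quota counting rule", {
  log <- cohort_log(3, clutch_events(c(50, 52, 55, 80, 81, 83), rep(10, 6)))
  expect_equal(assign_rounds(log)$labels, c(1, 1, 1, 2, 2, 2))

  # a death before round 2 shrinks its quota; the leftover clutch opens a
  # partial third round
  log2 <- cohort_log(3, clutch_events(c(50, 52, 55, 80, 81, 90), rep(10, 6)),
                     death_days = 70)
  asg2 <- assign_rounds(log2)
  expect_equal(asg2$labels, c(1, 1, 1, 2, 2, 3))
  expect_equal(asg2$rounds$quota, c(3, 2, 2))
  expect_equal(asg2$rounds$complete, c(TRUE, TRUE, FALSE))

  # one animal: one clutch per round
  log3 <- cohort_log(1, clutch_events(c(40, 70, 95), rep(5, 3)))
  expect_equal(assign_rounds(log3)$labels, 1:3)

  empty <- assign_rounds(cohort_log(2))
  expect_length(empty$labels, 0)
  expect_equal(nrow(empty$rounds), 0)
})

test_that("round assignment matches brute-force execution on random logs", {
  set.seed(11)
  for (case in 1:200) {
    cs <- random_cohort_case()
    log <- cohort_log(cs$n0, clutch_events(cs$days, rep(1, length(cs$days))),
                      death_days = cs$death_days)
    asg <- assign_rounds(log)
    expect_equal(asg$labels,
                 oracle_assign_rounds(cs$n0, cs$death_days, cs$days))
    # quota law: every round but possibly the last is exactly full
    r <- asg$rounds
    if (nrow(r) > 1) expect_true(all(r$complete[-nrow(r)]))
    if (nrow(r) >= 1) expect_true(all(r$n <= r$quota))
    expect_true(all(diff(asg$labels) >= 0))
  }
})

test_that("round assignment is invariant to input row order", {
  set.seed(5)
  days <- sort(sample(0:150, 12, replace = TRUE))
  sizes <- sample(1:50, 12, replace = TRUE)
  log <- cohort_log(4, clutch_events(days, sizes), death_days = c(60, 120))
  perm <- sample(12)
  log_perm <- cohort_log(4, clutch_events(days[perm], sizes[perm]),
                         death_days = c(60, 120))
  expect_equal(assign_rounds(log_perm)$labels, assign_rounds(log)$labels)
})

test_that("round summaries carry Student-t confidence intervals", {
  log <- cohort_log(2, clutch_events(c(100, 102), c(10, 14)))
  rs <- round_summaries(assign_rounds(log), log)
  expect_equal(rs$day_mean, 101)
  expect_equal(rs$size_mean, 12)
  hw <- qt(0.975, df = 1) * sd(c(100, 102)) / sqrt(2)
  expect_equal(rs$day_hi - rs$day_mean, hw)
  expect_equal(rs$day_lo, 101 - hw)

  # singleton round: mean only
  log1 <- cohort_log(1, clutch_events(40, 7))
  rs1 <- round_summaries(assign_rounds(log1), log1)
  expect_true(is.na(rs1$day_lo) && is.na(rs1$size_hi))

  # identical values: zero-width interval at the mean
  log0 <- cohort_log(3, clutch_events(c(50, 50, 50), c(9, 9, 9)))
  rs0 <- round_summaries(assign_rounds(log0), log0)
  expect_equal(rs0$day_lo, rs0$day_hi)
  expect_equal(rs0$day_lo, 50)

  expect_error(round_summaries(assign_rounds(log0), log), "match")
})

test_that("pseudo-cohort pooling conserves events and keeps ground truth", {
  recs <- records_ab()
  log <- build_pseudo_cohort(recs)
  expect_equal(log$n0, 2L)
  expect_equal(nrow(log$clutches), 3)
  expect_equal(sum(log$clutches$size), 60)
  expect_equal(log$death_days, c(100L, 142L))
  truth <- attr(log, "truth")
  expect_equal(truth$day, log$clutches$day)
  expect_equal(truth$size, log$clutches$size)
  expect_equal(truth$clutch_index[truth$parent_id == "A"], 1:2)

  # same-day ties keep stable (per-record input) order
  tie <- list(rec("A", 50, 10, 90), rec("B", 50, 20, 90))
  tlog <- build_pseudo_cohort(tie)
  expect_equal(attr(tlog, "truth")$parent_id, c("A", "B"))
})

test_that("deposition histograms use half-open five-day bins", {
  log <- cohort_log(5, clutch_events(c(0, 4, 5, 9, 10), rep(1, 5)))
  h <- bin_depositions(log, 5)
  expect_equal(h$count, c(2, 2, 1))
  expect_equal(h$bin_start, c(0, 5, 10))
  expect_equal(sum(h$count), nrow(log$clutches))

  expect_equal(nrow(bin_depositions(cohort_log(1))), 0)
  h1 <- bin_depositions(log, 1)
  expect_equal(sum(h1$count), 5)
  expect_equal(h1$count[h1$bin_start == 4], 1)
  expect_error(bin_depositions(log, 0), "width")
})

test_that("cohort series apply the last-seen-alive convention", {
  log <- cohort_log(3, clutch_events(c(50, 80), c(10, 12)), death_days = 70)
  s <- cohort_series(log)
  expect_equal(s$alive[s$day == 70], 3L)
  expect_equal(s$alive[s$day == 71], 2L)
  expect_equal(s$cum_embryos[s$day == 49], 0L)
  expect_equal(s$cum_embryos[s$day == 50], 10L)
  expect_equal(s$cum_embryos[s$day == 80], 22L)
  expect_true(all(diff(s$alive) <= 0))
  expect_true(all(diff(s$cum_clutches) >= 0))

  flat <- cohort_series(cohort_log(2))
  expect_equal(flat$alive, 2L)
  expect_equal(flat$cum_embryos, 0L)
})
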