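test_that("dist_spec validates inputs and draws stay within bounds", {
  expect_error(dist_spec(10, -1), "sd")
  expect_error(dist_spec(10, 1, min = 20, max = 30), "mean")
  expect_error(dist_spec(10, 1, min = 5, max = 2), "min > max")

  specs <- list(dist_spec(56.3, 8.7, 37, 68),
                dist_spec(20, 30, 1, 50),
                dist_spec(5, 2, min = 1),
                dist_spec(100, 10))
  for (spec in specs) for (law in c("calibrated", "clamp", "reject")) {
    set.seed(99)
    x <- draw_dist(spec, 500, law = law)
    expect_true(all(x >= spec$min & x <= spec$max))
  }
  # degenerate sd: point mass at the mean
  expect_equal(draw_dist(dist_spec(7), 3), rep(7, 3))
})

test_that("calibrated sampling reproduces the stated moments inside bounds", {
  # asymmetric bounds: plain truncation would shift the mean; the
  # calibrated law restores it
  spec <- dist_spec(140, 25.8, 120, 180)
  set.seed(3)
  x <- draw_dist(spec, 5e4)
  expect_equal(mean(x), 140, tolerance = 0.005)
  expect_equal(sd(x), 25.8, tolerance = 0.02)
  set.seed(3)
  xr <- draw_dist(spec, 5e4, law = "reject")
  expect_gt(mean(xr), 144)  # the bias the calibration removes
})

test_that("point-mass parameters simulate a fully deterministic record", {
  p <- point_mass_params()
  set.seed(1)
  r <- simulate_individual(p)
  expect_equal(r$clutches$day, c(56L, 84L, 112L))
  expect_equal(r$clutches$size, c(20L, 50L, 70L))
  expect_equal(r$death_day, 142L)
})

test_that("identical seeds give identical simulations, independent of n", {
  p <- make_params("hro_isolated")
  a <- simulate_cohort(p, 6, seed = 31)
  b <- simulate_cohort(p, 6, seed = 31)
  expect_equal(a$clutches, b$clutches)
  expect_equal(a$death_days, b$death_days)
  # per-individual substreams: the first 6 animals of a larger cohort are
  # the same animals
  c10 <- simulate_cohort(p, 10, seed = 31)
  recs6 <- attr(a, "records")
  recs10 <- attr(c10, "records")
  for (i in 1:6) expect_equal(recs10[[i]]$clutches, recs6[[i]]$clutches)

  s1 <- run_replicates(p, 4, runs = 3, seed = 17)
  s2 <- run_replicates(p, 4, runs = 3, seed = 17)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("pooled moments recover the generating means within 3 standard errors", {
  p <- make_params("hro_isolated")
  rr <- run_replicates(p, n = 16, runs = 100, seed = 7)
  zd <- as.data.frame(rr)[as.data.frame(rr)$metric == "zd_c1", ]
  expect_equal(zd$n, 1600)
  expect_lt(abs(zd$mean - 56.3), 3 * 8.7 / sqrt(1600))
  # truncation correctness across every drawn value
  pooled <- attr(rr, "pooled")
  expect_true(all(pooled$zd_c1 >= 37 & pooled$zd_c1 <= 68))
  expect_true(all(pooled$clutch_size_1 >= 1))
  expect_true(all(pooled$interval_all >= 1))
})

test_that("parameter estimation from records reproduces sample statistics", {
  est <- estimate_params_from_individuals(records_ab())
  expect_equal(est$zd_c1$mean, 55)
  expect_equal(est$zd_c1$sd, sd(c(50, 60)))
  expect_equal(est$zd_c1$min, 50)
  expect_equal(est$zd_c1$max, 60)
  expect_equal(est$inter_clutch[[1]]$mean, 30)
  expect_equal(unname(est$clutch_count), c(0, 0.5, 0.5))
  expect_equal(est$post_last_survival$mean, mean(c(62, 40)))
})

test_that("estimate -> simulate -> estimate is a fixed point for point masses", {
  p <- point_mass_params()
  recs <- lapply(1:4, function(i) simulate_individual(p, id = i))
  est <- estimate_params_from_individuals(recs)
  expect_equal(est$zd_c1$mean, p$zd_c1$mean)
  expect_equal(est$zd_c1$sd, 0)
  expect_equal(est$inter_clutch[[1]]$mean, 28)
  expect_equal(est$clutch_size[[3]]$mean, 70)
  expect_equal(unname(est$clutch_count["3"]), 1)
  expect_equal(est$post_last_survival$mean, 30)
})

test_that("cohort-based estimation agrees with the records behind a pseudo-cohort", {
  p <- point_mass_params()
  recs <- lapply(1:5, function(i) simulate_individual(p, id = i))
  log <- build_pseudo_cohort(recs)
  est <- estimate_params_from_cohort(log)
  expect_equal(est$zd_c1$mean, 56)
  expect_equal(est$inter_clutch[[1]]$mean, 28)
  expect_equal(est$clutch_size[[2]]$mean, 50)
  expect_equal(unname(est$clutch_count["3"]), 1)

  # single-round cohort: no interval specs, all mass on one clutch
  log1 <- cohort_log(3, clutch_events(c(40, 41, 42), c(5, 6, 7)))
  est1 <- estimate_params_from_cohort(log1)
  expect_length(est1$inter_clutch, 0)
  expect_equal(unname(est1$clutch_count["1"]), 1)
  expect_error(estimate_params_from_cohort(cohort_log(3)), "no clutches")
})

test_that("cohort estimation recovers generating parameters on separated rounds", {
  gen <- sim_params(zd_c1 = dist_spec(100, 4, 85, 115),
                    inter_clutch = list(dist_spec(60, 3, min = 1)),
                    clutch_size = list(dist_spec(30, 5, 10, 50),
                                       dist_spec(50, 5, 30, 70)),
                    clutch_count = c("2" = 1),
                    post_last_survival = dist_spec(40, 5, min = 0),
                    label = "separated")
  log <- simulate_cohort(gen, 40, seed = 13)
  est <- estimate_params_from_cohort(log)
  expect_lt(abs(est$zd_c1$mean - 100), 3 * 4 / sqrt(40))
  expect_lt(abs(est$inter_clutch[[1]]$mean - 60), 3)
  expect_lt(abs(est$clutch_size[[2]]$mean - 50), 3 * 5 / sqrt(40))
})

test_that("independent simulation accumulates day variance across rounds", {
  p <- make_params("hro_isolated")
  # day of the k-th clutch spreads with k (summed independent intervals):
  # the mechanism that cannot maintain tight within-round clustering
  recs <- attr(simulate_cohort(p, 300, seed = 29), "records")
  day1 <- vapply(recs, function(r) r$clutches$day[1], numeric(1))
  day3 <- vapply(recs, function(r)
    if (nrow(r$clutches) >= 3) r$clutches$day[3] else NA_real_, numeric(1))
  expect_gt(sd(day3, na.rm = TRUE), sd(day1))
})
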