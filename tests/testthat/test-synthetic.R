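test_that("presets reproduce the published summary blocks", {
  p <- make_params("hro_isolated")
  expect_equal(p$zd_c1[c("mean", "sd", "min", "max")],
               list(mean = 56.3, sd = 8.7, min = 37, max = 68))
  expect_equal(make_params("hoc_isolated")$zd_c1$mean, 140.0)
  expect_equal(make_params("hoc_isolated")$zd_c1$sd, 25.8)
  cs1 <- make_params("hau_cohort23")$clutch_size[[1]]
  expect_equal(cs1[c("mean", "sd", "min", "max")],
               list(mean = 94.2, sd = 41.0, min = 45, max = 179))
  expect_equal(sum(make_params("hro_cohort")$clutch_count), 1)
  expect_error(make_params("nope"), "hro_isolated")
  expect_setequal(clutch_presets(),
                  c("hro_isolated", "hro_cohort", "hau_cohort23",
                    "hau_cohort60", "hoc_isolated"))
})

test_that("generated datasets are deterministic and parse cleanly", {
  p <- make_params("hro_isolated")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds1 <- generate_dataset(p, 8, seed = 42, dir = d1)
  ds2 <- generate_dataset(p, 8, seed = 42, dir = d2)
  for (f in c("individuals.csv", "cohort.csv", "cohort.json", "truth.csv",
              "params.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  back <- read_individual_records(file.path(d1, "individuals.csv"))
  expect_equal(nrow(validate(back)), 0)
  log <- read_cohort_log(file.path(d1, "cohort.csv"))
  expect_equal(nrow(validate(log)), 0)
  expect_equal(nrow(log$clutches), nrow(ds1$truth))
  expect_equal(sum(log$clutches$size), sum(ds1$truth$size))
  p2 <- read_sim_params(file.path(d1, "params.json"))
  expect_equal(p2$zd_c1$mean, p$zd_c1$mean)
  expect_equal(p2$clutch_count, p$clutch_count)
})

test_that("with degenerate separation the inferred rounds equal the truth", {
  ds <- generate_dataset(point_mass_params(), 5, seed = 9)
  asg <- assign_rounds(ds$log)
  expect_equal(asg$labels, ds$truth$true_round)
  expect_equal(misassignment_rate(asg, ds$truth$true_round), 0)
})

test_that("generated records recover the preset parameters", {
  ds <- generate_dataset(make_params("hro_isolated"), 48, seed = 1)
  est <- estimate_params_from_individuals(ds$records)
  expect_lt(abs(est$zd_c1$mean - 56.3), 3 * 8.7 / sqrt(48))
  expect_lt(abs(est$clutch_size[[2]]$mean - 51.1), 3 * 16.3 / sqrt(40))
})

test_that("large samples converge to the preset moments", {
  ds <- generate_dataset(make_params("hro_isolated"), 5000, seed = 2)
  iv <- interval_stats(ds$records)
  expect_equal(iv$cum_mean[1], 56.3, tolerance = 0.01)
  expect_equal(iv$cum_sd[1], 8.7, tolerance = 0.03)
  st <- clutch_number_stats(ds$records)
  expect_equal(st$mean[2], 51.1, tolerance = 0.02)
  expect_true(all(st$min >= 1))
  # homogeneous population: cumulative interval means strictly increase
  expect_true(all(diff(iv$cum_mean) > 0))
})

test_that("an early death inflates the first-round quota as predicted", {
  # staggered first clutches, deterministic later schedule; kill the
  # last-laying animal after the first round has opened but before its own
  # first clutch: it still counts toward the quota, so only 9 true first
  # clutches exist and at least one second-round clutch is pulled into
  # round 1
  gen <- sim_params(zd_c1 = dist_spec(56, 8.7, 37, 68),
                    inter_clutch = list(dist_spec(28), dist_spec(28)),
                    clutch_size = list(dist_spec(20), dist_spec(50),
                                       dist_spec(70)),
                    clutch_count = c("3" = 1),
                    post_last_survival = dist_spec(30), label = "staggered")
  ds <- generate_dataset(gen, 10, seed = 4)
  day1 <- vapply(ds$records, function(r) r$clutches$day[1], numeric(1))
  stopifnot(max(day1) > min(day1))   # fixture sanity
  dead <- names(which.max(day1))
  ds2 <- inject_deaths(ds, data.frame(id = dead, death_day = min(day1)))
  asg <- assign_rounds(ds2$log)
  expect_equal(asg$rounds$quota[1], 10)
  expect_equal(sum(ds2$truth$true_round == 1), 9)
  mislabeled <- asg$labels == 1 & ds2$truth$true_round == 2
  expect_gte(sum(mislabeled), 1)
  expect_gt(misassignment_rate(asg, ds2$truth$true_round), 0)

  # no-op schedules leave the dataset untouched
  expect_equal(inject_deaths(ds, data.frame(id = character(),
                                            death_day = integer())), ds)
  late <- data.frame(id = names(ds$records),
                     death_day = max(ds$truth$day) + 5)
  ds3 <- inject_deaths(ds, late)
  expect_equal(assign_rounds(ds3$log)$labels,
               assign_rounds(ds$log)$labels)
  expect_error(inject_deaths(ds, data.frame(id = "ghost", death_day = 10)),
               "ghost")
})
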