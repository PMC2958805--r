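test_that("cohorts are reproducible under a fixed seed and respect population ranges", {
  spec <- cohort_spec(200, prop_male = 0.5, seed = 123)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a, b)
  c <- sample_cohort(cohort_spec(200, prop_male = 0.5, seed = 124))
  expect_false(identical(a, c))
  expect_equal(nrow(sample_cohort(cohort_spec(0))), 0)

  men <- sample_cohort(cohort_spec(10000, prop_male = 1, seed = 5))
  expect_true(all(men$leg_muscle_fraction >= 0.14 &
                    men$leg_muscle_fraction <= 0.275))
  expect_true(all(men$vo2max >= 38 & men$vo2max <= 52))
  women <- sample_cohort(cohort_spec(10000, prop_male = 0, seed = 6))
  expect_true(all(women$leg_muscle_fraction >= 0.18 &
                    women$leg_muscle_fraction <= 0.225))
  mixed <- sample_cohort(cohort_spec(500, prop_male = 0.5, seed = 8))
  expect_true(all(c("male", "female") %in% mixed$sex))
})

test_that("explicit ranges override the sex defaults, and bad specs are rejected", {
  narrow <- sample_cohort(cohort_spec(500, vo2max_range = c(50, 51), seed = 2))
  expect_true(all(narrow$vo2max >= 50 & narrow$vo2max <= 51))
  expect_error(cohort_spec(10, vo2max_range = c(52, 38)),
               class = "runfuel_spec_error")
  expect_error(cohort_spec(-3), class = "runfuel_spec_error")
  normal <- sample_cohort(cohort_spec(2000, sampling = "normal", seed = 3))
  expect_true(all(normal$leg_muscle_fraction >= 0.14 &
                    normal$leg_muscle_fraction <= 0.275))
})

test_that("the marathon energy table matches the model and rises with speed", {
  v342 <- 42.195 / 3.7
  row <- fig2_table(vo2max = 55, speeds = v342, quiet = TRUE)
  oracle <- cho_energy_required(runner_profile(mass = 1, vo2max = 55),
                                race_plan(42.195, speed_kmh = v342))
  expect_equal(row$cho_kcal_per_kg, oracle$cho_kcal_per_kg, tolerance = 1e-12)
  expect_equal(row$finish_time, "3:42:00")

  tbl <- fig2_table(vo2max = c(45, 55, 75), quiet = TRUE)
  by_cap <- split(tbl, tbl$vo2max)
  for (sub in by_cap) expect_true(all(diff(sub$cho_kcal_per_kg) > 0))
  # approaching the maximum aerobic speed the cost tends to 42.195 * f_cho(1)
  vmax <- max_aerobic_speed(55)
  lim <- fig2_table(vo2max = 55, speeds = vmax - 1e-9, quiet = TRUE)
  expect_equal(lim$cho_kcal_per_kg, 42.195 * f_cho(part, 1), tolerance = 1e-6)
})

test_that("supra-aerobic speeds are skipped from the energy table with a note", {
  expect_message(tbl <- fig2_table(vo2max = 35, speeds = c(10, 20)),
                 "supra-aerobic")
  expect_equal(nrow(tbl), 1)
})

test_that("the wall-distance table reproduces the high-intensity depletion band", {
  typical <- fig3_table(intensities = seq(0.80, 0.95, by = 0.01),
                        muscle_density_kcal_per_kg = 80,
                        leg_fractions = 0.214)
  expect_lt(min(typical$d_wall_km), 33.8)
  expect_gt(max(typical$d_wall_km), 33.8)
  easy <- fig3_table(intensities = 0.55,
                     muscle_density_kcal_per_kg = c(40, 60, 80, 100, 120, 144),
                     leg_fractions = 0.214)
  expect_true(all(easy$d_wall_km > 42.195))
  expect_true(all(!easy$hits_wall_marathon))
  curve <- fig3_table(muscle_density_kcal_per_kg = 80, leg_fractions = 0.214)
  expect_true(all(diff(curve$d_wall_km) < 0))
  expect_error(fig3_table(intensities = numeric(0)), class = "runfuel_spec_error")
})

test_that("VO2max estimates fall with heart-rate fraction and bracket the worked case", {
  tbl <- fig4_table()
  by_speed <- split(tbl, tbl$speed_mph)
  for (sub in by_speed) expect_true(all(diff(sub$vo2max_est) < 0))
  worked <- fig4_table(speeds_mph = 9, hr_fractions = 0.8)
  expect_gt(worked$vo2max_est, 55)
  expect_lt(worked$vo2max_est, 65)
  slow <- fig4_table(speeds_mph = 4)
  expect_equal(min(slow$vo2max_est), slow$vo2max_est[slow$hr_fraction == 1])
  expect_error(fig4_table(hr_fractions = c(0.5, 1.2)),
               class = "runfuel_domain_error")
})

test_that("figure tables write byte-identical CSVs across runs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_figure_tables(d1)
  p2 <- write_figure_tables(d2)
  expect_setequal(basename(p1), c("fig1.csv", "fig2.csv", "fig3.csv", "fig4.csv"))
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
})

test_that("plots build without evaluation errors", {
  expect_s3_class(autoplot(part), "ggplot")
  expect_s3_class(plot_marathon_energy(fig2_table(vo2max = c(45, 55), quiet = TRUE)),
                  "ggplot")
  expect_s3_class(plot_wall_distance(fig3_table()), "ggplot")
  expect_s3_class(plot_vo2max_curves(fig4_table()), "ggplot")
})

test_that("the CLI front end drives the model functions", {
  out <- capture.output(
    est <- runfuel_cli(c("estimate-vo2max", "--speed", "9", "--unit", "mph",
                         "--hr", "149", "--age", "30"))
  )
  expect_gt(est$vo2max, 55)
  expect_lt(est$vo2max, 65)
  expect_match(out[1], "vo2max")

  prof_path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("mass: 75", "vo2max: 55"), prof_path)
  out <- capture.output(
    pred <- runfuel_cli(c("predict-wall", "--profile", prof_path,
                          "--time", "3:42:00"))
  )
  expect_false(pred$will_hit_wall)
  expect_equal(pred$min_exogenous_cho_g, 0)

  out <- capture.output(
    fuel <- runfuel_cli(c("fueling-plan", "--profile", prof_path,
                          "--distance", "42.195", "--time", "3:42:00"))
  )
  expect_equal(fuel$min_exogenous_cho_g, 0)

  dir <- withr::local_tempdir()
  capture.output(runfuel_cli(c("make-figures", "--out", dir)))
  expect_setequal(list.files(dir),
                  c("fig1.csv", "fig2.csv", "fig3.csv", "fig4.csv"))

  out1 <- capture.output(
    c1 <- runfuel_cli(c("simulate-cohort", "--n", "5", "--seed", "9"))
  )
  out2 <- capture.output(
    c2 <- runfuel_cli(c("simulate-cohort", "--n", "5", "--seed", "9"))
  )
  expect_identical(c1, c2)

  expect_error(runfuel_cli("frobnicate"), "Unknown command")
  expect_output(runfuel_cli("help"), "usage: runfuel")
})
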