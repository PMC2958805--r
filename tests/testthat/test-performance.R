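marathon <- race_plan(42.195, finish_time = "3:42:00")

test_that("race plans demand exactly one pacing target", {
  expect_error(race_plan(42.195), class = "runfuel_config_error")
  expect_error(race_plan(42.195, finish_time = 3.7, speed_kmh = 11.4),
               class = "runfuel_config_error")
  expect_s3_class(race_plan(30, speed_kmh = 12), "race_plan")
  expect_s3_class(race_plan(10, intensity = 0.8), "race_plan")
  expect_error(race_plan(-5, intensity = 0.8), class = "runfuel_domain_error")
})

test_that("a plan resolves to the same intensity via time, speed, or intensity", {
  prof <- runner_profile(mass = 75, vo2max = 55)
  i_time <- resolve_intensity(prof, marathon)$intensity
  i_speed <- resolve_intensity(prof, race_plan(42.195, speed_kmh = 42.195 / 3.7))$intensity
  expect_equal(i_time, i_speed, tolerance = 1e-12)
  i_direct <- resolve_intensity(prof, race_plan(42.195, intensity = i_time))$intensity
  expect_equal(i_direct, i_time)
  no_cap <- runner_profile(mass = 75)
  expect_error(resolve_intensity(no_cap, marathon), class = "runfuel_config_error")
})

test_that("carbohydrate energy required is linear in distance and mass", {
  prof <- runner_profile(mass = 75, vo2max = 55)
  half <- race_plan(42.195 / 2, speed_kmh = 42.195 / 3.7)
  full <- race_plan(42.195, speed_kmh = 42.195 / 3.7)
  expect_equal(2 * cho_energy_required(prof, half)$cho_kcal,
               cho_energy_required(prof, full)$cho_kcal)
  heavier <- runner_profile(mass = 150, vo2max = 55)
  expect_equal(cho_energy_required(heavier, full)$cho_kcal,
               2 * cho_energy_required(prof, full)$cho_kcal)
  # a fat-only fuel mix costs no carbohydrate
  expect_equal(cho_energy_required(prof, race_plan(42.195, intensity = 0.6),
                                   partition = constant_partition(0))$cho_kcal,
               0)
})

test_that("wall distance falls with intensity, scales with reserves, ignores mass", {
  prof <- runner_profile(mass = 70, vo2max = 60)
  grid <- seq(0.5, 1, by = 0.02)
  d <- distance_to_wall(prof, grid)
  expect_true(all(diff(d) < 0))
  doubled <- runner_profile(mass = 70, vo2max = 60,
                            muscle_glycogen_density = 2 * 55,
                            liver_glycogen_density = 2 * 250)
  halfbase <- runner_profile(mass = 70, vo2max = 60,
                             muscle_glycogen_density = 55,
                             liver_glycogen_density = 250)
  expect_equal(distance_to_wall(doubled, 0.8), 2 * distance_to_wall(halfbase, 0.8))
  light <- runner_profile(mass = 50, vo2max = 60)
  heavy <- runner_profile(mass = 90, vo2max = 60)
  expect_equal(distance_to_wall(light, 0.85), distance_to_wall(heavy, 0.85))
  # no carbohydrate drain: the sentinel is an infinite distance
  expect_identical(distance_to_wall(prof, 0.8,
                                    partition = constant_partition(0)), Inf)
})

test_that("minimum leg fraction floors at zero when the liver alone suffices", {
  short <- race_plan(5, speed_kmh = 10)
  expect_equal(min_leg_fraction(60, short), 0)
  expect_gt(min_leg_fraction(55, marathon), 0)
})

test_that("muscle glycogen depletion responds exactly to midrace fueling", {
  prof <- runner_profile(mass = 70, vo2max = 60)
  plan30 <- race_plan(30, finish_time = 2.5)
  stations <- fueling_plan(schedule = data.frame(distance_km = seq(4, 28, 4),
                                                 grams = 20))
  expect_equal(stations$total_g, 140) # 7 stations x 20 g
  dry <- delta_muscle_glycogen(prof, plan30)
  fed <- delta_muscle_glycogen(prof, plan30, stations)
  expect_equal(dry$delta_kcal_per_kg_muscle - fed$delta_kcal_per_kg_muscle,
               140 * 4 / (70 * 0.214), tolerance = 1e-12)
  expect_gt(dry$delta_kcal_per_kg_muscle, fed$delta_kcal_per_kg_muscle)
  # mmol and kcal scales agree through the 0.72 conversion
  expect_equal(dry$delta_mmol_per_kg_muscle * 0.72, dry$delta_kcal_per_kg_muscle)
  no_legs <- suppressWarnings(runner_profile(mass = 70, vo2max = 60,
                                             leg_muscle_fraction = 0))
  expect_error(delta_muscle_glycogen(no_legs, plan30),
               class = "runfuel_domain_error")
})

test_that("depletion beyond the stored density is flagged, not clipped", {
  depleted <- runner_profile(mass = 70, vo2max = 60,
                             muscle_glycogen_density = 40,
                             liver_glycogen_density = 0)
  res <- delta_muscle_glycogen(depleted, race_plan(42.195, intensity = 0.9))
  expect_true(res$exceeds_stored)
  expect_gt(res$delta_kcal_per_kg_muscle, glycogen_density_kcal(40))
})

test_that("exogenous carbohydrate equals the energy deficit over four kcal per gram", {
  prof <- runner_profile(mass = 75, vo2max = 45)
  grams <- required_exogenous_cho(prof, marathon)
  # independent hand evaluation of the deficit with the packaged constants
  rho1 <- 0.88 * 686 / 6 + 0.12 * 2398 / 23
  vmax <- 45 * 60 / 22400 * rho1
  i <- (42.195 / 3.7) / vmax
  e_kcal <- 75 * 42.195 * (i^2 - 0.45 * i + 0.33)
  reserve <- 75 * (0.025 * 360 + 0.214 * 79.2)
  expect_equal(grams, (e_kcal - reserve) / 4, tolerance = 1e-9)
  expect_gt(grams, 0)
  # grams scale linearly with mass at fixed fractions and intensity
  prof2 <- runner_profile(mass = 150, vo2max = 45)
  expect_equal(required_exogenous_cho(prof2, marathon), 2 * grams,
               tolerance = 1e-9)
})

test_that("the fueling requirement is zero exactly when the wall lies beyond the race", {
  cohort <- sample_cohort(cohort_spec(50, seed = 99))
  plan <- race_plan(42.195, intensity = 0.8)
  exo <- required_exogenous_cho(cohort, plan)
  d_wall <- distance_to_wall(cohort, 0.8)
  expect_identical(exo == 0, d_wall >= 42.195)
  # boundary case: reserves tuned so the wall sits exactly at the finish line
  i <- 0.8
  f <- f_cho(part, i)
  md_mmol <- (42.195 * f - 9) / 0.214 / 0.72
  boundary <- runner_profile(mass = 70, vo2max = 80,
                             muscle_glycogen_density = md_mmol)
  expect_equal(distance_to_wall(boundary, i), 42.195, tolerance = 1e-9)
  expect_equal(required_exogenous_cho(boundary, race_plan(42.195, intensity = i)),
               0, tolerance = 1e-9)
})

test_that("an intensity can be recovered from its wall distance by root finding", {
  prof <- runner_profile(mass = 70, vo2max = 60)
  for (i_star in c(0.55, 0.72, 0.9)) {
    d_target <- distance_to_wall(prof, i_star)
    root <- uniroot(function(i) distance_to_wall(prof, i) - d_target,
                    interval = c(0.3, 1), tol = 1e-10)$root
    expect_equal(root, i_star, tolerance = 1e-6)
  }
})

test_that("uneven pacing always burns extra carbohydrate", {
  prof <- runner_profile(mass = 70, vo2max = 55)
  vmax <- max_aerobic_speed(55)
  expect_equal(pacing_penalty(prof, 42.195, 11.4, 11.4, 11.4), 0)
  withr::local_seed(404)
  for (k in 1:1000) {
    v_mean <- runif(1, 0.5, 0.85) * vmax
    v_lo <- runif(1, 0.4 * vmax, v_mean)
    v_hi <- runif(1, v_mean, 0.99 * vmax)
    pen <- pacing_penalty(prof, 42.195, v_mean, v_lo, v_hi)
    expect_gte(pen, 0)
  }
  # a proper split is strictly worse
  expect_gt(pacing_penalty(prof, 42.195, 11.4, 10, 13), 0)
})

test_that("the pacing penalty grows with the size of the split", {
  prof <- runner_profile(mass = 70, vo2max = 55)
  spreads <- seq(0.2, 2, by = 0.2)
  pens <- vapply(spreads, function(s) {
    pacing_penalty(prof, 42.195, 11.4, 11.4 - s, 11.4 + s)
  }, numeric(1))
  expect_true(all(diff(pens) > 0))
})

test_that("infeasible or inconsistent splits are rejected", {
  prof <- runner_profile(mass = 70, vo2max = 55)
  expect_error(pacing_penalty(prof, 42.195, 11.4, 12, 13),
               class = "runfuel_plan_error")
  expect_error(pacing_penalty(prof, 42.195, 11.4, 10, 13, fraction_lo = 0.9),
               class = "runfuel_plan_error")
})

test_that("race predictions satisfy their own consistency invariants", {
  cohort <- sample_cohort(cohort_spec(30, seed = 7))
  plan <- race_plan(42.195, intensity = 0.85)
  pred <- predict_race(cohort, plan)
  expect_identical(pred$will_hit_wall, pred$distance_to_wall_km < 42.195)
  expect_true(all(pred$min_exogenous_cho_g[!pred$will_hit_wall] == 0))
  expect_true(all(pred$min_exogenous_cho_g[pred$will_hit_wall] > 0))
  expect_equal(pred$cho_kcal, pred$cho_kcal_per_kg * pred$mass)
})

test_that("error bounds bracket the point predictions", {
  prof <- runner_profile(mass = 75, vo2max = 55)
  pred <- predict_race(prof, marathon, with_errors = TRUE)
  expect_lte(pred$cho_kcal_lo, pred$cho_kcal)
  expect_gte(pred$cho_kcal_hi, pred$cho_kcal)
  expect_lte(pred$distance_to_wall_km_lo, pred$distance_to_wall_km)
  expect_gte(pred$distance_to_wall_km_hi, pred$distance_to_wall_km)
  expect_lte(pred$rel_err_f_cho, 0.055)
})
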