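test_that("cohort generation is reproducible and respects the stated ranges", {
  a <- generate_cohort(12, seed = 1)
  b <- generate_cohort(12, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(12, seed = 2)))
  expect_true(all(a$ecw0 >= 14.8 & a$ecw0 <= 19.8))
  expect_true(all(a$weight > 40))
  expect_true(all(a$hct0 > 0.30 & a$hct0 < 0.55))
  expect_true(all(a$hb0 > 10))
  expect_equal(a$bmi, a$weight / (a$height / 100)^2)
  expect_error(generate_cohort(0), "positive integer")
  expect_error(generate_cohort(12, seed = "x"), "integer")
})

test_that("cohort moments match the generating distributions at large n", {
  big <- generate_cohort(10000, seed = 7)
  expect_lt(abs(mean(big$weight) - 67.5), 0.2)
  expect_lt(abs(mean(big$height) - 175.4), 0.2)
  expect_lt(abs(mean(big$ecw0) - (14.8 + 19.8) / 2), 0.1)
})

test_that("the crossover design is the published Latin arrangement", {
  d <- default_design()
  expect_equal(d$groups[[2]],
               c("tetrastarch6", "pentastarch10", "ringers_lactate",
                 "dextrose5"))
  expect_equal(length(d$groups) * length(d$groups[[1]]), 16)
  for (g in d$groups)
    expect_setequal(g, fluid_specs()$fluid)   # each fluid once per group
  expect_equal(d$washout_days, 7)
})

test_that("the arterial sampling schedule has the study's 14 times", {
  s <- sampling_schedule(60)
  expect_length(s, 14)
  expect_equal(s[1], 0)
  expect_equal(max(s), 240)
  expect_equal(s, c(0, 6, 18, 30, 42, 54, 65, 70, 75, 80, 90, 120, 180, 240))
  expect_error(sampling_schedule(-10), "positive")
})

test_that("fluid dosing follows the per-kg and fixed rules", {
  expect_equal(fluid_dose("ringers_lactate", 67.5), 2700)
  expect_equal(fluid_dose("dextrose5", 67.9), 1358)
  expect_equal(fluid_dose("tetrastarch6", 80), 1000)
  expect_equal(fluid_dose("pentastarch10", 50), 1000)
  expect_error(fluid_dose("saline", 70), "unknown fluid")
})

test_that("generated trials have the right shape and are seed-deterministic", {
  cohort <- generate_cohort(12, seed = 1)
  t1 <- generate_trial(cohort, seed = 5)
  t2 <- generate_trial(cohort, seed = 5)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 12 * 4 * 14)
  # one baseline row per subject x fluid, times strictly increasing
  for (key in split(t1, paste(t1$subject_id, t1$fluid))) {
    expect_equal(sum(key$time == 0), 1)
    expect_true(all(diff(key$time) > 0))
  }
  # dilution -> hemoglobin round trip at the stored baselines
  ok <- is.finite(t1$hb)
  back <- compute_dilution(t1$hb0[ok], t1$hb[ok], t1$hct0[ok])
  expect_lt(max(abs(back - t1$dilution[ok])), 1e-12)
  # ECW tracks peripheral expansion only for Ringer's lactate
  rl <- t1[t1$fluid == "ringers_lactate" & t1$subject_id == "S01", ]
  expect_gt(max(rl$ecw) - rl$ecw0[1], 0.3)
  ts <- t1[t1$fluid == "tetrastarch6" & t1$subject_id == "S01", ]
  expect_true(all(ts$ecw == ts$ecw0[1]))
})

test_that("noise-free generation equals the deterministic kinetic solution", {
  cohort <- generate_cohort(3, seed = 9)
  models <- preset_models()
  models <- lapply(models, function(m) {
    m$sigma <- 1e-300   # exactly-zero noise limit
    m$omega2 <- numeric(0)
    m
  })
  trial <- generate_trial(cohort, models = models, seed = 10)
  for (fl in fluid_specs()$fluid) {
    for (sid in cohort$subject_id) {
      rows <- trial[trial$fluid == fl & trial$subject_id == sid, ]
      subj <- cohort[cohort$subject_id == sid, ]
      p <- typical_params(models[[fl]], c(ecw0 = subj$ecw0))
      sched <- infusion_schedule(fluid_dose(fl, subj$weight), 60)
      sol <- vk_solve(p, sched, rows$time)
      expect_equal(rows$dilution, sol$dilution, tolerance = 1e-12)
    }
  }
})

test_that("large-clearance dextrose arms can show negative dilutions, unclipped", {
  cohort <- generate_cohort(12, seed = 21)
  trial <- generate_trial(cohort, seed = 22)
  dex <- trial[trial$fluid == "dextrose5" & trial$time > 60, ]
  expect_gt(sum(dex$dilution < 0), 0)
  expect_equal(sum(trial$dilution == 0 & trial$time > 0), 0)  # no clipping to 0
})

test_that("divided-dose mode conserves total volume and changes fine structure", {
  p <- kinetic_params("one_volume", k_r = 0.098, Vc0 = 16.3)
  const <- infusion_schedule(1000, 60)
  split10 <- infusion_schedule(1000, 60, n_doses = 10)
  tt <- c(3, 30, 57, 120, 240)
  a <- vk_solve(p, const, tt)
  b <- vk_solve(p, split10, tt)
  expect_equal(a$infused[tt >= 60], b$infused[tt >= 60])
  # long after the infusion the two dosing styles agree to a few percent
  # (input timing shifts the elimination convolution slightly)
  expect_equal(a$central_expansion[5], b$central_expansion[5], tolerance = 0.03)
  # but differ mid-infusion (pushes vs steady drip)
  expect_gt(abs(a$central_expansion[1] - b$central_expansion[1]), 0.005)
})
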