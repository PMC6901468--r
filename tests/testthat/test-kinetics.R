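test_that("the ECW covariate relation evaluates exactly", {
  expect_equal(vt0_from_ecw(16), 30.6)
  # theta2 = 1 collapses to theta1 + 1 for any ECW
  expect_equal(vt0_from_ecw(c(12, 16, 19), theta2 = 1), rep(14.8, 3))
  # frozen from an independent scalar evaluation of 13.8 + 16.8^(19.8/16)
  expect_equal(vt0_from_ecw(19.8), 46.63373102691338, tolerance = 1e-12)
  expect_error(vt0_from_ecw(-1), "> 0")
  expect_error(vt0_from_ecw(16, theta1 = -40), "non-positive")
})

test_that("one-volume limits: pure accumulation and exponential washout", {
  p0 <- kinetic_params("one_volume", k_r = 0, Vc0 = 10, k_b = 0)
  s <- vk_solve(p0, infusion_schedule(600, 60), c(0, 30, 60))
  expect_equal(s$central_expansion, c(0, 0.3, 0.6), tolerance = 1e-12)
  # post-infusion with k_b = 0: x(t) = x(60) exp(-(k_r/V0)(t - 60))
  p <- kinetic_params("one_volume", k_r = 0.098, Vc0 = 16.3, k_b = 0)
  s2 <- vk_solve(p, infusion_schedule(1000, 60), c(60, 90, 150, 240))
  expect_equal(s2$central_expansion[-1],
               s2$central_expansion[1] *
                 exp(-(0.098 / 16.3) * (s2$time[-1] - 60)),
               tolerance = 1e-12)
})

test_that("closed-form solutions agree with an RK4 oracle to 1e-8 relative", {
  set.seed(202)
  sched <- infusion_schedule(1000, 60)
  t_out <- c(30, 60, 120)
  for (i in 1:50) {
    p <- if (i %% 2 == 0) random_one_volume() else random_two_volume()
    a <- vk_solve(p, sched, t_out)
    o <- rk4_oracle(p, sched, t_out)
    expect_lt(max(abs(a$central_expansion - o$central) /
                    pmax(abs(o$central), 1e-3)), 1e-8)
    expect_lt(max(abs(a$cumulative_elimination - o$elim) /
                    pmax(abs(o$elim), 1e-3)), 1e-8)
    if (p$kind == "two_volume")
      expect_lt(max(abs(a$peripheral_expansion - o$peripheral) /
                      pmax(abs(o$peripheral), 1e-3)), 1e-8)
  }
})

test_that("mass balance closes at every output time", {
  set.seed(203)
  sched <- infusion_schedule(2700, 60)
  t_out <- c(0, 10, 33, 60, 61, 100, 240, 480)
  for (i in 1:50) {
    p <- if (i %% 2 == 0) random_one_volume() else random_two_volume()
    s <- vk_solve(p, sched, t_out)
    gap <- s$central_expansion + s$peripheral_expansion +
      s$cumulative_elimination - s$infused
    expect_lt(max(abs(gap)), 1e-9)
  }
})

test_that("cumulative elimination has the right degenerate limits", {
  # k_r = 0: elimination is the baseline loss k_b * t exactly
  p <- kinetic_params("one_volume", k_r = 0, Vc0 = 10, k_b = 0.0008)
  tt <- c(0, 60, 240)
  expect_equal(cumulative_elimination(p, infusion_schedule(500, 60), tt),
               0.0008 * tt, tolerance = 1e-12)
  # k_b = 0, long after a finite infusion: everything infused is eliminated
  p2 <- kinetic_params("one_volume", k_r = 0.3, Vc0 = 5, k_b = 0)
  e <- cumulative_elimination(p2, infusion_schedule(500, 60), 5000)
  expect_equal(e, 0.5, tolerance = 1e-6)
  expect_error(cumulative_elimination(p2, infusion_schedule(500, 60), -5),
               "non-negative")
})

test_that("equal relative expansion nulls the inter-compartmental flux", {
  # if x_c/Vc0 = x_t/Vt0, the coupling terms cancel and only elimination
  # drains the central space: dx_c/dt = -k_b - k_r x_c/Vc0 instantaneously
  p <- kinetic_params("two_volume", k_r = 0.081, Vc0 = 4.9, Vt0 = 30.6,
                      k_t = 0.617)
  A <- matrix(c(-(p$k_r + p$k_t) / p$Vc0, p$k_t / p$Vc0,
                p$k_t / p$Vt0, -p$k_t / p$Vt0), 2, 2)
  x <- c(p$Vc0, p$Vt0) * 0.1          # equal 10% relative expansion
  dx <- A %*% x
  expect_equal(dx[2], 0, tolerance = 1e-12)               # no net peripheral flux
  expect_equal(dx[1], -p$k_r * 0.1, tolerance = 1e-12)    # elimination only
})

test_that("two-volume collapses to one-volume as k_t goes to 0", {
  sched <- infusion_schedule(1000, 60)
  tt <- c(30, 60, 120, 240)
  p1 <- kinetic_params("one_volume", k_r = 0.081, Vc0 = 4.9)
  for (kt in c(0, 1e-6)) {
    p2 <- kinetic_params("two_volume", k_r = 0.081, Vc0 = 4.9, Vt0 = 30.6,
                         k_t = kt)
    a <- vk_solve(p1, sched, tt)$central_expansion
    b <- vk_solve(p2, sched, tt)$central_expansion
    expect_equal(b, a, tolerance = 1e-4)
  }
})

test_that("outputs are invariant to refinement of the time grid", {
  p <- random_two_volume_at <- kinetic_params("two_volume", k_r = 0.2,
                                              Vc0 = 7, Vt0 = 22, k_t = 0.4)
  sched <- infusion_schedule(1500, 60)
  coarse <- vk_solve(p, sched, c(45, 200))
  fine <- vk_solve(p, sched, c(1:60, seq(61, 240, 0.5)))
  expect_equal(coarse$central_expansion,
               fine$central_expansion[match(c(45, 200), fine$time)],
               tolerance = 1e-12)
  expect_equal(coarse$cumulative_elimination,
               fine$cumulative_elimination[match(c(45, 200), fine$time)],
               tolerance = 1e-12)
})

test_that("fluid comparison is linear in dose and reports sensible shapes", {
  cmp1 <- simulate_comparison(volume_ml = 1000)
  # a linear system started at rest: doubling the dose doubles everything
  # except the (dose-independent) baseline-loss contribution, removed here
  # by comparing models with k_b = 0
  pars <- lapply(stats::setNames(nm = fluid_specs()$fluid), function(f) {
    p <- typical_params(published_params(f), c(ecw0 = 16))
    p$k_b <- 0
    p
  })
  a <- simulate_comparison(volume_ml = 1000, params = pars)
  b <- simulate_comparison(volume_ml = 2000, params = pars)
  expect_equal(2 * a$curves$central_expansion, b$curves$central_expansion,
               tolerance = 1e-10)
  # dextrose: smallest end-of-infusion central expansion, small peripheral
  s <- cmp1$summary
  dex <- s[s$fluid == "dextrose5", ]
  expect_equal(dex$central_expansion_L, min(s$central_expansion_L))
  rl <- s[s$fluid == "ringers_lactate", ]
  expect_lt(dex$peripheral_expansion_L, rl$peripheral_expansion_L)
  expect_error(simulate_comparison(params = pars[1:3]), "missing parameters")
})
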