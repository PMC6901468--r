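# A small low-noise pentastarch-style world used by several blocks: the
# one-volume structural truth with modest IIV and a residual variance small
# enough that individual curves are well identified.
make_onevol_world <- function(n_subjects, seed, sigma = 1e-4,
                              omega2 = c(k_r = 0.04, Vc0 = 0.04)) {
  cohort <- generate_cohort(n_subjects, seed = seed)
  gen <- published_params("pentastarch10")
  gen$sigma <- sigma
  gen$omega2 <- omega2
  models <- preset_models()
  models$pentastarch10 <- gen
  trial <- generate_trial(cohort, models = models, seed = seed + 1000)
  list(data = estimation_data(trial, "pentastarch10"), gen = gen)
}

test_that("the inner objective has the stated algebraic limits", {
  w <- make_onevol_world(3, seed = 31)
  subj <- w$data$subjects[[1]]
  m <- w$gen
  # eta = 0, sigma = 1, Omega = I: objective = RSS + log-penalty constants
  m1 <- m; m1$sigma <- 1; m1$omega2 <- c(k_r = 1, Vc0 = 1)
  f <- volkin:::predict_subject(m1, m1$theta, c(k_r = 0, Vc0 = 0), subj)
  rss <- sum((subj$y - f)^2)
  expect_equal(individual_objective(m1, subj, c(0, 0)), rss, tolerance = 1e-12)
  # huge omega2: the minimizing eta reproduces an unpenalized least-squares fit
  m2 <- m; m2$omega2 <- c(k_r = 1e6, Vc0 = 1e6)
  pls <- function(model) {
    opt <- optim(c(0, 0), function(e)
      individual_objective(model, subj, e), method = "BFGS")
    volkin:::predict_subject(model, model$theta,
                             stats::setNames(opt$par, c("k_r", "Vc0")), subj)
  }
  f_free <- pls(m2)
  ols <- optim(log(c(0.038, 11.3)), function(lp) {
    p <- kinetic_params("one_volume", k_r = exp(lp[1]), Vc0 = exp(lp[2]))
    sum((subj$y - vk_solve(p, subj$schedule, subj$times)$dilution)^2)
  }, method = "BFGS")
  p_ols <- kinetic_params("one_volume", exp(ols$par[1]), Vc0 = exp(ols$par[2]))
  f_ols <- vk_solve(p_ols, subj$schedule, subj$times)$dilution
  # omega2 = 1e6 is a large-but-finite prior: agreement is approximate
  expect_equal(f_free, f_ols, tolerance = 1e-3)
  expect_error(individual_objective(m, subj, c(0, 0, 0)), "one entry per")
})

test_that("the inner objective matches a symbolic derivation on a 1-obs toy", {
  # y = theta e^eta + eps, one observation: objective is
  # (y - theta e^eta)^2/sigma + log sigma + eta^2/om + log om
  m <- vk_model("custom", theta = c(th = 2), omega2 = c(th = 0.3),
                sigma = 0.5,
                structural = function(t, s) rep(t[["th"]], length(s$y)))
  subj <- list(id = 1, y = 2.6)
  for (eta in c(-0.4, 0, 0.25)) {
    byhand <- (2.6 - 2 * exp(eta))^2 / 0.5 + log(0.5) + eta^2 / 0.3 + log(0.3)
    expect_equal(individual_objective(m, subj, eta), byhand,
                 tolerance = 1e-12)
  }
})

test_that("FOCE OFV equals the closed-form marginal -2LL on a linear toy", {
  # prediction linear in an additive Gaussian random effect: the
  # conditional linearization is exact, so the approximation must agree
  # with the analytically marginalized normal likelihood
  set.seed(77)
  subjects <- lapply(1:6, function(i) {
    x <- c(0.5, 1, 2, 3, 4.5)
    list(id = i, x = x,
         y = 1.8 * x + rnorm(1, 0, 0.4) * x + rnorm(5, 0, 0.25))
  })
  m <- vk_model("custom", theta = c(slope = 1.6), omega2 = c(slope = 0.2),
                sigma = 0.07, iiv = "additive",
                structural = function(th, s) th[["slope"]] * s$x)
  closed <- marginal_m2ll_linear(
    subjects, f0_fun = function(s) 1.6 * s$x, G_fun = function(s) cbind(s$x),
    omega2 = 0.2, sigma = 0.07)
  expect_equal(ofv(m, subjects), closed, tolerance = 1e-6)
})

test_that("OFV degenerates to the naive-pooled -2LL when omega2 = 0", {
  w <- make_onevol_world(4, seed = 41, sigma = 5e-4)
  m <- w$gen
  m$omega2 <- numeric(0)
  pooled <- sum(sapply(w$data$subjects, function(s) {
    f <- volkin:::predict_subject(m, m$theta, numeric(0), s)
    length(s$y) * log(2 * pi * m$sigma) + sum((s$y - f)^2) / m$sigma
  }))
  expect_equal(ofv(m, w$data), pooled, tolerance = 1e-10)
})

test_that("OFV is additive over independent subjects", {
  w <- make_onevol_world(3, seed = 51)
  m <- w$gen
  once <- ofv(m, w$data$subjects)
  twice <- ofv(m, c(w$data$subjects, w$data$subjects))
  expect_equal(twice, 2 * once, tolerance = 1e-8)
})

test_that("noise-free data recover the generating fixed effects", {
  w <- make_onevol_world(5, seed = 61, sigma = 1e-300, omega2 = numeric(0))
  m0 <- vk_model("one_volume", theta = c(k_r = 0.06, Vc0 = 8),
                 omega2 = numeric(0), sigma = 1e-6)
  fit <- fit_population(w$data, m0, se = FALSE)
  expect_equal(fit$theta[["k_r"]], 0.038, tolerance = 1e-4)
  expect_equal(fit$theta[["Vc0"]], 11.3, tolerance = 1e-4)
})

test_that("fits from two distant starting points agree", {
  w <- make_onevol_world(8, seed = 71, sigma = 1e-3)
  m1 <- vk_model("one_volume", theta = c(k_r = 0.01, Vc0 = 5),
                 omega2 = c(k_r = 0.2, Vc0 = 0.2), sigma = 0.01)
  m2 <- vk_model("one_volume", theta = c(k_r = 0.2, Vc0 = 25),
                 omega2 = c(k_r = 0.01, Vc0 = 0.01), sigma = 1e-5)
  f1 <- fit_population(w$data, m1, se = FALSE)
  f2 <- fit_population(w$data, m2, se = FALSE)
  expect_lt(abs(f1$ofv - f2$ofv), 0.1)
  expect_equal(f1$theta[["k_r"]], f2$theta[["k_r"]], tolerance = 1e-2)
})

test_that("the likelihood-ratio decision is threshold-exact at 3.84", {
  expect_true(compare_models(100, 100 - 12.06, df = 1)$accept_full)
  expect_false(compare_models(100, 100 - 3.83, df = 1)$accept_full)
  expect_true(compare_models(100, 100 - 3.85, df = 1)$accept_full)
  expect_error(compare_models(100, 90, df = 0), "not nested")
  expect_error(compare_models(100, 101, df = 1), "worse than the reduced")
  lrt <- compare_models(100, 95, df = 2)
  expect_equal(lrt$critical, qchisq(0.95, 2))
})

test_that("a strongly planted ECW effect on Vt0 is selected; empty search is a no-op", {
  # low residual noise so that per-subject Vt0 is identified; the ECW
  # relation then explains most of the between-subject Vt0 spread
  cohort <- generate_cohort(12, seed = 81)
  gen <- published_params("ringers_lactate")
  gen$sigma <- 2e-5
  models <- preset_models()
  models$ringers_lactate <- gen
  trial <- generate_trial(cohort, models = models, seed = 82)
  ed <- estimation_data(trial, "ringers_lactate")
  base <- vk_model("two_volume",
                   theta = c(k_r = 0.081, Vc0 = 4.9, k_t = 0.617, Vt0 = 33),
                   omega2 = c(k_r = 0.057, Vc0 = 0.051), sigma = 1e-4)
  bfit <- fit_population(ed, base, se = FALSE)
  cands <- list(list(param = "Vt0", covariate = "ecw0", form = "power_base",
                     ref = 16))
  out <- covariate_search(ed, bfit, cands)
  expect_length(out$selected, 1)
  expect_equal(out$selected[[1]]$covariate, "ecw0")
  expect_true(all(out$trajectory$delta_ofv[out$trajectory$passes] >= 3.84))
  # the refit relation evaluated at the reference ECW stays near 30.6 L
  vt0_ref <- out$fit$theta[["Vt0_theta1"]] + out$fit$theta[["Vt0_theta2"]]
  expect_equal(vt0_ref, 30.6, tolerance = 0.15)
  # empty candidate list returns the base fit unchanged
  noop <- covariate_search(ed, bfit, list())
  expect_identical(noop$fit$theta, bfit$theta)
  expect_equal(nrow(noop$trajectory), 0)
})

test_that("covariate selection keeps its type-I error near alpha", {
  # no covariate effects planted; two spurious candidates screened per
  # repetition (kept to 6 repetitions for runtime: the binomial bound below
  # is correspondingly loose)
  false_hits <- 0
  for (rep in 1:6) {
    w <- make_onevol_world(8, seed = 400 + rep, sigma = 5e-4)
    m0 <- w$gen
    m0$sigma <- 5e-4
    bfit <- fit_population(w$data, m0, init = "given", se = FALSE)
    cands <- list(
      list(param = "k_r", covariate = "weight", form = "linear", ref = 67.5),
      list(param = "Vc0", covariate = "ecw0", form = "linear", ref = 16))
    out <- covariate_search(w$data, bfit, cands)
    false_hits <- false_hits + length(out$selected)
  }
  # expectation ~ 6 * 2 * 0.05 = 0.6 false selections; P(X > 4) << 0.01
  expect_lte(false_hits, 4)
})

test_that("CWRES is calibrated under the true model and scales with sigma", {
  cohort <- generate_cohort(48, seed = 91)
  trial <- generate_trial(cohort, seed = 92)
  ed <- estimation_data(trial, "tetrastarch6")
  m <- published_params("tetrastarch6")
  fixall <- c(names(m$theta), paste0("omega2_", names(m$omega2)), "sigma")
  fit <- fit_population(ed, m, init = "given", se = FALSE, fix = fixall)
  r <- cwres(fit)
  expect_equal(length(r), 48 * 14)
  expect_true(all(is.finite(r)))
  expect_lt(abs(mean(r)), 0.1)
  expect_lt(abs(sd(r) - 1), 0.1)
  # pure residual-error model: scaling sigma by 4 halves CWRES exactly
  m0 <- m; m0$omega2 <- numeric(0)
  f1 <- fit_population(ed, m0, init = "given", se = FALSE, fix = fixall)
  m4 <- m0; m4$sigma <- 4 * m0$sigma
  f4 <- fit_population(ed, m4, init = "given", se = FALSE, fix = fixall)
  expect_equal(cwres(f4), cwres(f1) / 2, tolerance = 1e-10)
})
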