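# Independent oracles used across the suite.  These deliberately avoid the
# package's closed-form segment solutions: the ODEs are integrated by a
# plain fixed-step classical RK4 on the raw right-hand sides.

# RK4 integration of the one-/two-volume system plus the elimination
# integral, under a piecewise-constant infusion schedule.
rk4_oracle <- function(params, schedule, t_out, h = 0.02) {
  rate_at <- function(t) {
    idx <- findInterval(t, schedule$breaks)
    if (idx >= 1 && idx <= length(schedule$rates)) schedule$rates[idx] else 0
  }
  two <- params$kind == "two_volume"
  rhs <- function(t, s) {
    ki <- rate_at(t)
    dc <- s[1] / params$Vc0
    if (two) {
      dt_ <- s[2] / params$Vt0
      c(ki - params$k_b - params$k_r * dc - params$k_t * dc + params$k_t * dt_,
        params$k_t * dc - params$k_t * dt_,
        params$k_r * dc + params$k_b)
    } else {
      c(ki - params$k_b - params$k_r * dc, 0, params$k_r * dc + params$k_b)
    }
  }
  # never step across a rate discontinuity or an output time
  knots <- sort(unique(c(0, schedule$breaks, t_out)))
  knots <- knots[knots <= max(t_out)]
  s <- c(0, 0, 0)
  out <- matrix(NA_real_, length(t_out), 3)
  t_cur <- 0
  for (j in seq_along(knots)) {
    if (j > 1) {
      a <- knots[j - 1]; b <- knots[j]
      n <- max(1L, ceiling((b - a) / h))
      hh <- (b - a) / n
      for (i in seq_len(n)) {
        t0 <- a + (i - 1) * hh
        # evaluate the rate strictly inside the step to dodge the boundary
        k1 <- rhs(t0 + hh * 1e-9, s)
        k2 <- rhs(t0 + hh / 2, s + hh / 2 * k1)
        k3 <- rhs(t0 + hh / 2, s + hh / 2 * k2)
        k4 <- rhs(t0 + hh * (1 - 1e-9), s + hh * k3)
        s <- s + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      t_cur <- b
    }
    hit <- which(abs(t_out - knots[j]) < 1e-12)
    if (length(hit)) out[hit, ] <- matrix(s, length(hit), 3, byrow = TRUE)
  }
  list(central = out[, 1], peripheral = out[, 2], elim = out[, 3])
}

# Closed-form -2 log marginal likelihood for a model whose prediction is
# LINEAR in the (additive, Gaussian) random effect:
# y_i = f0_i + G_i eta_i + eps  ->  y_i ~ N(f0_i, G_i Omega G_i' + sigma I).
marginal_m2ll_linear <- function(subjects, f0_fun, G_fun, omega2, sigma) {
  sum(vapply(subjects, function(s) {
    f0 <- f0_fun(s)
    G <- G_fun(s)
    S <- G %*% (omega2 * t(G)) + diag(sigma, length(f0))
    r <- s$y - f0
    as.numeric(determinant(S)$modulus) + length(f0) * log(2 * pi) +
      sum(r * solve(S, r))
  }, numeric(1)))
}

# random but well-conditioned two-volume parameter draws
random_two_volume <- function() {
  kinetic_params("two_volume",
                 k_r = stats::runif(1, 0.02, 0.5),
                 Vc0 = stats::runif(1, 3, 18),
                 Vt0 = stats::runif(1, 5, 40),
                 k_t = stats::runif(1, 0.05, 0.7))
}

random_one_volume <- function() {
  kinetic_params("one_volume",
                 k_r = stats::runif(1, 0.02, 0.5),
                 Vc0 = stats::runif(1, 3, 18))
}

# small default set of population models keyed by fluid
preset_models <- function() {
  lapply(stats::setNames(nm = fluid_specs()$fluid), published_params)
}
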