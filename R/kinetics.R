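# Structural volume-kinetic models.
#
# One-volume model (expansion x = v - V0, dilution x/V0):
#   dx/dt = k_i - k_b - (k_r/V0) x
# Two-volume model (central x_c = v_c - Vc0, peripheral x_t = v_t - Vt0):
#   dx_c/dt = k_i - k_b - (k_r + k_t) x_c/Vc0 + k_t x_t/Vt0
#   dx_t/dt =             k_t x_c/Vc0         - k_t x_t/Vt0
# Both are linear with constant coefficients within each constant-rate
# infusion segment, so they are solved exactly segment by segment.

# phi1(z) = (e^z - 1)/z, phi2(z) = (e^z - 1 - z)/z^2, with series guards
# near z = 0 (these arise from integrating e^{At} against a constant input).
phi1 <- function(z) ifelse(abs(z) < 1e-6, 1 + z / 2 + z^2 / 6, expm1(z) / z)
phi2 <- function(z) ifelse(abs(z) < 1e-4, 0.5 + z / 6 + z^2 / 24,
                           (expm1(z) - z) / z^2)

#' Kinetic parameters for one subject and fluid
#'
#' @param kind `"one_volume"` or `"two_volume"`.
#' @param k_r Elimination clearance, L/min.
#' @param Vc0 Baseline central fluid space, L (the one-volume model's V0).
#' @param Vt0 Baseline peripheral fluid space, L (two-volume only).
#' @param k_t Distributional clearance, L/min (two-volume only).
#' @param k_b Baseline fluid loss (insensible losses etc.), L/min; fixed at
#'   0.0008 L/min (0.8 mL/min) and not estimated.
#' @return A `vk_params` list.
#' @export
#' @examples
#' kinetic_params("one_volume", k_r = 0.098, Vc0 = 16.3)
kinetic_params <- function(kind = c("one_volume", "two_volume"),
                           k_r, Vc0, Vt0 = NULL, k_t = NULL, k_b = 0.0008) {
  kind <- match.arg(kind)
  if (!is.finite(k_r) || k_r < 0) stop("k_r must be >= 0", call. = FALSE)
  stop_if_not_scalar_pos(Vc0, "Vc0")
  if (!is.finite(k_b) || k_b < 0) stop("k_b must be >= 0", call. = FALSE)
  if (kind == "two_volume") {
    stop_if_not_scalar_pos(Vt0, "Vt0")
    if (is.null(k_t) || !is.finite(k_t) || k_t < 0)
      stop("k_t must be >= 0 for the two-volume model", call. = FALSE)
  }
  structure(list(kind = kind, k_r = k_r, Vc0 = Vc0, Vt0 = Vt0,
                 k_t = k_t, k_b = k_b), class = "vk_params")
}

#' Peripheral baseline volume from extracellular water
#'
#' Covariate relation for the baseline peripheral fluid space of the
#' Ringer's lactate model: `Vt0 = theta1 + theta2^(ecw/ecw_ref)` litres,
#' with the published estimates theta1 = 13.8 L, theta2 = 16.8 L and a
#' 16 L reference extracellular water.
#'
#' @param ecw Extracellular water, L (vectorized).
#' @param theta1,theta2 Covariate fixed effects, L.
#' @param ecw_ref Reference extracellular water, L.
#' @return Vt0 in litres.
#' @export
#' @examples
#' vt0_from_ecw(16)    # 13.8 + 16.8 = 30.6 L
vt0_from_ecw <- function(ecw, theta1 = 13.8, theta2 = 16.8, ecw_ref = 16) {
  if (any(!is.finite(ecw) | ecw <= 0)) stop("ecw must be > 0", call. = FALSE)
  out <- theta1 + theta2^(ecw / ecw_ref)
  if (any(out <= 0))
    stop("covariate relation produced a non-positive Vt0", call. = FALSE)
  out
}

# --- exact segment solutions ------------------------------------------------

# One-volume segment: from state x0, input rate r (L/min), over local times
# tau (vector). Returns x(tau) and the running integral of x over [0, tau].
seg_one_volume <- function(p, r, x0, tau) {
  a <- p$k_r / p$Vc0
  b <- r - p$k_b
  x0 <- x0[1]
  z <- -a * tau
  x <- x0 * exp(z) + b * tau * phi1(z)
  ix <- x0 * tau * phi1(z) + b * tau^2 * phi2(z)
  list(x = rbind(x, 0), ix_central = ix)
}

# Analytic eigendecomposition of the 2x2 two-volume system matrix.  The
# off-diagonal product a12*a21 = k_t^2/(Vc0*Vt0) >= 0, so eigenvalues are
# always real; near-degenerate cases fall back to a sub-stepped RK4.
two_volume_matrix <- function(p) {
  matrix(c(-(p$k_r + p$k_t) / p$Vc0, p$k_t / p$Vc0,
           p$k_t / p$Vt0, -p$k_t / p$Vt0), 2, 2)
}

eigen2 <- function(A) {
  tr <- A[1, 1] + A[2, 2]
  disc <- (A[1, 1] - A[2, 2])^2 + 4 * A[1, 2] * A[2, 1]
  if (disc < 0) disc <- 0
  sq <- sqrt(disc)
  lam <- c((tr + sq) / 2, (tr - sq) / 2)
  vec_for <- function(l) {
    v1 <- c(A[1, 2], l - A[1, 1])
    v2 <- c(l - A[2, 2], A[2, 1])
    v <- if (sum(abs(v1)) >= sum(abs(v2))) v1 else v2
    n <- sqrt(sum(v^2))
    if (n == 0) return(NULL)
    v / n
  }
  V <- cbind(vec_for(lam[1]), vec_for(lam[2]))
  if (is.null(V) || ncol(V) < 2) return(NULL)
  dV <- V[1, 1] * V[2, 2] - V[1, 2] * V[2, 1]
  # relative eigen gap guard: defective/near-defective systems go to RK4
  if (!all(is.finite(V)) || abs(dV) < 1e-10) return(NULL)
  list(values = lam, vectors = V, det = dV)
}

# Two-volume segment: exact solution via the eigenbasis; x(tau) (2 x n) and
# the integral of the central expansion over [0, tau].
seg_two_volume <- function(p, r, x0, tau) {
  A <- two_volume_matrix(p)
  b <- c(r - p$k_b, 0)
  eg <- eigen2(A)
  if (is.null(eg)) return(seg_rk4(A, b, x0, tau))
  V <- eg$vectors
  Vi <- matrix(c(V[2, 2], -V[1, 2], -V[2, 1], V[1, 1]), 2, 2,
               byrow = TRUE) / eg$det
  c0 <- Vi %*% x0
  cb <- Vi %*% b
  z1 <- eg$values[1] * tau
  z2 <- eg$values[2] * tau
  m <- rbind(c0[1] * exp(z1) + cb[1] * tau * phi1(z1),
             c0[2] * exp(z2) + cb[2] * tau * phi1(z2))
  im <- rbind(c0[1] * tau * phi1(z1) + cb[1] * tau^2 * phi2(z1),
              c0[2] * tau * phi1(z2) + cb[2] * tau^2 * phi2(z2))
  list(x = V %*% m, ix_central = drop(V[1, , drop = FALSE] %*% im))
}

# Defensive fallback for (near-)defective segment matrices: classical RK4 on
# the augmented system (x, integral of x_c), sub-stepped finely.
seg_rk4 <- function(A, b, x0, tau) {
  f <- function(s) c(A %*% s[1:2] + b, s[1])
  out_x <- matrix(0, 2, length(tau))
  out_i <- numeric(length(tau))
  ord <- order(tau)
  s <- c(x0, 0)
  t_cur <- 0
  for (k in ord) {
    dt <- tau[k] - t_cur
    if (dt > 0) {
      n <- max(20L, ceiling(dt / 0.05))
      h <- dt / n
      for (i in seq_len(n)) {
        k1 <- f(s); k2 <- f(s + h / 2 * k1)
        k3 <- f(s + h / 2 * k2); k4 <- f(s + h * k3)
        s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      t_cur <- tau[k]
    }
    out_x[, k] <- s[1:2]
    out_i[k] <- s[3]
  }
  list(x = out_x, ix_central = out_i)
}

#' Solve a volume-kinetic model on a time grid
#'
#' Exact piecewise solution of the one- or two-volume model under a
#' piecewise-constant infusion profile.  Within each constant-rate segment
#' the linear system is solved in closed form (scalar exponential for the
#' one-volume model, analytic eigendecomposition for the two-volume model),
#' and the elimination integral
#' \eqn{\int_0^t (k_r\, x_c(s)/V_{c0} + k_b)\, ds} is accumulated in closed
#' form as well, so that central + peripheral expansion + cumulative
#' elimination equals the infused volume at every output time.
#'
#' @param params A [kinetic_params()] object.
#' @param schedule An [infusion_schedule()] object.
#' @param times Output times in minutes, sorted, non-negative.
#' @return A data.frame with columns `time`, `central_expansion` (L),
#'   `peripheral_expansion` (L, 0 for one-volume), `dilution`
#'   (central expansion / Vc0), `cumulative_elimination` (L) and
#'   `infused` (L).
#' @export
#' @examples
#' p <- kinetic_params("one_volume", k_r = 0.098, Vc0 = 16.3)
#' vk_solve(p, infusion_schedule(1000, 60), c(0, 30, 60, 120, 240))
vk_solve <- function(params, schedule, times) {
  stopifnot(inherits(params, "vk_params"), inherits(schedule, "vk_schedule"))
  core <- core_solve(params, schedule, times)
  bounds <- schedule$breaks
  rates <- c(schedule$rates, 0)
  starts <- bounds
  ends <- c(bounds[-1], Inf)
  infused <- vapply(times, function(t) {
    sum(pmax(0, pmin(t, ends) - starts) * rates)
  }, numeric(1))
  data.frame(
    time = times,
    central_expansion = core$x[1, ],
    peripheral_expansion = core$x[2, ],
    dilution = core$x[1, ] / params$Vc0,
    cumulative_elimination = core$elim,
    infused = infused
  )
}

# Segment-marching engine shared by `vk_solve` and the estimation hot path.
core_solve <- function(params, schedule, times) {
  if (any(!is.finite(times) | times < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  seg_fun <- if (params$kind == "one_volume") seg_one_volume else seg_two_volume
  bounds <- schedule$breaks
  rates <- c(schedule$rates, 0)        # rate after the last break is 0
  starts <- bounds                      # segment i: [starts[i], starts[i+1])
  ends <- c(bounds[-1], Inf)
  kr_vc <- params$k_r / params$Vc0

  n <- length(times)
  out_x <- matrix(0, 2, n)
  out_e <- numeric(n)
  x <- c(0, 0)
  elim <- 0
  for (i in seq_along(starts)) {
    in_seg <- times >= starts[i] & (times < ends[i] | i == length(starts))
    tau_out <- times[in_seg] - starts[i]
    seg_len <- ends[i] - starts[i]
    # evaluate outputs inside the segment, plus the segment end to carry state
    need_end <- is.finite(seg_len)
    tau <- c(tau_out, if (need_end) seg_len)
    if (length(tau) > 0) {
      sol <- seg_fun(params, rates[i], x, tau)
      e <- elim + kr_vc * sol$ix_central + params$k_b * tau
      if (any(in_seg)) {
        out_x[, in_seg] <- sol$x[, seq_along(tau_out), drop = FALSE]
        out_e[in_seg] <- e[seq_along(tau_out)]
      }
      if (need_end) {
        x <- sol$x[, length(tau)]
        elim <- e[length(tau)]
      }
    }
    if (!need_end) break
  }
  list(x = out_x, elim = out_e)
}

#' Cumulative eliminated volume
#'
#' Closed-form \eqn{\int_0^t (k_r\, x_c(s)/V_{c0} + k_b)\, ds}: the fluid
#' volume eliminated (urinary plus baseline losses) up to each time.
#'
#' @inheritParams vk_solve
#' @param times Times in minutes, sorted, non-negative.
#' @return Numeric vector of eliminated volumes in litres.
#' @export
cumulative_elimination <- function(params, schedule, times) {
  vk_solve(params, schedule, times)$cumulative_elimination
}

#' Deterministic comparison of the four study fluids
#'
#' Simulates a hypothetical volunteer receiving the same volume of each
#' fluid over the same duration, using the final population estimates
#' ([published_params()]) with the peripheral baseline space of the Ringer's
#' lactate model resolved from extracellular water.  Reports central and
#' peripheral expansion curves on a common grid, end-of-infusion summaries,
#' and the colloid:crystalloid ratios of end-of-infusion central expansion.
#'
#' @param volume_ml Volume of each fluid, mL (default 1000).
#' @param duration_min Infusion duration, minutes (default 60).
#' @param horizon_min Last simulated time, minutes (default 240).
#' @param ecw Extracellular water of the hypothetical volunteer, L
#'   (default 16).
#' @param grid_min Output grid spacing, minutes.
#' @param params Optional named list of [kinetic_params()] overriding the
#'   shipped presets (names are fluid names).
#' @return A `vk_comparison` list: `curves` (long data.frame: fluid, time,
#'   central/peripheral expansion, dilution, cumulative elimination),
#'   `summary` (per fluid end-of-infusion expansions and central share of
#'   the infused volume, %), and `ratios` (colloid x crystalloid matrix of
#'   end-of-infusion central-expansion ratios).
#' @export
#' @examples
#' cmp <- simulate_comparison()
#' cmp$summary
#' cmp$ratios["tetrastarch6", "ringers_lactate"]  # ~4-fold
simulate_comparison <- function(volume_ml = 1000, duration_min = 60,
                                horizon_min = 240, ecw = 16, grid_min = 1,
                                params = NULL) {
  fluids <- fluid_specs()$fluid
  if (is.null(params)) {
    params <- lapply(fluids, function(f) {
      typical_params(published_params(f), c(ecw0 = ecw))
    })
    names(params) <- fluids
  }
  missing <- setdiff(fluids, names(params))
  if (length(missing) > 0)
    stop("missing parameters for fluid(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sched <- infusion_schedule(volume_ml, duration_min)
  grid <- sort(unique(c(seq(0, horizon_min, by = grid_min), duration_min)))
  curves <- do.call(rbind, lapply(fluids, function(f) {
    sol <- vk_solve(params[[f]], sched, grid)
    cbind(fluid = f, sol)
  }))
  at_end <- curves[curves$time == duration_min, ]
  summary <- data.frame(
    fluid = at_end$fluid,
    central_expansion_L = at_end$central_expansion,
    peripheral_expansion_L = at_end$peripheral_expansion,
    central_share_pct = 100 * at_end$central_expansion / (volume_ml / 1000),
    stringsAsFactors = FALSE
  )
  colloids <- c("tetrastarch6", "pentastarch10")
  crystalloids <- c("ringers_lactate", "dextrose5")
  end_central <- stats::setNames(summary$central_expansion_L, summary$fluid)
  ratios <- outer(end_central[colloids], end_central[crystalloids], "/")
  structure(list(curves = curves, summary = summary, ratios = ratios,
                 volume_ml = volume_ml, duration_min = duration_min,
                 ecw = ecw),
            class = "vk_comparison")
}

#' @export
print.vk_comparison <- function(x, ...) {
  cat(sprintf("Fluid comparison: %.0f mL over %.0f min (ECW %.1f L)\n\n",
              x$volume_ml, x$duration_min, x$ecw))
  print(x$summary, row.names = FALSE, digits = 4)
  cat("\nEnd-of-infusion central expansion ratios (colloid / crystalloid):\n")
  print(round(x$ratios, 2))
  invisible(x)
}
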