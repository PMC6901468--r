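# Synthetic crossover-trial generator: virtual cohorts with the study's
# anthropometrics, the published 4x4 fluid sequences, and dilution time
# series simulated from the population kinetic models.

#' Generate a virtual volunteer cohort
#'
#' Draws healthy adult male volunteers matching the study population:
#' weight Normal(67.5, 5.1) kg truncated above 40 kg, height
#' Normal(175.4, 4.8) cm, age Uniform(21, 35) years, baseline extracellular
#' water Uniform(14.8, 19.8) L (the reported 10th-90th percentile range for
#' average adult males).  Baseline hemoglobin and hematocrit summaries were
#' not reported for the study population; physiologic adult-male defaults of
#' Normal(15, 1) g/dL (truncated above 10) and Normal(0.45, 0.02) (truncated
#' to 0.30-0.55) are used and are configurable.
#'
#' @param n_subjects Number of volunteers (default 12).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param hb0_mean,hb0_sd Baseline hemoglobin distribution, g/dL.
#' @param hct0_mean,hct0_sd Baseline hematocrit distribution (fraction).
#' @return A data.frame with one row per subject: `subject_id`, `weight`
#'   (kg), `height` (cm), `age` (yr), `bmi` (kg/m^2), `hb0` (g/dL), `hct0`,
#'   `ecw0` (L).
#' @export
#' @examples
#' generate_cohort(12, seed = 1)
generate_cohort <- function(n_subjects = 12, seed = NULL,
                            hb0_mean = 15, hb0_sd = 1,
                            hct0_mean = 0.45, hct0_sd = 0.02) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      n_subjects < 1 || n_subjects != round(n_subjects))
    stop("`n_subjects` must be a positive integer", call. = FALSE)
  n <- as.integer(n_subjects)
  with_seed(seed, {
    weight <- rnorm_trunc(n, 67.5, 5.1, lower = 40)
    height <- stats::rnorm(n, 175.4, 4.8)
    age <- stats::runif(n, 21, 35)
    hb0 <- rnorm_trunc(n, hb0_mean, hb0_sd, lower = 10)
    hct0 <- rnorm_trunc(n, hct0_mean, hct0_sd, lower = 0.30, upper = 0.55)
    ecw0 <- stats::runif(n, 14.8, 19.8)
    data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      weight = weight, height = height, age = age,
      bmi = weight / (height / 100)^2,
      hb0 = hb0, hct0 = hct0, ecw0 = ecw0,
      stringsAsFactors = FALSE
    )
  })
}

#' The study's crossover design
#'
#' Four groups, four periods, one week of washout; each group receives the
#' four fluids in its published sequence, every fluid appearing exactly once
#' per group.
#'
#' @return A `vk_design` list: `groups` (list of four fluid-name vectors)
#'   and `washout_days`.
#' @export
#' @examples
#' default_design()$groups[[2]]
default_design <- function() {
  structure(list(
    groups = list(
      c("ringers_lactate", "tetrastarch6", "dextrose5", "pentastarch10"),
      c("tetrastarch6", "pentastarch10", "ringers_lactate", "dextrose5"),
      c("pentastarch10", "dextrose5", "tetrastarch6", "ringers_lactate"),
      c("dextrose5", "ringers_lactate", "pentastarch10", "tetrastarch6")
    ),
    washout_days = 7
  ), class = "vk_design")
}

#' @export
print.vk_design <- function(x, ...) {
  cat("Crossover design:", length(x$groups), "groups x",
      length(x$groups[[1]]), "periods, washout", x$washout_days, "days\n")
  for (i in seq_along(x$groups))
    cat(sprintf("  group %d: %s\n", i, paste(x$groups[[i]], collapse = " -> ")))
  invisible(x)
}

#' Simulate a full crossover trial
#'
#' For every subject and fluid: draws per-parameter random effects
#' eta ~ Normal(0, omega2) and forms individual parameters theta * exp(eta)
#' (log-normal inter-individual variability); resolves the Ringer `Vt0`
#' from the subject's own extracellular water when the population model
#' carries the covariate; solves the fluid's kinetic model on the 14-sample
#' arterial schedule; and adds additive residual noise (variance `sigma`) to
#' the dilution.  Hemoglobin is back-computed from the noisy dilution via
#' [invert_dilution()], and the extracellular-water column tracks
#' baseline + peripheral expansion for Ringer's lactate (it stayed at
#' baseline for the other fluids in the study).  Negative noisy dilutions
#' are kept as-is.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param design A [default_design()]-style crossover design.
#' @param models Named list of population models (one per fluid), e.g.
#'   `lapply(setNames(nm = fluid_specs()$fluid), published_params)`.  Defaults
#'   to the shipped presets.
#' @param seed Integer seed for the random effects and residuals.
#' @param divided_doses If `TRUE`, infuse as ten discrete pushes instead of
#'   one constant rate (sensitivity mode).
#' @return A `vk_trial` data.frame, one row per observation, with columns
#'   `subject_id`, `fluid`, `period`, `time` (min), `infusion_rate`
#'   (mL/min), `dilution`, `hb` (g/dL), `ecw` (L), `excluded`, and the
#'   subject covariates (`weight`, `height`, `age`, `bmi`, `hb0`, `hct0`,
#'   `ecw0`).
#' @export
#' @examples
#' trial <- generate_trial(generate_cohort(12, seed = 1), seed = 2)
#' nrow(trial)  # 12 subjects x 4 fluids x 14 samples = 672
generate_trial <- function(cohort, design = default_design(), models = NULL,
                           seed = NULL, divided_doses = FALSE) {
  fluids <- fluid_specs()
  if (is.null(models)) {
    models <- lapply(stats::setNames(nm = fluids$fluid), published_params)
  }
  missing <- setdiff(fluids$fluid, names(models))
  if (length(missing) > 0)
    stop("no population model for fluid(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (m in models) {
    if (!is.null(m$sigma) && m$sigma < 0)
      stop("sigma must be non-negative", call. = FALSE)
  }
  n_groups <- length(design$groups)
  with_seed(seed, {
    rows <- vector("list", nrow(cohort) * nrow(fluids))
    k <- 0L
    for (i in seq_len(nrow(cohort))) {
      subj <- cohort[i, ]
      sequence <- design$groups[[(i - 1L) %% n_groups + 1L]]
      for (period in seq_along(sequence)) {
        fl <- sequence[period]
        spec <- fluids[fluids$fluid == fl, ]
        pop <- models[[fl]]
        dose <- fluid_dose(fl, subj$weight)
        sched <- if (divided_doses) {
          infusion_schedule(dose, spec$infusion_minutes, n_doses = 10)
        } else {
          infusion_schedule(dose, spec$infusion_minutes)
        }
        times <- sampling_schedule(spec$infusion_minutes)
        ipars <- draw_individual_params(pop, subj)
        sol <- vk_solve(ipars, sched, times)
        sd_res <- sqrt(pop$sigma)
        dil <- sol$dilution +
          if (sd_res > 0) stats::rnorm(length(times), 0, sd_res) else 0
        hb <- rep(NA_real_, length(times))
        ok <- 1 + dil * (1 - subj$hct0) > 0
        hb[ok] <- invert_dilution(subj$hb0, dil[ok], subj$hct0)
        ecw <- if (fl == "ringers_lactate") {
          subj$ecw0 + sol$peripheral_expansion
        } else {
          rep(subj$ecw0, length(times))
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          subject_id = subj$subject_id, fluid = fl, period = period,
          time = times,
          infusion_rate = 1000 * schedule_rate_at(sched, times),
          dilution = dil, hb = hb, ecw = ecw, excluded = FALSE,
          weight = subj$weight, height = subj$height, age = subj$age,
          bmi = subj$bmi, hb0 = subj$hb0, hct0 = subj$hct0,
          ecw0 = subj$ecw0, stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows[seq_len(k)])
    rownames(out) <- NULL
    class(out) <- c("vk_trial", "data.frame")
    out
  })
}

# One subject's kinetic parameters from a population model: resolve the
# covariate relations for this subject, then apply log-normal IIV to the
# parameters that carry it.
draw_individual_params <- function(pop, subj, eta = NULL) {
  om <- pop$omega2[pop$omega2 > 0]
  if (is.null(eta)) {
    eta <- stats::rnorm(length(om), 0, sqrt(om))
    names(eta) <- names(om)
  }
  base <- resolve_base(pop, pop$theta, as.list(subj))
  th <- apply_eta(base, eta, pop$iiv)
  if (pop$kind == "one_volume") {
    kinetic_params("one_volume", k_r = th[["k_r"]], Vc0 = th[["Vc0"]],
                   k_b = pop$k_b)
  } else {
    kinetic_params("two_volume", k_r = th[["k_r"]], Vc0 = th[["Vc0"]],
                   Vt0 = th[["Vt0"]], k_t = th[["k_t"]], k_b = pop$k_b)
  }
}
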