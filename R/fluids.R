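#' Study fluids and their dosing rules
#'
#' The four fluids of the crossover design: two crystalloids (Ringer's
#' lactate, 5\% dextrose in water) dosed per kilogram of body weight, and two
#' colloids (6\% tetrastarch, 10\% pentastarch) given as a fixed 1000 mL.
#' All are infused at a constant rate over 60 minutes.
#'
#' @return A data.frame with one row per fluid: `fluid`, `dose_per_kg`
#'   (mL/kg, `NA` for fixed doses), `dose_fixed` (mL, `NA` for per-kg doses),
#'   `infusion_minutes`, and `structural_kind` (`"one_volume"` for the
#'   colloids, `"two_volume"` for the crystalloids).
#' @export
#' @examples
#' fluid_specs()
fluid_specs <- function() {
  data.frame(
    fluid = c("ringers_lactate", "dextrose5", "tetrastarch6", "pentastarch10"),
    dose_per_kg = c(40, 20, NA, NA),
    dose_fixed = c(NA, NA, 1000, 1000),
    infusion_minutes = rep(60, 4),
    structural_kind = c("two_volume", "two_volume", "one_volume", "one_volume"),
    stringsAsFactors = FALSE
  )
}

#' Per-subject fluid dose
#'
#' @param fluid One of `"ringers_lactate"`, `"dextrose5"`, `"tetrastarch6"`,
#'   `"pentastarch10"`.
#' @param weight_kg Body weight in kg (used for per-kg doses only).
#' @return Dose in mL.
#' @export
#' @examples
#' fluid_dose("ringers_lactate", 67.5)  # 2700 mL
fluid_dose <- function(fluid, weight_kg) {
  spec <- fluid_specs()
  i <- match(fluid, spec$fluid)
  if (is.na(i)) stop("unknown fluid: ", fluid, call. = FALSE)
  if (!is.na(spec$dose_fixed[i])) return(spec$dose_fixed[i])
  stop_if_not_scalar_pos(weight_kg, "weight_kg")
  spec$dose_per_kg[i] * weight_kg
}

# Final population estimates, inter-individual variability (as %CV of the
# log-normal random effect) and residual variance per fluid.  The residual
# sigma is stored as a VARIANCE on the dilution scale; see `published_params()`.
# IIV is carried on k_r and Vc0 (the published table reports no IIV for k_t
# and Vt0 in the final models' %CV columns).
.vk_presets <- list(
  ringers_lactate = list(
    kind = "two_volume",
    theta = c(k_r = 0.081, Vc0 = 4.9, k_t = 0.617),
    vt0_covariate = c(theta1 = 13.8, theta2 = 16.8, ecw_ref = 16),
    cv_pct = c(k_r = 23.9, Vc0 = 22.6),
    sigma = 0.0013
  ),
  dextrose5 = list(
    kind = "two_volume",
    theta = c(k_r = 0.425, Vc0 = 4.7, k_t = 0.568, Vt0 = 5.4),
    cv_pct = c(k_r = 32.7, Vc0 = 70.9),
    sigma = 0.0014
  ),
  tetrastarch6 = list(
    kind = "one_volume",
    theta = c(k_r = 0.098, Vc0 = 16.3),
    cv_pct = c(k_r = 42.9, Vc0 = 29.3),
    sigma = 0.0020
  ),
  pentastarch10 = list(
    kind = "one_volume",
    theta = c(k_r = 0.038, Vc0 = 11.3),
    cv_pct = c(k_r = 30.5, Vc0 = 24.1),
    sigma = 0.0015
  )
)

#' Final population parameter presets
#'
#' Ships the published final-model population estimates for each fluid:
#' elimination clearance `k_r` (L/min), baseline central space `Vc0` (L),
#' and for the two-volume crystalloid models the distributional clearance
#' `k_t` (L/min) and baseline peripheral space `Vt0` (L).  For Ringer's
#' lactate `Vt0` is given by the extracellular-water covariate relation
#' (see [vt0_from_ecw()]) evaluated at `ecw`.  Inter-individual variability
#' is returned as log-normal variances `omega2` for `k_r` and `Vc0`;
#' the residual term is additive on the dilution scale.
#'
#' @param fluid Fluid name (see [fluid_specs()]).
#' @param sigma_as The published residual term is interpreted as a variance
#'   by default (`"variance"`, the estimation software's convention for an
#'   additive error model); `"sd"` treats it as a standard deviation.
#' @return A [vk_model()].  For Ringer's lactate the model carries the
#'   `Vt0 ~ ECW` covariate relation, with fixed effects `Vt0_theta1` and
#'   `Vt0_theta2`; resolve a typical subject with [typical_params()].
#' @export
#' @examples
#' published_params("pentastarch10")$theta
#' typical_params(published_params("ringers_lactate"), c(ecw0 = 16))$Vt0  # 30.6
published_params <- function(fluid, sigma_as = c("variance", "sd")) {
  sigma_as <- match.arg(sigma_as)
  p <- .vk_presets[[fluid]]
  if (is.null(p)) stop("unknown fluid: ", fluid, call. = FALSE)
  theta <- p$theta
  covariates <- list()
  if (!is.null(p$vt0_covariate)) {
    cv <- p$vt0_covariate
    theta[["Vt0_theta1"]] <- cv[["theta1"]]
    theta[["Vt0_theta2"]] <- cv[["theta2"]]
    covariates <- list(list(param = "Vt0", covariate = "ecw0",
                            form = "power_base", ref = cv[["ecw_ref"]]))
  }
  sigma <- if (sigma_as == "variance") p$sigma else p$sigma^2
  m <- vk_model(p$kind, theta = theta, omega2 = (p$cv_pct / 100)^2,
                sigma = sigma, covariates = covariates)
  m$fluid <- fluid
  m
}
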