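# Population model object shared by the trial simulator and the estimator.

#' Population volume-kinetic model
#'
#' Bundles a structural kind with its fixed effects, diagonal log-normal
#' inter-individual variability, and an additive residual error on the
#' dilution scale.  Covariate relations (e.g. the extracellular-water
#' relation for the Ringer `Vt0`) replace or modify a structural parameter
#' per subject; see [add_covariate()].
#'
#' @param kind `"one_volume"`, `"two_volume"`, or `"custom"` (then
#'   `structural` must be a `function(theta_i, subject)` returning the
#'   predicted observations for one subject).
#' @param theta Named fixed-effect vector.  Structural names are `k_r`,
#'   `Vc0` (and `k_t`, `Vt0` for two-volume); covariate relations introduce
#'   derived names such as `Vt0_theta1`.
#' @param omega2 Named vector of IIV variances (a subset of the structural
#'   parameter names); parameters absent from `omega2` carry no random
#'   effect.
#' @param sigma Residual variance (dilution scale).
#' @param covariates List of covariate specs (see [add_covariate()]).
#' @param iiv `"lognormal"` (`theta * exp(eta)`, the default) or
#'   `"additive"` (`theta + eta`; used mainly for analytic toy checks where
#'   the conditional-estimation approximation is exact).
#' @param k_b Fixed baseline loss, L/min.
#' @param structural Custom prediction function for `kind = "custom"`.
#' @return A `vk_model` list.
#' @export
#' @examples
#' vk_model("one_volume", theta = c(k_r = 0.038, Vc0 = 11.3),
#'          omega2 = c(k_r = 0.093, Vc0 = 0.058), sigma = 0.0015)
vk_model <- function(kind = c("one_volume", "two_volume", "custom"),
                     theta, omega2 = numeric(0), sigma,
                     covariates = list(), iiv = c("lognormal", "additive"),
                     k_b = 0.0008, structural = NULL) {
  kind <- match.arg(kind)
  iiv <- match.arg(iiv)
  if (is.null(names(theta)) || any(names(theta) == ""))
    stop("`theta` must be fully named", call. = FALSE)
  if (length(omega2) > 0 && (is.null(names(omega2)) || any(omega2 < 0)))
    stop("`omega2` must be named and non-negative", call. = FALSE)
  if (!is.numeric(sigma) || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  if (kind == "custom" && !is.function(structural))
    stop("`structural` function required for kind = \"custom\"", call. = FALSE)
  structure(list(kind = kind, theta = theta, omega2 = omega2, sigma = sigma,
                 covariates = covariates, iiv = iiv, k_b = k_b,
                 structural = structural),
            class = "vk_model")
}

#' Attach a covariate relation to a model
#'
#' Two functional forms are supported.  `"power_base"` replaces the target
#' parameter by `theta1 + theta2^(cov/ref)` (the form found for
#' `Vt0 ~ ECW`); it removes the original fixed effect and introduces
#' `<param>_theta1` and `<param>_theta2`, a net gain of one parameter
#' (df = 1 in the likelihood-ratio test).  `"linear"` multiplies the
#' parameter by `1 + beta * (cov - ref)/ref`, introducing `<param>_beta`
#' (df = 1).
#'
#' @param model A [vk_model()].
#' @param param Structural parameter the covariate acts on (e.g. `"Vt0"`).
#' @param covariate Subject covariate name (e.g. `"ecw0"`).
#' @param form `"power_base"` or `"linear"`.
#' @param ref Reference covariate value (default 16, the ECW reference, L).
#' @param init Optional named inits for the introduced fixed effects.
#' @return The extended `vk_model`.
#' @export
add_covariate <- function(model, param, covariate,
                          form = c("power_base", "linear"), ref = 16,
                          init = NULL) {
  form <- match.arg(form)
  theta <- model$theta
  if (form == "power_base") {
    if (!param %in% names(theta))
      stop("parameter not in model: ", param, call. = FALSE)
    val <- theta[[param]]
    theta <- theta[names(theta) != param]
    theta[[paste0(param, "_theta1")]] <-
      if (!is.null(init)) init[["theta1"]] else val / 2
    theta[[paste0(param, "_theta2")]] <-
      if (!is.null(init)) init[["theta2"]] else val / 2
  } else {
    if (!param %in% names(theta))
      stop("parameter not in model: ", param, call. = FALSE)
    theta[[paste0(param, "_beta")]] <-
      if (!is.null(init)) init[["beta"]] else 0
  }
  model$theta <- theta
  model$covariates <- c(model$covariates,
                        list(list(param = param, covariate = covariate,
                                  form = form, ref = ref)))
  model
}

# Resolve the structural parameter vector for one subject: start from the
# plain structural entries of theta, then apply covariate relations.
resolve_base <- function(model, theta, covs) {
  structural_names <- c("k_r", "Vc0", "k_t", "Vt0")
  base <- theta[names(theta) %in% structural_names]
  for (cv in model$covariates) {
    val <- covs[[cv$covariate]]
    if (is.null(val) || !is.finite(val))
      stop("subject lacks covariate: ", cv$covariate, call. = FALSE)
    if (cv$form == "power_base") {
      base[[cv$param]] <- theta[[paste0(cv$param, "_theta1")]] +
        theta[[paste0(cv$param, "_theta2")]]^(val / cv$ref)
    } else {
      base[[cv$param]] <- base[[cv$param]] *
        (1 + theta[[paste0(cv$param, "_beta")]] * (val - cv$ref) / cv$ref)
    }
  }
  base
}

apply_eta <- function(base, eta, iiv) {
  for (nm in names(eta)) {
    if (!nm %in% names(base)) next
    base[[nm]] <- if (iiv == "lognormal") base[[nm]] * exp(eta[[nm]])
                  else base[[nm]] + eta[[nm]]
  }
  base
}

# Predicted dilutions for one subject at its observation times.
predict_subject <- function(model, theta, eta, subj) {
  if (model$kind == "custom") {
    th_i <- apply_eta(theta, eta, model$iiv)
    return(model$structural(th_i, subj))
  }
  base <- resolve_base(model, theta, subj$covariates)
  th_i <- apply_eta(base, eta, model$iiv)
  pick <- function(nm) if (nm %in% names(th_i)) th_i[[nm]] else NULL
  p <- list(kind = model$kind, k_r = th_i[["k_r"]], Vc0 = th_i[["Vc0"]],
            Vt0 = pick("Vt0"), k_t = pick("k_t"), k_b = model$k_b)
  core_solve(p, subj$schedule, subj$times)$x[1, ] / p$Vc0
}

#' Typical-subject kinetic parameters from a population model
#'
#' Resolves the model's fixed effects (including covariate relations) for a
#' reference subject, returning plain [kinetic_params()].
#'
#' @param model A [vk_model()].
#' @param covariates Named covariate values of the reference subject, e.g.
#'   `c(ecw0 = 16)`.
#' @return A `vk_params` object.
#' @export
#' @examples
#' typical_params(published_params("ringers_lactate"), c(ecw0 = 16))
typical_params <- function(model, covariates = c(ecw0 = 16)) {
  base <- resolve_base(model, model$theta, as.list(covariates))
  if (model$kind == "one_volume") {
    kinetic_params("one_volume", k_r = base[["k_r"]], Vc0 = base[["Vc0"]],
                   k_b = model$k_b)
  } else {
    kinetic_params("two_volume", k_r = base[["k_r"]], Vc0 = base[["Vc0"]],
                   Vt0 = base[["Vt0"]], k_t = base[["k_t"]], k_b = model$k_b)
  }
}

#' Per-subject estimation units from a trial table
#'
#' Splits one fluid arm of a trial into the per-subject structures the
#' estimator consumes: observation times and dilutions (excluded rows
#' dropped), the subject's infusion schedule (reconstructed from the dose
#' rule and body weight), and the subject covariates.
#'
#' @param trial A `vk_trial` data.frame.
#' @param fluid Fluid name to extract.
#' @return A `vk_estdata` list with elements `subjects` (list of per-subject
#'   units), `fluid` and `n_obs`.
#' @export
estimation_data <- function(trial, fluid) {
  d <- trial[trial$fluid == fluid, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for fluid: ", fluid, call. = FALSE)
  spec <- fluid_specs()
  dur <- spec$infusion_minutes[spec$fluid == fluid]
  cov_names <- intersect(c("weight", "height", "age", "bmi", "hb0", "hct0",
                           "ecw0"), names(d))
  subjects <- lapply(split(d, d$subject_id), function(s) {
    s <- s[order(s$time), ]
    keep <- !s$excluded
    covs <- as.list(s[1, cov_names, drop = FALSE])
    list(id = s$subject_id[1],
         times = s$time[keep],
         y = s$dilution[keep],
         schedule = infusion_schedule(fluid_dose(fluid, covs$weight), dur),
         covariates = covs)
  })
  structure(list(subjects = unname(subjects), fluid = fluid,
                 n_obs = sum(!d$excluded)),
            class = "vk_estdata")
}

#' @export
print.vk_estdata <- function(x, ...) {
  cat(sprintf("Estimation data: %s, %d subjects, %d observations\n",
              x$fluid, length(x$subjects), x$n_obs))
  invisible(x)
}
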