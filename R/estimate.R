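# Nonlinear mixed-effects estimation in the first-order-conditional
# (FOCE-with-interaction) style: per-subject penalized least squares gives
# the conditional mode of the random effects, the model is linearized in
# eta at that mode, and the resulting Gaussian marginal supplies the
# approximate -2 log-likelihood (OFV).  With a purely additive residual
# error the interaction term is constant in eta, so the conditional-mode
# objective below is the exact joint density up to constants.

#' Per-subject penalized least-squares objective
#'
#' The inner objective whose minimizer over `eta` is the subject's
#' conditional mode:
#' \deqn{\sum_j \frac{(y_j - f_j(\theta, \eta))^2}{\sigma} + n \log\sigma
#'   + \eta^\top \Omega^{-1} \eta + \log|\Omega|}
#' (2-pi constants omitted).
#'
#' @param model A [vk_model()].
#' @param subj One subject unit (see [estimation_data()]): needs `times`,
#'   `y`, `schedule`, `covariates` (or whatever a custom structural reads).
#' @param eta Named random-effect vector matching the model's IIV spec.
#' @param theta,omega2,sigma Optional overrides of the model's values.
#' @return Scalar objective value.
#' @export
individual_objective <- function(model, subj, eta,
                                 theta = model$theta,
                                 omega2 = model$omega2,
                                 sigma = model$sigma) {
  om <- omega2[omega2 > 0]
  if (length(eta) != length(om))
    stop("`eta` must have one entry per IIV parameter", call. = FALSE)
  names(eta) <- names(om)
  f <- predict_subject(model, theta, eta, subj)
  if (any(!is.finite(f)))
    stop("non-finite structural prediction", call. = FALSE)
  r <- subj$y - f
  sum(r^2) / sigma + length(r) * log(sigma) +
    sum(eta^2 / om) + sum(log(om))
}

# Jacobian of the subject prediction w.r.t. eta (central differences).
jac_eta <- function(model, subj, theta, eta, h = 1e-4) {
  J <- matrix(0, length(subj$y), length(eta))
  for (k in seq_along(eta)) {
    ep <- eta; ep[k] <- ep[k] + h
    em <- eta; em[k] <- em[k] - h
    J[, k] <- (predict_subject(model, theta, ep, subj) -
                 predict_subject(model, theta, em, subj)) / (2 * h)
  }
  J
}

# Conditional mode of eta by damped Gauss-Newton on the penalized
# least-squares problem; falls back to nlminb if GN stalls.
inner_mode <- function(model, subj, theta, om, sigma, eta_init) {
  eta <- eta_init
  obj <- function(e) {
    f <- predict_subject(model, theta, e, subj)
    if (any(!is.finite(f))) return(Inf)
    sum((subj$y - f)^2) / sigma + sum(e^2 / om)
  }
  g_cur <- obj(eta)
  if (!is.finite(g_cur)) { eta[] <- 0; g_cur <- obj(eta) }
  for (it in 1:50) {
    f <- predict_subject(model, theta, eta, subj)
    r <- subj$y - f
    J <- jac_eta(model, subj, theta, eta)
    A <- crossprod(J) / sigma + diag(1 / om, length(om))
    b <- drop(crossprod(J, r)) / sigma - eta / om
    step <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (half in 1:8) {
      cand <- eta + lambda * step
      g_new <- obj(cand)
      if (is.finite(g_new) && g_new < g_cur - 1e-12) {
        eta <- cand; g_cur <- g_new; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved || sqrt(sum((lambda * step)^2)) < 1e-10) break
  }
  # polish / rescue with a general-purpose optimizer if GN made no progress
  if (!is.finite(g_cur)) {
    fit <- stats::nlminb(rep(0, length(om)), obj)
    eta <- fit$par
  }
  names(eta) <- names(om)
  eta
}

# FOCE contribution of one subject: linearize at the conditional mode and
# evaluate the Gaussian marginal -2 log-likelihood (with 2-pi constants).
foce_subject <- function(model, subj, theta, om, sigma, eta_init = NULL) {
  n <- length(subj$y)
  if (length(om) == 0L) {
    f <- predict_subject(model, theta, numeric(0), subj)
    r <- subj$y - f
    return(list(
      ofv = n * log(2 * pi * sigma) + sum(r^2) / sigma,
      eta = numeric(0), pred_ind = f, pred_lin = f,
      cwres = r / sqrt(sigma)))
  }
  eta_hat <- inner_mode(model, subj, theta, om, sigma,
                        if (is.null(eta_init)) rep(0, length(om)) else eta_init)
  f_hat <- predict_subject(model, theta, eta_hat, subj)
  if (any(!is.finite(f_hat)))
    stop("non-finite structural prediction at the conditional mode",
         call. = FALSE)
  Fj <- jac_eta(model, subj, theta, eta_hat)
  Sig <- Fj %*% (om * t(Fj)) + diag(sigma, n)
  L <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(L)) stop("linearized covariance not positive definite",
                       call. = FALSE)
  mu <- f_hat - drop(Fj %*% eta_hat)    # linearized population prediction
  r <- subj$y - mu
  w <- backsolve(L, r, transpose = TRUE)
  list(ofv = 2 * sum(log(diag(L))) + n * log(2 * pi) + sum(w^2),
       eta = eta_hat, pred_ind = f_hat, pred_lin = mu, cwres = w)
}

#' Approximate -2 log marginal likelihood (OFV)
#'
#' Sums the FOCE approximation over subjects at the given population
#' parameters.  Deterministic for fixed data and model.  With all IIV
#' variances zero this reduces to the naive-pooled -2 log-likelihood.
#'
#' @param model A [vk_model()].
#' @param data A `vk_estdata` (or plain list of subject units).
#' @param theta,omega2,sigma Optional overrides.
#' @param eta_warm Optional list of warm-start etas (internal use).
#' @return Scalar OFV (includes the `n log 2 pi` constant, so it is a true
#'   approximate -2 log-likelihood).
#' @export
ofv <- function(model, data, theta = model$theta, omega2 = model$omega2,
                sigma = model$sigma, eta_warm = NULL) {
  subjects <- if (inherits(data, "vk_estdata")) data$subjects else data
  if (length(subjects) == 0L) stop("no subjects", call. = FALSE)
  om <- omega2[omega2 > 0]
  total <- 0
  for (i in seq_along(subjects)) {
    res <- tryCatch(
      foce_subject(model, subjects[[i]], theta, om, sigma,
                   eta_init = eta_warm[[i]]),
      error = function(e) {
        stop(sprintf("subject %s: %s",
                     subjects[[i]]$id %||% i, conditionMessage(e)),
             call. = FALSE)
      })
    total <- total + res$ofv
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- population fit ---------------------------------------------------------

# Outer parameter packing: positive parameters on the log scale, linear
# covariate slopes (*_beta) unconstrained.
theta_transform <- function(nm) {
  ifelse(grepl("_beta$", nm), "identity", "log")
}

pack_params <- function(theta, om, sigma, est_theta, est_om, est_sigma) {
  tr <- theta_transform(est_theta)
  th <- unlist(theta[est_theta])
  th[tr == "log"] <- log(th[tr == "log"])
  p <- c(
    th,
    if (length(est_om)) log(om[est_om]),
    if (est_sigma) log(sigma)
  )
  names(p) <- c(est_theta,
                if (length(est_om)) paste0("omega2_", est_om),
                if (est_sigma) "sigma")
  p
}

unpack_params <- function(p, model, est_theta, est_om, est_sigma) {
  theta <- model$theta
  om <- model$omega2
  sigma <- model$sigma
  tr <- theta_transform(est_theta)
  for (i in seq_along(est_theta)) {
    theta[[est_theta[i]]] <- if (tr[i] == "log") exp(p[[est_theta[i]]])
                             else p[[est_theta[i]]]
  }
  for (nm in est_om) om[[nm]] <- exp(p[[paste0("omega2_", nm)]])
  if (est_sigma) sigma <- exp(p[["sigma"]])
  list(theta = theta, omega2 = om, sigma = sigma)
}

#' Fit a population model by FOCE-style estimation
#'
#' Minimizes [ofv()] over the fixed effects, IIV variances and residual
#' variance, all positivity-constrained via log-parameterization (linear
#' covariate slopes are unconstrained).  The default initialization first
#' runs a naive-pooled least-squares fit of the fixed effects.  IIV
#' variances that are zero in the supplied model are treated as structurally
#' absent and not estimated.
#'
#' @param data A `vk_estdata` from [estimation_data()] (or list of subject
#'   units).
#' @param model Initial [vk_model()].
#' @param init `"pooled"` (default) refines the fixed-effect inits by a
#'   naive-pooled fit; `"given"` starts from the model as supplied (useful
#'   for bootstrap refits started at the original estimates).
#' @param se Compute standard errors from the numerical Hessian of the OFV
#'   (reported only when the information matrix is positive definite).
#' @param fix Character vector of parameters to hold fixed: theta names,
#'   `"omega2_<name>"`, or `"sigma"`.
#' @param control List: `iter_max` (default 300), `rel_tol` (default 1e-10
#'   on the OFV).
#' @return A `vk_fit`: estimates (`theta`, `omega2`, `sigma`), `ofv`,
#'   standard errors and RSE\%, IIV \%CV, per-subject empirical-Bayes `eta`,
#'   a per-observation `pred` table (observed, population and individual
#'   predictions, CWRES), `convergence` metadata, and the updated `model`.
#' @export
fit_population <- function(data, model, init = c("pooled", "given"),
                           se = TRUE, fix = character(0), control = list()) {
  init <- match.arg(init)
  subjects <- if (inherits(data, "vk_estdata")) data$subjects else data
  n_obs <- sum(vapply(subjects, function(s) length(s$y), numeric(1)))
  ctrl <- utils::modifyList(list(iter_max = 300, rel_tol = 1e-10), control)

  est_theta <- setdiff(names(model$theta), fix)
  om_all <- model$omega2[model$omega2 > 0]
  est_om <- setdiff(names(om_all), sub("^omega2_", "",
                                       grep("^omega2_", fix, value = TRUE)))
  est_sigma <- !"sigma" %in% fix
  if (n_obs < length(est_theta))
    stop("fewer observations than fixed effects", call. = FALSE)

  m <- model
  m$omega2 <- om_all
  if (init == "pooled" && length(est_theta) > 0) {
    m <- pooled_init(subjects, m, est_theta)
  }

  # The inner conditional-mode search always starts from eta = 0, so the
  # outer objective is a deterministic function of the parameters (a
  # history-dependent warm start would contaminate the outer finite
  # difference gradients, because the FOCE marginal is not stationary in
  # the mode).
  objective <- function(p) {
    pars <- unpack_params(p, m, est_theta, est_om, est_sigma)
    total <- 0
    for (i in seq_along(subjects)) {
      # warnings (NaN etc.) can arise while the optimizer probes infeasible
      # regions; the guard below turns those points into a large objective
      res <- tryCatch(
        suppressWarnings(foce_subject(m, subjects[[i]], pars$theta,
                                      pars$omega2[pars$omega2 > 0],
                                      pars$sigma)),
        error = function(e) NULL)
      if (is.null(res) || !is.finite(res$ofv)) return(1e10)
      total <- total + res$ofv
    }
    total
  }

  p0 <- pack_params(m$theta, om_all, m$sigma, est_theta, est_om, est_sigma)
  opt <- if (length(p0) == 0L) {
    # everything fixed: evaluation-only "fit" (EB etas, predictions, CWRES)
    list(par = p0, convergence = 0L, message = "all parameters fixed",
         iterations = 0L, evaluations = c(`function` = 0L, gradient = 0L))
  } else {
    stats::nlminb(p0, objective,
                  control = list(iter.max = ctrl$iter_max,
                                 eval.max = 10 * ctrl$iter_max,
                                 rel.tol = ctrl$rel_tol))
  }
  pars <- unpack_params(opt$par, m, est_theta, est_om, est_sigma)
  final <- m
  final$theta <- pars$theta
  final$omega2 <- pars$omega2
  final$sigma <- pars$sigma

  # per-subject details at the optimum
  om_fin <- final$omega2[final$omega2 > 0]
  details <- lapply(seq_along(subjects), function(i) {
    foce_subject(final, subjects[[i]], final$theta, om_fin, final$sigma)
  })
  eta_mat <- do.call(rbind, lapply(details, function(d) d$eta))
  if (!is.null(eta_mat)) rownames(eta_mat) <-
      vapply(subjects, function(s) as.character(s$id %||% ""), character(1))
  pred <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    data.frame(subject_id = s$id %||% i, time = s$times, observed = s$y,
               pred_pop = predict_subject(final, final$theta,
                                          stats::setNames(rep(0, length(om_fin)),
                                                          names(om_fin)), s),
               pred_ind = details[[i]]$pred_ind,
               cwres = details[[i]]$cwres,
               stringsAsFactors = FALSE)
  }))
  ofv_final <- sum(vapply(details, function(d) d$ofv, numeric(1)))

  ses <- rses <- NULL
  if (se && length(p0) > 0L) {
    H <- tryCatch(numDeriv::hessian(objective, opt$par), error = function(e) NULL)
    if (!is.null(H)) {
      Vp <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(Vp) && all(is.finite(Vp)) && all(diag(Vp) > 0) &&
          all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)) {
        se_p <- sqrt(diag(Vp))
        names(se_p) <- names(opt$par)
        # delta method back to the natural scale for log-parameterized terms
        natural <- c(final$theta[est_theta],
                     stats::setNames(final$omega2[est_om],
                                     paste0("omega2_", est_om)),
                     if (est_sigma) c(sigma = final$sigma))
        tr <- c(theta_transform(est_theta),
                rep("log", length(est_om) + as.integer(est_sigma)))
        ses <- ifelse(tr == "log", abs(natural) * se_p, se_p)
        rses <- 100 * ses / abs(natural)
      }
    }
  }

  structure(list(
    model = final,
    theta = final$theta, omega2 = final$omega2, sigma = final$sigma,
    ofv = ofv_final,
    se = ses, rse_pct = rses,
    cv_pct = 100 * sqrt(final$omega2),
    eta = eta_mat,
    pred = pred,
    n_obs = n_obs,
    n_params = length(est_theta) + length(est_om) + as.integer(est_sigma),
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations,
                       evaluations = opt$evaluations,
                       converged = opt$convergence == 0),
    fluid = if (inherits(data, "vk_estdata")) data$fluid else NA_character_
  ), class = "vk_fit")
}

# Naive-pooled initialization: least squares over the fixed effects with all
# random effects at zero.
pooled_init <- function(subjects, model, est_theta) {
  tr <- theta_transform(est_theta)
  p0 <- unlist(model$theta[est_theta])
  p0[tr == "log"] <- log(p0[tr == "log"])
  names(p0) <- est_theta
  rss <- function(p) {
    theta <- model$theta
    for (i in seq_along(est_theta)) {
      theta[[est_theta[i]]] <- if (tr[i] == "log") exp(p[[est_theta[i]]])
                               else p[[est_theta[i]]]
    }
    tot <- 0
    for (s in subjects) {
      f <- tryCatch(suppressWarnings(predict_subject(model, theta,
                                                     numeric(0), s)),
                    error = function(e) NULL)
      if (is.null(f) || any(!is.finite(f))) return(1e10)
      tot <- tot + sum((s$y - f)^2)
    }
    tot
  }
  opt <- stats::nlminb(p0, rss, control = list(iter.max = 200))
  for (i in seq_along(est_theta)) {
    model$theta[[est_theta[i]]] <-
      if (tr[i] == "log") exp(opt$par[[est_theta[i]]]) else opt$par[[est_theta[i]]]
  }
  n_obs <- sum(vapply(subjects, function(s) length(s$y), numeric(1)))
  model$sigma <- max(opt$objective / n_obs, 1e-8)
  model
}

#' Likelihood-ratio comparison of nested models
#'
#' Accepts the fuller model when the OFV drop reaches the chi-square
#' critical value (3.84 at alpha = 0.05, df = 1).
#'
#' @param fit_reduced,fit_full `vk_fit` objects (or bare OFV numbers).
#' @param df Degrees of freedom; defaults to the parameter-count difference.
#' @param alpha Significance level (default 0.05).
#' @return A `vk_lrt` list: `accept_full`, `delta_ofv`, `critical`, `df`,
#'   `p_value`.
#' @export
#' @examples
#' compare_models(100, 87.94, df = 1)  # drop 12.06: accept
compare_models <- function(fit_reduced, fit_full, df = NULL, alpha = 0.05) {
  ofv_r <- if (inherits(fit_reduced, "vk_fit")) fit_reduced$ofv else fit_reduced
  ofv_f <- if (inherits(fit_full, "vk_fit")) fit_full$ofv else fit_full
  if (is.null(df)) {
    if (!inherits(fit_reduced, "vk_fit") || !inherits(fit_full, "vk_fit"))
      stop("`df` required when OFVs are given as bare numbers", call. = FALSE)
    df <- fit_full$n_params - fit_reduced$n_params
  }
  if (df <= 0)
    stop("models are not nested in the stated direction (df <= 0)",
         call. = FALSE)
  delta <- ofv_r - ofv_f
  if (delta < -0.01)
    stop("full model fits worse than the reduced model beyond tolerance",
         call. = FALSE)
  crit <- stats::qchisq(1 - alpha, df)
  structure(list(accept_full = delta >= crit, delta_ofv = delta,
                 critical = crit, df = df,
                 p_value = stats::pchisq(max(delta, 0), df,
                                         lower.tail = FALSE)),
            class = "vk_lrt")
}

#' @export
print.vk_lrt <- function(x, ...) {
  cat(sprintf("delta OFV = %.3f vs chi-square(%d) critical %.3f: %s (p = %.4g)\n",
              x$delta_ofv, x$df, x$critical,
              if (x$accept_full) "accept full model" else "keep reduced model",
              x$p_value))
  invisible(x)
}

#' Forward covariate selection by likelihood ratio
#'
#' Tests each candidate covariate relation against the current model; the
#' candidate with the largest OFV drop that reaches the chi-square
#' criterion is added, and the search repeats until no candidate passes.
#' Ties are broken by fewer added parameters, then candidate order.
#'
#' @param data A `vk_estdata`.
#' @param base_fit A `vk_fit` for the covariate-free model.
#' @param candidates List of candidate specs: each a list with `param`,
#'   `covariate`, `form` (`"power_base"` or `"linear"`), optional `ref`
#'   (default 16) and `df` (default 1).
#' @param alpha Significance level for each addition.
#' @return A list: `fit` (final model fit), `selected` (list of accepted
#'   candidates), `trajectory` (one row per tested candidate per step:
#'   OFVs, drop, decision).
#' @export
covariate_search <- function(data, base_fit, candidates, alpha = 0.05) {
  current <- base_fit
  remaining <- candidates
  selected <- list()
  rows <- list()
  step <- 0L
  while (length(remaining) > 0L) {
    step <- step + 1L
    trials <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      cand <- remaining[[i]]
      ext_model <- add_covariate(current$model, cand$param, cand$covariate,
                                 form = cand$form, ref = cand$ref %||% 16)
      fit <- tryCatch(
        fit_population(data, ext_model, init = "given", se = FALSE),
        error = function(e) NULL)
      df <- cand$df %||% 1
      delta <- if (is.null(fit)) NA_real_ else current$ofv - fit$ofv
      passes <- is.finite(delta) && delta >= stats::qchisq(1 - alpha, df)
      trials[[i]] <- list(fit = fit, delta = delta, df = df, passes = passes)
      rows[[length(rows) + 1L]] <- data.frame(
        step = step, param = cand$param, covariate = cand$covariate,
        form = cand$form, ofv_base = current$ofv,
        ofv_candidate = if (is.null(fit)) NA_real_ else fit$ofv,
        delta_ofv = delta, df = df, passes = passes,
        stringsAsFactors = FALSE)
    }
    passing <- which(vapply(trials, function(t) isTRUE(t$passes), logical(1)))
    if (length(passing) == 0L) break
    deltas <- vapply(trials[passing], function(t) t$delta, numeric(1))
    dfs <- vapply(trials[passing], function(t) t$df, numeric(1))
    best <- passing[order(-deltas, dfs, seq_along(passing))[1]]
    selected[[length(selected) + 1L]] <- remaining[[best]]
    current <- trials[[best]]$fit
    remaining <- remaining[-best]
  }
  trajectory <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(), param = character(), covariate = character(),
               form = character(), ofv_base = numeric(),
               ofv_candidate = numeric(), delta_ofv = numeric(),
               df = numeric(), passes = logical())
  list(fit = current, selected = selected, trajectory = trajectory)
}

#' Conditional weighted residuals
#'
#' Residuals standardized by the full FOCE-linearized covariance (Cholesky
#' whitening), so that under a correct model they have mean ~0 and SD ~1.
#'
#' @param fit A `vk_fit`.
#' @return Numeric vector, one entry per non-excluded observation (in the
#'   order of `fit$pred`).
#' @export
cwres <- function(fit) {
  stopifnot(inherits(fit, "vk_fit"))
  fit$pred$cwres
}

#' @export
print.vk_fit <- function(x, ...) {
  cat(sprintf("Population volume-kinetic fit (%s model%s)\n",
              x$model$kind,
              if (!is.na(x$fluid)) paste0(", ", x$fluid) else ""))
  cat(sprintf("OFV: %.3f  (%d observations, %d parameters)%s\n",
              x$ofv, x$n_obs, x$n_params,
              if (!x$convergence$converged) "  [NOT CONVERGED]" else ""))
  est <- data.frame(estimate = signif(unlist(x$theta), 4))
  if (!is.null(x$rse_pct)) {
    r <- x$rse_pct[rownames(est)]
    est$rse_pct <- round(unname(r), 1)
  }
  print(est)
  if (length(x$omega2) > 0) {
    cat("IIV %CV:", paste(sprintf("%s %.1f", names(x$cv_pct), x$cv_pct),
                          collapse = ", "), "\n")
  }
  cat(sprintf("sigma (residual variance): %.5g\n", x$sigma))
  invisible(x)
}

#' @export
coef.vk_fit <- function(object, ...) {
  c(object$theta,
    stats::setNames(object$omega2, paste0("omega2_", names(object$omega2))),
    sigma = object$sigma)
}
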