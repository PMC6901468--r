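# Internal validation: nonparametric bootstrap (resampling subjects) and
# numerical/visual predictive checks.

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement to the original count, refits each
#' replicate (initialized at the original estimates, which speeds
#' convergence), and summarizes the replicate estimates by their median and
#' 2.5-97.5 percentiles.  Replicates whose refit fails or does not converge
#' are counted and excluded from the summary.
#'
#' @param data A `vk_estdata`.
#' @param fit The original `vk_fit`.
#' @param n_replicates Number of bootstrap datasets (the study's methods
#'   describe 1000; its results table footnote says 2000 -- the default
#'   here is 1000 and the count is always reported alongside the summary).
#' @param seed Integer seed for the resampling.
#' @return A `vk_boot`: `summary` (data.frame: parameter, median, q2.5,
#'   q97.5), `replicates` (matrix of replicate estimates), `n_replicates`,
#'   `n_failed`.
#' @export
vk_bootstrap <- function(data, fit, n_replicates = 1000, seed = NULL) {
  stopifnot(inherits(fit, "vk_fit"))
  subjects <- if (inherits(data, "vk_estdata")) data$subjects else data
  n <- length(subjects)
  if (n < 2) stop("bootstrap needs at least 2 subjects", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  with_seed(seed, {
    reps <- vector("list", n_replicates)
    failed <- 0L
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot_data <- subjects[idx]
      rf <- tryCatch(
        fit_population(boot_data, fit$model, init = "given", se = FALSE),
        error = function(e) NULL)
      if (is.null(rf) || !rf$convergence$converged) {
        failed <- failed + 1L
        next
      }
      reps[[b]] <- coef(rf)
    }
    reps <- reps[!vapply(reps, is.null, logical(1))]
    if (length(reps) == 0L) stop("all bootstrap replicates failed",
                                 call. = FALSE)
    mat <- do.call(rbind, reps)
    qs <- apply(mat, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
    structure(list(
      summary = data.frame(parameter = colnames(mat),
                           median = qs[1, ], q2.5 = qs[2, ], q97.5 = qs[3, ],
                           row.names = NULL, stringsAsFactors = FALSE),
      replicates = mat,
      n_replicates = n_replicates,
      n_failed = failed
    ), class = "vk_boot")
  })
}

#' @export
print.vk_boot <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d replicates (%d failed)\n",
              x$n_replicates, x$n_failed))
  s <- x$summary
  s$`median (2.5-97.5%)` <- sprintf("%.4g (%.4g-%.4g)",
                                    s$median, s$q2.5, s$q97.5)
  print(s[, c("parameter", "median (2.5-97.5%)")], row.names = FALSE)
  invisible(x)
}

#' Predictive check of a fitted model
#'
#' Simulates `n_sim` replicate datasets at the observed design (same
#' subjects, sampling times and covariates), drawing new random effects and
#' residuals from the fitted model, and summarizes them as 5/50/95 percentile
#' prediction lines per nominal sampling time, with 95\% confidence bands on
#' the outer lines.  Reports the fraction of observed dilutions falling
#' outside the 90\% prediction interval (the numerical predictive check).
#'
#' @param fit A `vk_fit`.
#' @param data The `vk_estdata` the model was fitted to.
#' @param n_sim Number of simulated datasets (>= 100; default 1000).
#' @param seed Integer seed.
#' @return A `vk_vpc`: `bands` (per time bin: q5, q50, q95 and the 95\% CIs
#'   of q5 and q95), `fraction_outside`, `n_outside`, `n_obs`, and the
#'   per-observation `outside` flags.
#' @export
predictive_check <- function(fit, data, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(fit, "vk_fit"))
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  subjects <- if (inherits(data, "vk_estdata")) data$subjects else data
  model <- fit$model
  om <- model$omega2[model$omega2 > 0]
  sd_res <- sqrt(model$sigma)
  times_all <- unlist(lapply(subjects, function(s) s$times))
  y_all <- unlist(lapply(subjects, function(s) s$y))
  n_obs <- length(y_all)

  with_seed(seed, {
    sims <- matrix(NA_real_, n_obs, n_sim)
    for (k in seq_len(n_sim)) {
      pos <- 0L
      for (s in subjects) {
        eta <- stats::setNames(stats::rnorm(length(om), 0, sqrt(om)),
                               names(om))
        f <- predict_subject(model, model$theta, eta, s)
        ni <- length(f)
        sims[pos + seq_len(ni), k] <- f + stats::rnorm(ni, 0, sd_res)
        pos <- pos + ni
      }
    }
    if (any(!is.finite(sims)))
      stop("simulation produced non-finite dilutions", call. = FALSE)

    bins <- sort(unique(times_all))
    per_bin <- function(tm) {
      rows <- which(times_all == tm)
      pooled <- sims[rows, , drop = FALSE]
      q <- stats::quantile(pooled, c(0.05, 0.5, 0.95))
      # CI of the outer lines: percentile-of-percentile across simulations
      q5s <- apply(pooled, 2, stats::quantile, probs = 0.05)
      q95s <- apply(pooled, 2, stats::quantile, probs = 0.95)
      c(q5 = q[[1]], q50 = q[[2]], q95 = q[[3]],
        q5_lo = stats::quantile(q5s, 0.025)[[1]],
        q5_hi = stats::quantile(q5s, 0.975)[[1]],
        q95_lo = stats::quantile(q95s, 0.025)[[1]],
        q95_hi = stats::quantile(q95s, 0.975)[[1]])
    }
    bands <- as.data.frame(t(vapply(bins, per_bin, numeric(7))))
    bands <- cbind(time = bins, bands)

    lo <- bands$q5[match(times_all, bands$time)]
    hi <- bands$q95[match(times_all, bands$time)]
    outside <- y_all < lo | y_all > hi
    structure(list(bands = bands,
                   fraction_outside = mean(outside),
                   n_outside = sum(outside), n_obs = n_obs,
                   outside = outside, n_sim = n_sim),
              class = "vk_vpc")
  })
}

#' @export
print.vk_vpc <- function(x, ...) {
  cat(sprintf(
    "Predictive check: %d simulations, %d observations, %.1f%% outside the 90%% interval\n",
    x$n_sim, x$n_obs, 100 * x$fraction_outside))
  invisible(x)
}

#' Goodness-of-fit table
#'
#' Per-observation table of observed dilution, population prediction,
#' individual (empirical-Bayes) prediction and CWRES, for the usual
#' observed-vs-predicted and residual diagnostics.  Excluded observations
#' never enter the fit and are therefore absent.
#'
#' @param fit A `vk_fit`.
#' @return A data.frame with columns `subject_id`, `time`, `observed`,
#'   `pred_pop`, `pred_ind`, `cwres`.
#' @export
gof_tables <- function(fit) {
  stopifnot(inherits(fit, "vk_fit"))
  fit$pred
}
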