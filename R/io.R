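# Dataset and result I/O.  The on-disk dialect is a long-format CSV in the
# style of nonlinear mixed-effects datasets:
#   ID, FLUID, PERIOD, TIME, RATE, DV, HB, MDV, EXCL, WT, HT, AGE, BMI,
#   HB0, HCT0, ECW
# TIME in minutes from infusion start, RATE in mL/min (the rate of the
# active infusion segment), DV the dimensionless plasma dilution, MDV = 1
# marking non-observation rows, EXCL = 1 marking excluded observations.

.trial_cols <- c(ID = "subject_id", FLUID = "fluid", PERIOD = "period",
                 TIME = "time", RATE = "infusion_rate", DV = "dilution",
                 HB = "hb", WT = "weight", HT = "height", AGE = "age",
                 BMI = "bmi", HB0 = "hb0", HCT0 = "hct0", ECW = "ecw")

#' Write a trial dataset to CSV
#'
#' @param trial A `vk_trial` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  out <- data.frame(lapply(.trial_cols, function(cn) trial[[cn]]),
                    stringsAsFactors = FALSE)
  names(out) <- names(.trial_cols)
  out$MDV <- 0L
  out$EXCL <- as.integer(trial$excluded)
  out <- out[, c("ID", "FLUID", "PERIOD", "TIME", "RATE", "DV", "HB", "MDV",
                 "EXCL", "WT", "HT", "AGE", "BMI", "HB0", "HCT0", "ECW")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial dataset from CSV
#'
#' Validates the declared header and the structural invariants: numeric
#' times, strictly increasing within subject and fluid, and exactly one
#' baseline (TIME 0) row per subject and fluid.  Row-level problems are
#' reported with their line numbers.  Rows with `MDV = 1` or `EXCL = 1` are
#' retained but flagged `excluded`.
#'
#' @param path CSV file path.
#' @return A `vk_trial` data.frame (see [generate_trial()]).
#' @export
read_trial <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("ID", "FLUID", "TIME", "DV")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0)
    stop("dataset is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(raw$TIME))
    stop("TIME must be numeric (minutes)", call. = FALSE)
  grab <- function(cn, default) if (cn %in% names(raw)) raw[[cn]] else default
  n <- nrow(raw)
  trial <- data.frame(
    subject_id = as.character(raw$ID), fluid = raw$FLUID,
    period = grab("PERIOD", NA_integer_), time = raw$TIME,
    infusion_rate = grab("RATE", NA_real_), dilution = raw$DV,
    hb = grab("HB", NA_real_),
    ecw = grab("ECW", NA_real_),
    excluded = (grab("EXCL", rep(0L, n)) == 1L) | (grab("MDV", rep(0L, n)) == 1L),
    weight = grab("WT", NA_real_), height = grab("HT", NA_real_),
    age = grab("AGE", NA_real_), bmi = grab("BMI", NA_real_),
    hb0 = grab("HB0", NA_real_), hct0 = grab("HCT0", NA_real_),
    ecw0 = NA_real_,
    stringsAsFactors = FALSE
  )
  # baseline ECW: the TIME 0 value of the ECW column
  line_no <- seq_len(n) + 1L  # header is line 1
  for (key in split(seq_len(n), paste(trial$subject_id, trial$fluid))) {
    tt <- trial$time[key]
    if (is.unsorted(tt, strictly = TRUE)) {
      bad <- key[which(diff(tt) <= 0)[1] + 1L]
      stop(sprintf("line %d: TIME not strictly increasing within %s/%s",
                   line_no[bad], trial$subject_id[bad], trial$fluid[bad]),
           call. = FALSE)
    }
    base <- key[tt == 0]
    if (length(base) != 1L)
      stop(sprintf("%s/%s: expected exactly one TIME 0 baseline row, found %d",
                   trial$subject_id[key[1]], trial$fluid[key[1]],
                   length(base)), call. = FALSE)
    trial$ecw0[key] <- trial$ecw[base]
  }
  if (any(!is.finite(trial$dilution))) {
    bad <- which(!is.finite(trial$dilution))[1]
    stop(sprintf("line %d: non-finite DV", line_no[bad]), call. = FALSE)
  }
  class(trial) <- c("vk_trial", "data.frame")
  trial
}

#' Read an exclusion list
#'
#' @param path CSV with columns `ID`, `FLUID`, `TIME`.
#' @return A data.frame suitable for [apply_exclusions()].
#' @export
read_exclusions <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ID", "FLUID", "TIME")
  if (!all(need %in% names(raw)))
    stop("exclusion list needs columns ID, FLUID, TIME", call. = FALSE)
  data.frame(subject_id = as.character(raw$ID), fluid = raw$FLUID,
             time = raw$TIME, stringsAsFactors = FALSE)
}

#' Serialize a fit to JSON
#'
#' Writes estimates, RSE\%, IIV \%CV, OFV and convergence metadata.
#'
#' @param fit A `vk_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    kind = fit$model$kind,
    fluid = fit$fluid,
    theta = as.list(fit$theta),
    omega2 = as.list(fit$omega2),
    cv_pct = as.list(fit$cv_pct),
    sigma = fit$sigma,
    se = if (!is.null(fit$se)) as.list(fit$se),
    rse_pct = if (!is.null(fit$rse_pct)) as.list(fit$rse_pct),
    ofv = fit$ofv,
    n_obs = fit$n_obs,
    n_params = fit$n_params,
    convergence = fit$convergence
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Parameter table in the published layout
#'
#' One row per parameter with `Estimate (RSE, \%CV)` formatting, optionally
#' joined with bootstrap `Median (2.5-97.5\%)` columns.
#'
#' @param fit A `vk_fit`.
#' @param boot Optional `vk_boot` for the same model.
#' @return A data.frame.
#' @export
fit_table <- function(fit, boot = NULL) {
  nm <- names(fit$theta)
  est <- unlist(fit$theta)
  rse <- if (!is.null(fit$rse_pct)) fit$rse_pct[nm] else rep(NA_real_, length(nm))
  cv <- rep(NA_real_, length(nm))
  cv[match(names(fit$cv_pct), nm)] <- fit$cv_pct
  tab <- data.frame(
    parameter = c(nm, "sigma"),
    estimate = c(est, fit$sigma),
    rse_pct = c(unname(rse), if (!is.null(fit$rse_pct))
      unname(fit$rse_pct["sigma"]) else NA_real_),
    iiv_cv_pct = c(cv, NA_real_),
    stringsAsFactors = FALSE
  )
  if (!is.null(boot)) {
    i <- match(tab$parameter, boot$summary$parameter)
    tab$boot_median <- boot$summary$median[i]
    tab$boot_q2.5 <- boot$summary$q2.5[i]
    tab$boot_q97.5 <- boot$summary$q97.5[i]
  }
  tab
}

#' Run a simulation scenario from a YAML file
#'
#' Scenario keys: `volume_ml`, `duration_min`, `horizon_min`, `ecw`
#' (all optional, defaulting to the 1000 mL / 60 min / 240 min / 16 L
#' reference scenario) and `out_csv` (optional path; when given, the
#' per-fluid expansion curves are written there).
#'
#' @param path YAML scenario file.
#' @return The [simulate_comparison()] result, invisibly if `out_csv` was
#'   written.
#' @export
run_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  cmp <- simulate_comparison(
    volume_ml = cfg$volume_ml %||% 1000,
    duration_min = cfg$duration_min %||% 60,
    horizon_min = cfg$horizon_min %||% 240,
    ecw = cfg$ecw %||% 16
  )
  if (!is.null(cfg$out_csv)) {
    utils::write.csv(cmp$curves, cfg$out_csv, row.names = FALSE)
    return(invisible(cmp))
  }
  cmp
}

#' Read a population model specification from YAML
#'
#' Keys: `kind` (`one_volume`/`two_volume`), `theta` (named map), `omega2`
#' (named map, optional), `sigma`, optional `covariates` (list of maps with
#' `param`, `covariate`, `form`, `ref`).
#'
#' @param path YAML model file.
#' @return A [vk_model()].
#' @export
read_model_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  m <- vk_model(cfg$kind,
                theta = unlist(cfg$theta),
                omega2 = if (is.null(cfg$omega2)) numeric(0)
                         else unlist(cfg$omega2),
                sigma = cfg$sigma)
  for (cv in cfg$covariates) {
    m$covariates <- c(m$covariates,
                      list(list(param = cv$param, covariate = cv$covariate,
                                form = cv$form, ref = cv$ref %||% 16)))
  }
  m
}

#' Read a run configuration
#'
#' YAML configuration for the synthetic-trial generator: cohort size, seed,
#' baseline hemoglobin/hematocrit distributions, and divided-dose mode.
#' Unknown keys are ignored.
#'
#' @param path YAML file.
#' @return A named list of arguments for [generate_cohort()] /
#'   [generate_trial()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("n_subjects", "seed", "hb0_mean", "hb0_sd", "hct0_mean",
             "hct0_sd", "divided_doses")
  cfg[intersect(names(cfg), known)]
}
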