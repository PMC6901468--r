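#' Hemoglobin-derived plasma dilution
#'
#' Converts a hemoglobin measurement into the relative expansion of the
#' central plasma space,
#' \deqn{d(t) = \frac{Hb_0/Hb(t) - 1}{1 - Hct_0},}
#' using the baseline hemoglobin and baseline hematocrit (the hematocrit
#' carries no time index in this transform).  The dilution is negative when
#' hemoglobin rises above baseline, as observed in several volunteers during
#' 5\% dextrose infusion; negative values are legitimate observations and are
#' never clipped.
#'
#' @param hb0 Baseline hemoglobin, g/dL (> 0).
#' @param hb_t Hemoglobin at time t, g/dL (> 0); vectorized.
#' @param hct0 Baseline hematocrit as a fraction in (0, 1).
#' @return Dimensionless plasma dilution.
#' @export
#' @examples
#' compute_dilution(15, 12.5, 0.40)   # 1/3
#' compute_dilution(14, 14.5, 0.45)   # negative: hemoconcentration
compute_dilution <- function(hb0, hb_t, hct0) {
  check_hb(hb0, "hb0")
  check_hb(hb_t, "hb_t")
  check_hct(hct0)
  ((hb0 / hb_t) - 1) / (1 - hct0)
}

#' Hemoglobin from plasma dilution
#'
#' Algebraic inverse of [compute_dilution()]:
#' `hb_t = hb0 / (1 + dilution * (1 - hct0))`.  Used by the synthetic-trial
#' generator to back-compute hemoglobin from a noisy dilution.
#'
#' @inheritParams compute_dilution
#' @param dilution Plasma dilution; may be negative as long as
#'   `1 + dilution * (1 - hct0) > 0`.
#' @return Hemoglobin in g/dL.
#' @export
#' @examples
#' invert_dilution(15, 1/3, 0.40)  # 12.5
invert_dilution <- function(hb0, dilution, hct0) {
  check_hb(hb0, "hb0")
  check_hct(hct0)
  denom <- 1 + dilution * (1 - hct0)
  if (any(!is.finite(denom) | denom <= 0))
    stop("dilution too negative: implied hemoglobin is not positive",
         call. = FALSE)
  hb0 / denom
}

check_hb <- function(x, name) {
  if (any(!is.finite(x) | x <= 0))
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
}

check_hct <- function(x) {
  if (any(!is.finite(x) | x <= 0 | x >= 1))
    stop("`hct0` must lie strictly between 0 and 1", call. = FALSE)
}

#' Flag excluded observations
#'
#' Marks individual (subject, fluid, time) observations as excluded from
#' estimation while retaining them in the table, mirroring judgment-based
#' removal of implausible points (e.g. a dilution far below its neighbours
#' attributed to measurement error).  Exclusion is idempotent: flagging an
#' already-flagged row is a no-op.
#'
#' @param trial A `vk_trial` data.frame (see [generate_trial()] /
#'   [read_trial()]).
#' @param exclusions A data.frame with columns `subject_id`, `fluid`, `time`
#'   referencing existing rows.
#' @return The trial with the `excluded` flag set on the referenced rows.
#' @export
apply_exclusions <- function(trial, exclusions) {
  stopifnot(is.data.frame(trial))
  if (is.null(exclusions) || nrow(exclusions) == 0L) return(trial)
  need <- c("subject_id", "fluid", "time")
  if (!all(need %in% names(exclusions)))
    stop("`exclusions` needs columns subject_id, fluid, time", call. = FALSE)
  for (i in seq_len(nrow(exclusions))) {
    hit <- trial$subject_id == exclusions$subject_id[i] &
      trial$fluid == exclusions$fluid[i] &
      abs(trial$time - exclusions$time[i]) < 1e-9
    if (!any(hit))
      stop(sprintf("exclusion %s/%s/t=%s matches no row",
                   exclusions$subject_id[i], exclusions$fluid[i],
                   format(exclusions$time[i])), call. = FALSE)
    trial$excluded[hit] <- TRUE
  }
  trial
}

#' Optional automated consistency screen
#'
#' Flags observations whose dilution deviates from the linear interpolation
#' of their two neighbours (within subject and fluid) by more than
#' `threshold` in absolute value.  The study removed points by judgment,
#' not by rule; this screen is therefore off by default everywhere and only
#' offered as a reviewing aid.
#'
#' @inheritParams apply_exclusions
#' @param threshold Absolute deviation (dilution units) above which a point
#'   is flagged.
#' @return A data.frame of candidate exclusions (`subject_id`, `fluid`,
#'   `time`, `dilution`, `interpolated`, `deviation`).
#' @export
screen_outliers <- function(trial, threshold = 0.2) {
  out <- list()
  for (key in split(seq_len(nrow(trial)),
                    interaction(trial$subject_id, trial$fluid, drop = TRUE))) {
    d <- trial[key, ]
    d <- d[order(d$time), ]
    n <- nrow(d)
    if (n < 3) next
    for (j in 2:(n - 1)) {
      w <- (d$time[j] - d$time[j - 1]) / (d$time[j + 1] - d$time[j - 1])
      interp <- (1 - w) * d$dilution[j - 1] + w * d$dilution[j + 1]
      dev <- d$dilution[j] - interp
      if (is.finite(dev) && abs(dev) > threshold) {
        out[[length(out) + 1L]] <- data.frame(
          subject_id = d$subject_id[j], fluid = d$fluid[j], time = d$time[j],
          dilution = d$dilution[j], interpolated = interp, deviation = dev)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(subject_id = character(), fluid = character(),
                      time = numeric(), dilution = numeric(),
                      interpolated = numeric(), deviation = numeric()))
  do.call(rbind, out)
}
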