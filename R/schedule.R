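#' Infusion rate profile
#'
#' Builds a piecewise-constant infusion rate profile.  By default the full
#' volume is delivered at a single constant rate over `duration_min`, which
#' treats the study's ten equally-divided manual doses over one hour as an
#' approximately continuous infusion.  Setting `n_doses` switches to an
#' explicit divided-dose mode for sensitivity checks: each of the `n_doses`
#' equal aliquots is pushed over `bolus_minutes` at the start of its
#' `duration_min / n_doses` slot, with zero rate in between.
#'
#' @param volume_ml Total volume infused, mL.
#' @param duration_min Total infusion duration, minutes (default 60).
#' @param n_doses Optional number of divided doses (e.g. 10).
#' @param bolus_minutes Minutes over which each divided dose is pushed
#'   (default 1); must not exceed the slot length.
#' @return A `vk_schedule`: list with `breaks` (segment boundary times, min,
#'   starting at 0) and `rates` (L/min within each segment; rate is 0 after
#'   the last break), plus `volume_ml` and `duration_min`.
#' @export
#' @examples
#' infusion_schedule(1000, 60)                 # 1 L/h constant
#' infusion_schedule(1000, 60, n_doses = 10)   # ten 100-mL pushes
infusion_schedule <- function(volume_ml, duration_min = 60,
                              n_doses = NULL, bolus_minutes = 1) {
  stop_if_not_scalar_pos(volume_ml, "volume_ml")
  stop_if_not_scalar_pos(duration_min, "duration_min")
  if (is.null(n_doses)) {
    breaks <- c(0, duration_min)
    rates <- volume_ml / duration_min / 1000
  } else {
    slot <- duration_min / n_doses
    if (bolus_minutes > slot)
      stop("`bolus_minutes` exceeds the divided-dose slot", call. = FALSE)
    starts <- (seq_len(n_doses) - 1) * slot
    rate <- volume_ml / n_doses / bolus_minutes / 1000
    breaks <- sort(unique(c(starts, starts + bolus_minutes, duration_min)))
    rates <- vapply(breaks[-length(breaks)], function(t0) {
      active <- any(starts <= t0 & t0 < starts + bolus_minutes)
      if (active) rate else 0
    }, numeric(1))
  }
  structure(list(breaks = breaks, rates = rates,
                 volume_ml = volume_ml, duration_min = duration_min),
            class = "vk_schedule")
}

# infusion rate (L/min) active at each time (rate of the segment [b_i, b_{i+1}))
schedule_rate_at <- function(schedule, times) {
  idx <- findInterval(times, schedule$breaks)
  out <- numeric(length(times))
  inside <- idx >= 1L & idx <= length(schedule$rates)
  out[inside] <- schedule$rates[idx[inside]]
  out
}

#' Arterial sampling schedule
#'
#' The study's 14 arterial samples: one baseline draw, five draws just before
#' divided doses 2, 4, 6, 8 and 10 (at 6, 18, 30, 42 and 54 min when the
#' infusion is split into ten 6-minute doses), and eight draws at 5, 10, 15,
#' 20, 30, 60, 120 and 180 min after the end of the infusion.
#'
#' @param infusion_minutes Infusion duration in minutes (default 60; must be
#'   divisible into ten equal divided doses).
#' @return Numeric vector of 14 sampling times in minutes from infusion start.
#' @export
#' @examples
#' sampling_schedule()  # 0, 6, 18, ..., 240
sampling_schedule <- function(infusion_minutes = 60) {
  stop_if_not_scalar_pos(infusion_minutes, "infusion_minutes")
  slot <- infusion_minutes / 10
  pre <- slot * c(1, 3, 5, 7, 9)            # before doses 2, 4, 6, 8, 10
  post <- infusion_minutes + c(5, 10, 15, 20, 30, 60, 120, 180)
  c(0, pre, post)
}

#' @export
print.vk_schedule <- function(x, ...) {
  cat(sprintf("Infusion: %.0f mL over %.0f min, %d segment(s)\n",
              x$volume_ml, x$duration_min, length(x$rates)))
  invisible(x)
}
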