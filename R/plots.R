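# Diagnostic figures (ggplot2 is suggested, not required).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' Goodness-of-fit panels
#'
#' Observed dilution vs population prediction (with identity line) and
#' CWRES vs population prediction.
#'
#' @param fit A `vk_fit`.
#' @return A list of two ggplot objects: `obs_vs_pred`, `cwres_vs_pred`.
#' @export
plot_gof <- function(fit) {
  need_ggplot()
  d <- gof_tables(fit)
  p1 <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pred_pop,
                                        y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(linetype = "dashed", colour = "goldenrod") +
    ggplot2::labs(x = "Population prediction", y = "Plasma dilution")
  p2 <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pred_pop, y = .data$cwres)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Population prediction", y = "CWRES")
  list(obs_vs_pred = p1, cwres_vs_pred = p2)
}

#' Predictive-check panel
#'
#' Observed dilutions overlaid on the 5/50/95 percentile prediction lines
#' and the confidence bands of the outer lines.
#'
#' @param vpc A `vk_vpc` from [predictive_check()].
#' @param data The `vk_estdata` used for the check.
#' @return A ggplot object.
#' @export
plot_vpc <- function(vpc, data) {
  need_ggplot()
  subjects <- if (inherits(data, "vk_estdata")) data$subjects else data
  obs <- do.call(rbind, lapply(subjects, function(s)
    data.frame(time = s$times, dilution = s$y)))
  b <- vpc$bands
  ggplot2::ggplot(b, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q5_lo, ymax = .data$q5_hi),
                         fill = "darkgreen", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q95_lo,
                                      ymax = .data$q95_hi),
                         fill = "darkgreen", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$q50), colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$q5), colour = "blue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$q95), colour = "blue") +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(x = .data$time, y = .data$dilution),
                        shape = 3, alpha = 0.5) +
    ggplot2::labs(x = "Time (min)", y = "Plasma dilution")
}

#' Fluid-comparison curves
#'
#' Central and peripheral expansion time courses for the four fluids.
#'
#' @param cmp A `vk_comparison` from [simulate_comparison()].
#' @return A ggplot object (facetted central/peripheral).
#' @export
plot_comparison <- function(cmp) {
  need_ggplot()
  d <- rbind(
    data.frame(fluid = cmp$curves$fluid, time = cmp$curves$time,
               expansion = cmp$curves$central_expansion, space = "central"),
    data.frame(fluid = cmp$curves$fluid, time = cmp$curves$time,
               expansion = cmp$curves$peripheral_expansion,
               space = "peripheral")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$expansion,
                                  colour = .data$fluid)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~space) +
    ggplot2::labs(x = "Time (min)", y = "Volume expansion (L)")
}
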