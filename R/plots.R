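#' Plot a trial
#'
#' Velocity traces (solid, left axis context) and the perceived risk with its
#' dynamic thresholds for both drivers over a trial. Replanning events are
#' marked on the velocity panel; the characteristic intermittent control
#' shows as piece-wise linear velocity segments.
#'
#' @param object A `cei_trial` from [run_trial()].
#' @param ... Unused.
#' @return A ggplot object (two facets: velocity, risk).
#' @export
autoplot.cei_trial <- function(object, ...) {
  log <- object$log
  vel <- tidyr::pivot_longer(
    dplyr::select(log, "t", left = "v_left", right = "v_right"),
    c("left", "right"), names_to = "driver", values_to = "value")
  vel$panel <- "velocity [m/s]"
  risk <- tidyr::pivot_longer(
    dplyr::select(log, "t", left = "risk_left", right = "risk_right"),
    c("left", "right"), names_to = "driver", values_to = "value")
  risk$panel <- "perceived risk"
  thr <- tidyr::pivot_longer(
    dplyr::select(log, "t",
                  left.upper = "rho_u_left", left.lower = "rho_l_left",
                  right.upper = "rho_u_right", right.lower = "rho_l_right"),
    -"t", names_to = c("driver", "bound"), names_sep = "\\.",
    values_to = "value")
  thr$panel <- "perceived risk"
  ev <- dplyr::bind_rows(
    tibble::tibble(t = log$t, driver = "left", event = log$event_left,
                   value = log$v_left),
    tibble::tibble(t = log$t, driver = "right", event = log$event_right,
                   value = log$v_right))
  ev <- dplyr::filter(ev, !.data$event %in% c("none", "initial"))
  ev$panel <- "velocity [m/s]"
  ggplot2::ggplot(dplyr::bind_rows(vel, risk),
                  ggplot2::aes(x = .data$t, y = .data$value,
                               colour = .data$driver)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_line(data = thr,
                       ggplot2::aes(linetype = .data$bound), na.rm = TRUE,
                       alpha = 0.5) +
    ggplot2::geom_point(data = ev, ggplot2::aes(shape = .data$event),
                        size = 2, na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = paste("condition", object$condition$label)) +
    ggplot2::theme_minimal()
}

#' Plot batch-level behavioral summaries
#'
#' Per-condition means of the merge gap (with interquartile ranges), the
#' probability that the left driver merges first (with 95% CIs), or the mean
#' absolute maximum velocity deviation.
#'
#' @param batch A `cei_batch` from [run_batch()].
#' @param measure `"gap"`, `"who_first"`, or `"deviation"`.
#' @return A ggplot object.
#' @export
plot_batch_summary <- function(batch,
                               measure = c("gap", "who_first", "deviation")) {
  measure <- match.arg(measure)
  sm <- batch_summary(batch, "condition")
  p <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$condition))
  if (measure == "gap") {
    p + ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean_gap,
                                              ymin = .data$gap_q25,
                                              ymax = .data$gap_q75)) +
      ggplot2::labs(y = "merge gap [m]", x = "condition") +
      ggplot2::theme_minimal()
  } else if (measure == "who_first") {
    p + ggplot2::geom_pointrange(ggplot2::aes(y = .data$p_left_first,
                                              ymin = .data$p_left_ci_lo,
                                              ymax = .data$p_left_ci_hi)) +
      ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
      ggplot2::labs(y = "P(left merges first)", x = "condition") +
      ggplot2::theme_minimal()
  } else {
    p + ggplot2::geom_col(ggplot2::aes(y = .data$mean_abs_max_dev)) +
      ggplot2::labs(y = "mean |max velocity deviation| [m/s]",
                    x = "condition") +
      ggplot2::theme_minimal()
  }
}
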