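#' Plot an SFSI table
#'
#' Bar chart of per-genotype SFSI in ascending order, with the population
#' reference line at SFSI = 1 and the check variety highlighted when the
#' table carries one.
#'
#' @param object An [sfsi_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfsi_table
#' @export
autoplot.sfsi_table <- function(object, ...) {
  d <- as_tibble(object)
  check_id <- attr(object, "check_id")
  d$is_check <- !is.null(check_id) & d$genotype == (check_id %||% "")
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$genotype, .data$sfsi),
    y = .data$sfsi, fill = .data$is_check
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35", `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Soil fertility susceptibility index",
      title = attr(object, "trait"),
      subtitle = sprintf("SI = %.2f; dashed line: population-average susceptibility", attr(object, "si"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a tolerance classification
#'
#' Scatter of percent reduction against SFSI, coloured by label, with the
#' check's SFSI and the table-mean PR as reference lines.
#'
#' @param object A [classify_tolerance()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tolerance_report
#' @export
autoplot.tolerance_report <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$sfsi, y = .data$pr_percent, colour = .data$label)
  ) +
    ggplot2::geom_vline(xintercept = attr(object, "check_sfsi"), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = thr$susceptible_sfsi_min, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = thr$mean_pr, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = "Soil fertility susceptibility index",
      y = "Reduction under low fertility (%)",
      colour = NULL,
      subtitle = sprintf(
        "dashed: check SFSI (%.2f) and mean PR; dotted: susceptibility threshold (%.2f)",
        attr(object, "check_sfsi"), thr$susceptible_sfsi_min
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot Dunnett comparisons against the check
#'
#' Estimated genotype-minus-check differences with approximate 95%
#' intervals (estimate +/- 2 standard errors), coloured by adjusted
#' significance band.
#'
#' @param object A [dunnett_vs_check()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dunnett_result
#' @export
autoplot.dunnett_result <- function(object, ...) {
  d <- as_tibble(object)
  d$band <- factor(ifelse(d$signif == "", "n.s.", d$signif),
    levels = c("***", "**", "*", "+", "n.s.")
  )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$genotype, .data$estimate),
    colour = .data$band
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(
        xmin = .data$estimate - 2 * .data$se,
        xmax = .data$estimate + 2 * .data$se
      ),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf(
        "Difference vs check '%s' under %s (g plant⁻¹)",
        attr(object, "check_id"), attr(object, "treatment")
      ),
      y = NULL, colour = "Adjusted p"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an SFSI recovery experiment
#'
#' True against mean estimated SFSI per genotype with the identity line;
#' vertical bars show +/- RMSE around the mean estimate.
#'
#' @param object A [recovery_experiment()] summary.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_summary
#' @export
autoplot.recovery_summary <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$true_sfsi, y = .data$mean_estimate)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_estimate - .data$rmse,
        ymax = .data$mean_estimate + .data$rmse
      ),
      width = 0
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "True SFSI", y = "Mean estimated SFSI",
      subtitle = sprintf("%d simulated trials; bars: RMSE", attr(object, "n_sims"))
    ) +
    ggplot2::theme_minimal()
}
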