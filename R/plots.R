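#' Plot a Vincentized quantile profile
#'
#' One line per condition, quantile RT against quantile probability —
#' the standard quantile-plot panel.
#'
#' @param object a [vincentize()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.quantile_profile <- function(object, ...) {
  by <- attr(object, "by")
  d <- tibble::as_tibble(object)
  d$condition <- do.call(paste, c(d[, by, drop = FALSE], sep = " / "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$prob, y = .data$quantile,
                                  colour = .data$condition,
                                  group = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Quantile", y = "RT (s)", colour = NULL,
                  title = "Vincentized quantile profile") +
    ggplot2::theme_minimal()
}

#' Plot a delta profile
#'
#' Quantile-wise condition difference against quantile probability,
#' with the per-subject spread shown as +/- 1 SE, and a zero reference
#' line — the standard delta-plot panel.
#'
#' @param object a [delta_profile()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.delta_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  subj <- attr(object, "subject_deltas")
  if (!is.null(subj) && nrow(subj) > 0) {
    se <- subj |>
      dplyr::group_by(.data$prob) |>
      dplyr::summarise(se = sd(.data$delta) / sqrt(dplyr::n()), .groups = "drop")
    d <- dplyr::left_join(d, se, by = "prob")
  } else {
    d$se <- NA_real_
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$prob, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$delta - .data$se,
                                      ymax = .data$delta + .data$se),
                         alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Quantile", y = "Delta RT (s)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot per-condition sensitivity and criterion
#'
#' Side-by-side panels of d' and the conventional criterion per
#' condition (plots always use the conventional sign of c, not the
#' reversed-sign model parameterisation).
#'
#' @param object a [dprime_criterion()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sdt_estimates <- function(object, ...) {
  by <- attr(object, "by")
  d <- tibble::as_tibble(object)
  d$condition <- do.call(paste, c(d[, by, drop = FALSE], sep = " / "))
  long <- tidyr::pivot_longer(d, c("dprime", "criterion"),
                              names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = c("dprime", "criterion"),
                         labels = c("d'", "criterion c"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::facet_wrap(~ .data$measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Recognition memory (SDT)") +
    ggplot2::theme_minimal()
}
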