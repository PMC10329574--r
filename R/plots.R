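#' Plot methods
#'
#' ggplot2 views of the report objects: the precision-recall curve, the
#' AP-vs-threshold sweep, the per-center metric panel (dot plot per center
#' and metric) and the clinician-agreement bar chart.
#'
#' @name plots
NULL

#' @rdname plots
#' @param object a `pv_pr_curve`.
#' @param ... unused.
#' @export
autoplot.pv_pr_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = criterion_label(attr(object, "criterion"))) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.pv_ap_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$threshold, y = .data$ap)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "IoU threshold", y = "AP", title = attr(object, "kind")) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.pv_center_panel <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$center_id != "all",
                      !is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5, colour = "grey60") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$center_id),
                         width = 0.12, height = 0, size = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Value", colour = "Center") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.pv_agreement <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("frac_useful_accepted", "frac_not_useful_rejected"),
                        names_to = "fraction", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$criterion, y = .data$value,
                                   fill = .data$fraction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Agreement fraction", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param x a report object.
#' @export
plot.pv_pr_curve <- function(x, ...) print(autoplot.pv_pr_curve(x, ...))
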