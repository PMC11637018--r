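# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training log of a fit
#'
#' @param x A `uamt_fit`.
#' @param ... Unused.
#' @return Long tibble: `step`, `epoch`, `component`, `value` for the
#'   supervised, consistency and total loss and the consistency weight.
#' @export
tidy.uamt_fit <- function(x, ...) {
  tidyr::pivot_longer(x$log,
                      cols = c("sup", "dice_loss", "ce", "con", "lambda",
                               "total"),
                      names_to = "component", values_to = "value")
}

#' One-row summary of a fit
#' @param x A `uamt_fit`.
#' @param ... Unused.
#' @return Tibble with step count, final loss components and model size.
#' @export
glance.uamt_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(steps = nrow(x$log), epochs = max(x$log$epoch),
                 final_sup = last$sup, final_con = last$con,
                 lambda_max = x$config$loss$lambda_max,
                 ema_decay = x$config$trainer$ema_decay,
                 n_params = count_params(x$student_params))
}

#' Tidy per-case metrics
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return Long tibble: `case_id`, `metric`, `value`.
#' @export
tidy.metric_report <- function(x, ...) {
  tidyr::pivot_longer(x$per_case, cols = c("dsc", "jaccard", "hd95", "asd"),
                      names_to = "metric", values_to = "value")
}

#' One-row aggregate of a metric report
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return Wide tibble of per-metric means and sds.
#' @export
glance.metric_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                             values_from = c("mean", "sd"), names_sep = "_")
  dplyr::mutate(wide, n_cases = nrow(x$per_case), units = x$units)
}

#' Training-curve plot
#' @param object A `uamt_fit`.
#' @param ... Unused.
#' @return A ggplot: loss components over training steps.
#' @export
autoplot.uamt_fit <- function(object, ...) {
  df <- dplyr::filter(tidy(object),
                      .data$component %in% c("sup", "con", "total"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "loss",
                  title = "Mean-teacher training losses") +
    ggplot2::theme_minimal()
}

#' Per-case metric plot
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot: per-case metric values with the aggregate mean.
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 3, shape = 18) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = paste0("value (", object$units, ")"),
                  title = "Per-case segmentation metrics") +
    ggplot2::theme_minimal()
}
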