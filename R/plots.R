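#' Kaplan-Meier step plot
#'
#' @param km A `km_fit` from [km_estimate()], or a named list of them
#'   (one curve per stratum).
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  if (inherits(km, "km_fit")) km <- list(all = km)
  dat <- purrr::imap_dfr(km, function(fit, name) {
    dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1, stratum = name),
      dplyr::mutate(fit$steps[, c("time", "surv")], stratum = name)
    )
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$stratum)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' HRD-index distribution with the classification threshold
#'
#' Histogram of cohort HRD indices with the high-HRD cutoff as a dashed
#' line; when a `trimodal_fit` is supplied its fitted boundary is drawn
#' too.
#'
#' @param metrics Per-sample tibble with an `hrd_index` column.
#' @param config An [hrd_config()].
#' @param trimodal Optional [fit_trimodal_cutoff()] result.
#' @return A ggplot object.
#' @export
plot_hrd_distribution <- function(metrics, config = hrd_config(),
                                  trimodal = NULL) {
  p <- ggplot2::ggplot(metrics, ggplot2::aes(x = .data$hrd_index)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = config$hrd_index_cutoff,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "HRD index (LOH + TAI + LST)", y = "Samples") +
    ggplot2::theme_minimal()
  if (!is.null(trimodal)) {
    p <- p + ggplot2::geom_vline(xintercept = trimodal$cutoff,
                                 linetype = "dotted", colour = "steelblue")
  }
  p
}

#' Mutational catalog bar plot
#'
#' @param catalog A `mutational_catalog` tibble.
#' @return A ggplot object.
#' @export
plot_catalog <- function(catalog) {
  dat <- dplyr::mutate(catalog,
                       channel = factor(.data$channel, levels = .data$channel))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$channel, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Mutations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 4,
                                                       vjust = 0.5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.km_fit <- function(object, ...) plot_km(object)

#' @exportS3Method ggplot2::autoplot
autoplot.hrd_cohort <- function(object, ...) {
  plot_hrd_distribution(object$metrics, object$config, object$trimodal)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
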