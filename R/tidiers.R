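#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the four cohort tests
#'
#' @param x A `gf_cohort_result` from [run_cohort_tests()].
#' @param ... Unused.
#' @return A tibble with one row per test: `test`, `statistic`, `p_value`,
#'   `n`, `method`.
#' @export
tidy.gf_cohort_result <- function(x, ...) {
  x$tests
}

#' One-row summary of a cohort analysis
#'
#' @param x A `gf_cohort_result`.
#' @param ... Unused.
#' @return A one-row tibble with sample counts and the four p-values
#'   (`p_rs_V1`, `p_rs_V2`, `p_sr_responders`, `p_sr_nonresponders`).
#' @export
glance.gf_cohort_result <- function(x, ...) {
  p <- stats::setNames(x$tests$p_value, paste0("p_", x$tests$test))
  dplyr::bind_cols(
    tibble(
      n_samples = nrow(x$per_sample),
      n_undefined_rate = x$excluded$undefined_rate,
      n_unlabelled_patients = x$excluded$unlabelled_patients
    ),
    as_tibble(as.list(p))
  )
}

#' Plot butyrate production rates by group and visit
#'
#' `type = "group"` shows the cross-sectional comparison (boxplots of
#' responders vs nonresponders, faceted by visit); `type = "paired"` shows
#' the longitudinal comparison (V1-V2 trajectories, one line per patient,
#' faceted by response group).
#'
#' @param object A `gf_cohort_result`.
#' @param type `"group"` or `"paired"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gf_cohort_result <- function(object, type = c("group", "paired"),
                                      ...) {
  type <- match.arg(type)
  d <- dplyr::filter(object$per_sample, !is.na(.data$butyrate_rate),
                     !is.na(.data$response_group))
  if (type == "group") {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$response_group,
                                    y = .data$butyrate_rate,
                                    fill = .data$response_group)) +
      ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
      ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.6) +
      ggplot2::facet_wrap(ggplot2::vars(.data$visit)) +
      ggplot2::labs(x = NULL, y = "predicted butyrate production rate",
                    fill = NULL) +
      ggplot2::theme_bw() +
      ggplot2::theme(legend.position = "none")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$visit,
                                    y = .data$butyrate_rate)) +
      ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                         alpha = 0.4, colour = "grey40") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$visit), size = 1) +
      ggplot2::facet_wrap(ggplot2::vars(.data$response_group)) +
      ggplot2::labs(x = NULL, y = "predicted butyrate production rate") +
      ggplot2::theme_bw() +
      ggplot2::theme(legend.position = "none")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
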