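#' VAF histogram of a sample's (or cohort's) variant records
#'
#' The diagnostic plot behind the barcode method: germline heterozygotes
#' form a symmetric peak around VAF 0.5, sequencing artifacts a bump near
#' zero, and an expanded clone a shoulder at half its cell fraction.  The
#' three analysis windows are shaded.
#'
#' @param variants Variant tibble with `depth` and `alt_reads`.
#' @param binwidth Histogram bin width on the VAF axis.
#' @param windows A [vaf_windows()] table.
#' @return A ggplot object.
#' @export
plot_vaf_profile <- function(variants, binwidth = 0.01,
                             windows = vaf_windows()) {
  df <- dplyr::mutate(variants, vaf = .data$alt_reads / .data$depth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vaf)) +
    ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue4") +
    ggplot2::labs(x = "variant allele fraction", y = "variants") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.germline_ratio_model
#' @export
autoplot.germline_ratio_model <- function(object, ...) {
  ggplot2::ggplot(object$ratios,
                  ggplot2::aes(x = .data$depth, y = .data$ratio,
                               colour = .data$center)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$source)) +
    ggplot2::labs(x = "read depth",
                  y = "HIGH / MID germline count ratio",
                  title = "Germline contamination ratio model") +
    ggplot2::theme_minimal()
}

#' Plot methods for fitted objects
#'
#' `autoplot.germline_ratio_model()` draws the fitted r(center, depth)
#' curves; `autoplot.ivw_fit()` draws the instrument effects with the
#' origin-constrained IVW line; `plot_ch_calls()` shows the estimated
#' somatic count distribution against the effective threshold.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot.germline_ratio_model
#' @export
autoplot.ivw_fit <- function(object, ...) {
  eff <- object$effects
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$beta_exposure,
                                    y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - 1.96 * .data$se_outcome,
      ymax = .data$beta_outcome + 1.96 * .data$se_outcome
    ), width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_exposure - 1.96 * .data$se_exposure,
      xmax = .data$beta_exposure + 1.96 * .data$se_exposure
    ), height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = object$slope,
                         colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "exposure effect", y = "outcome effect",
                  title = sprintf("IVW slope %.3g (p = %.2g)",
                                  object$slope, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.germline_ratio_model
#' @param ch_calls Tibble from [call_ch()].
#' @export
plot_ch_calls <- function(ch_calls, ...) {
  ggplot2::ggplot(ch_calls,
                  ggplot2::aes(x = .data$estimated_somatic,
                               fill = .data$is_ch)) +
    ggplot2::geom_histogram(bins = 60, boundary = 0) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~center) +
    ggplot2::labs(x = "estimated somatic singletons (VAF 0.10-0.25)",
                  y = "samples", fill = "CH call") +
    ggplot2::theme_minimal()
}
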