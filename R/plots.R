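#' Plot optimizer convergence with mean +/- sd bands
#'
#' @param object A `convergence_report` tibble (see
#'   [convergence_report()]).
#' @param ... Unused.
#' @return A ggplot object: per-generation mean best fitness with a
#'   one-standard-deviation ribbon.
#' @export
autoplot.convergence_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "Generation", y = "Best fitness (-logLik)",
                  title = "Optimizer convergence (mean ± sd)") +
    ggplot2::theme_minimal()
}

#' Overlay a clean, noisy and denoised signal
#'
#' @param clean,noisy,denoised Tidy signal tibbles on a common time
#'   grid (`noisy` optional).
#' @return A ggplot object, one facet per trace.
#' @export
plot_denoise <- function(clean, denoised, noisy = NULL) {
  frames <- list(clean = clean, denoised = denoised)
  if (!is.null(noisy)) frames$noisy <- noisy
  df <- dplyr::bind_rows(lapply(names(frames), function(nm)
    tibble(time = frames[[nm]]$time, value = frames[[nm]]$value,
           trace = nm)))
  df$trace <- factor(df$trace, levels = c("clean", "noisy", "denoised"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$trace)) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude") +
    ggplot2::theme_minimal()
}

#' Bar chart of benchmark output SNR by method
#'
#' @param object A `denoise_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object with mean output SNR and sd error bars.
#' @export
autoplot.denoise_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$method, y = .data$snr_db_mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$snr_db_mean - .data$snr_db_sd,
      ymax = .data$snr_db_mean + .data$snr_db_sd), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Output SNR (dB)",
                  title = sprintf("Denoising benchmark (%s)",
                                  object$modality)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
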