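# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs scale_color_manual facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a reflectance spectrum
#'
#' @param object A `reflectance_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reflectance_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$wavelength, y = .data$R)) +
    geom_line(color = "steelblue") +
    labs(x = "Wavelength (nm)", y = "Reflectance",
         title = "Multilayer reflectance spectrum")
}

#' Plot an absorption spectrum
#'
#' @param object An `absorption_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.absorption_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$wavelength, y = .data$intensity)) +
    geom_line(color = "darkorange") +
    labs(x = "Wavelength (nm)", y = "Intensity (a.u.)",
         title = "Broadened absorption spectrum")
}

#' Plot an ROI color trace
#'
#' Per-frame mean R, G and B over the region of interest, against time.
#'
#' @param object An `roi_trace` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roi_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("R", "G", "B"),
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c("R", "G", "B"))
  ggplot(long, aes(x = .data$time_s, y = .data$value,
                   color = .data$channel)) +
    geom_line() + geom_point() +
    scale_color_manual(values = c(R = "red3", G = "green4", B = "blue3")) +
    labs(x = "Time (s)", y = "Mean channel intensity (0-255)",
         title = "ROI color dynamics")
}

#' Plot a titration fit
#'
#' Observed points with the fitted two-state curve.
#'
#' @param object A `titration_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.titration_fit <- function(object, ...) {
  grid <- seq(min(object$data$pH), max(object$data$pH), length.out = 200)
  curve <- titration_model(grid, object$pK, object$A_acid, object$A_base,
                           object$n)
  ggplot(object$data, aes(x = .data$pH, y = .data$absorbance)) +
    geom_point() +
    geom_line(data = curve, color = "steelblue") +
    labs(x = "pH", y = "Absorbance",
         title = sprintf("Two-state titration fit (pK = %.2f)", object$pK))
}

#' Plot per-sample functional-category percentages
#'
#' @param breakdown Output of [category_percentages()].
#' @return A ggplot.
#' @export
plot_category_breakdown <- function(breakdown) {
  ggplot(breakdown, aes(x = .data$category, y = .data$percent)) +
    geom_col(fill = "grey40") +
    facet_wrap(~sample) +
    labs(x = NULL, y = "% of peptides") +
    ggplot2::coord_flip()
}
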