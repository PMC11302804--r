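# Figure-style visualisation of the pooled dose-difference histograms.

#' Plot pooled dose-difference histograms with Gaussian fits
#'
#' Six-panel display (two algorithms by full/lateral/inferior region) of
#' the pooled calculated-minus-measured histograms, each overlaid with its
#' fitted Gaussian and annotated with mean and SD. Requires ggplot2.
#'
#' @param bundle a `report_bundle` from [run_pipeline()] (film stage on).
#' @return A ggplot object.
#' @export
plot_dose_difference_histograms <- function(bundle) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (is.null(bundle$histograms))
    stop("bundle has no histograms (film stage disabled?)")
  hh <- do.call(rbind, lapply(names(bundle$histograms), function(k) {
    h <- bundle$histograms[[k]]
    parts <- strsplit(k, "_(?=[^_]+$)", perl = TRUE)[[1]]
    data.frame(algorithm = parts[1], region = parts[2],
               mid = h$mids, count = h$counts)
  }))
  ff <- do.call(rbind, lapply(names(bundle$gaussian_fits), function(k) {
    f <- bundle$gaussian_fits[[k]]
    parts <- strsplit(k, "_(?=[^_]+$)", perl = TRUE)[[1]]
    xs <- seq(min(hh$mid), max(hh$mid), length.out = 200)
    data.frame(algorithm = parts[1], region = parts[2], x = xs,
               y = f$amplitude * exp(-(xs - f$mean)^2 / (2 * f$sd^2)),
               label = sprintf("%.1f +/- %.1f%%", f$mean, f$sd))
  }))
  hh$region <- factor(hh$region, c("full", "lateral", "inferior"))
  ff$region <- factor(ff$region, c("full", "lateral", "inferior"))
  ggplot2::ggplot(hh, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey70") +
    ggplot2::geom_line(data = ff[!is.na(ff$y), ],
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "red") +
    ggplot2::geom_text(data = unique(ff[, c("algorithm", "region",
                                            "label")]),
                       ggplot2::aes(label = .data$label),
                       x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                       colour = "red", size = 3, inherit.aes = FALSE) +
    ggplot2::facet_grid(algorithm ~ region) +
    ggplot2::labs(x = "calculated - measured dose (% of prescription)",
                  y = "pixel count") +
    ggplot2::theme_minimal()
}
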