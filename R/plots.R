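#' 2-D droplet scatter plot
#'
#' Standard two-channel droplet plot (HEX amplitude on the x axis, FAM on
#' the y axis), optionally with the threshold cutoffs drawn and droplets
#' coloured by their called group.
#'
#' @param droplets Tibble with `fam` and `hex` columns.
#' @param t Optional [thresholds()] row.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_droplets <- function(droplets, t = NULL, alpha = 0.3) {
  p <- ggplot2::ggplot(droplets, ggplot2::aes(x = .data$hex, y = .data$fam))
  if (!is.null(t)) {
    droplets <- mutate(droplets, group = dplyr::case_when(
      .data$fam > t$fam_cutoff & .data$hex > t$hex_cutoff ~ "FAM+/HEX+",
      .data$fam > t$fam_cutoff ~ "FAM+/HEX-",
      .data$hex > t$hex_cutoff ~ "FAM-/HEX+",
      .default = "FAM-/HEX-"
    ))
    p <- ggplot2::ggplot(droplets,
                         ggplot2::aes(x = .data$hex, y = .data$fam,
                                      colour = .data$group)) +
      ggplot2::geom_hline(yintercept = t$fam_cutoff, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = t$hex_cutoff, linetype = "dashed")
  }
  p + ggplot2::geom_point(alpha = alpha, size = 0.4) +
    ggplot2::labs(x = "HEX amplitude", y = "FAM amplitude",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' Copy-number estimates against aCGH-assigned copy number
#'
#' Boxplots of per-sample ddPCR estimates per aCGH copy-number group with
#' the linear regression trend line, the standard visual for comparing
#' the two methods.
#'
#' @param samples Tibble with `cn_estimate` and `acgh_cn`.
#' @return A ggplot object.
#' @export
plot_cn_concordance <- function(samples) {
  samples <- filter(samples, !is.na(.data$acgh_cn))
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$acgh_cn,
                                        y = .data$cn_estimate)) +
    ggplot2::geom_boxplot(ggplot2::aes(group = .data$acgh_cn),
                          outlier.shape = NA, width = 0.6) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "aCGH-assigned copy number",
                  y = "ddPCR copy-number estimate") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cn_concordance
#' @param object A `cn_concordance` result.
#' @param ... Unused.
#' @method autoplot cn_concordance
#' @export
autoplot.cn_concordance <- function(object, ...) {
  plot_cn_concordance(object$samples)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
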