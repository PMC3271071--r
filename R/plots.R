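## ggplot2 graphics: Ramachandran scatter/histograms, MAE by
## observed-angle bin, and the chain-level CC distribution.

#' Ramachandran plot
#'
#' Scatter of (phi, psi) coloured by secondary structure (with proline
#' separated when residue identities are available), the classic view
#' of the SS-specific angle clusters.
#'
#' @param data per-residue tibble with columns `phi`, `psi` and
#'   optionally `ss` and `aa`.
#' @return a ggplot object.
#' @export
plot_ramachandran <- function(data) {
  stopifnot(all(c("phi", "psi") %in% names(data)))
  data <- filter(data, !is.na(.data$phi), !is.na(.data$psi))
  if ("ss" %in% names(data)) {
    data <- mutate(data, group = dplyr::case_when(
      ("aa" %in% names(data)) & .data$aa == "P" ~ "proline",
      .data$ss == "H" ~ "helix",
      .data$ss == "E" ~ "strand",
      TRUE ~ "coil"))
  } else {
    data <- mutate(data, group = "residue")
  }
  ggplot2::ggplot(data, ggplot2::aes(.data$phi, .data$psi,
                                     colour = .data$group)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 60)) +
    ggplot2::scale_y_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 60)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(phi ~ "(degrees)"),
                  y = expression(psi ~ "(degrees)"), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Angle histogram
#'
#' @param data per-residue tibble.
#' @param which `"phi"` or `"psi"`.
#' @param binwidth histogram bin width in degrees.
#' @return a ggplot object.
#' @export
plot_angle_histogram <- function(data, which = c("phi", "psi"),
                                 binwidth = 10) {
  which <- match.arg(which)
  data <- filter(data, !is.na(.data[[which]]))
  ggplot2::ggplot(data, ggplot2::aes(.data[[which]])) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = -180,
                            fill = "steelblue", colour = "white") +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 60)) +
    ggplot2::labs(x = paste(which, "(degrees)"), y = "residues") +
    ggplot2::theme_minimal()
}

#' @method autoplot torsion_report
#' @export
autoplot.torsion_report <- function(object, ...) {
  bins <- filter(object$strata, .data$stratification == "angle_bin") |>
    mutate(mid = as.numeric(.data$stratum))
  ggplot2::ggplot(bins, ggplot2::aes(.data$mid, .data$mae)) +
    ggplot2::geom_col(width = 18, fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 60)) +
    ggplot2::labs(
      x = sprintf("observed %s (degrees, 20-degree bins)",
                  object$angle %||% "angle"),
      y = sprintf("MAE (degrees, %s)", object$mode)) +
    ggplot2::theme_minimal()
}

#' Chain-level correlation distribution
#'
#' @param report a `torsion_report` from [evaluate_predictions()].
#' @return a ggplot object (histogram of per-chain CC).
#' @export
plot_chain_cc <- function(report) {
  stopifnot(inherits(report, "torsion_report"))
  chains <- filter(report$strata, .data$stratification == "chain",
                   !is.na(.data$cc))
  ggplot2::ggplot(chains, ggplot2::aes(.data$cc)) +
    ggplot2::geom_histogram(binwidth = 0.1, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "per-chain Pearson CC", y = "chains") +
    ggplot2::theme_minimal()
}
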