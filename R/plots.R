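# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reconstructed free-energy profile
#'
#' @param object A `qdh_fes` tibble.
#' @param minima Optionally a [find_minima()] tibble to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qdh_fes <- function(object, minima = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$angle, y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 60)) +
    ggplot2::labs(
      x = "angular position (deg)", y = "free energy (kcal/mol)",
      title = "Reconstructed free-energy profile"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(minima) && nrow(minima) > 0) {
    p <- p + ggplot2::geom_point(
      data = minima,
      ggplot2::aes(x = .data$position, y = .data$value),
      color = "red", size = 2
    )
  }
  p
}

#' Plot a melting curve with its two-state fit
#'
#' @param object A `qdh_melt_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qdh_melt_fit <- function(object, ...) {
  d <- object$curve
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature, y = .data$ellipticity)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$tm, linetype = 2, color = "red") +
    ggplot2::labs(
      x = "temperature (°C)", y = "ellipticity",
      title = sprintf("Two-state melting fit: Tm = %.1f °C", object$tm)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    d$fitted <- as.numeric(predict(object$fit))
    p <- p + ggplot2::geom_line(
      data = d, ggplot2::aes(y = .data$fitted),
      color = "blue"
    )
  }
  p
}

#' Plot a structure model projected onto a plane
#'
#' A quick diagnostic scatter of atom positions, colored by residue role
#' (quartet, pair, other, ligand) when a topology is attached.
#'
#' @param structure A single-model structure tibble.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @return A ggplot.
#' @export
plot_structure <- function(structure, plane = c("xy", "xz", "yz")) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  topo <- attr(structure, "topology")
  role <- rep("other", nrow(structure))
  if (!is.null(topo)) {
    role[structure$resid %in% unlist(topo$quartets)] <- "quartet"
    role[structure$resid %in% unlist(topo$wc_pairs)] <- "duplex"
  }
  role[structure$ligand] <- "ligand"
  d <- mutate(structure, role = role)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data[[ax[1]]], y = .data[[ax[2]]], color = .data$role
  )) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = paste(ax[1], "(Å)"), y = paste(ax[2], "(Å)")
    ) +
    ggplot2::theme_minimal()
}
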