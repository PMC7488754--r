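#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' Time courses of the three pools on one panel.
#'
#' @param object A `dde_trajectory`.
#' @param from Start of the plotted window (default 0).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dde_trajectory <- function(object, from = 0, ...) {
  df <- object |>
    tibble::as_tibble() |>
    dplyr::filter(.data$t >= from) |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "pool",
                        values_to = "concentration")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$concentration,
                                   colour = .data$pool)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (min)", y = "concentration",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a crossing set
#'
#' Poincaré crossing ordinates against crossing time; a finite set of
#' horizontal levels indicates a cycle, a band an irregular attractor.
#'
#' @param object A `crossing_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossing_set <- function(object, ...) {
  sec <- attr(object, "section")
  ord <- if (!is.null(sec) && sec$variable == "y") "x" else "y"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$t, .data[[ord]])) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "crossing time (min)", y = paste(ord, "at crossing")) +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram
#'
#' Crossing ordinates of every attractor branch against the scanned
#' parameter; branches are colour-coded.
#'
#' @param object A `bifurcation_diagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bifurcation_diagram <- function(object, ...) {
  spec <- attr(object, "spec")
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$ordinate))
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$ordinate,
                                   colour = factor(.data$branch))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = spec$parameter, y = "crossing ordinate") +
    ggplot2::theme_minimal()
}

#' Plot a regime table as a tile map
#'
#' @param tab A `regime_table`.
#' @return A ggplot object.
#' @export
plot_regime_table <- function(tab) {
  df <- tibble::as_tibble(tab) |>
    dplyr::mutate(row = sprintf("h_b=%g, k_x=%g", .data$h_b, .data$k_x),
                  col = sprintf("K_a=%g\nk_rz=%g", .data$K_a, .data$k_rz))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$symbol)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$symbol), size = 3) +
    ggplot2::labs(x = NULL, y = NULL, fill = "regime") +
    ggplot2::theme_minimal()
}
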