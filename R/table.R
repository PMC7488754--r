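#' Regime table over a parameter grid
#'
#' Recomputes, cell by cell, the regime summary tables: for a fixed synthesis
#' nonlinearity `h_x`, every combination of `(h_b, k_x)` rows with
#' `K_a` and `k_rz` columns is classified by a multi-start attractor census
#' (with `k_dz = 1 - k_rz`) and rendered in the table alphabet
#' `S, 0, P, 2P, ..., QP, C, P+C`. Cells whose census resolves nothing are
#' rendered `UNRESOLVED`, never coerced.
#'
#' @param h_x Synthesis Hill coefficient for the whole table.
#' @param h_b_values,k_x_values Row axes (defaults: the studied grids
#'   5/10/15/20 and 10/20/40).
#' @param K_a_values,k_rz_values Column axes (defaults 1/2/3 and 0/0.5/1).
#' @param k_b Maximum FMRP phosphorylation rate held fixed (default 200).
#' @param base_p,base_d Base configuration; delays default to
#'   `tau_a = 1, tau_b = 2, tau_r = 3, tau_e = 3`.
#' @param n_starts,seed,settings,tolerances,section Census controls; see
#'   [attractor_census()].
#' @return A tibble of class `regime_table`, one row per cell: `h_b`, `k_x`,
#'   `K_a`, `k_rz`, `symbol`, `n_attractors`.
#' @export
regime_table <- function(h_x, h_b_values = c(5, 10, 15, 20),
                         k_x_values = c(10, 20, 40),
                         K_a_values = c(1, 2, 3),
                         k_rz_values = c(0, 0.5, 1),
                         k_b = 200,
                         base_p = model_params(),
                         base_d = delay_params(1, 2, 3, 3),
                         n_starts = 12, seed = 0,
                         settings = integration_settings(),
                         tolerances = regime_tolerances(),
                         section = poincare_section()) {
  grid <- expand.grid(k_rz = k_rz_values, K_a = K_a_values,
                      k_x = k_x_values, h_b = h_b_values)
  cells <- purrr::pmap(grid, function(k_rz, K_a, k_x, h_b) {
    p <- set_params(base_p, h_x = h_x, h_b = h_b, k_x = k_x, K_a = K_a,
                    k_b = k_b)
    p <- with_recycling(p, k_rz)
    cen <- tryCatch(
      attractor_census(p, base_d, section, n_starts, seed,
                       settings = settings, tolerances = tolerances),
      error = function(e) NULL
    )
    tibble::tibble(
      h_b = h_b, k_x = k_x, K_a = K_a, k_rz = k_rz,
      symbol = if (is.null(cen)) "UNRESOLVED" else regime_symbol(cen),
      n_attractors = if (is.null(cen)) NA_integer_ else
        sum(cen$category != "UNRESOLVED")
    )
  })
  out <- dplyr::bind_rows(cells)
  structure(out, class = c("regime_table", class(out)), h_x = h_x)
}

#' Render a regime table in the wide row/column layout
#'
#' One row per `(h_b, k_x)` pair, one column per `(K_a, k_rz)` combination,
#' mirroring the printed summary tables cell for cell.
#'
#' @param tab A `regime_table`.
#' @return A wide tibble.
#' @export
format_regime_table <- function(tab) {
  tab |>
    tibble::as_tibble() |>
    dplyr::mutate(col = sprintf("Ka=%g,krz=%g", .data$K_a, .data$k_rz)) |>
    dplyr::select("h_b", "k_x", "col", "symbol") |>
    tidyr::pivot_wider(names_from = "col", values_from = "symbol")
}
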