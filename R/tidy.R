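#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a regime label
#'
#' @param x A `regime_label`.
#' @param ... Unused.
#' @return One-row tibble: `category`, `multiplicity`, `amplitude`,
#'   `sensitive`, `n_clusters`.
#' @export
tidy.regime_label <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    category = x$category,
    multiplicity = x$multiplicity,
    amplitude = d$amplitude,
    sensitive = if (is.null(d$sensitive)) NA else d$sensitive,
    n_clusters = if (is.null(d$cluster_trace)) NA_integer_ else
      as.integer(d$cluster_trace[["full"]])
  )
}

#' Tidy / summarize an attractor census
#'
#' `tidy()` returns the per-attractor rows with ordinates unnested;
#' `glance()` one row with the attractor count and the census symbol.
#'
#' @param x An `attractor_census`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.attractor_census <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::unnest_longer("ordinates", values_to = "ordinate",
                         keep_empty = TRUE)
}

#' @rdname tidy.attractor_census
#' @export
glance.attractor_census <- function(x, ...) {
  tibble::tibble(
    n_attractors = sum(x$category != "UNRESOLVED"),
    n_unresolved = sum(x$category == "UNRESOLVED"),
    symbol = regime_symbol(x)
  )
}

#' Glance at a bifurcation diagram
#'
#' @param x A `bifurcation_diagram`.
#' @param ... Unused.
#' @return One row per regime block along the scanned axis: `symbol`,
#'   `from`, `to` (grid extent over which the per-value symbol is constant).
#' @export
glance.bifurcation_diagram <- function(x, ...) {
  s <- summarize_diagram(x)
  blocks <- rle(s$symbol)
  ends <- cumsum(blocks$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  tibble::tibble(symbol = blocks$values,
                 from = s$value[starts], to = s$value[ends])
}
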