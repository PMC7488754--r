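#' Poincaré section
#'
#' A plane `variable = level` in the (x, y, z) phase space, with a crossing
#' direction filter. The bifurcation studies use `x = 2` by default; levels
#' 1, 1.5, 2.3, 2.5 appear for settings whose attractor misses the default
#' plane.
#'
#' @param variable One of `"x"`, `"y"`, `"z"`.
#' @param level Finite section level (concentration).
#' @param direction `"increasing"`, `"decreasing"` or `"both"`.
#' @return An object of class `poincare_section`.
#' @export
poincare_section <- function(variable = "x", level = 2,
                             direction = c("increasing", "decreasing",
                                           "both")) {
  variable <- match.arg(variable, c("x", "y", "z"))
  direction <- match.arg(direction)
  if (!is.finite(level)) stop("section level must be finite", call. = FALSE)
  structure(list(variable = variable, level = level, direction = direction),
            class = "poincare_section")
}

#' Crossings of a trajectory with a Poincaré section
#'
#' Locates sign changes of `variable - level` between consecutive record
#' nodes after the transient cutoff, refines each crossing instant by linear
#' interpolation of the bracketing segment (error O(h^2)), applies the
#' direction filter, and interpolates the remaining coordinates at the
#' refined instants. An empty result is legitimate: some attractors never
#' reach the chosen plane.
#'
#' @param traj A `dde_trajectory` (or any tibble with columns t, x, y, z).
#' @param section A [poincare_section()].
#' @param t_transient Discard all crossings at `t <= t_transient`; default
#'   half of the recorded span.
#' @return A tibble of class `crossing_set` with columns `t`, `x`, `y`, `z`
#'   (the section variable held at `level`), sorted by `t`.
#' @export
poincare_crossings <- function(traj, section = poincare_section(),
                               t_transient = NULL) {
  stopifnot(inherits(section, "poincare_section"))
  if (is.null(t_transient)) t_transient <- max(traj$t) / 2
  if (t_transient < 0) stop("t_transient must be >= 0", call. = FALSE)
  keep <- traj$t >= t_transient
  tt <- traj$t[keep]
  v <- traj[[section$variable]][keep]
  g <- v - section$level
  n <- length(g)
  empty <- tibble::tibble(t = numeric(0), x = numeric(0), y = numeric(0),
                          z = numeric(0))
  if (n < 2) {
    return(structure(empty, class = c("crossing_set", class(empty)),
                     section = section, t_transient = t_transient))
  }
  i <- which(g[-n] * g[-1] < 0 | (g[-n] == 0 & g[-1] != 0))
  if (section$direction == "increasing") i <- i[g[i + 1] > g[i]]
  if (section$direction == "decreasing") i <- i[g[i + 1] < g[i]]
  if (length(i) == 0) {
    return(structure(empty, class = c("crossing_set", class(empty)),
                     section = section, t_transient = t_transient))
  }
  frac <- -g[i] / (g[i + 1] - g[i])
  tc <- tt[i] + frac * (tt[i + 1] - tt[i])
  lin <- function(col) {
    w <- traj[[col]][keep]
    w[i] + frac * (w[i + 1] - w[i])
  }
  out <- tibble::tibble(t = tc, x = lin("x"), y = lin("y"), z = lin("z"))
  out[[section$variable]] <- section$level
  structure(out, class = c("crossing_set", class(out)),
            section = section, t_transient = t_transient)
}

# One-dimensional agglomerative clustering by gap splitting: sorted values
# are cut wherever consecutive points are farther apart than tol. Returns
# integer cluster ids aligned with the input order.
.cluster_1d <- function(v, tol) {
  if (length(v) == 0) return(integer(0))
  o <- order(v)
  s <- v[o]
  cut <- c(0, cumsum(diff(s) > tol))
  id <- integer(length(v))
  id[o] <- cut + 1L
  id
}

.cluster_centers <- function(v, id) {
  as.numeric(tapply(v, id, mean))
}
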