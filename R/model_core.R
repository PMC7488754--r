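#' Generalized Hill rate
#'
#' The saturating control law \eqn{f(u) = k_0 + k (u/K)^h / (1 + (u/K)^h)}
#' used for translation activation, suppression and receptor
#' synthesis/incorporation. Monotone nondecreasing in `u` and bounded in
#' `[k0, k0 + k]`.
#'
#' @param u Controlling concentration (vectorized, >= 0).
#' @param k0 Constitutive (basal) rate.
#' @param k Maximum signal-dependent rate increment.
#' @param K Half-saturation concentration (> 0); `hill_rate(K, ...)` equals
#'   `k0 + k/2`.
#' @param h Hill coefficient (>= 1); sets the steepness of the response.
#' @return Numeric vector of rates, same length as `u`.
#' @examples
#' hill_rate(0, k0 = 1, k = 200, K = 3, h = 15)   # basal rate
#' hill_rate(3, k0 = 1, k = 200, K = 3, h = 15)   # half-saturation
#' @export
hill_rate <- function(u, k0, k, K, h) {
  if (any(K <= 0)) stop("half-saturation K must be positive", call. = FALSE)
  if (any(h < 1)) stop("Hill coefficient h must be >= 1", call. = FALSE)
  if (any(u < 0)) stop("controlling concentration u must be >= 0",
                       call. = FALSE)
  r <- (u / K)^h
  out <- k0 + k * r / (1 + r)
  out[is.infinite(r)] <- k0 + k
  out
}

#' Right-hand side of the delayed model
#'
#' Evaluates the instantaneous derivatives given the current state and the
#' four lagged values the circuit reads: the receptor pool at the activation
#' and suppression lags (`x_lag_a`, `x_lag_b`), the FMRP pool at the
#' translation lag (`y_lag_e`), and the endosomal pool at the recycling lag
#' (`z_lag_r`):
#' \deqn{dx/dt = f_x(y(t-\tau_e)) + k_{rz} z(t-\tau_r) - (k_{rx}+k_{dx}) x}
#' \deqn{dy/dt = f_a(x(t-\tau_a)) (y_0 - y) - f_b(x(t-\tau_b)) y}
#' \deqn{dz/dt = k_{rx} x - (k_{rz}+k_{dz}) z}
#'
#' @param state Named numeric triple `c(x=, y=, z=)`, nonnegative.
#' @param x_lag_a,x_lag_b,y_lag_e,z_lag_r Lagged concentrations (>= 0).
#' @param p A [model_params()] object.
#' @return Named numeric triple of derivatives `(dx, dy, dz)`.
#' @export
model_rhs <- function(state, x_lag_a, x_lag_b, y_lag_e, z_lag_r, p) {
  vals <- c(state, x_lag_a, x_lag_b, y_lag_e, z_lag_r)
  if (any(vals < 0)) stop("states and lagged values must be nonnegative",
                          call. = FALSE)
  x <- state[["x"]]; y <- state[["y"]]; z <- state[["z"]]
  dx <- hill_rate(y_lag_e, p$k_x0, p$k_x, p$K_x, p$h_x) +
    p$k_rz * z_lag_r - (p$k_rx + p$k_dx) * x
  dy <- hill_rate(x_lag_a, p$k_a0, p$k_a, p$K_a, p$h_a) * (p$y0 - y) -
    hill_rate(x_lag_b, p$k_b0, p$k_b, p$K_b, p$h_b) * y
  dz <- p$k_rx * x - (p$k_rz + p$k_dz) * z
  c(dx = dx, dy = dy, dz = dz)
}

# Scalar fixed-point residual in x*. Delays drop out at equilibrium, so the
# fixed points satisfy
#   z* = k_rx x* / (k_rz + k_dz)
#   y* = f_a(x*) y0 / (f_a(x*) + f_b(x*))
#   g(x*) = f_x(y*) + k_rz z* - (k_rx + k_dx) x* = 0.
.equilibrium_residual <- function(x, p) {
  denom <- p$k_rz + p$k_dz
  z <- if (denom > 0) p$k_rx * x / denom else 0
  fa <- hill_rate(x, p$k_a0, p$k_a, p$K_a, p$h_a)
  fb <- hill_rate(x, p$k_b0, p$k_b, p$K_b, p$h_b)
  y <- ifelse(fa + fb > 0, fa * p$y0 / (fa + fb), 0)
  hill_rate(y, p$k_x0, p$k_x, p$K_x, p$h_x) + p$k_rz * z -
    (p$k_rx + p$k_dx) * x
}

#' Equilibria of the model (delay-independent)
#'
#' At a fixed point the delayed arguments equal the state, so the equilibrium
#' system is the zero-derivative algebra of the instantaneous vector field.
#' The `z` and `y` equations solve explicitly in terms of `x*`, leaving a
#' scalar residual in `x*` which is scanned for sign changes on a grid and
#' refined by bisection ([stats::uniroot()]).
#'
#' If the endosomal outflow `k_rz + k_dz` is zero, an equilibrium requires
#' `x* = 0` (otherwise `z` grows without bound); only the origin branch is
#' then considered.
#'
#' @param p A [model_params()] object.
#' @param x_max Upper end of the `x*` search interval.
#' @param grid_n Number of grid points for the sign scan (>= 2).
#' @param tol Residual tolerance passed to the bisection refinement.
#' @return A tibble with columns `x`, `y`, `z`, `residual`, one row per
#'   equilibrium found (possibly zero rows).
#' @export
find_equilibria <- function(p, x_max = 10, grid_n = 1000, tol = 1e-12) {
  stopifnot(x_max > 0, grid_n >= 2)
  if (p$k_rz + p$k_dz <= 0 && p$k_rx > 0) {
    roots <- if (abs(.equilibrium_residual(0, p)) < 1e-9) 0 else numeric(0)
  } else {
    xs <- seq(0, x_max, length.out = grid_n)
    g <- .equilibrium_residual(xs, p)
    roots <- xs[g == 0]
    flips <- which(g[-1] * g[-length(g)] < 0)
    for (i in flips) {
      r <- stats::uniroot(.equilibrium_residual, c(xs[i], xs[i + 1]), p = p,
                          tol = tol)
      roots <- c(roots, r$root)
    }
    roots <- sort(unique(roots))
  }
  if (length(roots) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          residual = numeric(0)))
  }
  denom <- p$k_rz + p$k_dz
  z <- if (denom > 0) p$k_rx * roots / denom else rep(0, length(roots))
  fa <- hill_rate(roots, p$k_a0, p$k_a, p$K_a, p$h_a)
  fb <- hill_rate(roots, p$k_b0, p$k_b, p$K_b, p$h_b)
  y <- ifelse(fa + fb > 0, fa * p$y0 / (fa + fb), 0)
  tibble::tibble(x = roots, y = y, z = z,
                 residual = .equilibrium_residual(roots, p))
}
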