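#' Tolerances for regime classification
#'
#' @param stationary_amp Post-transient peak-to-peak amplitude of `x` below
#'   which the solution counts as stationary (absolute, default 1e-4).
#' @param zero_norm Final-state max-norm below which a stationary solution
#'   counts as the zero solution (default 1e-6).
#' @param cluster_tol Gap tolerance for clustering Poincaré crossing
#'   ordinates (default 1e-2; the ordinates span order 1).
#' @param cluster_cap Largest cluster count still considered periodic
#'   (default 64).
#' @param theta Sensitivity threshold: the twin divergence must reach this
#'   fraction of the oscillation amplitude for the dynamics to count as
#'   sensitive to initial data (default 0.1; the criterion is an
#'   order-of-magnitude test).
#' @param merge_tol Absolute tolerance for merging attractor signatures in a
#'   census (default 0.05).
#' @param min_crossings Minimum post-transient crossing count required before
#'   an oscillatory label is assigned (default 50).
#' @return A list of class `regime_tolerances`.
#' @export
regime_tolerances <- function(stationary_amp = 1e-4, zero_norm = 1e-6,
                              cluster_tol = 1e-2, cluster_cap = 64,
                              theta = 0.1, merge_tol = 0.05,
                              min_crossings = 50) {
  structure(list(stationary_amp = stationary_amp, zero_norm = zero_norm,
                 cluster_tol = cluster_tol, cluster_cap = cluster_cap,
                 theta = theta, merge_tol = merge_tol,
                 min_crossings = min_crossings),
            class = "regime_tolerances")
}

.new_regime_label <- function(category, multiplicity = NA_integer_,
                              diagnostics = list()) {
  structure(list(category = category,
                 multiplicity = as.integer(multiplicity),
                 diagnostics = diagnostics),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat("<regime_label>", x$category)
  if (!is.na(x$multiplicity) && x$category == "PERIODIC") {
    cat(" (", x$multiplicity, " crossing cluster",
        if (x$multiplicity > 1) "s", ")", sep = "")
  }
  cat("\n  amplitude:", format(x$diagnostics$amplitude, digits = 4), "\n")
  if (!is.null(x$diagnostics$sensitive)) {
    cat("  sensitive to initial data:", x$diagnostics$sensitive, "\n")
  }
  invisible(x)
}

# Is the sequence of cluster ids cyclic with period k (same cluster revisited
# every k crossings)? A small violation fraction absorbs boundary effects of
# the transient cutoff.
.is_cyclic <- function(id, k, max_viol = 0.02) {
  n <- length(id)
  if (n <= k) return(FALSE)
  mismatch <- sum(id[seq_len(n - k)] != id[seq_len(n - k) + k])
  mismatch / (n - k) <= max_viol
}

#' Divergence of a twin trajectory pair
#'
#' The sensitivity half of the chaos criterion: the pointwise difference of
#' the `x` components of two integrations whose initial data differ by a
#' small epsilon. The pair is flagged sensitive when the post-transient
#' maximum of |x1 - x2| reaches a fraction `theta` of the post-transient
#' peak-to-peak amplitude of the base oscillation, i.e. when the difference
#' becomes comparable with the fluctuation amplitude.
#'
#' @param pair A list of two `dde_trajectory` objects sharing a time grid
#'   (as returned by [integrate_twin()]).
#' @param t_transient Window start for the verdict; default half the span.
#' @param tolerances A [regime_tolerances()] object (only `theta` is used).
#' @return A tibble of class `twin_divergence` with columns `t`, `dx`, and
#'   attributes `sensitive` (logical), `max_divergence` and `amplitude`.
#' @export
sensitivity_divergence <- function(pair, t_transient = NULL,
                                   tolerances = regime_tolerances()) {
  a <- pair[[1]]; b <- pair[[2]]
  if (length(a$t) != length(b$t) || any(a$t != b$t)) {
    stop("twin trajectories must share the same time grid", call. = FALSE)
  }
  if (is.null(t_transient)) t_transient <- max(a$t) / 2
  dx <- a$x - b$x
  w <- a$t >= t_transient
  amp <- diff(range(a$x[w]))
  maxd <- max(abs(dx[w]))
  sensitive <- amp > 0 && maxd >= tolerances$theta * amp
  out <- tibble::tibble(t = a$t, dx = dx)
  structure(out, class = c("twin_divergence", class(out)),
            sensitive = sensitive, max_divergence = maxd, amplitude = amp)
}

#' Classify the long-term regime of a trajectory
#'
#' Implements the two-criteria diagnosis: the structure of the Poincaré
#' crossing set and (for the chaotic/quasi-periodic distinction) the
#' sensitivity of the solution to its initial data.
#'
#' * `STATIONARY`: post-transient peak-to-peak amplitude of `x` below
#'   `stationary_amp`; additionally `ZERO` when the final state max-norm is
#'   below `zero_norm`.
#' * `PERIODIC`: the crossing ordinates form a stable number of clusters
#'   (identical counts on the two halves of the window, at most
#'   `cluster_cap`), revisited in cyclic order; the multiplicity is the
#'   cluster count.
#' * `CHAOTIC`: unordered cluster structure *and* twin divergence reaching
#'   the fluctuation-amplitude scale.
#' * `QUASIPERIODIC`: unordered/growing cluster structure without
#'   sensitivity (the section traces closed curves rather than a finite
#'   point set).
#' * `UNRESOLVED`: not enough information (too few crossings, or no
#'   divergence series supplied when one is needed). Never a guess.
#'
#' @param traj A `dde_trajectory`.
#' @param crossings A `crossing_set` for `traj` (post-transient).
#' @param divergence Optional `twin_divergence` for the same setting;
#'   required to separate chaos from quasi-periodicity.
#' @param tolerances A [regime_tolerances()] object.
#' @param t_transient Window start; default half the span.
#' @return A `regime_label`.
#' @export
classify_regime <- function(traj, crossings = NULL, divergence = NULL,
                            tolerances = regime_tolerances(),
                            t_transient = NULL) {
  if (is.null(t_transient)) t_transient <- max(traj$t) / 2
  w <- traj$t >= t_transient
  amp <- diff(range(traj$x[w]))
  final <- unlist(traj[nrow(traj), c("x", "y", "z")])
  diag <- list(amplitude = amp, final_state = final,
               t_transient = t_transient)

  if (amp < tolerances$stationary_amp) {
    if (max(abs(final)) < tolerances$zero_norm) {
      return(.new_regime_label("ZERO", diagnostics = diag))
    }
    return(.new_regime_label("STATIONARY", diagnostics = diag))
  }

  if (is.null(crossings) || nrow(crossings) < tolerances$min_crossings) {
    diag$note <- "oscillatory but too few section crossings"
    return(.new_regime_label("UNRESOLVED", diagnostics = diag))
  }

  sec <- attr(crossings, "section")
  ord_var <- if (!is.null(sec) && sec$variable == "y") "x" else "y"
  ord <- crossings[[ord_var]]
  id <- .cluster_1d(ord, tolerances$cluster_tol)
  k_all <- max(id)
  half <- nrow(crossings) %/% 2
  k1 <- max(.cluster_1d(ord[seq_len(half)], tolerances$cluster_tol))
  k2 <- max(.cluster_1d(ord[(half + 1):length(ord)], tolerances$cluster_tol))
  diag$cluster_trace <- c(first_half = k1, second_half = k2, full = k_all)
  diag$ordinates <- .cluster_centers(ord, id)

  periodic <- k_all <= tolerances$cluster_cap && k1 == k_all &&
    k2 == k_all && .is_cyclic(id, k_all)
  if (periodic) {
    return(.new_regime_label("PERIODIC", multiplicity = k_all,
                             diagnostics = diag))
  }

  if (is.null(divergence)) {
    diag$note <- "aperiodic crossing structure; sensitivity verdict needed"
    return(.new_regime_label("UNRESOLVED", diagnostics = diag))
  }
  diag$sensitive <- attr(divergence, "sensitive")
  diag$max_divergence <- attr(divergence, "max_divergence")
  if (diag$sensitive) {
    return(.new_regime_label("CHAOTIC", diagnostics = diag))
  }
  .new_regime_label("QUASIPERIODIC", diagnostics = diag)
}

#' Integrate and classify one model setting
#'
#' Convenience orchestration used by the censuses and scans: integrates the
#' Cauchy problem, applies the stationarity test, collects Poincaré
#' crossings (falling back to a section through the middle of the observed
#' `x` range when the requested plane is never reached), and -- only when the
#' crossing structure is aperiodic and `sensitivity = "auto"` -- runs the
#' twin integration to separate chaos from quasi-periodicity.
#'
#' @inheritParams integrate_dde
#' @param section A [poincare_section()].
#' @param tolerances A [regime_tolerances()].
#' @param t_transient Window start; default half of `t_end`.
#' @param sensitivity `"auto"` (run twins when needed) or `"never"` (label
#'   aperiodic oscillations `UNRESOLVED`).
#' @param epsilon Twin perturbation size.
#' @return A `regime_label` whose diagnostics include the crossing set
#'   (`crossings`), the section actually used, and a `section_missed` flag.
#' @export
classify_setting <- function(p, d, history = standard_history(),
                             settings = integration_settings(),
                             section = poincare_section(),
                             tolerances = regime_tolerances(),
                             t_transient = NULL,
                             sensitivity = c("auto", "never"),
                             epsilon = 1e-6) {
  sensitivity <- match.arg(sensitivity)
  traj <- integrate_dde(p, d, history, settings, validate = FALSE)
  if (is.null(t_transient)) t_transient <- max(traj$t) / 2
  label <- classify_regime(traj, NULL, tolerances = tolerances,
                           t_transient = t_transient)
  if (label$category %in% c("ZERO", "STATIONARY")) return(label)

  cr <- poincare_crossings(traj, section, t_transient)
  section_missed <- FALSE
  if (nrow(cr) < tolerances$min_crossings) {
    # attractor misses the requested plane: re-section at mid-range of x
    w <- traj$t >= t_transient
    mid <- mean(range(traj$x[w]))
    fallback <- poincare_section(section$variable, mid, section$direction)
    cr2 <- poincare_crossings(traj, fallback, t_transient)
    if (nrow(cr2) > nrow(cr)) {
      cr <- cr2
      section_missed <- TRUE
    }
  }
  label <- classify_regime(traj, cr, tolerances = tolerances,
                           t_transient = t_transient)
  if (label$category == "UNRESOLVED" && sensitivity == "auto" &&
      !is.null(label$diagnostics$cluster_trace)) {
    pair <- integrate_twin(p, d, history, settings, epsilon = epsilon)
    div <- sensitivity_divergence(pair, t_transient, tolerances)
    label <- classify_regime(traj, cr, div, tolerances, t_transient)
  }
  label$diagnostics$crossings <- cr
  label$diagnostics$section_missed <- section_missed
  label$diagnostics$history <- .as_history(history, d) |> attr("value")
  label
}
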