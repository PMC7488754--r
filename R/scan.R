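#' Specification of a one-parameter scan
#'
#' Describes a bifurcation scan: which parameter to sweep (any model or
#' delay field), over which ordered grid, whether the endosomal-outflow
#' coupling `k_dz = 1 - k_rz` is applied at each point, which Poincaré
#' section to record, and the per-point census settings.
#'
#' @param parameter Field name of [model_params()] or [delay_params()].
#' @param values Strictly monotone, nonempty numeric grid.
#' @param couple_k_dz Apply `k_dz = 1 - k_rz` at each grid point (only
#'   meaningful when scanning or holding `k_rz` in `[0, 1]`).
#' @param section A [poincare_section()].
#' @param n_starts,seed,start_box Census settings per grid point; see
#'   [attractor_census()]. `n_starts = 1` scans the standard history only.
#' @param settings An [integration_settings()].
#' @param tolerances A [regime_tolerances()].
#' @param sensitivity Passed to [classify_setting()].
#' @return An object of class `scan_spec`.
#' @export
scan_spec <- function(parameter, values, couple_k_dz = FALSE,
                      section = poincare_section(),
                      n_starts = 1, seed = 0,
                      start_box = rbind(c(0, 0, 0), c(5, 1, 10)),
                      settings = integration_settings(),
                      tolerances = regime_tolerances(),
                      sensitivity = "auto") {
  all_fields <- c(names(formals(model_params)), names(formals(delay_params)))
  parameter <- match.arg(parameter, all_fields)
  if (length(values) == 0) stop("scan grid must be nonempty", call. = FALSE)
  dv <- diff(values)
  if (length(dv) > 0 && !(all(dv > 0) || all(dv < 0))) {
    stop("scan grid must be strictly monotone", call. = FALSE)
  }
  if (couple_k_dz && parameter == "k_dz") {
    stop("cannot couple k_dz while scanning it", call. = FALSE)
  }
  structure(list(parameter = parameter, values = as.numeric(values),
                 couple_k_dz = couple_k_dz, section = section,
                 n_starts = n_starts, seed = seed, start_box = start_box,
                 settings = settings, tolerances = tolerances,
                 sensitivity = sensitivity),
            class = "scan_spec")
}

.apply_scan_point <- function(spec, base_p, base_d, value) {
  p <- base_p; d <- base_d
  if (spec$parameter %in% names(p)) {
    p <- do.call(set_params,
                 c(list(p), stats::setNames(list(value), spec$parameter)))
  } else {
    d <- do.call(set_params,
                 c(list(d), stats::setNames(list(value), spec$parameter)))
  }
  if (spec$couple_k_dz) p <- set_params(p, k_dz = 1 - p$k_rz)
  list(p = p, d = d)
}

#' Run a one-parameter bifurcation scan
#'
#' At each grid value the parameter is set (with the `k_dz = 1 - k_rz`
#' coupling applied if requested), a multi-start attractor census is run,
#' and every crossing-ordinate cluster center of every attractor is
#' recorded. Branch identities are threaded across adjacent grid values by
#' nearest-signature matching, so that a branch can be followed through the
#' diagram. Failures at single points are recorded as `UNRESOLVED` cells and
#' the scan continues.
#'
#' @param spec A [scan_spec()].
#' @param base_p,base_d Base configuration ([model_params()],
#'   [delay_params()]) from which each grid point deviates.
#' @return A tibble of class `bifurcation_diagram`: one row per (grid value,
#'   branch, ordinate) with columns `value`, `branch`, `category`,
#'   `multiplicity`, `amplitude`, `n_basin`, `ordinate`. The generating
#'   configuration is attached as attributes.
#' @export
scan_parameter <- function(spec, base_p = model_params(),
                           base_d = delay_params()) {
  stopifnot(inherits(spec, "scan_spec"))
  res <- vector("list", length(spec$values))
  prev_sigs <- NULL
  next_branch_id <- 1L
  for (i in seq_along(spec$values)) {
    v <- spec$values[i]
    pd <- .apply_scan_point(spec, base_p, base_d, v)
    cen <- tryCatch(
      attractor_census(pd$p, pd$d, spec$section, spec$n_starts, spec$seed,
                       spec$start_box, spec$settings, spec$tolerances,
                       sensitivity = spec$sensitivity),
      error = function(e) NULL
    )
    if (is.null(cen) || nrow(cen) == 0) {
      res[[i]] <- tibble::tibble(value = v, branch = NA_integer_,
                                 category = "UNRESOLVED",
                                 multiplicity = NA_integer_,
                                 amplitude = NA_real_, n_basin = NA_integer_,
                                 ordinate = NA_real_)
      prev_sigs <- NULL
      next
    }
    # thread branch ids: match this point's attractors to the previous
    # point's by category + nearest mean crossing level
    ids <- integer(nrow(cen))
    for (j in seq_len(nrow(cen))) {
      matched <- NA_integer_
      if (!is.null(prev_sigs)) {
        cand <- prev_sigs[prev_sigs$category == cen$category[j], ,
                          drop = FALSE]
        if (nrow(cand) > 0) {
          dist <- abs(cand$mean_level - cen$mean_level[j])
          if (min(dist) < max(spec$tolerances$merge_tol * 4, 0.2)) {
            matched <- cand$id[which.min(dist)]
          }
        }
      }
      if (is.na(matched)) {
        matched <- next_branch_id
        next_branch_id <- next_branch_id + 1L
      }
      ids[j] <- matched
    }
    prev_sigs <- tibble::tibble(id = ids, category = cen$category,
                                mean_level = cen$mean_level)
    ords <- cen$ordinates
    rows <- lapply(seq_len(nrow(cen)), function(j) {
      o <- ords[[j]]
      if (length(o) == 0) o <- NA_real_
      tibble::tibble(value = v, branch = ids[j],
                     category = cen$category[j],
                     multiplicity = cen$multiplicity[j],
                     amplitude = cen$amplitude[j],
                     n_basin = cen$n_basin[j], ordinate = o)
    })
    res[[i]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(res)
  structure(out, class = c("bifurcation_diagram", class(out)),
            spec = spec, base_params = base_p, base_delays = base_d)
}

#' Per-grid-value regime summary of a diagram
#'
#' Collapses a bifurcation diagram to one row per grid value with the census
#' symbol (see [regime_symbol()]) and the attractor count.
#'
#' @param diagram A `bifurcation_diagram`.
#' @return A tibble with columns `value`, `symbol`, `n_attractors`.
#' @export
summarize_diagram <- function(diagram) {
  per_value <- function(df) {
    one_per_branch <- df$category[!duplicated(df$branch) & !is.na(df$branch)]
    tibble::tibble(
      symbol = if (length(one_per_branch) == 0) "UNRESOLVED" else
        regime_symbol(tibble::tibble(category = one_per_branch)),
      n_attractors = length(unique(df$branch[!is.na(df$branch)]))
    )
  }
  diagram |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$value) |>
    dplyr::group_modify(~ per_value(.x)) |>
    dplyr::ungroup()
}

#' Locate a regime transition along a scanned axis
#'
#' Finds every adjacent pair of grid values where the per-value regime
#' changes from `from` to `to`, then refines each bracket by bisection,
#' re-running the census at probe points, until the bracket is narrower than
#' `refine_tol`. The refined threshold always lies inside the bracket
#' reported.
#'
#' @param diagram A `bifurcation_diagram` (carries its generating
#'   configuration).
#' @param from,to Category names (`"PERIODIC"`, `"STATIONARY"`, `"ZERO"`,
#'   `"CHAOTIC"`, `"QUASIPERIODIC"`) describing the transition sought. A
#'   grid value matches a category if any of its resolved attractors has it;
#'   `"STATIONARY"` also matches `"ZERO"`.
#' @param refine_tol Bracket width at which bisection stops (parameter
#'   units).
#' @return A tibble with one row per transition: `lower`, `upper`,
#'   `threshold` (bracket midpoint after refinement). Zero rows when the
#'   diagram has no such transition.
#' @export
locate_transition <- function(diagram, from, to, refine_tol = 0.005) {
  spec <- attr(diagram, "spec")
  base_p <- attr(diagram, "base_params")
  base_d <- attr(diagram, "base_delays")
  match_cat <- function(cats, want) {
    cats <- cats[!is.na(cats)]
    if (want == "STATIONARY") return(any(cats %in% c("STATIONARY", "ZERO")))
    any(cats == want)
  }
  value_cat <- function(v) {
    pd <- .apply_scan_point(spec, base_p, base_d, v)
    cen <- attractor_census(pd$p, pd$d, spec$section, spec$n_starts,
                            spec$seed, spec$start_box, spec$settings,
                            spec$tolerances, sensitivity = spec$sensitivity)
    cen$category
  }
  vals <- sort(unique(diagram$value))
  has <- function(v, want) {
    cats <- diagram$category[diagram$value == v]
    match_cat(cats, want)
  }
  out <- list()
  for (i in seq_len(length(vals) - 1)) {
    if (has(vals[i], from) && !has(vals[i], to) &&
        has(vals[i + 1], to) && !has(vals[i + 1], from)) {
      lo <- vals[i]; hi <- vals[i + 1]
      while (hi - lo > refine_tol) {
        mid <- (lo + hi) / 2
        cats <- value_cat(mid)
        if (match_cat(cats, from) && !match_cat(cats, to)) {
          lo <- mid
        } else {
          hi <- mid
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(lower = lo, upper = hi,
                                               threshold = (lo + hi) / 2)
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(lower = numeric(0), upper = numeric(0),
                          threshold = numeric(0)))
  }
  dplyr::bind_rows(out)
}
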