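# Attractor signatures and the multi-start census.
#
# A signature condenses one classified trajectory into the quantities that
# identify its attractor on the Poincaré section: the sorted distinct
# crossing-ordinate cluster centers, the oscillation amplitude and the mean
# crossing level. Within one basin the signature is invariant (within
# tolerance) to the initial history, which is what lets signatures from
# different starts be merged.

.make_signature <- function(label) {
  d <- label$diagnostics
  ord <- d$ordinates
  list(category = label$category,
       multiplicity = label$multiplicity,
       ordinates = if (is.null(ord)) numeric(0) else sort(ord),
       amplitude = d$amplitude,
       mean_level = if (is.null(ord) || length(ord) == 0) {
         mean(d$final_state)
       } else {
         mean(ord)
       },
       final_state = d$final_state,
       section_missed = isTRUE(d$section_missed))
}

# Two signatures describe the same attractor when the categories agree and
# the identifying numbers coincide within tolerance. Periodic attractors are
# compared cluster-by-cluster (Poincaré ordinates are phase-invariant);
# stationary ones by their fixed point; irregular (chaotic/quasi-periodic)
# ones by the extent and mean of their crossing band, scaled to amplitude.
.same_signature <- function(a, b, tol) {
  if (a$category != b$category) return(FALSE)
  if (a$category %in% c("ZERO", "STATIONARY")) {
    return(max(abs(a$final_state - b$final_state)) < tol)
  }
  if (a$category == "PERIODIC") {
    if (length(a$ordinates) != length(b$ordinates)) return(FALSE)
    return(max(abs(a$ordinates - b$ordinates)) < tol)
  }
  band <- function(s) c(min(s$ordinates), max(s$ordinates), s$mean_level)
  scale <- max(a$amplitude, b$amplitude, 1)
  all(abs(band(a) - band(b)) < pmax(tol, 0.1 * scale))
}

#' Multi-start census of coexisting attractors
#'
#' Integrates the model from `n_starts` constant histories -- the standard
#' history (2.5, 0.5, 5) plus `n_starts - 1` draws uniform in `start_box` --
#' classifies each long-term regime, and merges signatures that describe the
#' same attractor. Coexistence of several distinct signatures is the model's
#' attractor multiplicity at this parameter point.
#'
#' @inheritParams classify_setting
#' @param n_starts Total number of initial histories (>= 1; the first is
#'   always the standard history).
#' @param seed RNG seed for the start draws (census output is seed-invariant
#'   for generous `n_starts`).
#' @param start_box 2x3 matrix of lower/upper bounds for the random starts;
#'   default x in [0, 5], y in [0, 1], z in [0, 10].
#' @param include_standard Include the standard history as the first start.
#' @return A tibble of class `attractor_census` with one row per distinct
#'   attractor: `branch`, `category`, `multiplicity`, `amplitude`,
#'   `mean_level`, `n_basin` (starts attracted), and `ordinates`
#'   (list-column of crossing-ordinate cluster centers).
#' @examples
#' \donttest{
#' p <- with_recycling(model_params(), 1)
#' cen <- attractor_census(p, delay_params(1, 2, 3, 5), n_starts = 4,
#'                         settings = integration_settings(t_end = 1000))
#' }
#' @export
attractor_census <- function(p, d, section = poincare_section(),
                             n_starts = 12, seed = 0,
                             start_box = rbind(c(0, 0, 0), c(5, 1, 10)),
                             settings = integration_settings(),
                             tolerances = regime_tolerances(),
                             t_transient = NULL,
                             sensitivity = c("auto", "never"),
                             include_standard = TRUE) {
  sensitivity <- match.arg(sensitivity)
  stopifnot(n_starts >= 1)
  starts <- list()
  if (include_standard) starts[[1]] <- standard_history()
  n_random <- n_starts - length(starts)
  if (n_random > 0) {
    rng <- .with_seed(seed, {
      matrix(stats::runif(3 * n_random,
                          min = rep(start_box[1, ], each = n_random),
                          max = rep(start_box[2, ], each = n_random)),
             ncol = 3)
    })
    for (i in seq_len(n_random)) {
      starts[[length(starts) + 1]] <-
        stats::setNames(rng[i, ], c("x", "y", "z"))
    }
  }

  sigs <- list()   # distinct signatures
  basin <- integer(0)
  unresolved <- list()
  for (s in starts) {
    label <- classify_setting(p, d, s, settings, section, tolerances,
                              t_transient, sensitivity)
    sig <- .make_signature(label)
    sig$history <- s
    if (label$category == "UNRESOLVED") {
      unresolved[[length(unresolved) + 1]] <- sig
      next
    }
    hit <- 0L
    for (j in seq_along(sigs)) {
      if (.same_signature(sigs[[j]], sig, tolerances$merge_tol)) {
        hit <- j
        break
      }
    }
    if (hit > 0) {
      basin[hit] <- basin[hit] + 1L
    } else {
      sigs[[length(sigs) + 1]] <- sig
      basin <- c(basin, 1L)
    }
  }

  rows <- function(sg, nb) {
    tibble::tibble(
      category = vapply(sg, `[[`, "", "category"),
      multiplicity = vapply(sg, function(s) as.integer(s$multiplicity),
                            integer(1)),
      amplitude = vapply(sg, `[[`, numeric(1), "amplitude"),
      mean_level = vapply(sg, `[[`, numeric(1), "mean_level"),
      n_basin = nb,
      section_missed = vapply(sg, `[[`, logical(1), "section_missed"),
      ordinates = lapply(sg, `[[`, "ordinates")
    )
  }
  out <- if (length(sigs) > 0) {
    rows(sigs, basin)
  } else {
    rows(list(), integer(0))
  }
  if (length(unresolved) > 0) {
    out <- dplyr::bind_rows(out, rows(unresolved, rep(1L,
                                                      length(unresolved))))
  }
  out <- dplyr::mutate(out, branch = dplyr::row_number(), .before = 1)
  structure(out, class = c("attractor_census", class(out)),
            params = p, delays = d, section = section, seed = seed,
            n_starts = n_starts)
}

# Evaluate expr under a local RNG state so censuses are reproducible without
# disturbing the caller's stream.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Render a census as a regime-table symbol
#'
#' Maps a census to the table alphabet: `0` (zero solution), `S`
#' (stationary), `P`/`2P`/`3P`... (that many coexisting periodic
#' attractors), `QP` (quasi-periodic), `C` (chaos), `P+C` (periodic and
#' chaotic coexisting), `UNRESOLVED` when only unresolved members exist.
#'
#' @param census An `attractor_census`.
#' @return A single character symbol.
#' @export
regime_symbol <- function(census) {
  cat_ <- census$category
  resolved <- cat_[cat_ != "UNRESOLVED"]
  if (length(resolved) == 0) return("UNRESOLVED")
  n_per <- sum(resolved == "PERIODIC")
  has_chaos <- any(resolved == "CHAOTIC")
  has_qp <- any(resolved == "QUASIPERIODIC")
  if (n_per > 0 && has_chaos) return("P+C")
  if (has_chaos) return("C")
  if (has_qp) return("QP")
  if (n_per == 1) return("P")
  if (n_per > 1) return(paste0(n_per, "P"))
  if (all(resolved == "ZERO")) return("0")
  "S"
}
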