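#' Model parameters for the synaptic local-translation circuit
#'
#' Constructs the full rate-constant set of the three-variable model: a pool
#' `x` of active membrane receptors maintained by FMRP-dependent de novo
#' synthesis and by return of receptors from the recycling endosome, a pool
#' `y` of active (dephosphorylated) FMRP bounded by the capacity `y0`, and an
#' endosomal pool `z`. Activation, suppression and synthesis are generalized
#' Hill controls \eqn{f(u) = k_0 + k (u/K)^h / (1 + (u/K)^h)}.
#'
#' Defaults are the model's basic parameter set, extended with the synthesis
#' half-saturation `K_x = 1` (on the FMRP-capacity scale, `K_x = y0`) and zero
#' constitutive synthesis `k_x0 = 0`, consistent with the zero stationary
#' states the model exhibits at strong suppression.
#'
#' @param k_a0,k_a Constitutive and maximum signal-dependent FMRP
#'   dephosphorylation rates (1/min).
#' @param K_a Half-saturation of translation activation (concentration).
#' @param h_a Hill coefficient of activation (dimensionless, >= 1). The
#'   dephosphorylation step is direct (PP2A), so the default is the minimal
#'   nonlinearity 1.
#' @param y0 Total FMRP capacity (concentration).
#' @param k_b0,k_b Constitutive and maximum FMRP phosphorylation rates
#'   (1/min); phosphorylation runs through the multi-step mTOR pathway.
#' @param K_b Half-saturation of translation suppression (concentration);
#'   activation precedes suppression, so `K_a <= K_b` is required.
#' @param h_b Hill coefficient of suppression (dimensionless, >= 1).
#' @param k_x0,k_x Constitutive and maximum FMRP-dependent rates of receptor
#'   synthesis and membrane incorporation (concentration/min).
#' @param K_x Half-saturation of the synthesis control (concentration).
#' @param h_x Hill coefficient of synthesis/incorporation (dimensionless).
#' @param k_dx Membrane receptor degradation rate (1/min).
#' @param k_rx Rate of receptor inclusion into the endosome (1/min).
#' @param k_dz Endosomal degradation rate (1/min).
#' @param k_rz Recycling efficiency: rate of receptor return from the
#'   endosome to the membrane (1/min). `k_rz = 0` switches recycling off.
#' @param ... For `model_params()`, named overrides of any field.
#'
#' @return An object of class `model_params`: a named list of numeric scalars.
#' @examples
#' p <- model_params(k_rz = 0.25)
#' p$k_rz
#' @export
model_params <- function(k_a0 = 0, k_a = 1, K_a = 1, h_a = 1, y0 = 1,
                         k_b0 = 1, k_b = 200, K_b = 3, h_b = 15,
                         k_x0 = 0, k_x = 40, K_x = 1, h_x = 3,
                         k_dx = 0.1, k_rx = 0.9, k_dz = 0.8, k_rz = 0.2) {
  p <- list(k_a0 = k_a0, k_a = k_a, K_a = K_a, h_a = h_a, y0 = y0,
            k_b0 = k_b0, k_b = k_b, K_b = K_b, h_b = h_b,
            k_x0 = k_x0, k_x = k_x, K_x = K_x, h_x = h_x,
            k_dx = k_dx, k_rx = k_rx, k_dz = k_dz, k_rz = k_rz)
  p <- lapply(p, as.numeric)
  structure(p, class = "model_params")
}

#' Delay parameters
#'
#' The four transport/processing delays of the circuit, in minutes:
#' `tau_a` (signal to FMRP dephosphorylation), `tau_b` (signal to FMRP
#' phosphorylation via mTOR), `tau_r` (endosomal residence before return to
#' the membrane), and `tau_e` (translation elongation plus membrane
#' incorporation of the new receptor). Defaults are the basic set
#' (1, 1, 10, 15); most regime studies override to
#' `tau_a = 1, tau_b = 2, tau_r = 3` with `tau_e` in 3--5.
#'
#' @param tau_a,tau_b,tau_r,tau_e Nonnegative delays (minutes).
#' @return An object of class `delay_params`.
#' @export
delay_params <- function(tau_a = 1, tau_b = 1, tau_r = 10, tau_e = 15) {
  d <- list(tau_a = as.numeric(tau_a), tau_b = as.numeric(tau_b),
            tau_r = as.numeric(tau_r), tau_e = as.numeric(tau_e))
  structure(d, class = "delay_params")
}

#' @rdname model_params
#' @export
basic_params <- function(...) {
  model_params(...)
}

#' The standard constant initial history
#'
#' The reference Cauchy problem starts from the constant history
#' x = 2.5, y = 0.5, z = 5 on the whole pre-interval.
#'
#' @return Named numeric triple `c(x = 2.5, y = 0.5, z = 5)`.
#' @export
standard_history <- function() c(x = 2.5, y = 0.5, z = 5)

#' Update a parameter object by name
#'
#' Applies named overrides to a `model_params` or `delay_params` object.
#' Unknown names are an error.
#'
#' @param p A `model_params` or `delay_params` object.
#' @param ... Named scalar replacements.
#' @return The updated object, same class.
#' @export
set_params <- function(p, ...) {
  ov <- list(...)
  if (length(ov) == 0) return(p)
  bad <- setdiff(names(ov), names(p))
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (nm in names(ov)) p[[nm]] <- as.numeric(ov[[nm]])
  p
}

# Variation limits explored in the regime studies; validation warns (never
# errors) when a value leaves these, so the tool stays a general explorer.
.variation_limits <- list(
  h_x = c(1, 3), h_b = c(5, 20), k_x = c(10, 40), k_b = c(100, 200),
  K_a = c(1, 3), k_rz = c(0, 1),
  tau_b = c(1, 5), tau_e = c(3, 20), tau_r = c(3, 15)
)

#' Validate a model/delay configuration
#'
#' Errors on hard invariant violations (negative rates, nonpositive
#' half-saturations, Hill coefficients below 1, `K_a > K_b`, negative delays,
#' and -- when `scan_convention = TRUE` -- a broken `k_dz = 1 - k_rz`
#' coupling or `k_rz` outside `[0, 1]`). Values outside the study's variation
#' limits only raise warnings.
#'
#' @param p A `model_params` object.
#' @param d A `delay_params` object.
#' @param scan_convention Logical; enforce the degradation/recycling coupling
#'   `k_dz = 1 - k_rz` used in the recycling scans.
#' @param warn Emit warnings for values outside the studied variation limits
#'   (hard invariant violations always error).
#' @return Invisibly, a list with elements `params` and `delays` (unchanged).
#' @export
validate_params <- function(p, d = delay_params(), scan_convention = FALSE,
                            warn = TRUE) {
  stopifnot(inherits(p, "model_params"), inherits(d, "delay_params"))
  v <- unlist(p)
  if (any(!is.finite(v))) stop("non-finite model parameter", call. = FALSE)
  nonneg <- c("k_a0", "k_a", "k_b0", "k_b", "k_x0", "k_x",
              "k_dx", "k_rx", "k_dz", "k_rz")
  if (any(v[nonneg] < 0)) {
    stop("rate constants must be nonnegative: ",
         paste(nonneg[v[nonneg] < 0], collapse = ", "), call. = FALSE)
  }
  if (p$K_a <= 0 || p$K_b <= 0 || p$K_x <= 0) {
    stop("half-saturation constants K_a, K_b, K_x must be positive",
         call. = FALSE)
  }
  if (p$h_a < 1 || p$h_b < 1 || p$h_x < 1) {
    stop("Hill coefficients h_a, h_b, h_x must be >= 1", call. = FALSE)
  }
  if (p$y0 <= 0) stop("FMRP capacity y0 must be positive", call. = FALSE)
  if (p$K_a > p$K_b) {
    stop("activation must be at least as efficient as suppression: K_a <= K_b",
         call. = FALSE)
  }
  dv <- unlist(d)
  if (any(!is.finite(dv)) || any(dv < 0)) {
    stop("delays must be finite and nonnegative", call. = FALSE)
  }
  if (scan_convention) {
    if (p$k_rz < 0 || p$k_rz > 1) {
      stop("scan convention requires k_rz in [0, 1]", call. = FALSE)
    }
    if (abs(p$k_dz - (1 - p$k_rz)) > 1e-10) {
      stop("scan convention requires k_dz = 1 - k_rz", call. = FALSE)
    }
  }
  all_vals <- c(v, dv)
  if (!warn) return(invisible(list(params = p, delays = d)))
  for (nm in names(.variation_limits)) {
    lim <- .variation_limits[[nm]]
    if (all_vals[[nm]] < lim[1] || all_vals[[nm]] > lim[2]) {
      warning(sprintf("%s = %g lies outside the studied range [%g, %g]",
                      nm, all_vals[[nm]], lim[1], lim[2]), call. = FALSE)
    }
  }
  invisible(list(params = p, delays = d))
}

#' Apply the recycling scan convention
#'
#' Sets `k_rz` and couples `k_dz = 1 - k_rz`, the convention under which the
#' recycling scans are run (total endosomal outflow held at 1/min).
#'
#' @param p A `model_params` object.
#' @param k_rz Recycling efficiency in `[0, 1]`.
#' @return The updated `model_params`.
#' @export
with_recycling <- function(p, k_rz) {
  stopifnot(k_rz >= 0, k_rz <= 1)
  set_params(p, k_rz = k_rz, k_dz = 1 - k_rz)
}

#' Read / write flat parameter configuration files
#'
#' YAML key-value files using the field names of [model_params()] and
#' [delay_params()]. Unknown keys are an error. The file shipped at
#' `system.file("extdata", "basic_set_2.yaml", package = "synaptodyn")`
#' encodes the basic set.
#'
#' @param path File path.
#' @return `read_params()`: list with `params` and `delays`.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  params_from_list(cfg)
}

#' @rdname read_params
#' @param p,d Parameter and delay objects.
#' @export
write_params <- function(p, d, path) {
  yaml::write_yaml(c(unclass(p), unclass(d)), path)
  invisible(path)
}

#' Build parameter objects from a flat named list
#'
#' @param cfg Named list mixing `model_params` and `delay_params` fields.
#' @return List with elements `params` and `delays`.
#' @export
params_from_list <- function(cfg) {
  pk <- names(formals(model_params))
  dk <- names(formals(delay_params))
  bad <- setdiff(names(cfg), c(pk, dk))
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- do.call(model_params, cfg[intersect(names(cfg), pk)])
  d <- do.call(delay_params, cfg[intersect(names(cfg), dk)])
  list(params = p, delays = d)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.delay_params <- function(x, ...) {
  cat("<delay_params> (minutes)\n")
  print(unlist(x))
  invisible(x)
}
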