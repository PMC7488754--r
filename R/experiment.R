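#' Run a configured experiment and write its artifact bundle
#'
#' Drives the package from a flat YAML configuration: parameter/delay
#' overrides on top of the basic set, a mode (`simulate`, `scan`, `census`,
#' or `table`), and mode-specific settings. Outputs are written as TSV files
#' plus a run manifest recording the full resolved configuration, the seed
#' and the package version, so a bundle is reproducible from its manifest
#' alone. An empty configuration integrates a single trajectory from the
#' basic set.
#'
#' Config keys: any [model_params()]/[delay_params()] field; `mode`;
#' `t_end`, `h`, `seed`, `n_starts`; `section_variable`, `section_level`;
#' `scan_parameter`, `scan_from`, `scan_to`, `scan_step`, `couple_k_dz`;
#' `h_x`, `k_b` (table mode).
#'
#' @param config Path to a YAML file, or a named list.
#' @param out_dir Output directory (created if missing).
#' @param seed Overrides the config seed when not `NULL`.
#' @return Invisibly, a list with the resolved config and the paths written.
#' @export
run_experiment <- function(config = list(), out_dir = tempfile("run"),
                           seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg)) cfg <- list()
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 0
  if (is.null(cfg$mode)) cfg$mode <- "simulate"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pk <- names(formals(model_params))
  dk <- names(formals(delay_params))
  known <- c(pk, dk, "mode", "t_end", "h", "seed", "n_starts",
             "section_variable", "section_level", "scan_parameter",
             "scan_from", "scan_to", "scan_step", "couple_k_dz",
             "h_x", "k_b")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pd <- params_from_list(cfg[intersect(names(cfg), c(pk, dk))])
  p <- pd$params; d <- pd$delays
  settings <- integration_settings(
    h = cfg$h, t_end = if (is.null(cfg$t_end)) 4000 else cfg$t_end)
  section <- poincare_section(
    variable = if (is.null(cfg$section_variable)) "x" else
      cfg$section_variable,
    level = if (is.null(cfg$section_level)) 2 else cfg$section_level)
  n_starts <- if (is.null(cfg$n_starts)) 12 else cfg$n_starts

  paths <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(as.data.frame(df), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths[[length(paths) + 1]] <<- path
    path
  }

  if (cfg$mode == "simulate") {
    traj <- integrate_dde(p, d, settings = settings)
    write_trajectory(traj, file.path(out_dir, "trajectory.tsv"))
    paths <- c(paths, file.path(out_dir, "trajectory.tsv"))
    cr <- poincare_crossings(traj, section)
    wr(cr, "crossings.tsv")
  } else if (cfg$mode == "census") {
    cen <- attractor_census(p, d, section, n_starts, cfg$seed,
                            settings = settings)
    flat <- dplyr::mutate(
      tibble::as_tibble(cen),
      ordinates = vapply(.data$ordinates,
                         function(o) paste(format(o, digits = 10),
                                           collapse = ","), ""))
    wr(flat, "census.tsv")
  } else if (cfg$mode == "scan") {
    if (is.null(cfg$scan_parameter)) {
      stop("scan mode needs scan_parameter", call. = FALSE)
    }
    values <- seq(cfg$scan_from, cfg$scan_to,
                  by = if (is.null(cfg$scan_step)) 0.01 else cfg$scan_step)
    spec <- scan_spec(cfg$scan_parameter, values,
                      couple_k_dz = isTRUE(cfg$couple_k_dz),
                      section = section, n_starts = n_starts,
                      seed = cfg$seed, settings = settings)
    diagram <- scan_parameter(spec, p, d)
    wr(tibble::as_tibble(diagram), "diagram.tsv")
    wr(summarize_diagram(diagram), "regimes.tsv")
  } else if (cfg$mode == "table") {
    tab <- regime_table(
      h_x = if (is.null(cfg$h_x)) p$h_x else cfg$h_x,
      k_b = if (is.null(cfg$k_b)) 200 else cfg$k_b,
      base_p = p, base_d = d, n_starts = n_starts, seed = cfg$seed,
      settings = settings, section = section)
    wr(tibble::as_tibble(tab), "regime_table.tsv")
    wr(format_regime_table(tab), "regime_table_wide.tsv")
  } else {
    stop("unknown mode: ", cfg$mode, call. = FALSE)
  }

  manifest <- c(
    list(package = "synaptodyn",
         version = as.character(utils::packageVersion("synaptodyn"))),
    cfg,
    list(params = unclass(p), delays = unclass(d))
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(config = cfg, paths = c(paths, manifest_path),
                 out_dir = out_dir))
}

#' Shipped experiment configurations
#'
#' Returns the path of a configuration file installed with the package:
#' `basic_set_2` (the basic parameter set), `fig2a` (the translation-delay
#' scan at 25% recycling), `fig6a`/`fig6b` (the recycling scans at the
#' minimum and maximum varying-parameter sets), `table1` (the `h_x = 2`
#' regime table).
#'
#' @param name Configuration name.
#' @return A file path.
#' @export
experiment_config <- function(name = c("basic_set_2", "fig2a", "fig6a",
                                       "fig6b", "table1")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".yaml"), package = "synaptodyn",
              mustWork = TRUE)
}
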