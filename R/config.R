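#' Default run configuration
#'
#' The full configuration with every section (`load`, `cell`, `sf`,
#' `sampling`, `langevin`, `output`) at its default value.
#'
#' @return A named list of sections (class `"run_config"`).
#' @export
default_config <- function() {
  structure(list(
    load = list(eps_amp = 0.1, f = 1, r = 0, eps_mean = 0),
    cell = list(R0 = 1, R_N = 0.5, mu_cyto = 0.68, kappa_cyto = 2.8,
                mu_nuc = 1.36, kappa_nuc = 5.6,
                suspension_radius_factor = 0.96,
                suspension_stress_factor = 0.45),
    sf = list(sigma_max = 9.5, eps_rate_0 = 0.1, k_v = 1.6, eps_ss = 0.35,
              mu_b0 = 0, mu_u0 = 0, omega = 1, kT = 1, n_T = 1,
              eta_max = 0.72, mu_ref = -10.553, n_angular = 36L),
    sampling = list(n_samples = 20000L, n_time = 64L, a_min = 0.3, a_max = 4),
    langevin = list(dt_hat = 1e-3, t_end_hat = 100, n_traj = 200,
                    gamma_over_Hs = 500, fd_step = 1e-4, record_every = 100L),
    output = list(dir = "cyclicell-output", digits = 8L),
    base_seed = 1L
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unspecified values from
#' [default_config()], and rejects unknown sections or keys. An empty file
#' yields the full defaults. Basic physical validity (nonnegative
#' amplitude and frequency, biaxiality in `[0, 1]`, positive moduli) is
#' enforced by constructing the parameter objects.
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  for (sec in names(user)) {
    if (sec == "base_seed") {
      cfg$base_seed <- as.integer(user$base_seed)
      next
    }
    if (!sec %in% names(cfg))
      stop("unknown config section: '", sec, "'")
    if (!is.list(user[[sec]]))
      stop("config section '", sec, "' must be a mapping")
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown key '", key, "' in config section '", sec, "'")
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  # constructors carry the invariants; errors name the offending field
  do.call(cyclic_load, cfg$load)
  do.call(sf_params, cfg$sf)
  do.call(cell_params, cfg$cell)
  with(cfg$sampling, {
    if (n_samples < 1) stop("sampling: n_samples must be >= 1")
    if (n_time < 8) stop("sampling: n_time must be >= 8")
    if (a_min <= 0 || a_max <= a_min) stop("sampling: need 0 < a_min < a_max")
  })
  do.call(langevin_settings, c(cfg$langevin, list(seed = cfg$base_seed)))
  invisible(cfg)
}

#' Write a configuration back to YAML
#'
#' @param cfg A `"run_config"` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Model objects from a configuration
#'
#' @param cfg A `"run_config"` list.
#' @return A list with `load`, `sfp`, `cp` (suspension energy attached),
#'   `sampling`, `langevin` settings.
#' @export
config_objects <- function(cfg) {
  load <- do.call(cyclic_load, cfg$load)
  sfp <- do.call(sf_params, cfg$sf)
  cp <- with_suspension_energy(sfp, do.call(cell_params, cfg$cell))
  list(load = load, sfp = sfp, cp = cp, sampling = cfg$sampling,
       langevin = do.call(langevin_settings,
                          c(cfg$langevin, list(seed = cfg$base_seed))))
}

#' Stable hash of a configuration
#'
#' Used to stamp output files so results can be traced to the exact
#' configuration that produced them.
#'
#' @param cfg A `"run_config"` list.
#' @return A 32-character hexadecimal string.
#' @export
digest_config <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}
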