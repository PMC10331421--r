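# YAML configuration files. Sections: world (floor-plan paths), patients,
# nurses, iat, policy, run {horizon, seed, n_runs}. Paths are resolved
# relative to the config file's directory.

#' Read a simulation configuration from YAML
#'
#' @param path Path to the YAML file. Expected layout:
#' ```yaml
#' world:
#'   floorplan: demo_ward.map      # sidecar defaults to demo_ward.json
#' patients: {n: 3, dis_level: 0.01, mean_step: 1.0, sd_step: 0.2,
#'            reorient_prob: 0.005}
#' nurses: {n: 2, speed: 1.0, discovery_radius: 2}
#' iat: {p_detect: 0.1, p_cue_success: 0.3, cue_cooldown: 5}
#' policy: "smart_watch:0"
#' run: {horizon: 1000, seed: 1, n_runs: 10}
#' ```
#' Omitted parameter keys fall back to the package defaults.
#'
#' @return A [sim_config()]; the requested number of runs is attached as
#'   attribute `n_runs`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    ws_abort(paste0("config file not found: ", path), "wardsim_error_config")
  }
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  if (is.null(y$world) || is.null(y$world$floorplan)) {
    ws_abort("config is missing world.floorplan", "wardsim_error_config")
  }
  map_path <- y$world$floorplan
  if (!file.exists(map_path)) map_path <- file.path(base, y$world$floorplan)
  sidecar_path <- y$world$sidecar
  if (!is.null(sidecar_path) && !file.exists(sidecar_path)) {
    sidecar_path <- file.path(base, y$world$sidecar)
  }
  plan <- read_floorplan(map_path, sidecar_path)

  pick <- function(section, key, default) {
    v <- y[[section]][[key]]
    if (is.null(v)) default else v
  }
  pp <- patient_params(dis_level = pick("patients", "dis_level", 0.01),
                       mean_step = pick("patients", "mean_step", 1.0),
                       sd_step = pick("patients", "sd_step", 0.2),
                       reorient_prob = pick("patients", "reorient_prob", 0.005))
  np <- nurse_params(speed = pick("nurses", "speed", 1.0),
                     discovery_radius = pick("nurses", "discovery_radius", 2))
  ip <- iat_params(p_detect = pick("iat", "p_detect", 0.1),
                   p_cue_success = pick("iat", "p_cue_success", 0.3),
                   cue_cooldown = pick("iat", "cue_cooldown", 5))
  pol <- parse_policy(y$policy %||% "smart_watch:0")
  cfg <- sim_config(plan,
                    patient_params = pp, iat_params = ip, nurse_params = np,
                    policy = pol,
                    n_patients = pick("patients", "n", 3),
                    n_nurses = pick("nurses", "n", 2),
                    horizon = pick("run", "horizon", 1000),
                    seed = pick("run", "seed", 1),
                    schedule_shuffle = pick("run", "schedule_shuffle", TRUE),
                    floorplan_path = map_path)
  attr(cfg, "n_runs") <- pick("run", "n_runs", 1)
  cfg
}

#' Path to the shipped demo configuration
#'
#' The demo config references the demo ward fixtures under the package's
#' `extdata` directory and carries the default study conditions.
#'
#' @return Path to `demo_config.yaml`.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "wardsim", mustWork = TRUE)
}
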