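# Parameter objects for patients, the smart-watch device, nurses, and the
# assistive policy. All parameters are plain validated lists; defaults are
# the demo study conditions shipped with the package.

#' Patient behavior parameters
#'
#' @param dis_level Probability, per en-route tick, that an oriented patient
#'   becomes disoriented.
#' @param mean_step Mean step length per tick, in cell units.
#' @param sd_step Step-length standard deviation (cell units). Steps are
#'   drawn from a normal distribution truncated below at 0.
#' @param reorient_prob Probability per tick that an unguided disoriented
#'   patient spontaneously regains orientation. Kept small so that guided
#'   recovery dominates, but non-zero so that runs without any help do not
#'   have an absorbing disoriented state; set to 0 to disable.
#' @return A `patient_params` list.
#' @export
patient_params <- function(dis_level = 0.01, mean_step = 1.0, sd_step = 0.2,
                           reorient_prob = 0.005) {
  stopifnot(is_prob(dis_level), is_prob(reorient_prob),
            is.numeric(mean_step), mean_step > 0,
            is.numeric(sd_step), sd_step >= 0)
  structure(list(dis_level = dis_level, mean_step = mean_step,
                 sd_step = sd_step, reorient_prob = reorient_prob),
            class = "patient_params")
}

#' Smart-watch (assistive device) parameters
#'
#' @param p_detect Per-tick probability that an ongoing disorientation is
#'   detected by the watch (geometric detection latency).
#' @param p_cue_success Probability that a single orientation cue restores
#'   the wearer's orientation.
#' @param cue_cooldown Ticks between cue attempts (>= 1).
#' @return An `iat_params` list.
#' @export
iat_params <- function(p_detect = 0.1, p_cue_success = 0.3, cue_cooldown = 5) {
  stopifnot(is_prob(p_detect), is_prob(p_cue_success),
            is_count(cue_cooldown), cue_cooldown >= 1)
  structure(list(p_detect = p_detect, p_cue_success = p_cue_success,
                 cue_cooldown = as.integer(cue_cooldown)),
            class = "iat_params")
}

#' Nurse parameters
#'
#' @param speed Walking speed in cell units per tick. Applies both to
#'   responding and to escorting (a guided walk proceeds at the pace of the
#'   pair, so responding is not modeled as faster).
#' @param discovery_radius Radius (cell units) within which a routine nurse
#'   notices an unguided disoriented patient when no smart watch is in use.
#' @return A `nurse_params` list.
#' @export
nurse_params <- function(speed = 1.0, discovery_radius = 2) {
  stopifnot(is.numeric(speed), speed > 0,
            is.numeric(discovery_radius), discovery_radius >= 0)
  structure(list(speed = speed, discovery_radius = discovery_radius),
            class = "nurse_params")
}

#' Assistive policy
#'
#' Three policy variants are modeled: `"smart_watch"` (the device detects
#' disorientation, issues cues, and calls a nurse after `n_help` failed
#' cues; `n_help = 0` calls immediately upon detection), `"nurse_only"`
#' (no device; nurses must discover disoriented patients within their
#' discovery radius), and `"no_help"` (patients are left unattended).
#'
#' @param variant One of `"smart_watch"`, `"nurse_only"`, `"no_help"`.
#' @param n_help Number of failed cue interventions tolerated before a nurse
#'   is called (smart-watch variant only).
#' @return A `policy` list with a human-readable `label`.
#' @export
#' @examples
#' policy("smart_watch", n_help = 3)$label
#' parse_policy("smart_watch:5")
policy <- function(variant = c("smart_watch", "nurse_only", "no_help"), n_help = NULL) {
  variant <- match.arg(variant)
  if (variant == "smart_watch") {
    if (is.null(n_help) || !is_count(n_help)) {
      ws_abort("smart_watch policy requires n_help >= 0", "wardsim_error_policy")
    }
    n_help <- as.integer(n_help)
    label <- paste0("Nhelp=", n_help)
  } else {
    if (!is.null(n_help)) {
      ws_abort("n_help is only meaningful for the smart_watch variant", "wardsim_error_policy")
    }
    label <- if (variant == "nurse_only") "Nurse Only" else "No Help"
  }
  structure(list(variant = variant, n_help = n_help, label = label),
            class = "policy")
}

#' @rdname policy
#' @param text Policy string: `"smart_watch:<n_help>"`, `"nurse_only"` or
#'   `"no_help"`.
#' @export
parse_policy <- function(text) {
  text <- trimws(text)
  if (grepl("^smart_watch:[0-9]+$", text)) {
    return(policy("smart_watch", n_help = as.integer(sub("^smart_watch:", "", text))))
  }
  if (text == "nurse_only") return(policy("nurse_only"))
  if (text == "no_help") return(policy("no_help"))
  ws_abort(paste0("unknown policy string: '", text,
                  "' (expected smart_watch:<n>, nurse_only or no_help)"),
           "wardsim_error_policy")
}
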