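# Agent behavior: patient movement and orientation dynamics, the smart-watch
# detection/cue/escalation automaton, and nurse response/guidance.
#
# All stochastic rules draw from R's global RNG; the simulation engine seeds
# it once per run, so every operation here is reproducible given the run
# seed. State objects are plain lists so they can be built directly in tests.

#' Construct a patient state
#'
#' @param id Agent identifier (e.g. `"P1"`).
#' @param position Position `c(x, y)` in cell units.
#' @param destination Name of the destination currently walked to.
#' @param orientation `"ORIENTED"` or `"DISORIENTED"`.
#' @param guidance `"NONE"` or `"NURSE_GUIDED"`.
#' @param failed_cues Failed smart-watch cues in the current episode.
#' @param heading Walking direction in radians (used while disoriented).
#' @return A `patient_state` list. Engine bookkeeping fields (`route`,
#'   `progress`, `detected`, `call_made`, `last_cue_tick`, `schedule`,
#'   `sched_idx`) are initialized empty.
#' @export
patient_state <- function(id, position, destination,
                          orientation = "ORIENTED", guidance = "NONE",
                          failed_cues = 0L, heading = 0) {
  structure(list(id = id, position = as.numeric(position),
                 destination = destination,
                 orientation = orientation, guidance = guidance,
                 failed_cues = as.integer(failed_cues), heading = heading,
                 route = NULL, progress = 0,
                 detected = FALSE, call_made = FALSE, last_cue_tick = NA_integer_,
                 schedule = NULL, sched_idx = 1L,
                 reached_dest = FALSE, needs_route = FALSE),
            class = "patient_state")
}

#' Construct a nurse state
#'
#' @param id Agent identifier (e.g. `"N1"`).
#' @param position Position `c(x, y)`.
#' @param station Station cell `c(row, col)` the nurse returns to.
#' @param task `"ROUTINE"`, `"RESPONDING"` or `"GUIDING"`.
#' @param assigned_patient Patient id while responding/guiding, else `NULL`.
#' @return A `nurse_state` list.
#' @export
nurse_state <- function(id, position, station, task = "ROUTINE",
                        assigned_patient = NULL) {
  structure(list(id = id, position = as.numeric(position), station = station,
                 task = task, assigned_patient = assigned_patient,
                 route = NULL, progress = 0, target_cell = NULL,
                 at_station = FALSE),
            class = "nurse_state")
}

#' Sample one step length
#'
#' Draws from a normal distribution with mean `mean_step` and standard
#' deviation `sd_step`, truncated below at 0 (rejection sampling; with
#' `sd_step = 0` the draw is exactly `mean_step`).
#'
#' @param params A [patient_params()] object.
#' @return Step length in cell units (>= 0).
#' @export
sample_step_length <- function(params) {
  if (params$sd_step == 0) return(params$mean_step)
  for (i in 1:100) {
    s <- stats::rnorm(1, params$mean_step, params$sd_step)
    if (s >= 0) return(s)
  }
  0
}

#' Advance an oriented patient along its route
#'
#' The patient advances along the shortest route to its destination by one
#' sampled step length, clamped at the destination (no overshoot). Reaching
#' the destination cell sets `reached_dest`; the engine records the
#' `DEST_REACHED` event and assigns the next scheduled destination.
#'
#' @param patient A `patient_state` with `orientation = "ORIENTED"`.
#' @param route The route to the patient's destination (defaults to the one
#'   stored on the state).
#' @param params A [patient_params()] object.
#' @return The updated `patient_state`.
#' @export
oriented_move <- function(patient, route = patient$route, params) {
  if (is.null(route) || nrow(route$waypoints) == 0) {
    # an empty route is only legal if the patient already sits at the target
    if (!is.null(route)) {
      patient$reached_dest <- TRUE
      return(patient)
    }
    ws_abort("oriented patient has no route to its destination",
             "wardsim_error_internal")
  }
  step <- sample_step_length(params)
  patient$progress <- min(patient$progress + step, route$total_length)
  patient$position <- route_position(route, patient$progress)
  if (patient$progress >= route$total_length) {
    patient$reached_dest <- TRUE
  }
  patient
}

#' Move an unguided disoriented patient (correlated random walk)
#'
#' The heading is perturbed by a uniform turn in `[-turn_range, turn_range]`
#' and a step of sampled length is taken in that direction. If the step
#' would land on a non-walkable cell the heading is resampled (up to 8
#' attempts), after which the patient stays in place.
#'
#' @param patient A `patient_state` with `orientation = "DISORIENTED"` and
#'   `guidance = "NONE"`.
#' @param plan The `floor_plan`.
#' @param params A [patient_params()] object.
#' @param turn_range Maximum turn per tick, radians (default 90 degrees).
#' @return The updated `patient_state`.
#' @export
disoriented_move <- function(patient, plan, params, turn_range = pi / 2) {
  step <- sample_step_length(params)
  heading <- patient$heading
  for (attempt in 1:8) {
    heading <- if (attempt == 1 && turn_range > 0) {
      patient$heading + stats::runif(1, -turn_range, turn_range)
    } else if (turn_range > 0) {
      stats::runif(1, 0, 2 * pi)
    } else {
      patient$heading
    }
    x <- patient$position[1] + step * cos(heading)
    y <- patient$position[2] + step * sin(heading)
    if (walkable_at(plan, x, y)) {
      patient$position <- c(x, y)
      patient$heading <- heading
      return(patient)
    }
    if (turn_range == 0) break
  }
  patient
}

#' Orientation transitions at a decision point
#'
#' An oriented, en-route patient becomes disoriented with probability
#' `dis_level`; an unguided disoriented patient spontaneously reorients
#' with probability `reorient_prob`. Nurse-guided patients never transition
#' here (guidance release happens in [nurse_step()]). The `transitioned`
#' field of the result is `"DISORIENT"`, `"REORIENT"` or `NA`; on
#' reorientation `needs_route` is set so the engine adopts a fresh shortest
#' route to the current destination.
#'
#' @param patient A `patient_state`.
#' @param params A [patient_params()] object.
#' @return The updated `patient_state`.
#' @export
transition_orientation <- function(patient, params) {
  patient$transitioned <- NA_character_
  if (patient$guidance == "NURSE_GUIDED") return(patient)
  if (patient$orientation == "ORIENTED") {
    if (params$dis_level > 0 && stats::runif(1) < params$dis_level) {
      patient$orientation <- "DISORIENTED"
      patient$heading <- stats::runif(1, 0, 2 * pi)
      patient$transitioned <- "DISORIENT"
    }
  } else {
    if (params$reorient_prob > 0 && stats::runif(1) < params$reorient_prob) {
      patient <- reset_watch_state(patient)
      patient$orientation <- "ORIENTED"
      patient$needs_route <- TRUE
      patient$transitioned <- "REORIENT"
    }
  }
  patient
}

reset_watch_state <- function(patient) {
  patient$detected <- FALSE
  patient$call_made <- FALSE
  patient$failed_cues <- 0L
  patient$last_cue_tick <- NA_integer_
  patient
}

#' One tick of the smart-watch automaton
#'
#' While the wearer is disoriented and not yet detected, detection fires
#' with probability `p_detect` per tick. Once detected: if `failed_cues`
#' has reached the policy's `n_help`, a nurse is called (once per episode);
#' otherwise, each time the cue cooldown has elapsed, a cue is issued and
#' succeeds with probability `p_cue_success` (restoring orientation and
#' resetting the episode state) or fails (incrementing `failed_cues`).
#' Non-smart-watch policies emit nothing.
#'
#' @param patient A `patient_state`.
#' @param iat An [iat_params()] object.
#' @param policy A [policy()] object.
#' @param tick Current tick (0-based).
#' @return List with elements `patient` (updated state) and `events`
#'   (character vector drawn from DETECT, CUE_ISSUED, CUE_SUCCESS,
#'   CUE_FAIL, NURSE_CALLED, REORIENT).
#' @export
iat_step <- function(patient, iat, policy, tick) {
  events <- character(0)
  if (policy$variant != "smart_watch" ||
      patient$orientation != "DISORIENTED" ||
      patient$guidance == "NURSE_GUIDED") {
    return(list(patient = patient, events = events))
  }
  if (!patient$detected) {
    if (iat$p_detect > 0 && stats::runif(1) < iat$p_detect) {
      patient$detected <- TRUE
      patient$last_cue_tick <- as.integer(tick)
      events <- c(events, "DETECT")
    }
  }
  if (patient$detected && !patient$call_made) {
    if (patient$failed_cues >= policy$n_help) {
      patient$call_made <- TRUE
      events <- c(events, "NURSE_CALLED")
    } else if (tick - patient$last_cue_tick >= iat$cue_cooldown) {
      patient$last_cue_tick <- as.integer(tick)
      events <- c(events, "CUE_ISSUED")
      if (iat$p_cue_success > 0 && stats::runif(1) < iat$p_cue_success) {
        patient <- reset_watch_state(patient)
        patient$orientation <- "ORIENTED"
        patient$needs_route <- TRUE
        events <- c(events, "CUE_SUCCESS", "REORIENT")
      } else {
        patient$failed_cues <- patient$failed_cues + 1L
        events <- c(events, "CUE_FAIL")
      }
    }
  }
  list(patient = patient, events = events)
}

# one event record; `patient` cross-references the patient a nurse event is
# about, `dest` names the destination for DEST_REACHED
ev_rec <- function(tick, id, ev, patient = NA_character_, dest = NA_character_) {
  list(t = as.integer(tick), id = id, ev = ev, patient = patient, dest = dest)
}

#' One tick of a nurse
#'
#' Routine nurses stay at (or walk back to) their station; the nearest
#' routine nurse claims the oldest pending call and responds; responding
#' nurses walk the shortest route to the patient's current position and,
#' on arrival (within 1 cell), start guiding; guiding nurses escort the
#' patient along the shortest route to the patient's destination, the
#' patient's position following the nurse, and release the patient
#' (reoriented) at the destination. Under the nurse-only policy a routine
#' nurse that comes within `discovery_radius` of an unguided disoriented
#' patient discovers them and responds; under no-help nurses never respond
#' nor discover. Calls whose patient has already reoriented are dropped
#' with a CANCELLED event.
#'
#' @param nurse A `nurse_state`.
#' @param params A [nurse_params()] object.
#' @param plan The `floor_plan`.
#' @param pending_calls Character vector of patient ids (oldest first).
#' @param patients Named list of `patient_state`s.
#' @param tick Current tick.
#' @param pol The active [policy()].
#' @param nurses Optional named list of all nurse states (used to decide
#'   whether this nurse is the nearest routine nurse for a call).
#' @return List with elements `nurse`, `patients`, `pending_calls`,
#'   `events` (list of event records).
#' @export
nurse_step <- function(nurse, params, plan, pending_calls, patients, tick,
                       pol = policy("smart_watch", 0), nurses = NULL) {
  events <- list()

  claimable <- function(pid) {
    p <- patients[[pid]]
    !is.null(p) && p$orientation == "DISORIENTED" && p$guidance == "NONE"
  }

  if (nurse$task == "ROUTINE" && pol$variant != "no_help") {
    # drop stale calls, then claim the oldest live one if we are nearest
    while (length(pending_calls) > 0) {
      pid <- pending_calls[1]
      if (!claimable(pid)) {
        events[[length(events) + 1L]] <- ev_rec(tick, nurse$id, "CANCELLED", patient = pid)
        pending_calls <- pending_calls[-1]
        next
      }
      pcell <- cell_of(patients[[pid]]$position)
      dfield <- distance_field(plan, pcell)
      mycell <- cell_of(nurse$position)
      mydist <- dfield[mycell[1], mycell[2]]
      nearer_exists <- FALSE
      if (!is.null(nurses)) {
        for (other in nurses) {
          if (other$id != nurse$id && other$task == "ROUTINE") {
            oc <- cell_of(other$position)
            od <- dfield[oc[1], oc[2]]
            if (!is.na(od) && !is.na(mydist) && od < mydist) nearer_exists <- TRUE
          }
        }
      }
      if (nearer_exists || is.na(mydist)) break
      nurse$task <- "RESPONDING"
      nurse$assigned_patient <- pid
      nurse$route <- shortest_route(plan, nurse$position, patients[[pid]]$position)
      nurse$progress <- 0
      nurse$target_cell <- pcell
      pending_calls <- pending_calls[-1]
      break
    }
  }

  if (nurse$task == "ROUTINE" && pol$variant == "nurse_only") {
    for (pid in names(patients)) {
      if (claimable(pid) &&
          straight_line_distance(nurse$position, patients[[pid]]$position) <= params$discovery_radius) {
        events[[length(events) + 1L]] <- ev_rec(tick, nurse$id, "DISCOVERED", patient = pid)
        nurse$task <- "RESPONDING"
        nurse$assigned_patient <- pid
        nurse$route <- shortest_route(plan, nurse$position, patients[[pid]]$position)
        nurse$progress <- 0
        nurse$target_cell <- cell_of(patients[[pid]]$position)
        break
      }
    }
  }

  if (nurse$task == "RESPONDING") {
    pid <- nurse$assigned_patient
    if (!claimable(pid)) {
      events[[length(events) + 1L]] <- ev_rec(tick, nurse$id, "CANCELLED", patient = pid)
      nurse$task <- "ROUTINE"
      nurse$assigned_patient <- NULL
      nurse$route <- NULL
    } else {
      pcell <- cell_of(patients[[pid]]$position)
      if (is.null(nurse$route) || !all(pcell == nurse$target_cell)) {
        nurse$route <- shortest_route(plan, nurse$position, patients[[pid]]$position)
        nurse$progress <- 0
        nurse$target_cell <- pcell
      }
      if (nurse$route$total_length > 0) {
        nurse$progress <- min(nurse$progress + params$speed, nurse$route$total_length)
        nurse$position <- route_position(nurse$route, nurse$progress)
      }
      if (straight_line_distance(nurse$position, patients[[pid]]$position) <= 1) {
        events[[length(events) + 1L]] <- ev_rec(tick, nurse$id, "NURSE_ARRIVED", patient = pid)
        events[[length(events) + 1L]] <- ev_rec(tick, nurse$id, "GUIDE_START", patient = pid)
        nurse$task <- "GUIDING"
        p <- patients[[pid]]
        p$guidance <- "NURSE_GUIDED"
        patients[[pid]] <- p
        dest_cell <- plan$destinations[[p$destination]]
        nurse$route <- shortest_route(plan, nurse$position, cell_center(dest_cell))
        nurse$progress <- 0
        nurse$target_cell <- dest_cell
      }
    }
  } else if (nurse$task == "GUIDING") {
    pid <- nurse$assigned_patient
    p <- patients[[pid]]
    nurse$progress <- min(nurse$progress + params$speed, nurse$route$total_length)
    if (nurse$route$total_length > 0) {
      nurse$position <- route_position(nurse$route, nurse$progress)
    }
    p$position <- nurse$position
    if (nurse$progress >= nurse$route$total_length) {
      events[[length(events) + 1L]] <- ev_rec(tick, nurse$id, "GUIDE_END", patient = pid)
      events[[length(events) + 1L]] <- ev_rec(tick, pid, "DEST_REACHED", dest = p$destination)
      p <- reset_watch_state(p)
      p$orientation <- "ORIENTED"
      p$guidance <- "NONE"
      p$reached_dest <- FALSE
      p <- advance_schedule(p, plan)
      nurse$task <- "ROUTINE"
      nurse$assigned_patient <- NULL
      nurse$route <- NULL
      nurse$target_cell <- NULL
    }
    patients[[pid]] <- p
  } else if (nurse$task == "ROUTINE") {
    station_center <- cell_center(nurse$station)
    if (straight_line_distance(nurse$position, station_center) > 1e-9) {
      if (is.null(nurse$route) || is.null(nurse$target_cell) ||
          !all(nurse$target_cell == nurse$station)) {
        nurse$route <- shortest_route(plan, nurse$position, station_center)
        nurse$progress <- 0
        nurse$target_cell <- nurse$station
      }
      if (nurse$route$total_length > 0) {
        nurse$progress <- min(nurse$progress + params$speed, nurse$route$total_length)
        nurse$position <- route_position(nurse$route, nurse$progress)
      } else {
        nurse$position <- station_center
      }
    }
  }

  nurse$at_station <- nurse$task == "ROUTINE" &&
    straight_line_distance(nurse$position, cell_center(nurse$station)) <= 1e-9
  list(nurse = nurse, patients = patients, pending_calls = pending_calls,
       events = events)
}

# move to the next destination in the cyclic activity schedule and adopt a
# fresh shortest route; states built outside the engine may have no
# schedule, in which case the current destination is kept
advance_schedule <- function(patient, plan) {
  if (!is.null(patient$schedule)) {
    patient$sched_idx <- patient$sched_idx %% length(patient$schedule) + 1L
    patient$destination <- patient$schedule[patient$sched_idx]
  }
  dest_cell <- plan$destinations[[patient$destination]]
  patient$route <- shortest_route(plan, patient$position, cell_center(dest_cell))
  patient$progress <- 0
  patient$reached_dest <- FALSE
  patient
}
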