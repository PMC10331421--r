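# The discrete-time simulation loop. Each tick applies, in fixed order:
# orientation transitions -> smart-watch step -> nurse step -> movement,
# then snapshots every agent's state. All randomness flows from R's global
# RNG, seeded once per run, so serialized protocols are a pure function of
# (config, seed).

#' Simulation configuration
#'
#' @param plan A `floor_plan` (e.g. [demo_ward()]).
#' @param patient_params,iat_params,nurse_params Parameter objects; see
#'   [patient_params()], [iat_params()], [nurse_params()].
#' @param policy A [policy()] object.
#' @param n_patients,n_nurses Agent counts. `n_nurses = 0` is only legal
#'   when the policy never involves nurses responding (no-help, or
#'   smart-watch setups whose calls are deliberately left unserved).
#' @param horizon Number of ticks per run (fixed-time termination).
#' @param seed Default seed for [run_simulation()].
#' @param schedule_shuffle Shuffle each patient's cyclic destination
#'   schedule at run start (default); otherwise patients cycle the
#'   destination list in order, rotated by patient index.
#' @param floorplan_path Optional provenance: the file the plan came from.
#' @return A `sim_config` object. Its `digest` field identifies the
#'   simulation condition (everything except the seed), so runs of the same
#'   condition can be pooled and compared.
#' @export
#' @examples
#' cfg <- sim_config(demo_ward(), horizon = 100, n_patients = 2)
#' cfg$digest
sim_config <- function(plan,
                       patient_params = wardsim::patient_params(),
                       iat_params = wardsim::iat_params(),
                       nurse_params = wardsim::nurse_params(),
                       policy = wardsim::policy("smart_watch", n_help = 0),
                       n_patients = 3, n_nurses = 2,
                       horizon = 1000, seed = 1,
                       schedule_shuffle = TRUE,
                       floorplan_path = NULL) {
  if (!inherits(plan, "floor_plan")) {
    ws_abort("plan must be a floor_plan", "wardsim_error_config")
  }
  if (!is_count(horizon) || horizon < 1) {
    ws_abort("horizon must be a positive integer", "wardsim_error_config")
  }
  if (!is_count(n_patients) || n_patients < 1) {
    ws_abort("n_patients must be >= 1", "wardsim_error_config")
  }
  if (!is_count(n_nurses)) {
    ws_abort("n_nurses must be a non-negative integer", "wardsim_error_config")
  }
  if (n_nurses == 0 && policy$variant == "nurse_only") {
    ws_abort("nurse_only policy requires at least one nurse", "wardsim_error_config")
  }
  txt <- floorplan_text(plan)
  digest <- ws_digest(list(
    map = txt$map, sidecar = txt$sidecar,
    patient = unclass(patient_params), iat = unclass(iat_params),
    nurse = unclass(nurse_params),
    policy = list(variant = policy$variant, n_help = policy$n_help),
    n_patients = as.integer(n_patients), n_nurses = as.integer(n_nurses),
    horizon = as.integer(horizon), schedule_shuffle = isTRUE(schedule_shuffle)
  ))
  structure(list(plan = plan, floorplan_path = floorplan_path,
                 patient_params = patient_params, iat_params = iat_params,
                 nurse_params = nurse_params, policy = policy,
                 n_patients = as.integer(n_patients),
                 n_nurses = as.integer(n_nurses),
                 horizon = as.integer(horizon), seed = as.integer(seed),
                 schedule_shuffle = isTRUE(schedule_shuffle),
                 digest = digest),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s | %d patients, %d nurses, horizon %d, seed %d\n",
              x$policy$label, x$n_patients, x$n_nurses, x$horizon, x$seed))
  invisible(x)
}

#' Run one seeded simulation
#'
#' Executes exactly `config$horizon` ticks and returns the run protocol:
#' the per-tick state table for every agent plus the ordered event list.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `run_protocol`: list with `config_digest`, `plan_digest`,
#'   `seed`, `horizon`, `policy_label`, `agents` (tibble: id, role,
#'   start_dest), `state` (tibble: t, id, role, x, y, ori, guide, task)
#'   and `events` (tibble: t, id, ev, patient, dest).
#' @export
#' @examples
#' cfg <- sim_config(demo_ward(), horizon = 50, seed = 1)
#' prot <- run_simulation(cfg)
#' nrow(prot$state)  # 50 ticks x 5 agents
run_simulation <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) {
    ws_abort("config must be a sim_config", "wardsim_error_config")
  }
  seed <- as.integer(seed)
  set.seed(seed)
  plan <- config$plan
  pp <- config$patient_params
  ip <- config$iat_params
  np <- config$nurse_params
  pol <- config$policy
  # hot-loop locals
  dis_level <- pp$dis_level
  reorient_prob <- pp$reorient_prob
  mean_step <- pp$mean_step
  sd_step <- pp$sd_step
  disc_r2 <- np$discovery_radius^2
  horizon <- config$horizon
  n_pat <- config$n_patients
  n_nur <- config$n_nurses
  dest_names <- names(plan$destinations)

  # --- initialize agents ---
  patients <- list()
  for (i in seq_len(n_pat)) {
    sched <- if (config$schedule_shuffle) {
      sample(dest_names)
    } else {
      dest_names[(seq_along(dest_names) + i - 2L) %% length(dest_names) + 1L]
    }
    start_cell <- plan$destinations[[sched[1]]]
    p <- patient_state(paste0("P", i), cell_center(start_cell), sched[2])
    p$schedule <- sched
    p$sched_idx <- 2L
    p$route <- shortest_route(plan, p$position,
                              cell_center(plan$destinations[[sched[2]]]))
    patients[[p$id]] <- p
  }
  nurses <- list()
  if (n_nur > 0) {
    stations <- plan$nurse_stations
    for (j in seq_len(n_nur)) {
      st <- stations[[(j - 1L) %% length(stations) + 1L]]
      n <- nurse_state(paste0("N", j), cell_center(st), st)
      n$at_station <- TRUE
      nurses[[n$id]] <- n
    }
  }
  pat_ids <- names(patients)
  nur_ids <- names(nurses)
  ids <- c(pat_ids, nur_ids)
  n_agents <- length(ids)

  # --- state history (column per agent) ---
  st_x <- matrix(NA_real_, horizon, n_agents, dimnames = list(NULL, ids))
  st_y <- matrix(NA_real_, horizon, n_agents, dimnames = list(NULL, ids))
  st_dis <- matrix(NA, horizon, n_pat, dimnames = list(NULL, pat_ids))
  st_gui <- matrix(NA, horizon, n_pat, dimnames = list(NULL, pat_ids))
  st_task <- matrix(NA_character_, horizon, max(n_nur, 1),
                    dimnames = list(NULL, if (n_nur > 0) nur_ids else "none"))

  events <- vector("list", 256L)
  n_ev <- 0L
  push_ev <- function(rec) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(events)) length(events) <<- 2L * length(events)
    events[[n_ev]] <<- rec
  }
  pending_calls <- character(0)

  # hot-loop geometry locals (wandering is inlined below; disoriented_move
  # implements the identical rule for standalone use)
  walk_grid <- plan$walkable
  grid_h <- plan$height
  grid_w <- plan$width
  smart_watch <- pol$variant == "smart_watch"
  nurse_only <- pol$variant == "nurse_only"
  pat_seq <- seq_len(n_pat)
  nur_seq <- seq_len(n_nur)

  for (t in 0:(horizon - 1L)) {
    row <- t + 1L
    # 1. orientation transitions (inlined transition_orientation: the
    # common no-transition tick costs a single runif per patient)
    for (k in pat_seq) {
      p <- patients[[k]]
      if (p$guidance == "NURSE_GUIDED") next
      if (p$orientation == "ORIENTED") {
        if (dis_level > 0 && runif(1) < dis_level) {
          p$orientation <- "DISORIENTED"
          p$heading <- runif(1, 0, 2 * pi)
          push_ev(ev_rec(t, p$id, "DISORIENT"))
          patients[[k]] <- p
        }
      } else if (reorient_prob > 0 && runif(1) < reorient_prob) {
        p <- reset_watch_state(p)
        p$orientation <- "ORIENTED"
        p$route <- shortest_route(plan, p$position,
                                  cell_center(plan$destinations[[p$destination]]))
        p$progress <- 0
        push_ev(ev_rec(t, p$id, "REORIENT"))
        patients[[k]] <- p
      }
    }
    # 2. smart-watch step (only disoriented wearers engage the automaton)
    if (smart_watch) {
      for (k in pat_seq) {
        p <- patients[[k]]
        if (p$orientation != "DISORIENTED" || p$guidance == "NURSE_GUIDED") next
        res <- iat_step(p, ip, pol, t)
        p <- res$patient
        for (ev in res$events) {
          push_ev(ev_rec(t, p$id, ev))
          if (ev == "NURSE_CALLED" && !(p$id %in% pending_calls)) {
            pending_calls <- c(pending_calls, p$id)
          }
        }
        if (p$needs_route) {
          p$route <- shortest_route(plan, p$position,
                                    cell_center(plan$destinations[[p$destination]]))
          p$progress <- 0
          p$needs_route <- FALSE
        }
        patients[[k]] <- p
      }
    }
    # 3. nurses. Fast path: a routine nurse parked at its station with no
    # pending call and (nurse-only) no discoverable patient nearby does
    # nothing this tick, so nurse_step is skipped.
    for (j in nur_seq) {
      nrs <- nurses[[j]]
      idle <- nrs$task == "ROUTINE" && isTRUE(nrs$at_station) &&
        length(pending_calls) == 0
      if (idle && nurse_only) {
        for (k in pat_seq) {
          p <- patients[[k]]
          if (p$orientation == "DISORIENTED" && p$guidance == "NONE" &&
              (p$position[1] - nrs$position[1])^2 +
              (p$position[2] - nrs$position[2])^2 <= disc_r2) {
            idle <- FALSE
            break
          }
        }
      }
      if (!idle) {
        res <- nurse_step(nrs, np, plan, pending_calls, patients, t,
                          pol = pol, nurses = nurses)
        nrs <- res$nurse
        nurses[[j]] <- nrs
        patients <- res$patients
        pending_calls <- res$pending_calls
        for (rec in res$events) push_ev(rec)
      }
      kk <- n_pat + j
      st_x[row, kk] <- nrs$position[1]
      st_y[row, kk] <- nrs$position[2]
      st_task[row, j] <- nrs$task
    }
    # 4. movement (inlined oriented_move / sample_step_length / correlated
    # random walk), then the end-of-tick snapshot
    for (k in pat_seq) {
      p <- patients[[k]]
      if (p$guidance == "NURSE_GUIDED") {
        st_x[row, k] <- p$position[1]
        st_y[row, k] <- p$position[2]
        st_dis[row, k] <- TRUE
        st_gui[row, k] <- TRUE
        next
      }
      step <- if (sd_step == 0) mean_step else {
        s <- rnorm(1, mean_step, sd_step)
        while (s < 0) s <- rnorm(1, mean_step, sd_step)
        s
      }
      if (p$orientation == "ORIENTED") {
        route <- p$route
        len <- route$total_length
        prog <- p$progress + step
        if (prog >= len) {
          p$progress <- len
          if (len > 0) p$position <- route$waypoints[len + 1L, ]
          push_ev(ev_rec(t, p$id, "DEST_REACHED", dest = p$destination))
          p <- advance_schedule(p, plan)
        } else {
          seg <- floor(prog)
          frac <- prog - seg
          a <- route$waypoints[seg + 1L, ]
          b <- route$waypoints[seg + 2L, ]
          p$position <- a + frac * (b - a)
          p$progress <- prog
        }
        st_dis[row, k] <- FALSE
      } else {
        px <- p$position[1]
        py <- p$position[2]
        for (attempt in 1:8) {
          heading <- if (attempt == 1) p$heading + runif(1, -pi / 2, pi / 2)
                     else runif(1, 0, 2 * pi)
          nx <- px + step * cos(heading)
          ny <- py + step * sin(heading)
          col <- floor(nx) + 1
          rw <- floor(ny) + 1
          if (rw >= 1 && rw <= grid_h && col >= 1 && col <= grid_w &&
              walk_grid[rw, col]) {
            p$position <- c(nx, ny)
            p$heading <- heading
            break
          }
        }
        st_dis[row, k] <- TRUE
      }
      st_x[row, k] <- p$position[1]
      st_y[row, k] <- p$position[2]
      st_gui[row, k] <- FALSE
      patients[[k]] <- p
    }
  }

  # --- assemble protocol ---
  state <- tibble::tibble(
    t = rep(0:(horizon - 1L), times = n_agents),
    id = rep(ids, each = horizon),
    role = rep(c(rep("patient", n_pat), rep("nurse", n_nur)), each = horizon),
    x = as.vector(st_x),
    y = as.vector(st_y),
    ori = c(ifelse(as.vector(st_dis), "D", "O"),
            rep(NA_character_, horizon * n_nur)),
    guide = c(ifelse(as.vector(st_gui), "G", "N"),
              rep(NA_character_, horizon * n_nur)),
    task = c(rep(NA_character_, horizon * n_pat),
             if (n_nur > 0) as.vector(st_task[, seq_len(n_nur), drop = FALSE]))
  )
  state <- dplyr::arrange(state, .data$t, .data$id)

  ev_tbl <- if (n_ev > 0) {
    evs <- events[seq_len(n_ev)]
    tibble::tibble(
      t = vapply(evs, function(e) e$t, integer(1)),
      id = vapply(evs, function(e) e$id, character(1)),
      ev = vapply(evs, function(e) e$ev, character(1)),
      patient = vapply(evs, function(e) e$patient, character(1)),
      dest = vapply(evs, function(e) e$dest, character(1))
    )
  } else {
    tibble::tibble(t = integer(0), id = character(0), ev = character(0),
                   patient = character(0), dest = character(0))
  }

  agents <- tibble::tibble(
    id = ids,
    role = c(rep("patient", n_pat), rep("nurse", n_nur)),
    start_dest = c(unname(vapply(patients, function(p) p$schedule[1], character(1))),
                   rep(NA_character_, n_nur))
  )

  structure(list(config_digest = config$digest,
                 plan_digest = floorplan_digest(plan),
                 seed = seed, horizon = horizon,
                 policy_label = pol$label,
                 n_patients = n_pat, n_nurses = n_nur,
                 agents = agents, state = state, events = ev_tbl),
            class = "run_protocol")
}

#' Run a batch of independent seeded simulations
#'
#' Run `i` (0-based) uses seed `base_seed + i`, so a batch of `n_runs` runs
#' equals the corresponding single runs and batches with the same base seed
#' are pairable across policy conditions.
#'
#' @param config A [sim_config()].
#' @param n_runs Number of runs (>= 1).
#' @param base_seed First seed.
#' @return List of `run_protocol`s.
#' @export
run_batch <- function(config, n_runs, base_seed = config$seed) {
  stopifnot(is_count(n_runs), n_runs >= 1)
  purrr::map(0:(n_runs - 1L), function(i) run_simulation(config, base_seed + i))
}

#' Expected step count between two destinations
#'
#' Averages, over all completed origin-to-destination legs in the supplied
#' protocols, the number of ticks from leg start to the `DEST_REACHED`
#' event. The expected step count is not a simulation parameter; it arises
#' from analysis of multiple run protocols.
#'
#' @param protocols List of `run_protocol`s.
#' @param patient_filter Optional character vector of patient ids.
#' @param origin,dest Destination names; `NULL` matches any.
#' @return A tibble with columns `mean_ticks` and `n_legs`.
#' @export
expected_step_count <- function(protocols, patient_filter = NULL,
                                origin = NULL, dest = NULL) {
  if (inherits(protocols, "run_protocol")) protocols <- list(protocols)
  durations <- numeric(0)
  for (prot in protocols) {
    pats <- prot$agents$id[prot$agents$role == "patient"]
    if (!is.null(patient_filter)) pats <- intersect(pats, patient_filter)
    for (pid in pats) {
      reached <- prot$events[prot$events$ev == "DEST_REACHED" & prot$events$id == pid, ]
      if (nrow(reached) == 0) next
      start_dest <- prot$agents$start_dest[prot$agents$id == pid]
      leg_origin <- c(start_dest, reached$dest[-nrow(reached)])
      # the first leg starts before tick 0 (the patient departs at tick 0),
      # so its notional start tick is -1: durations count movement ticks
      leg_start <- c(-1L, reached$t[-nrow(reached)])
      keep <- rep(TRUE, nrow(reached))
      if (!is.null(origin)) keep <- keep & leg_origin == origin
      if (!is.null(dest)) keep <- keep & reached$dest == dest
      durations <- c(durations, (reached$t - leg_start)[keep])
    }
  }
  if (length(durations) == 0) {
    ws_abort("no completed legs match the requested origin/destination",
             "wardsim_error_empty_sample")
  }
  tibble::tibble(mean_ticks = mean(durations), n_legs = length(durations))
}

#' @export
print.run_protocol <- function(x, ...) {
  cat(sprintf("<run_protocol> %s | seed %d | horizon %d | %d patients, %d nurses | %d events\n",
              x$policy_label, x$seed, x$horizon, x$n_patients, x$n_nurses,
              nrow(x$events)))
  invisible(x)
}
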