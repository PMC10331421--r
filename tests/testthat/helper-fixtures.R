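# Shared fixture builders: tiny floor plans, a hand-built scoring protocol,
# and random connected grids for routing property tests.

# straight one-cell-high corridor of n cells (a wall row below keeps the
# map at the 2-row minimum) with destinations at both ends
corridor_plan <- function(n = 10, stations = list(c(0, 0))) {
  load_floorplan(paste0(strrep(".", n), "\n", strrep("#", n)),
                 list(destinations = list(A = c(0, 0), B = c(0, n - 1)),
                      nurse_stations = stations))
}

# fully open w x h room, destinations in opposite corners
open_plan <- function(w = 5, h = 5) {
  load_floorplan(paste(rep(strrep(".", w), h), collapse = "\n"),
                 list(destinations = list(A = c(0, 0), B = c(h - 1, w - 1)),
                      nurse_stations = list(c(0, w - 1))))
}

# random connected grid <= 20 x 20 for routing property tests: random walls,
# then keep only the largest 4-connected walkable component
random_grid <- function(w, h, p_wall = 0.3) {
  walk <- matrix(stats::runif(w * h) > p_wall, h, w)
  walk[1, 1] <- TRUE
  comp <- matrix(0L, h, w)
  label <- 0L
  for (start in which(walk)) {
    if (comp[start] != 0L) next
    label <- label + 1L
    frontier <- start
    comp[start] <- label
    while (length(frontier) > 0) {
      rows <- (frontier - 1L) %% h + 1L
      nb <- c(frontier[rows > 1L] - 1L, frontier[rows < h] + 1L,
              frontier[frontier > h] - h, frontier[frontier <= h * (w - 1L)] + h)
      nb <- unique(nb[walk[nb] & comp[nb] == 0L])
      comp[nb] <- label
      frontier <- nb
    }
  }
  sizes <- tabulate(comp)
  walk & comp == which.max(sizes)
}

# hand-built 100-tick protocol with exactly known scores: one patient and
# one nurse; the patient is disoriented for `dis_ticks` ticks of which the
# last `guided_ticks` are nurse-guided; the nurse spends `busy_ticks`
# responding/guiding. All geometry is a 12-cell corridor.
fixture_protocol <- function(horizon = 100, dis_ticks = 20, guided_ticks = 5,
                             busy_ticks = 30) {
  stopifnot(guided_ticks <= dis_ticks, dis_ticks <= horizon,
            busy_ticks >= guided_ticks, busy_ticks <= horizon)
  t <- 0:(horizon - 1)
  dis_start <- 10L
  dis <- t >= dis_start & t < dis_start + dis_ticks
  guided <- t >= dis_start + dis_ticks - guided_ticks & t < dis_start + dis_ticks
  # nurse: responds before guiding, then other responding later in the run
  busy <- guided
  extra <- busy_ticks - guided_ticks
  busy[t >= 60 & t < 60 + extra] <- TRUE
  pstate <- tibble::tibble(
    t = t, id = "P1", role = "patient",
    x = pmin(0.5 + t * 0.1, 11.5), y = 0.5,
    ori = ifelse(dis, "D", "O"), guide = ifelse(guided, "G", "N"),
    task = NA_character_)
  nstate <- tibble::tibble(
    t = t, id = "N1", role = "nurse",
    x = 5.5, y = 0.5, ori = NA_character_, guide = NA_character_,
    task = ifelse(busy, ifelse(guided, "GUIDING", "RESPONDING"), "ROUTINE"))
  # events use end-of-tick snapshot semantics: a patient disoriented at tick
  # a and released at tick b shows "D" for ticks a .. b-1
  events <- tibble::tibble(
    t = as.integer(c(dis_start,
                     dis_start + dis_ticks - guided_ticks,
                     dis_start + dis_ticks - guided_ticks,
                     dis_start + dis_ticks,
                     dis_start + dis_ticks)),
    id = c("P1", "N1", "N1", "N1", "P1"),
    ev = c("DISORIENT", "NURSE_ARRIVED", "GUIDE_START", "GUIDE_END", "REORIENT"),
    patient = c(NA, "P1", "P1", "P1", NA),
    dest = NA_character_)
  # the fixture is synthetic: its digest marks it as hand-built
  structure(list(config_digest = "fixture-digest", plan_digest = "fixture-plan",
                 seed = 0L, horizon = as.integer(horizon),
                 policy_label = "Nhelp=0", n_patients = 1L, n_nurses = 1L,
                 agents = tibble::tibble(id = c("P1", "N1"),
                                         role = c("patient", "nurse"),
                                         start_dest = c("A", NA)),
                 state = dplyr::arrange(dplyr::bind_rows(pstate, nstate), t, id),
                 events = events),
            class = "run_protocol")
}

# small demo-ward config for engine tests
demo_cfg <- function(horizon = 200, seed = 1, ...) {
  sim_config(demo_ward(), horizon = horizon, seed = seed, ...)
}

# accounting identity helpers used by engine and acceptance tests:
# disoriented tick counts derived from the state table and from the event
# stream must agree for every patient
state_dis_ticks <- function(prot, pid) {
  st <- prot$state
  sum(st$id == pid & st$ori == "D", na.rm = TRUE)
}

event_dis_ticks <- function(prot, pid) {
  ev <- prot$events
  ev <- ev[(ev$id == pid & ev$ev %in% c("DISORIENT", "REORIENT")) |
             (ev$ev == "GUIDE_END" & !is.na(ev$patient) & ev$patient == pid), ]
  total <- 0L
  open_t <- NA_integer_
  for (i in seq_len(nrow(ev))) {
    if (ev$ev[i] == "DISORIENT") {
      open_t <- ev$t[i]
    } else if (!is.na(open_t)) {
      total <- total + (ev$t[i] - open_t)
      open_t <- NA_integer_
    }
  }
  if (!is.na(open_t)) total <- total + (prot$horizon - open_t)
  total
}
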