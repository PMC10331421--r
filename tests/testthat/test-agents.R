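test_that("step-length sampler follows the truncated normal contract", {
  # degenerate distribution: no randomness at all
  p0 <- patient_params(sd_step = 0)
  set.seed(1)
  expect_identical(replicate(5, sample_step_length(p0)), rep(1.0, 5))
  # truncation: heavily negative-mass settings still never go below 0
  pt <- patient_params(mean_step = 0.1, sd_step = 5)
  set.seed(2)
  expect_true(all(replicate(500, sample_step_length(pt)) >= 0))
  # law of large numbers on the nominal demo setting
  pn <- patient_params(mean_step = 1, sd_step = 0.2)
  set.seed(3)
  draws <- replicate(10000, sample_step_length(pn))
  expect_lt(abs(mean(draws) - 1), 0.01)
  set.seed(4)
  draws <- replicate(50000, sample_step_length(pn))
  expect_lt(abs(stats::sd(draws) - 0.2) / 0.2, 0.05)
})

test_that("oriented movement advances along the route and clamps at the destination", {
  corr <- corridor_plan(10)
  route <- shortest_route(corr, c(0.5, 0.5), c(9.5, 0.5))
  pp <- patient_params(mean_step = 1, sd_step = 0)
  p <- patient_state("P1", c(0.5, 0.5), "B")
  p$route <- route
  # deterministic limit: exactly 9 unit segments -> 9 ticks to arrive
  ticks <- 0
  while (!p$reached_dest) {
    p <- oriented_move(p, params = pp)
    ticks <- ticks + 1
    expect_lte(ticks, 20)
  }
  expect_equal(ticks, 9)
  expect_equal(p$position, c(9.5, 0.5))
  # clamping: a large sampled step never overshoots
  p2 <- patient_state("P1", c(0.5, 0.5), "B")
  p2$route <- route
  p2$progress <- 8.8
  big <- patient_params(mean_step = 5, sd_step = 0)
  p2 <- oriented_move(p2, params = big)
  expect_true(p2$reached_dest)
  expect_equal(p2$position, c(9.5, 0.5))
  # a patient with no route at all is an internal inconsistency
  p3 <- patient_state("P1", c(0.5, 0.5), "B")
  expect_error(oriented_move(p3, params = pp), class = "wardsim_error_internal")
})

test_that("disoriented wandering respects walls", {
  # boxed into a single walkable pocket: never moves
  pocket <- load_floorplan("###\n#.#\n###",
                           list(destinations = list(A = c(1, 1), B = c(1, 1)),
                                nurse_stations = list()))
  pp <- patient_params()
  p <- patient_state("P1", c(1.5, 1.5), "A", orientation = "DISORIENTED")
  set.seed(5)
  for (i in 1:50) {
    p <- disoriented_move(p, pocket, pp)
    # never leaves the single walkable cell (row 2, col 2)
    expect_identical(c(floor(p$position[2]) + 1, floor(p$position[1]) + 1), c(2, 2))
  }
  # long unguided walk on the demo ward: every visited cell is walkable
  plan <- demo_ward()
  p <- patient_state("P1", c(5.5, 2.5), "room_1", orientation = "DISORIENTED")
  set.seed(6)
  ok <- TRUE
  for (i in 1:2000) {
    p <- disoriented_move(p, plan, pp)
    cell <- c(floor(p$position[2]) + 1, floor(p$position[1]) + 1)
    ok <- ok && plan$walkable[cell[1], cell[2]]
  }
  expect_true(ok)
})

test_that("zero turn range reduces wandering to straight-line walking", {
  corr <- corridor_plan(200)
  pp <- patient_params(mean_step = 1, sd_step = 0)
  p <- patient_state("P1", c(0.5, 0.5), "B", orientation = "DISORIENTED",
                     heading = 0)
  traj <- matrix(NA_real_, 51, 2)
  traj[1, ] <- p$position
  set.seed(7)
  for (i in 1:50) {
    p <- disoriented_move(p, corr, pp, turn_range = 0)
    traj[i + 1, ] <- p$position
  }
  expect_equal(path_length(traj), 50 * 1.0)
  expect_equal(p$position[1], 50.5)
})

test_that("orientation transitions follow the disorientation probability", {
  corr <- corridor_plan(10)
  # zero probability: never leaves ORIENTED
  p <- patient_state("P1", c(0.5, 0.5), "B")
  set.seed(8)
  for (i in 1:200) {
    p <- transition_orientation(p, patient_params(dis_level = 0))
    expect_identical(p$orientation, "ORIENTED")
  }
  # certain event: disoriented at the first en-route tick
  set.seed(9)
  p <- transition_orientation(patient_state("P1", c(0.5, 0.5), "B"),
                              patient_params(dis_level = 1))
  expect_identical(p$orientation, "DISORIENTED")
  expect_identical(p$transitioned, "DISORIENT")
  # guided patients never transition here
  g <- patient_state("P1", c(0.5, 0.5), "B", orientation = "DISORIENTED",
                     guidance = "NURSE_GUIDED")
  set.seed(10)
  g <- transition_orientation(g, patient_params(dis_level = 1, reorient_prob = 1))
  expect_identical(g$orientation, "DISORIENTED")
  # empirical rate inside the exact 99% binomial interval at n = 10000
  pp <- patient_params(dis_level = 0.25)
  set.seed(11)
  hits <- 0L
  for (i in 1:10000) {
    q <- transition_orientation(patient_state("P1", c(0.5, 0.5), "B"), pp)
    hits <- hits + (q$orientation == "DISORIENTED")
  }
  bounds <- stats::qbinom(c(0.005, 0.995), 10000, 0.25) / 10000
  expect_gte(hits / 10000, bounds[1])
  expect_lte(hits / 10000, bounds[2])
})

test_that("the cue automaton escalates after exactly n_help failed cues", {
  iat <- iat_params(p_detect = 1, p_cue_success = 0, cue_cooldown = 1)
  pol <- policy("smart_watch", n_help = 2)
  p <- patient_state("P1", c(0.5, 0.5), "B", orientation = "DISORIENTED")
  seen <- character(0)
  set.seed(12)
  for (t in 0:10) {
    res <- iat_step(p, iat, pol, t)
    p <- res$patient
    seen <- c(seen, res$events)
    if ("NURSE_CALLED" %in% res$events) break
  }
  expect_identical(seen, c("DETECT", "CUE_ISSUED", "CUE_FAIL",
                           "CUE_ISSUED", "CUE_FAIL", "NURSE_CALLED"))
  expect_lte(p$failed_cues, 2L)

  # immediate escalation: n_help = 0 calls on the first tick of the episode
  p0 <- patient_state("P1", c(0.5, 0.5), "B", orientation = "DISORIENTED")
  res <- iat_step(p0, iat_params(p_detect = 1), policy("smart_watch", 0), 0)
  expect_identical(res$events, c("DETECT", "NURSE_CALLED"))

  # non-watch policies emit nothing for any state
  for (variant in c("nurse_only", "no_help")) {
    res <- iat_step(p0, iat_params(p_detect = 1), policy(variant), 0)
    expect_identical(res$events, character(0))
  }

  # failed_cues is bounded by n_help under any seed
  set.seed(13)
  for (rep in 1:20) {
    nh <- sample(0:4, 1)
    polr <- policy("smart_watch", nh)
    iatr <- iat_params(p_detect = 0.5, p_cue_success = 0.3, cue_cooldown = 1)
    q <- patient_state("P1", c(0.5, 0.5), "B", orientation = "DISORIENTED")
    for (t in 0:60) {
      q <- iat_step(q, iatr, polr, t)$patient
      expect_lte(q$failed_cues, nh)
      if (q$orientation == "ORIENTED") break
    }
  }
})

test_that("a cue success restores orientation and resets the episode state", {
  iat <- iat_params(p_detect = 1, p_cue_success = 1, cue_cooldown = 1)
  pol <- policy("smart_watch", n_help = 3)
  p <- patient_state("P1", c(0.5, 0.5), "B", orientation = "DISORIENTED")
  set.seed(14)
  p <- iat_step(p, iat, pol, 0)$patient    # DETECT
  res <- iat_step(p, iat, pol, 1)          # CUE_ISSUED + CUE_SUCCESS
  expect_true(all(c("CUE_ISSUED", "CUE_SUCCESS", "REORIENT") %in% res$events))
  expect_identical(res$patient$orientation, "ORIENTED")
  expect_false(res$patient$detected)
  expect_identical(res$patient$failed_cues, 0L)
})

test_that("nurses respond, arrive on schedule, guide, and queue excess calls", {
  corr <- corridor_plan(12, stations = list(c(0, 0)))
  np <- nurse_params(speed = 2)
  pol <- policy("smart_watch", 0)
  # arrival after ceil(distance / speed) ticks on a straight corridor
  nurse <- nurse_state("N1", c(0.5, 0.5), c(1L, 1L), task = "ROUTINE")
  patient <- patient_state("P1", c(6.5, 0.5), "A", orientation = "DISORIENTED")
  patients <- list(P1 = patient)
  pending <- "P1"
  arrived_at <- NA
  for (t in 0:9) {
    res <- nurse_step(nurse, np, corr, pending, patients, t, pol = pol)
    nurse <- res$nurse
    patients <- res$patients
    pending <- res$pending_calls
    if (any(vapply(res$events, function(e) e$ev == "NURSE_ARRIVED", logical(1)))) {
      arrived_at <- t
      break
    }
  }
  expect_equal(arrived_at, ceiling(6 / 2) - 1)  # ticks 0,1,2 -> 3 ticks of travel
  expect_identical(nurse$task, "GUIDING")
  expect_identical(patients$P1$guidance, "NURSE_GUIDED")

  # a second simultaneous call waits in the queue until GUIDE_END
  p2 <- patient_state("P2", c(11.5, 0.5), "A", orientation = "DISORIENTED")
  patients$P2 <- p2
  pending <- "P2"
  saw_guide_end <- FALSE
  for (t in 10:60) {
    res <- nurse_step(nurse, np, corr, pending, patients, t, pol = pol)
    nurse <- res$nurse
    patients <- res$patients
    pending <- res$pending_calls
    evs <- vapply(res$events, function(e) e$ev, character(1))
    if (!saw_guide_end && length(pending) > 0) {
      expect_identical(pending, "P2")  # still queued while guiding P1
    }
    if ("GUIDE_END" %in% evs) { saw_guide_end <- TRUE }
    if (saw_guide_end && nurse$task == "RESPONDING") break
  }
  expect_true(saw_guide_end)
  expect_identical(nurse$assigned_patient, "P2")

  # a call whose patient already reoriented is dropped with CANCELLED
  nr <- nurse_state("N9", c(0.5, 0.5), c(1L, 1L))
  ok_p <- patient_state("P3", c(3.5, 0.5), "A", orientation = "ORIENTED")
  res <- nurse_step(nr, np, corr, "P3", list(P3 = ok_p), 0, pol = pol)
  expect_identical(res$pending_calls, character(0))
  expect_true(any(vapply(res$events, function(e) e$ev == "CANCELLED", logical(1))))
})

test_that("nurse-only discovery fires within the discovery radius on the same tick", {
  corr <- corridor_plan(12, stations = list(c(0, 2)))
  np <- nurse_params(speed = 1, discovery_radius = 5)
  nurse <- nurse_state("N1", c(2.5, 0.5), c(1L, 3L), task = "ROUTINE")
  patient <- patient_state("P1", c(3.0, 0.5), "A", orientation = "DISORIENTED")
  res <- nurse_step(nurse, np, corr, character(0), list(P1 = patient), 0,
                    pol = policy("nurse_only"))
  evs <- vapply(res$events, function(e) e$ev, character(1))
  expect_true("DISCOVERED" %in% evs)
  expect_identical(res$nurse$assigned_patient, "P1")
})
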