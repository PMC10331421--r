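# Ethical Compliance Quantification: value models map run protocols to
# scores in [0, 1]; ECQ evaluation fills a runs x value-models score matrix
# per policy condition and summarizes it, enabling policy comparison.
#
# Polarity matters for reading the scores: VIOLATION models (safety,
# fairness_guidance) are best at 0; COMPLIANCE models (efficiency,
# fairness_quotient) are best at 1.

check_patient_id <- function(protocol, patient_id) {
  pats <- protocol$agents$id[protocol$agents$role == "patient"]
  if (!patient_id %in% pats) {
    ws_abort(paste0("unknown patient id: ", patient_id), "wardsim_error_lookup")
  }
  invisible(patient_id)
}

#' Safety scores (violation polarity)
#'
#' `safety_original()` scores the fraction of a patient's ticks spent
#' disoriented, regardless of whether a nurse is guiding them — the naive
#' operationalization of "unsafe time". `safety_refined()` counts only
#' ticks spent disoriented *and unguided*: time at a nurse's side is safe.
#' The contrast between the two is the worked example of value-
#' operationalization feedback: the original version scores
#' immediate-escalation policies as *less* safe, which is implausible, and
#' the refined version corrects it.
#'
#' @param protocol A `run_protocol`.
#' @param patient_id Patient id (e.g. `"P1"`).
#' @return Violation score in `[0, 1]`.
#' @export
safety_original <- function(protocol, patient_id) {
  check_patient_id(protocol, patient_id)
  st <- protocol$state
  rows <- st$id == patient_id
  sum(st$ori[rows] == "D") / protocol$horizon
}

#' @rdname safety_original
#' @export
safety_refined <- function(protocol, patient_id) {
  check_patient_id(protocol, patient_id)
  st <- protocol$state
  rows <- st$id == patient_id
  sum(st$ori[rows] == "D" & st$guide[rows] == "N") / protocol$horizon
}

#' Fairness of caregiver time (violation polarity)
#'
#' The fraction of total nurse duty time (`n_nurses x horizon` ticks) spent
#' responding to or guiding disoriented patients — caregiver time lost to
#' route guidance. Its complement is the time available for other forms of
#' caregiving.
#'
#' @param protocol A `run_protocol` with at least one nurse.
#' @return Violation score in `[0, 1]`.
#' @export
fairness_guidance <- function(protocol) {
  if (protocol$n_nurses == 0) {
    ws_abort("fairness_guidance is undefined for runs without nurses",
             "wardsim_error_undefined_score")
  }
  st <- protocol$state
  busy <- sum(st$task %in% c("RESPONDING", "GUIDING"), na.rm = TRUE)
  busy / (protocol$n_nurses * protocol$horizon)
}

#' Route efficiency of one completed leg (compliance polarity)
#'
#' The ratio of straight-line distance between the leg's endpoints to the
#' distance actually travelled, clamped to `[0, 1]`. A perfectly straight
#' walk scores 1; wandering lowers the score.
#'
#' @param trajectory An n x 2 matrix (or data frame with x/y columns) of
#'   positions for one completed leg; must have at least 2 positions and
#'   positive path length.
#' @return Compliance score in `[0, 1]`.
#' @export
efficiency <- function(trajectory) {
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) < 2 || path_length(trajectory) == 0) {
    ws_abort("efficiency is undefined for a degenerate leg (needs >= 2 positions and positive path length)",
             "wardsim_error_degenerate_leg")
  }
  clamp01(straight_line_distance(trajectory[1, ], trajectory[nrow(trajectory), ]) /
            path_length(trajectory))
}

#' Fairness quotient of two efficiency scores (compliance polarity)
#'
#' `min(a, b) / max(a, b)`: symmetric in its arguments and equal to 1 iff
#' both stakeholders experience equal efficiency (optimal fairness).
#'
#' @param eff_a,eff_b Efficiency scores in `(0, 1]`.
#' @return Compliance score in `(0, 1]`.
#' @export
fairness_quotient <- function(eff_a, eff_b) {
  if (!is.numeric(eff_a) || !is.numeric(eff_b) || eff_a <= 0 || eff_b <= 0 ||
      eff_a > 1 || eff_b > 1) {
    ws_abort("fairness_quotient requires efficiency scores in (0, 1]",
             "wardsim_error_undefined_quotient")
  }
  min(eff_a, eff_b) / max(eff_a, eff_b)
}

#' Extract per-leg trajectories for one patient
#'
#' Legs are delimited by `DEST_REACHED` events; the trajectory of a leg is
#' the sequence of recorded positions from the previous arrival (or the
#' run's start destination) to the arrival tick.
#'
#' @param protocol A `run_protocol`.
#' @param patient_id Patient id.
#' @return List of n x 2 position matrices, one per completed leg (possibly
#'   empty).
#' @export
patient_leg_trajectories <- function(protocol, patient_id) {
  check_patient_id(protocol, patient_id)
  st <- protocol$state[protocol$state$id == patient_id, ]
  st <- st[order(st$t), ]
  reached <- protocol$events[protocol$events$ev == "DEST_REACHED" &
                               protocol$events$id == patient_id, ]
  if (nrow(reached) == 0) return(list())
  bounds <- c(-1L, reached$t)
  lapply(seq_len(nrow(reached)), function(k) {
    # state records are end-of-tick snapshots: a leg runs from the previous
    # arrival snapshot (or tick 0 for the first leg) to the arrival tick
    ticks <- max(bounds[k], 0L):bounds[k + 1L]
    as.matrix(st[st$t %in% ticks, c("x", "y")])
  })
}

#' Count a qualitative requirement over runs
#'
#' Evaluates a requirement predicate once per protocol. The predicate
#' returns `TRUE` when the requirement is satisfied (observed), `FALSE`
#' when it is violated, and `NA` when it does not apply to the run.
#'
#' @param protocols List of `run_protocol`s.
#' @param predicate Function `run_protocol -> TRUE/FALSE/NA`.
#' @return A tibble with columns `n_runs`, `observed`, `violated`,
#'   `fraction_violated` (violated / evaluated runs; 0 when the predicate
#'   never applied).
#' @export
count_requirement <- function(protocols, predicate) {
  if (inherits(protocols, "run_protocol")) protocols <- list(protocols)
  stopifnot(length(protocols) >= 1)
  res <- vapply(protocols, function(p) as.logical(predicate(p)), logical(1))
  observed <- sum(res, na.rm = TRUE)
  violated <- sum(!res, na.rm = TRUE)
  evaluated <- observed + violated
  tibble::tibble(n_runs = length(protocols), observed = observed,
                 violated = violated,
                 fraction_violated = if (evaluated == 0) 0 else violated / evaluated)
}

# ---- value models ----

#' Define a value model
#'
#' A value model is a named scoring function from a run protocol to a score
#' in `[0, 1]`, together with its polarity (`"VIOLATION"`: 0 is fully
#' compliant; `"COMPLIANCE"`: 1 is optimal).
#'
#' @param name Short name used in score tables and plot legends.
#' @param score_fn Function `run_protocol -> numeric scalar`; output is
#'   clamped to `[0, 1]`.
#' @param polarity `"VIOLATION"` or `"COMPLIANCE"`.
#' @param patient_fn Optional function `(run_protocol, patient_id) ->
#'   score` providing per-patient scores (kept for distributional
#'   analysis).
#' @return A `value_model`.
#' @export
value_model <- function(name, score_fn, polarity = c("VIOLATION", "COMPLIANCE"),
                        patient_fn = NULL) {
  polarity <- match.arg(polarity)
  stopifnot(is.character(name), length(name) == 1, is.function(score_fn))
  structure(list(name = name, score_fn = score_fn, polarity = polarity,
                 patient_fn = patient_fn),
            class = "value_model")
}

aggregate_patients <- function(protocol, patient_fn, aggregate) {
  pats <- protocol$agents$id[protocol$agents$role == "patient"]
  scores <- vapply(pats, function(pid) patient_fn(protocol, pid), numeric(1))
  if (aggregate == "max") max(scores) else mean(scores)
}

#' Built-in value models
#'
#' `vm_safety_original()` and `vm_safety_refined()` aggregate the
#' per-patient safety scores within a run (mean by default, `"max"` for a
#' worst-case reading); `vm_fairness_guidance()` scores caregiver time lost
#' to guidance; `vm_efficiency()` averages leg efficiency over all
#' patients' completed legs (runs without a completed leg score the partial
#' first leg, and a patient who never moved scores 1).
#'
#' @param aggregate `"mean"` or `"max"` across patients within a run.
#' @return A [value_model()].
#' @export
vm_safety_original <- function(aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  value_model("safety_original",
              function(p) aggregate_patients(p, safety_original, aggregate),
              "VIOLATION", patient_fn = safety_original)
}

#' @rdname vm_safety_original
#' @export
vm_safety_refined <- function(aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  value_model("safety_refined",
              function(p) aggregate_patients(p, safety_refined, aggregate),
              "VIOLATION", patient_fn = safety_refined)
}

#' @rdname vm_safety_original
#' @export
vm_fairness_guidance <- function() {
  value_model("fairness", fairness_guidance, "VIOLATION")
}

#' @rdname vm_safety_original
#' @export
vm_efficiency <- function() {
  value_model("efficiency", function(protocol) {
    pats <- protocol$agents$id[protocol$agents$role == "patient"]
    scores <- unlist(lapply(pats, function(pid) {
      legs <- patient_leg_trajectories(protocol, pid)
      if (length(legs) == 0) {
        st <- protocol$state[protocol$state$id == pid, c("x", "y")]
        if (path_length(as.matrix(st)) == 0) return(1)
        legs <- list(as.matrix(st))
      }
      vapply(legs, function(traj) {
        if (nrow(traj) < 2 || path_length(traj) == 0) 1 else efficiency(traj)
      }, numeric(1))
    }))
    mean(scores)
  }, "COMPLIANCE")
}

builtin_value_models <- function(names) {
  all <- list(safety_original = vm_safety_original(),
              safety_refined = vm_safety_refined(),
              fairness = vm_fairness_guidance(),
              efficiency = vm_efficiency())
  unknown <- setdiff(names, names(all))
  if (length(unknown) > 0) {
    ws_abort(paste0("unknown value model(s): ", paste(unknown, collapse = ", "),
                    " (available: ", paste(names(all), collapse = ", "), ")"),
             "wardsim_error_lookup")
  }
  unname(all[names])
}

# score one protocol under all value models; returns per-run and
# per-patient score rows
score_protocol <- function(protocol, value_models, policy_label, run_index) {
  rows <- purrr::map(value_models, function(vm) {
    tibble::tibble(policy = policy_label, run = run_index,
                   seed = protocol$seed, config_digest = protocol$config_digest,
                   value = vm$name, polarity = vm$polarity,
                   score = clamp01(vm$score_fn(protocol)))
  })
  pat_rows <- purrr::map(value_models, function(vm) {
    if (is.null(vm$patient_fn)) return(NULL)
    pats <- protocol$agents$id[protocol$agents$role == "patient"]
    tibble::tibble(policy = policy_label, run = run_index,
                   seed = protocol$seed, patient = pats,
                   value = vm$name,
                   score = vapply(pats, function(pid) {
                     clamp01(vm$patient_fn(protocol, pid))
                   }, numeric(1)))
  })
  list(scores = dplyr::bind_rows(rows), patient_scores = dplyr::bind_rows(pat_rows))
}

empty_scores <- function() {
  tibble::tibble(policy = character(0), run = integer(0), seed = integer(0),
                 config_digest = character(0), value = character(0),
                 polarity = character(0), score = numeric(0))
}

new_ecq_result <- function(scores, patient_scores, policy_order) {
  structure(list(scores = scores, patient_scores = patient_scores,
                 policy_order = policy_order),
            class = "ecq_result")
}

#' Evaluate value models over a set of run protocols
#'
#' All protocols must come from the same simulation condition (identical
#' config digests): ECQ compares like with like. Per-run scores are the
#' value-model outputs; per-patient safety scores are kept alongside.
#'
#' @param protocols List of `run_protocol`s (same config digest).
#' @param value_models List of [value_model()]s (possibly empty).
#' @param policy_label Label for the condition; defaults to the protocols'
#'   policy label.
#' @return An `ecq_result`; see [tidy.ecq_result()] / [glance.ecq_result()].
#' @export
ecq_evaluate <- function(protocols, value_models, policy_label = NULL) {
  if (inherits(protocols, "run_protocol")) protocols <- list(protocols)
  stopifnot(length(protocols) >= 1)
  digests <- vapply(protocols, function(p) p$config_digest, character(1))
  if (length(unique(digests)) > 1) {
    ws_abort("protocols mix different simulation conditions (config digests differ)",
             "wardsim_error_heterogeneous")
  }
  policy_label <- policy_label %||% protocols[[1]]$policy_label %||% "condition"
  if (length(value_models) == 0) {
    return(new_ecq_result(empty_scores(), NULL, policy_label))
  }
  if (inherits(value_models, "value_model")) value_models <- list(value_models)
  scored <- purrr::imap(protocols, function(p, i) {
    score_protocol(p, value_models, policy_label, as.integer(i))
  })
  new_ecq_result(dplyr::bind_rows(purrr::map(scored, "scores")),
                 dplyr::bind_rows(purrr::map(scored, "patient_scores")),
                 policy_label)
}

#' Sweep a list of policies and evaluate value models
#'
#' For each policy the same `n_runs` seeds (`base_seed + 0 ... n_runs - 1`)
#' are used, so conditions are paired and Monte-Carlo noise largely cancels
#' in cross-policy comparisons. Protocols are scored as they are produced
#' and not retained.
#'
#' @param config A [sim_config()]; its `policy` field is replaced by each
#'   swept policy in turn.
#' @param policies List of [policy()] objects (or policy strings).
#' @param n_runs Runs per policy.
#' @param value_models List of [value_model()]s.
#' @param base_seed First seed, shared across policies.
#' @return An `ecq_result` whose `scores` tibble has one row per
#'   run x value model x policy.
#' @export
#' @examples
#' cfg <- sim_config(demo_ward(), horizon = 200)
#' res <- policy_sweep(cfg, list("smart_watch:0", "no_help"), n_runs = 2,
#'                     value_models = list(vm_safety_refined()), base_seed = 1)
#' glance(res)
policy_sweep <- function(config, policies, n_runs, value_models, base_seed = 1) {
  stopifnot(length(policies) >= 1, is_count(n_runs), n_runs >= 1)
  policies <- purrr::map(policies, function(p) {
    if (is.character(p)) parse_policy(p) else p
  })
  labels <- vapply(policies, function(p) p$label, character(1))
  all_scores <- list()
  all_patients <- list()
  for (k in seq_along(policies)) {
    cfg <- sim_config(config$plan,
                      patient_params = config$patient_params,
                      iat_params = config$iat_params,
                      nurse_params = config$nurse_params,
                      policy = policies[[k]],
                      n_patients = config$n_patients,
                      n_nurses = config$n_nurses,
                      horizon = config$horizon, seed = config$seed,
                      schedule_shuffle = config$schedule_shuffle)
    for (i in seq_len(n_runs)) {
      prot <- run_simulation(cfg, base_seed + i - 1L)
      scored <- score_protocol(prot, value_models, labels[k], i)
      all_scores[[length(all_scores) + 1L]] <- scored$scores
      all_patients[[length(all_patients) + 1L]] <- scored$patient_scores
    }
  }
  new_ecq_result(dplyr::bind_rows(all_scores), dplyr::bind_rows(all_patients),
                 labels)
}

# ---- broom-style accessors ----

#' Tidy and summarize ECQ results
#'
#' `tidy()` returns the per-run score table (one row per run x value model
#' x policy, with seed and config-digest provenance); `glance()` returns
#' per policy x value model summaries (mean, median, quartiles, min, max,
#' n); both recompute nothing — summaries always match the score matrix.
#'
#' @param x An `ecq_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ecq_result
#' @export
tidy.ecq_result <- function(x, ...) {
  x$scores
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidy.ecq_result
#' @method glance ecq_result
#' @export
glance.ecq_result <- function(x, ...) {
  x$scores |>
    dplyr::group_by(.data$policy, .data$value, .data$polarity) |>
    dplyr::summarise(mean = mean(.data$score), median = stats::median(.data$score),
                     q25 = stats::quantile(.data$score, 0.25),
                     q75 = stats::quantile(.data$score, 0.75),
                     min = min(.data$score), max = max(.data$score),
                     n_runs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$policy, order_policy_labels(unique(.data$policy))),
                   .data$value)
}

#' @export
print.ecq_result <- function(x, ...) {
  cat(sprintf("<ecq_result> %d policies x %d value models, %d score rows\n",
              length(unique(x$scores$policy)), length(unique(x$scores$value)),
              nrow(x$scores)))
  if (nrow(x$scores) > 0) print(glance(x))
  invisible(x)
}

# canonical policy display order: Nhelp ascending, then Nurse Only, No Help
order_policy_labels <- function(labels) {
  labels <- unique(labels)
  nhelp <- grepl("^Nhelp=", labels)
  nh <- labels[nhelp][order(as.integer(sub("^Nhelp=", "", labels[nhelp])))]
  rest <- c(intersect(c("Nurse Only", "No Help"), labels),
            setdiff(labels[!nhelp], c("Nurse Only", "No Help")))
  c(nh, rest)
}

#' Export ECQ scores and summaries
#'
#' `write_scores_csv()` writes one row per run x value model (columns:
#' policy, run, seed, value, polarity, score); `write_summary_json()`
#' writes the [glance.ecq_result()] summaries as JSON keyed by policy.
#'
#' @param result An `ecq_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(result, path) {
  utils::write.csv(result$scores[, c("policy", "run", "seed", "value",
                                     "polarity", "score")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
write_summary_json <- function(result, path) {
  g <- glance(result)
  by_policy <- split(g[, setdiff(names(g), "policy")], g$policy)
  by_policy <- by_policy[order_policy_labels(names(by_policy))]
  jsonlite::write_json(by_policy, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
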