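# Run-protocol JSONL serialization. Layout: first line a header record
# {config_digest, plan_digest, seed, horizon, policy, agents}; then one
# state record per tick per agent {"t","id","pos":[x,y],"ori","guide","task"};
# then event records {"t","id","ev","patient","dest"}. Numbers are written
# with full round-trip precision so write -> read is the identity and
# serialized bytes are a pure function of (config, seed).

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # shortest exact representation: prefer fewer digits when they round-trip
  for (digits in c(1L, 6L, 10L, 15L)) {
    cand <- sprintf(paste0("%.", digits, "g"), x)
    ok <- as.numeric(cand) == x
    out[ok] <- cand[ok]
  }
  out
}

json_str <- function(x) {
  ifelse(is.na(x), "null", paste0('"', gsub('"', '\\\\"', x), '"'))
}

#' Write / read run protocols (JSONL)
#'
#' @param protocol A `run_protocol`.
#' @param path File path. `write_protocol()` can append, so several
#'   protocols may share one file; [read_protocols()] reads them all and
#'   `read_protocol()` reads the first.
#' @param append Append to an existing protocol file.
#' @return `write_protocol()` returns `path` invisibly; the readers return
#'   `run_protocol` objects (validated; schema or invariant violations
#'   raise `wardsim_error_parse` naming the offending line or invariant).
#' @export
write_protocol <- function(protocol, path, append = FALSE) {
  stopifnot(inherits(protocol, "run_protocol"))
  header <- jsonlite::toJSON(
    list(config_digest = protocol$config_digest,
         plan_digest = protocol$plan_digest,
         seed = protocol$seed, horizon = protocol$horizon,
         policy = protocol$policy_label,
         agents = protocol$agents),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  st <- protocol$state
  state_lines <- sprintf(
    '{"t":%d,"id":%s,"pos":[%s,%s],"ori":%s,"guide":%s,"task":%s}',
    st$t, json_str(st$id), fmt_num(st$x), fmt_num(st$y),
    json_str(st$ori), json_str(st$guide), json_str(st$task))
  ev <- protocol$events
  event_lines <- if (nrow(ev) > 0) {
    sprintf('{"t":%d,"id":%s,"ev":%s,"patient":%s,"dest":%s}',
            ev$t, json_str(ev$id), json_str(ev$ev),
            json_str(ev$patient), json_str(ev$dest))
  } else {
    character(0)
  }
  con <- file(path, open = if (append) "ab" else "wb")
  on.exit(close(con))
  writeLines(c(as.character(header), state_lines, event_lines), con)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocols <- function(path) {
  if (!file.exists(path)) {
    ws_abort(paste0("protocol file not found: ", path), "wardsim_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    ws_abort("missing header record: protocol file is empty", "wardsim_error_parse")
  }
  is_header <- grepl('"config_digest"', lines, fixed = TRUE)
  if (!is_header[1]) {
    ws_abort("missing header record on line 1", "wardsim_error_parse")
  }
  starts <- which(is_header)
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map2(starts, ends, function(s, e) {
    parse_protocol_lines(lines[s:e], first_line = s)
  })
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  read_protocols(path)[[1]]
}

parse_protocol_lines <- function(lines, first_line = 1L) {
  header <- tryCatch(
    jsonlite::fromJSON(lines[1], simplifyVector = TRUE),
    error = function(e) {
      ws_abort(paste0("malformed header record on line ", first_line),
               "wardsim_error_parse")
    })
  for (field in c("config_digest", "seed", "horizon", "agents")) {
    if (is.null(header[[field]])) {
      ws_abort(paste0("header record is missing field '", field, "' (line ",
                      first_line, ")"), "wardsim_error_parse")
    }
  }
  body <- lines[-1]
  body_line_no <- first_line + seq_along(body)
  bad <- !grepl("^\\{", body)
  if (any(bad)) {
    ws_abort(paste0("malformed record on line ", body_line_no[which(bad)[1]]),
             "wardsim_error_parse")
  }
  is_event <- grepl('"ev":', body, fixed = TRUE)
  parse_block <- function(txt, what, line_nos) {
    if (length(txt) == 0) return(NULL)
    arr <- paste0("[", paste(txt, collapse = ","), "]")
    tryCatch(
      jsonlite::fromJSON(arr, simplifyVector = TRUE),
      error = function(e) {
        # bisect to report the offending line
        for (i in seq_along(txt)) {
          ok <- tryCatch({jsonlite::fromJSON(txt[i]); TRUE},
                         error = function(e) FALSE)
          if (!ok) {
            ws_abort(paste0("malformed ", what, " record on line ", line_nos[i]),
                     "wardsim_error_parse")
          }
        }
        ws_abort(paste0("malformed ", what, " records"), "wardsim_error_parse")
      })
  }
  st_df <- parse_block(body[!is_event], "state", body_line_no[!is_event])
  ev_df <- parse_block(body[is_event], "event", body_line_no[is_event])
  if (is.null(st_df)) {
    ws_abort("protocol contains no state records", "wardsim_error_parse")
  }
  pos <- do.call(rbind, st_df$pos)
  agents <- tibble::as_tibble(header$agents)
  if (!"start_dest" %in% names(agents)) agents$start_dest <- NA_character_
  role_of <- stats::setNames(agents$role, agents$id)
  state <- tibble::tibble(
    t = as.integer(st_df$t), id = as.character(st_df$id),
    role = unname(role_of[as.character(st_df$id)]),
    x = as.numeric(pos[, 1]), y = as.numeric(pos[, 2]),
    ori = as.character(st_df$ori), guide = as.character(st_df$guide),
    task = as.character(st_df$task))
  events <- if (is.null(ev_df)) {
    tibble::tibble(t = integer(0), id = character(0), ev = character(0),
                   patient = character(0), dest = character(0))
  } else {
    tibble::tibble(t = as.integer(ev_df$t), id = as.character(ev_df$id),
                   ev = as.character(ev_df$ev),
                   patient = as.character(ev_df$patient),
                   dest = as.character(ev_df$dest))
  }
  prot <- structure(list(
    config_digest = header$config_digest,
    plan_digest = header$plan_digest,
    seed = as.integer(header$seed),
    horizon = as.integer(header$horizon),
    policy_label = header$policy %||% NA_character_,
    n_patients = sum(agents$role == "patient"),
    n_nurses = sum(agents$role == "nurse"),
    agents = agents, state = state, events = events),
    class = "run_protocol")
  validate_protocol(prot)
  prot
}

#' Validate run-protocol invariants
#'
#' Checks that the state table has exactly `horizon x n_agents` records,
#' that events are sorted by tick, that GUIDE_START/GUIDE_END strictly
#' alternate per patient, and that every NURSE_ARRIVED is preceded by a
#' NURSE_CALLED or DISCOVERED for that patient. Violations raise
#' `wardsim_error_parse` naming the invariant.
#'
#' @param protocol A `run_protocol`.
#' @return The protocol, invisibly.
#' @export
validate_protocol <- function(protocol) {
  n_agents <- nrow(protocol$agents)
  if (nrow(protocol$state) != protocol$horizon * n_agents) {
    ws_abort(sprintf(
      "invariant violated: state table has %d records, expected horizon x agents = %d",
      nrow(protocol$state), protocol$horizon * n_agents), "wardsim_error_parse")
  }
  ev <- protocol$events
  if (nrow(ev) > 0) {
    if (is.unsorted(ev$t)) {
      ws_abort("invariant violated: events are not sorted by tick",
               "wardsim_error_parse")
    }
    if (any(ev$t < 0 | ev$t >= protocol$horizon)) {
      ws_abort("invariant violated: event tick outside [0, horizon)",
               "wardsim_error_parse")
    }
    guides <- ev[ev$ev %in% c("GUIDE_START", "GUIDE_END"), ]
    if (nrow(guides) > 0) {
      for (pid in unique(guides$patient)) {
        seqs <- guides$ev[guides$patient == pid]
        expect_next <- "GUIDE_START"
        for (e in seqs) {
          if (e != expect_next) {
            ws_abort(paste0("invariant violated: GUIDE_START/GUIDE_END do not alternate for ",
                            pid), "wardsim_error_parse")
          }
          expect_next <- if (e == "GUIDE_START") "GUIDE_END" else "GUIDE_START"
        }
      }
    }
    arrived <- which(ev$ev == "NURSE_ARRIVED")
    for (i in arrived) {
      pid <- ev$patient[i]
      prior <- ev[seq_len(i - 1L), ]
      if (!any(prior$ev %in% c("NURSE_CALLED", "DISCOVERED") &
               (prior$id == pid | (!is.na(prior$patient) & prior$patient == pid)))) {
        ws_abort(paste0("invariant violated: NURSE_ARRIVED for ", pid,
                        " without preceding NURSE_CALLED or DISCOVERED"),
                 "wardsim_error_parse")
      }
    }
  }
  invisible(protocol)
}
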