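# Visualizations: trajectory maps on the floor plan (orientation-colored)
# and per-policy score box plots.

#' Plot patient trajectories on the floor plan
#'
#' Renders the walkable grid with each patient's trajectory drawn as
#' segments colored by orientation state at the end of each step (oriented
#' = blue, disoriented = red by default). Several protocols can be shown as
#' small multiples, e.g. over increasing disorientation probability.
#'
#' @param protocols A `run_protocol` or list of them; each must reference
#'   the given floor plan (matching `plan_digest`).
#' @param plan The `floor_plan` the runs used.
#' @param labels Optional panel labels (one per protocol; default
#'   `"policy, seed"`). Panels keep the supplied order.
#' @param patients Optional patient ids to include (default all).
#' @param colors Length-2 named vector `c(oriented = , disoriented = )`.
#' @param file Optional output path (PNG/SVG/PDF via [ggplot2::ggsave()]).
#' @param width,height Device size in inches when writing to `file`.
#' @return The ggplot object, invisibly when writing to file.
#' @export
plot_trajectories <- function(protocols, plan, labels = NULL, patients = NULL,
                              colors = c(oriented = "#2166ac", disoriented = "#b2182b"),
                              file = NULL, width = 8, height = 5) {
  if (inherits(protocols, "run_protocol")) protocols <- list(protocols)
  plan_dig <- floorplan_digest(plan)
  for (p in protocols) {
    if (!is.null(p$plan_digest) && !identical(p$plan_digest, plan_dig)) {
      ws_abort("protocol was produced on a different floor plan (plan digest mismatch)",
               "wardsim_error_plan_mismatch")
    }
  }
  if (is.null(labels)) {
    labels <- vapply(protocols, function(p) {
      paste0(p$policy_label %||% "run", ", seed ", p$seed)
    }, character(1))
  }
  segs <- purrr::imap(protocols, function(prot, i) {
    st <- prot$state[prot$state$role == "patient", ]
    if (!is.null(patients)) st <- st[st$id %in% patients, ]
    st |>
      dplyr::arrange(.data$id, .data$t) |>
      dplyr::group_by(.data$id) |>
      dplyr::mutate(xend = dplyr::lead(.data$x), yend = dplyr::lead(.data$y),
                    state = ifelse(dplyr::lead(.data$ori) == "D",
                                   "disoriented", "oriented")) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$xend)) |>
      dplyr::mutate(panel = labels[[i]])
  }) |> dplyr::bind_rows()
  segs$panel <- factor(segs$panel, levels = unique(unlist(labels)))

  walls <- which(!plan$walkable, arr.ind = TRUE)
  wall_df <- tibble::tibble(x = walls[, "col"] - 0.5, y = walls[, "row"] - 0.5)

  gg <- ggplot2::ggplot() +
    ggplot2::geom_tile(data = wall_df,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       fill = "grey25", width = 1, height = 1) +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       color = .data$state),
                          linewidth = 0.3, alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(oriented = unname(colors["oriented"]),
                                           disoriented = unname(colors["disoriented"])),
                                name = "patient state") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = width, height = height, dpi = 150)
    return(invisible(gg))
  }
  gg
}

#' Per-policy score box plots
#'
#' Grouped box plots of value-model scores: x = policy (ordered Nhelp
#' ascending, then Nurse Only, then No Help), y = score, one color per
#' value model, with the polarity of each model stated in the legend.
#' Whiskers are standard Tukey 1.5 IQR.
#'
#' @param result An `ecq_result` with at least one score row.
#' @param file Optional output path.
#' @param width,height Device size in inches when writing to `file`.
#' @return The ggplot object, invisibly when writing to file.
#' @export
plot_score_boxplots <- function(result, file = NULL, width = 8, height = 4.5) {
  scores <- if (inherits(result, "ecq_result")) result$scores else result
  if (is.null(scores) || nrow(scores) == 0) {
    ws_abort("no scores to plot (empty ECQ result)", "wardsim_error_empty_input")
  }
  scores <- dplyr::mutate(
    scores,
    policy = factor(.data$policy, levels = order_policy_labels(.data$policy)),
    value_lab = paste0(.data$value, " (",
                       ifelse(.data$polarity == "VIOLATION", "violation", "compliance"),
                       ")"))
  gg <- ggplot2::ggplot(scores,
                        ggplot2::aes(x = .data$policy, y = .data$score,
                                     fill = .data$value_lab)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "value model") +
    ggplot2::labs(x = "policy", y = "score") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = width, height = height, dpi = 150)
    return(invisible(gg))
  }
  gg
}

#' @rdname plot_score_boxplots
#' @param object An `ecq_result`.
#' @param ... Passed to [plot_score_boxplots()].
#' @method autoplot ecq_result
#' @export
autoplot.ecq_result <- function(object, ...) {
  plot_score_boxplots(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
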