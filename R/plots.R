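# ggplot2 views of the summary objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a replication timing profile
#'
#' Mean replication time per chromosomal position with a ribbon of +/- one
#' standard error of the mean.
#'
#' @param object A `bcs_timing_profile` from [bcs_replication_timing()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bcs_timing_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean_time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_time - .data$sem,
                                      ymax = .data$mean_time + .data$sem),
                         fill = "grey70", alpha = 0.6, na.rm = TRUE) +
    ggplot2::geom_line(colour = "firebrick", na.rm = TRUE) +
    ggplot2::labs(x = "chromosomal position (kb)",
                  y = "mean replication time",
                  title = "Replication timing profile") +
    ggplot2::theme_minimal()
}

#' Plot per-cell Ada and meAda traces
#'
#' One line per replicate colony for each molecule species.
#'
#' @param object A `bcs_population_trace` from [bcs_ada_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bcs_population_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("ada_per_cell", "meada_per_cell"),
                            names_to = "species", values_to = "per_cell")
  df$species <- ifelse(df$species == "ada_per_cell", "Ada", "meAda")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$per_cell,
                                   group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.5, colour = "steelblue", na.rm = TRUE) +
    ggplot2::facet_wrap(~species, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time", y = "molecules per live cell",
                  title = "Ada response of a growing population") +
    ggplot2::theme_minimal()
}

#' Plot a phosphorylation dose-response curve
#'
#' Steady-state phosphorylated fraction against the kinase:phosphatase
#' ratio on a log axis, with between-replicate standard deviations.
#'
#' @param object A `bcs_dose_response` from [bcs_dose_response()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bcs_dose_response <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$mean_fraction)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_fraction - .data$sd,
                                        ymax = .data$mean_fraction + .data$sd),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::geom_point(size = 2, colour = "darkgreen") +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "kinase : phosphatase ratio",
                  y = "phosphorylated fraction",
                  title = "Multisite phosphorylation dose-response") +
    ggplot2::theme_minimal()
}

#' Plot the action timeline of an event log
#'
#' Cumulative counts over time of the most frequent action types.
#'
#' @param object A `bcs_eventlog`.
#' @param max_actions Number of distinct action types to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bcs_eventlog <- function(object, max_actions = 8L, ...) {
  df <- tibble::tibble(time = object$time,
                       action = sub("\\[.*$", "", object$action))
  top <- names(sort(table(df$action), decreasing = TRUE))[seq_len(min(max_actions,
    length(unique(df$action))))]
  df <- df[df$action %in% top, , drop = FALSE]
  df <- dplyr::mutate(dplyr::group_by(df, .data$action),
                      count = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$count,
                                   colour = .data$action)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "cumulative events", colour = "action") +
    ggplot2::theme_minimal()
}
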