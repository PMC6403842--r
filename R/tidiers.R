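# broom-style accessors and ggplot2 autoplot methods for run records.

#' Tidy a run record
#'
#' Returns the per-frame metrics as one tibble: extruder state joined with
#' knot identifications (TAD experiments) or with the demixing series (melt
#' experiment).
#'
#' @param x A `run_record`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.run_record <- function(x, ...) {
  if (x$experiment == "melt_demix") {
    x$extruders |>
      group_by(frame = .data$frame) |>
      summarise(mean_progress = mean(.data$progress),
                all_stopped = all(.data$stopped_left & .data$stopped_right),
                .groups = "drop") |>
      left_join(x$demixing |>
                  group_by(frame = .data$frame) |>
                  summarise(total_interchain_area =
                              .data$total_interchain_area[1],
                            .groups = "drop"),
                by = "frame")
  } else {
    x$knots |>
      select(frame = "frame", ring = "ring", knot = "name",
             crossing_estimate = "crossing_estimate",
             determinant = "determinant") |>
      left_join(x$extruders |>
                  group_by(frame = .data$frame) |>
                  summarise(mean_progress = mean(.data$progress),
                            .groups = "drop"),
                by = "frame")
  }
}

#' One-row summary of a run record
#'
#' @param x A `run_record`.
#' @param ... Unused.
#' @return A one-row tibble: experiment, seed, steps, completion, initial
#'   and final knot (or linked-pair and interfacial-area figures for the
#'   melt).
#' @export
glance.run_record <- function(x, ...) {
  base <- tibble(experiment = x$experiment, seed = x$config$seed,
                 steps = x$steps, completed = x$completed)
  if (x$experiment == "melt_demix") {
    base |> mutate(
      unknotted_rings = sum(x$outcome$final_knots$name == "0_1"),
      n_rings = nrow(x$outcome$final_knots),
      initial_linked_pairs = x$outcome$initial_linked_pairs,
      final_linked_pairs = x$outcome$final_linked_pairs,
      initial_interchain_area = x$outcome$initial_interchain_area,
      final_interchain_area = x$outcome$final_interchain_area
    )
  } else {
    base |> mutate(
      initial_knot = x$knots$name[x$knots$frame == min(x$knots$frame)][1],
      final_knot = x$outcome$final_knots$name[1],
      unknotted = .data$final_knot == "0_1"
    )
  }
}

#' Plot a run record
#'
#' For the TAD experiments: knot determinant and extrusion progress against
#' MD step. For the melt: the inter-chain Voronoi interfacial area against
#' MD step (the demixing curve).
#'
#' @param object A `run_record`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.run_record <- function(object, ...) {
  td <- tidy(object)
  if (object$experiment == "melt_demix") {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$frame,
                                     y = .data$total_interchain_area)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "MD step", y = "inter-chain area (sigma^2)",
                    title = "Demixing during loop extrusion")
  } else {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$frame, y = .data$determinant)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "MD step", y = "knot determinant |Delta(-1)|",
                    title = sprintf("Knot simplification (%s)",
                                    object$experiment))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Demixing-curve plot
#'
#' @param series A [demixing_series()] tibble.
#' @return A ggplot object.
#' @export
plot_demixing <- function(series) {
  df <- series |>
    group_by(frame = .data$frame) |>
    summarise(total = .data$total_interchain_area[1], .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$total)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "frame", y = "inter-chain area (sigma^2)")
}

#' Tidy a tessellation into its facet table
#'
#' @param x A `voro_tessellation`.
#' @param ... Unused.
#' @return The facet tibble (bead, neighbor, area, ring, ring_neighbor).
#' @export
tidy.voro_tessellation <- function(x, ...) x$facets
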