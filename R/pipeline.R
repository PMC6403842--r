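# End-to-end drivers for the three reproduced experiments:
#   1. single_tad  — knotted 133-bead loop, cohesin-handcuff extrusion,
#                    unknotting at the phantom (Top2B) border.
#   2. three_tad   — 400-bead circle with a delocalised trefoil spanning
#                    three TADs, three handcuffs (concurrent or sequential).
#   3. melt_demix  — 8 confined rings, topological equilibration, simplified
#                    migrating-bond extrusion, decatenation and demixing.
# Every run is exactly reproducible from (config, seed); outcomes are always
# recomputed from the final coordinates by the topology module, never cached.

new_run_record <- function(experiment, config, frames, knots, extruders,
                           demixing, outcome, steps, completed) {
  structure(list(experiment = experiment, config = config, frames = frames,
                 knots = knots, extruders = extruders, demixing = demixing,
                 outcome = outcome, steps = steps, completed = completed),
            class = "run_record")
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record: %s> %d MD steps, %s\n", x$experiment, x$steps,
              if (x$completed) "extrusion complete" else "incomplete"))
  if (!is.null(x$outcome$final_knots)) {
    cat("final knots:", paste(x$outcome$final_knots$name, collapse = ", "), "\n")
  }
  invisible(x)
}

frame_rows <- function(sys, frame) {
  tibble(frame = frame, bead = sys$bead, ring = sys$ring,
         x = sys$x, y = sys$y, z = sys$z,
         cohesin = sys$cohesin)
}

knot_rows <- function(sys, frame, rings = NULL, seed = 1L) {
  rings <- rings %||% sort(unique(sys$ring[!sys$cohesin]))
  bind_rows(lapply(rings, function(r) {
    identify_knot(ring_curve(sys, r), seed = seed) |>
      mutate(ring = r, frame = frame)
  }))
}

#' Run the single-TAD unknotting experiment
#'
#' Generates the knotted ring, relaxes it, threads a cohesin handcuff at the
#' site diametrically opposite the TAD border, then alternates MD with
#' walk-advance decisions until both cohesin rings stop at the CTCF beads
#' (or the step budget runs out, in which case the outcome is marked
#' incomplete rather than an error). The knot type is tracked along the run;
#' the outcome records the final knot of the chromatin ring, identified from
#' the final frame alone.
#'
#' @param cfg An [experiment_config()] (`"single_tad"`).
#' @param budget Maximum MD steps (default 2e6).
#' @param walk_interval MD steps between walk-advance decisions.
#' @param sample_every MD steps between trajectory/extruder samples.
#' @param knot_every MD steps between knot identifications.
#' @param post_steps Relaxation steps after extrusion completes.
#' @param progress Emit progress lines to stderr.
#' @return A `run_record`.
#' @export
run_single_tad <- function(cfg = experiment_config("single_tad"),
                           budget = 2e6, walk_interval = 200L,
                           sample_every = 5000L, knot_every = 10000L,
                           post_steps = 20000L, progress = FALSE) {
  stopifnot(cfg$experiment == "single_tad")
  ip <- integrator_params(seed = cfg$seed)
  ff <- force_field()
  sys <- single_tad_ring(cfg)
  # thread the handcuff while the ring is still in its smooth parametric
  # shape (the local geometry is guaranteed clash-free there), then
  # thermalise briefly with everything in place before walking starts
  lh <- load_handcuff(sys, attr(sys, "start_site"), ip)
  sys <- lh$system; hc <- lh$handcuff
  sys <- step_langevin(sys, ff, ip, 3000L)

  run_handcuff_loop(sys, list(hc), cfg, ip, ff, budget, walk_interval,
                    sample_every, knot_every, post_steps, progress,
                    experiment = "single_tad", mode = "concurrent")
}

#' Run the three-TAD delocalised-knot experiment
#'
#' As [run_single_tad()], but on the 400-bead three-TAD circle with one
#' handcuff per TAD. In `"concurrent"` mode all three extrusions advance
#' together; in `"sequential"` mode each runs to completion before the next
#' starts (the two protocols lead to the same topological outcome).
#'
#' @inheritParams run_single_tad
#' @param mode `"concurrent"` or `"sequential"`.
#' @return A `run_record`.
#' @export
run_three_tad <- function(cfg = experiment_config("three_tad"),
                          mode = c("concurrent", "sequential"),
                          budget = 2e6, walk_interval = 200L,
                          sample_every = 5000L, knot_every = 20000L,
                          post_steps = 20000L, progress = FALSE) {
  stopifnot(cfg$experiment == "three_tad")
  mode <- match.arg(mode)
  ip <- integrator_params(seed = cfg$seed)
  ff <- force_field()
  sys <- three_tad_circle(cfg)
  # handcuffs are threaded on the smooth starting shape (cf. run_single_tad);
  # the construct is deliberately not pre-equilibrated, which keeps the
  # quasi-symmetric three-TAD starting configuration
  hcs <- list()
  for (s in attr(sys, "tads")$start_site) {
    lh <- load_handcuff(sys, s, ip)
    sys <- lh$system
    hcs[[length(hcs) + 1]] <- lh$handcuff
  }
  sys <- step_langevin(sys, ff, ip, 3000L)
  run_handcuff_loop(sys, hcs, cfg, ip, ff, budget, walk_interval,
                    sample_every, knot_every, post_steps, progress,
                    experiment = "three_tad", mode = mode)
}

run_handcuff_loop <- function(sys, hcs, cfg, ip, ff, budget, walk_interval,
                              sample_every, knot_every, post_steps, progress,
                              experiment, mode) {
  chrom_ring <- hcs[[1]]$chrom_ring
  frames <- list(frame_rows(sys, 0L))
  knots <- list(knot_rows(sys, 0L, rings = chrom_ring, seed = cfg$seed))
  exst <- list(bind_rows(lapply(hcs, extruder_state, system = sys, frame = 0L)))
  step <- 0L
  done <- function() all(vapply(hcs, function(h) h$stopped_a && h$stopped_b, TRUE))

  while (step < budget && !done()) {
    sys <- step_langevin(sys, ff, ip, walk_interval)
    step <- step + walk_interval
    active <- seq_along(hcs)
    if (mode == "sequential") {
      inc <- which(!vapply(hcs, function(h) h$stopped_a && h$stopped_b, TRUE))
      active <- inc[1]
    }
    for (k in active) {
      aw <- advance_walk(sys, hcs[[k]])
      sys <- aw$system
      hcs[[k]] <- aw$handcuff
    }
    if (step %% sample_every == 0) {
      frames[[length(frames) + 1]] <- frame_rows(sys, step)
      exst[[length(exst) + 1]] <-
        bind_rows(lapply(hcs, extruder_state, system = sys, frame = step))
    }
    if (step %% knot_every == 0) {
      knots[[length(knots) + 1]] <-
        knot_rows(sys, step, rings = chrom_ring, seed = cfg$seed)
      if (progress) {
        inform(sprintf("%s step %d: knot %s, progress %s", experiment, step,
                       tail(knots, 1)[[1]]$name[1],
                       paste(sprintf("%.2f", vapply(hcs, extrusion_progress,
                                                    0, system = sys)),
                             collapse = "/")))
      }
    }
  }
  completed <- done()
  if (post_steps > 0) {
    sys <- step_langevin(sys, ff, ip, post_steps)
    step <- step + as.integer(post_steps)
  }
  frames[[length(frames) + 1]] <- frame_rows(sys, step)
  final_knots <- knot_rows(sys, step, rings = chrom_ring, seed = cfg$seed)
  knots[[length(knots) + 1]] <- final_knots
  exst[[length(exst) + 1]] <-
    bind_rows(lapply(hcs, extruder_state, system = sys, frame = step))

  outcome <- list(
    final_knots = final_knots,
    status = if (completed) "complete" else "incomplete",
    handcuffs = hcs
  )
  new_run_record(experiment, cfg, bind_rows(frames), bind_rows(knots),
                 bind_rows(exst), NULL, outcome, step, completed)
}

#' Run the melt decatenation/demixing experiment
#'
#' Topologically equilibrates the confined multi-ring melt, then starts one
#' simplified migrating-bond extruder per ring — simultaneously, each at the
#' site most distant from that ring's phantom (Top2B) border — and runs MD
#' with bond migration until every extruder has stopped at its border (or
#' the budget runs out). Records the inter-chain Voronoi area along the run
#' and the full topology report (knots and pairwise linking) before and
#' after.
#'
#' @inheritParams run_single_tad
#' @param md_interval MD steps between bond-migration decisions.
#' @param frame_interval MD steps between stored frames (used for the
#'   demixing series).
#' @param equilibration Arguments forwarded to [equilibrated_melt()] (list).
#' @param system Optionally a pre-equilibrated melt system (with
#'   `melt_report`), to reuse across runs.
#' @return A `run_record`; `$demixing` holds the interfacial-area series and
#'   `$outcome` the before/after topology reports.
#' @export
run_melt_demix <- function(cfg = experiment_config("melt_demix"),
                           budget = 5e6, md_interval = 150L,
                           frame_interval = 30000L, post_steps = 10000L,
                           equilibration = list(), progress = FALSE,
                           system = NULL) {
  stopifnot(cfg$experiment == "melt_demix")
  ip <- integrator_params(seed = cfg$seed)
  ff <- force_field()
  sys <- system %||%
    do.call(equilibrated_melt, c(list(cfg = cfg), equilibration,
                                 list(progress = progress)))
  initial_report <- attr(sys, "melt_report")

  rings <- sort(unique(sys$ring[!sys$cohesin]))
  exs <- list()
  for (r in rings) {
    beads <- ring_beads(sys, r)
    n <- length(beads)
    border <- which((sys$ctcf | sys$phantom)[match(beads, sys$bead)])
    mid <- round(mean(border))
    site <- beads[wrap_index(as.integer(mid + n / 2), n)]
    se <- simple_extruder(sys, site)
    sys <- se$system
    exs[[length(exs) + 1]] <- se$extruder
  }

  frames <- list(frame_rows(sys, 0L))
  exst <- list(bind_rows(lapply(exs, extruder_state, system = sys, frame = 0L)))
  step <- 0L
  done <- function() all(vapply(exs, function(e) e$left_stopped && e$right_stopped, TRUE))
  while (step < budget && !done()) {
    sys <- step_langevin(sys, ff, ip, md_interval)
    step <- step + md_interval
    for (k in seq_along(exs)) {
      se <- step_simple_extrusion(sys, exs[[k]])
      sys <- se$system
      exs[[k]] <- se$extruder
    }
    if (step %% frame_interval < md_interval) {
      frames[[length(frames) + 1]] <- frame_rows(sys, step)
      exst[[length(exst) + 1]] <-
        bind_rows(lapply(exs, extruder_state, system = sys, frame = step))
      if (progress) {
        inform(sprintf("melt step %d: mean progress %.2f", step,
                       mean(vapply(exs, extrusion_progress, 0, system = sys))))
      }
    }
  }
  completed <- done()
  if (post_steps > 0) {
    sys <- step_langevin(sys, ff, ip, post_steps)
    step <- step + as.integer(post_steps)
  }
  frames[[length(frames) + 1]] <- frame_rows(sys, step)
  exst[[length(exst) + 1]] <-
    bind_rows(lapply(exs, extruder_state, system = sys, frame = step))

  traj <- bind_rows(frames) |> filter(!.data$cohesin)
  demix <- demixing_series(traj, sphere_radius = attr(sys, "sphere_radius"))
  final_report <- topology_report(sys, seed = cfg$seed)

  outcome <- list(
    final_knots = final_report,
    initial_knots = initial_report,
    initial_linked_pairs = attr(initial_report, "linked_pairs"),
    final_linked_pairs = attr(final_report, "linked_pairs"),
    initial_interchain_area =
      demix$total_interchain_area[demix$frame == min(demix$frame)][1],
    final_interchain_area =
      demix$total_interchain_area[demix$frame == max(demix$frame)][1],
    status = if (completed) "complete" else "incomplete",
    extruders = exs
  )
  new_run_record("melt_demix", cfg, bind_rows(frames), NULL,
                 bind_rows(exst), demix, outcome, step, completed)
}

# virtual closure of the extruded arc: the arc's beads plus the straight
# chord back from the last anchor to the first (the anchors are held
# together by the extruder, so the chord is short)
extruded_arc_curve <- function(system, ex) {
  if (inherits(ex, "cohesin_handcuff")) {
    ring_id <- ex$chrom_ring; a <- ex$anchor_a; b <- ex$anchor_b
  } else {
    ring_id <- ex$ring_id; a <- ex$left_anchor; b <- ex$right_anchor
  }
  beads <- ring_beads(system, ring_id)
  n <- length(beads)
  ia <- match(a, beads); ib <- match(b, beads)
  idx <- wrap_index(seq(ia, ia + (ib - ia) %% n), n)
  if (length(idx) < 3) return(NULL)
  as_closed_curve(positions(system)[beads[idx], , drop = FALSE])
}
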