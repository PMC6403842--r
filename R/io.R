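# Plain-text interchange: XYZ trajectories (ring id encoded in the atom-name
# column), flat key-value run configs, and run-record export.

#' Write beads or a trajectory to an XYZ file
#'
#' One frame per XYZ record: bead count, a comment line `frame <k>`, then
#' one `R<ring> x y z` line per bead. Accepts a `chain_system` (one frame)
#' or a trajectory tibble with a `frame` column.
#'
#' @param x A `chain_system` or a tibble with frame/ring/x/y/z columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  df <- if (inherits(x, "chain_system")) {
    tibble(frame = 0L, ring = x$ring, !!!list(x = x$x, y = x$y, z = x$z))
  } else {
    as_tibble(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in split(df, df$frame)) {
    writeLines(c(sprintf("%d", nrow(fr)),
                 sprintf("frame %s", fr$frame[1]),
                 sprintf("R%d %.6f %.6f %.6f", fr$ring, fr$x, fr$y, fr$z)),
               con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path XYZ file as written by [write_xyz()] (ring id in the
#'   atom-name column, e.g. `R3`).
#' @return Tibble: frame, bead, ring, x, y, z.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) abort(sprintf("malformed XYZ at line %d", i))
    comment <- lines[i + 1L]
    fr <- suppressWarnings(as.integer(sub("^frame\\s+", "", comment)))
    if (is.na(fr)) fr <- frame
    body <- lines[seq(i + 2L, i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    out[[length(out) + 1]] <- tibble(
      frame = fr, bead = seq_len(n),
      ring = as.integer(sub("^R", "", vapply(parts, `[[`, "", 1))),
      x = as.numeric(vapply(parts, `[[`, "", 2)),
      y = as.numeric(vapply(parts, `[[`, "", 3)),
      z = as.numeric(vapply(parts, `[[`, "", 4))
    )
    i <- i + 2L + n
    frame <- fr + 1L
  }
  bind_rows(out)
}

#' Read a flat key-value run configuration
#'
#' Parses `key = value` lines (TOML-style scalars: numbers, `true`/`false`,
#' quoted or bare strings; `#` comments). Returned as a named list suitable
#' for `do.call(experiment_config, ...)`.
#'
#' @param path Config file.
#' @return Named list.
#' @export
read_config_kv <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "\\s*=\\s*")[[1]]
    key <- kv[1]
    val <- kv[2]
    out[[key]] <- if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else if (grepl("^[-0-9.eE, ]+$", val) && grepl("[0-9]", val)) {
      as.numeric(strsplit(val, ",\\s*")[[1]])
    } else {
      val
    }
  }
  out
}

#' Export a run record to a directory
#'
#' Writes `trajectory.xyz`, `metrics.csv` (per-frame extruder state joined
#' with knot calls where available), `demixing.csv` (melt runs) and
#' `outcome.json`.
#'
#' @param record A `run_record`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_xyz(record$frames, file.path(dir, "trajectory.xyz"))
  utils::write.csv(record$extruders, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(record$demixing)) {
    utils::write.csv(record$demixing, file.path(dir, "demixing.csv"),
                     row.names = FALSE)
  }
  oc <- record$outcome
  json <- list(
    experiment = record$experiment,
    steps = record$steps,
    status = oc$status,
    final_knots = if (!is.null(oc$final_knots)) {
      lapply(seq_len(nrow(oc$final_knots)), function(i) {
        list(ring = oc$final_knots$ring[i], name = oc$final_knots$name[i],
             crossing_estimate = oc$final_knots$crossing_estimate[i],
             determinant = oc$final_knots$determinant[i])
      })
    },
    initial_linked_pairs = oc$initial_linked_pairs,
    final_linked_pairs = oc$final_linked_pairs,
    initial_interchain_area = oc$initial_interchain_area,
    final_interchain_area = oc$final_interchain_area
  )
  jsonlite::write_json(json[!vapply(json, is.null, TRUE)],
                       file.path(dir, "outcome.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
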