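#' Read a long-format protrusion track table
#'
#' Reads the canonical comma-delimited track table: one row per tracked
#' protrusion per imaging session. Required columns are `mouse_id`,
#' `genotype`, `age_group`, `dendrite_id`, `feature_id`, `session_day`,
#' `status`, `x_um`, `y_um`, `z_um`; coordinates may be blank where a feature
#' is absent. Statuses are normalised case-insensitively to
#' `present`/`absent`/`filopodia`. The imaging schedule of each mouse is the
#' sorted set of distinct `session_day` values observed for that mouse, so
#' reading is invariant to row order.
#'
#' @param path Path to a CSV file.
#' @return A `spine_tracks` tibble, rows ordered by mouse, dendrite, feature
#'   and session day.
#' @seealso [write_track_table()], [validate_tracks()]
#' @export
#' @examples
#' tracks <- simulate_mouse(simulation_config(), mouse_id = "m1",
#'                          genotype = "WT", seed = 1)
#' tf <- tempfile(fileext = ".csv")
#' write_track_table(tracks, tf)
#' identical(read_track_table(tf), tracks)
read_track_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("track table not found: ", path), class = "spinedyn_io_error")
  }
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               progress = FALSE))
  missing_cols <- setdiff(.track_cols, hdr)
  if (length(missing_cols) > 0) {
    abort(
      paste0("track table lacks required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "spinedyn_format_error"
    )
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      mouse_id = readr::col_character(),
      genotype = readr::col_character(),
      age_group = readr::col_character(),
      dendrite_id = readr::col_character(),
      feature_id = readr::col_character(),
      session_day = readr::col_integer(),
      status = readr::col_character(),
      x_um = readr::col_double(),
      y_um = readr::col_double(),
      z_um = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  raw$status <- tolower(trimws(raw$status))
  bad <- which(!raw$status %in% .statuses)
  if (length(bad) > 0) {
    abort(
      paste0("invalid status '", raw$status[bad[1]], "' at data row ",
             bad[1], " (allowed: ", paste(.statuses, collapse = ", "), ")"),
      class = "spinedyn_value_error"
    )
  }
  # genotype / age_group must be constant within a mouse
  lab <- dplyr::distinct(raw, .data$mouse_id, .data$genotype, .data$age_group)
  dup <- lab$mouse_id[duplicated(lab$mouse_id)]
  if (length(dup) > 0) {
    abort(
      paste0("mouse '", dup[1],
             "' carries inconsistent genotype/age_group labels"),
      class = "spinedyn_consistency_error"
    )
  }
  as_spine_tracks(raw[.track_cols])
}

#' Write a track table
#'
#' Writes a `spine_tracks` tibble (or any data frame with the canonical
#' columns) as UTF-8 CSV, statuses lowercase, rows sorted by mouse, dendrite,
#' feature and session day so that write/read round-trips are identities.
#'
#' @param tracks A track table (see [read_track_table()] for columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  tracks <- as_spine_tracks(tracks)
  readr::write_csv(tracks, path, progress = FALSE)
  invisible(path)
}

#' Coerce to a spine_tracks tibble
#'
#' Checks required columns, normalises statuses and row order, and stamps the
#' `spine_tracks` class. Used by all readers and the simulator.
#'
#' @param x A data frame with the canonical track columns.
#' @return A `spine_tracks` tibble.
#' @export
as_spine_tracks <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.track_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing track column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spinedyn_format_error")
  }
  x <- tibble::as_tibble(x)[.track_cols]
  x$status <- tolower(trimws(x$status))
  x$session_day <- as.integer(x$session_day)
  x <- dplyr::arrange(x, .data$mouse_id, .data$dendrite_id,
                      .data$feature_id, .data$session_day)
  class(x) <- unique(c("spine_tracks", class(x)))
  x
}

#' Per-mouse imaging schedules
#'
#' @param tracks A track table.
#' @return A tibble with one row per mouse and a list-column `schedule` of
#'   sorted distinct session days.
#' @export
imaging_schedules <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(schedule = list(sort(unique(.data$session_day))),
                     .groups = "drop")
}

# internal: days of one mouse's schedule
mouse_schedule <- function(tracks) sort(unique(tracks$session_day))

# internal: error unless every feature has a status at every session of its
# mouse's schedule and at least one non-absent session (the tracker forces an
# explicit call per timepoint; missing rows are never imputed)
assert_complete_tracks <- function(tracks) {
  chk <- tracks |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::mutate(.n_sessions = length(unique(.data$session_day))) |>
    dplyr::group_by(.data$mouse_id, .data$dendrite_id, .data$feature_id) |>
    dplyr::summarise(
      complete = dplyr::n() == .data$.n_sessions[1] &&
        !anyDuplicated(.data$session_day),
      observed = any(.data$status != "absent"),
      .groups = "drop"
    )
  if (any(!chk$complete)) {
    bad <- chk[!chk$complete, ][1, ]
    abort(paste0("feature '", bad$feature_id, "' (mouse '", bad$mouse_id,
                 "') lacks a status for some session of its schedule"),
          class = "spinedyn_schedule_error")
  }
  if (any(!chk$observed)) {
    bad <- chk[!chk$observed, ][1, ]
    abort(paste0("feature '", bad$feature_id, "' (mouse '", bad$mouse_id,
                 "') is absent at every session"),
          class = "spinedyn_value_error")
  }
  invisible(tracks)
}

#' Validate a track table
#'
#' Report-returning validation: never errors, never mutates. Flags mice whose
#' day-0 feature count falls below the 150-protrusion minimum required for a
#' reliable per-animal estimate, features missing a status for a scheduled
#' session, invalid statuses, and schedules that do not start at day 0 or
#' have fewer than two sessions. Also tabulates day-0 features by status.
#'
#' @param tracks A track table.
#' @param min_features Minimum day-0 feature count per mouse before a warning
#'   is issued (default 150).
#' @return A list with tibbles `issues` (columns `mouse_id`, `severity`,
#'   `message`) and `day0_counts` (features by day-0 status per mouse).
#' @export
validate_tracks <- function(tracks, min_features = 150) {
  tracks <- as_spine_tracks(tracks)
  issues <- list()
  add <- function(mouse, severity, message) {
    issues[[length(issues) + 1]] <<-
      tibble::tibble(mouse_id = mouse, severity = severity, message = message)
  }

  bad_status <- tracks[!tracks$status %in% .statuses, ]
  for (i in seq_len(nrow(bad_status))) {
    add(bad_status$mouse_id[i], "error",
        paste0("invalid status '", bad_status$status[i], "' for feature '",
               bad_status$feature_id[i], "'"))
  }

  for (m in unique(tracks$mouse_id)) {
    tm <- tracks[tracks$mouse_id == m, ]
    sched <- mouse_schedule(tm)
    if (length(sched) < 2) {
      add(m, "error", "schedule has fewer than 2 sessions")
    }
    if (sched[1] != 0) {
      add(m, "error", "schedule does not start at day 0")
    }
    per_feat <- tm |>
      dplyr::group_by(.data$dendrite_id, .data$feature_id) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$session_day),
                       observed = any(.data$status != "absent"),
                       .groups = "drop")
    n_missing <- sum(per_feat$n != length(sched))
    if (n_missing > 0) {
      add(m, "error", paste0(n_missing,
                             " feature(s) lack a status for some session"))
    }
    if (any(!per_feat$observed)) {
      add(m, "error", paste0(sum(!per_feat$observed),
                             " feature(s) absent at every session"))
    }
    n_day0 <- sum(tm$session_day == sched[1] & tm$status != "absent")
    if (n_day0 < min_features) {
      add(m, "warning", paste0("only ", n_day0, " day-0 features, below ",
                               min_features, " minimum"))
    }
  }

  day0_counts <- tracks |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::filter(.data$session_day == min(.data$session_day)) |>
    dplyr::count(.data$mouse_id, .data$status, name = "n_features") |>
    dplyr::ungroup()

  list(
    issues = if (length(issues) > 0) dplyr::bind_rows(issues) else
      tibble::tibble(mouse_id = character(), severity = character(),
                     message = character()),
    day0_counts = day0_counts
  )
}
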