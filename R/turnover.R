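#' Two-session spine turnover per mouse
#'
#' Compares each tracked protrusion between two imaging sessions and counts,
#' per mouse: stable spines (present at both), eliminated spines (present at
#' `session_a`, absent at `session_b`) and formed spines (absent at
#' `session_a`, present at `session_b`). The turnover ratio is
#' \deqn{TO = (N_{elim} + N_{form}) / (N_{elim} + N_{form} + 2 N_{stable}),}
#' 0 for a static dendrite and 1 for complete replacement. Counts are summed
#' over all of a mouse's dendrites before the ratio is formed (animal-level
#' estimates; group summaries should average per-mouse ratios).
#'
#' With `include_filopodia = FALSE` (default) turnover is a spine statistic:
#' features scored `filopodia` at `session_a` are excluded from the
#' eliminated/stable counts and features filopodial at `session_b` from the
#' formed count. With `TRUE`, any non-absent status counts as present.
#'
#' @param tracks A track table.
#' @param session_a,session_b Session days, `session_a < session_b`, both in
#'   every analysed mouse's schedule.
#' @param include_filopodia Count filopodia as protrusions? Default `FALSE`.
#' @return A tibble with one row per mouse: `mouse_id`, `genotype`,
#'   `age_group`, `n_eliminated`, `n_formed`, `n_stable`, `ratio`.
#'   `ratio` is `NA` when all three counts are zero (flagged by the
#'   `undefined` column).
#' @export
#' @examples
#' cfg <- simulation_config(schedule = c(0L, 1L, 2L), f0 = 0.25)
#' tracks <- simulate_mouse(cfg, "m1", "WT", "juvenile", seed = 7)
#' count_turnover(tracks, 0, 2)
count_turnover <- function(tracks, session_a, session_b,
                           include_filopodia = FALSE) {
  tracks <- as_spine_tracks(tracks)
  if (!(session_a < session_b)) {
    abort("session_a must precede session_b", class = "spinedyn_value_error")
  }
  assert_complete_tracks(tracks)
  for (m in unique(tracks$mouse_id)) {
    sched <- mouse_schedule(tracks[tracks$mouse_id == m, ])
    if (!all(c(session_a, session_b) %in% sched)) {
      abort(paste0("session ", session_a, " or ", session_b,
                   " not in schedule of mouse '", m, "'"),
            class = "spinedyn_value_error")
    }
  }

  two <- tracks |>
    dplyr::filter(.data$session_day %in% c(session_a, session_b)) |>
    dplyr::mutate(which = ifelse(.data$session_day == session_a, "a", "b")) |>
    tidyr::pivot_wider(
      id_cols = c("mouse_id", "genotype", "age_group", "dendrite_id",
                  "feature_id"),
      names_from = "which", values_from = "status"
    )

  if (include_filopodia) {
    two$a <- ifelse(two$a == "filopodia", "present", two$a)
    two$b <- ifelse(two$b == "filopodia", "present", two$b)
  }

  res <- two |>
    dplyr::filter(.data$a != "absent" | .data$b != "absent") |>
    dplyr::group_by(.data$mouse_id, .data$genotype, .data$age_group) |>
    dplyr::summarise(
      n_eliminated = sum(.data$a == "present" & .data$b == "absent"),
      n_formed = sum(.data$a == "absent" & .data$b == "present"),
      n_stable = sum(.data$a == "present" & .data$b == "present"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      denom = .data$n_eliminated + .data$n_formed + 2 * .data$n_stable,
      undefined = .data$denom == 0,
      ratio = ifelse(.data$undefined, NA_real_,
                     (.data$n_eliminated + .data$n_formed) / .data$denom)
    ) |>
    dplyr::select(-"denom")
  if (nrow(res) == 0) {
    abort("no analyzable features between the two sessions",
          class = "spinedyn_value_error")
  }
  res
}

#' Filopodial fraction at first imaging
#'
#' Proportion of all analysed features present at the first imaging session
#' that were scored as filopodia, per mouse.
#'
#' @param tracks A track table.
#' @return Tibble with one row per mouse: `numerator` (day-0 filopodia),
#'   `denominator` (day-0 non-absent features) and `fraction`.
#' @export
filopodial_fraction <- function(tracks) {
  tracks <- as_spine_tracks(tracks)
  res <- tracks |>
    dplyr::group_by(.data$mouse_id, .data$genotype, .data$age_group) |>
    dplyr::filter(.data$session_day == min(.data$session_day)) |>
    dplyr::summarise(
      numerator = sum(.data$status == "filopodia"),
      denominator = sum(.data$status != "absent"),
      .groups = "drop"
    )
  if (any(res$denominator == 0)) {
    abort("a mouse has no day-0 features", class = "spinedyn_value_error")
  }
  res$fraction <- res$numerator / res$denominator
  res
}

#' Spine density
#'
#' Spines per micrometre of dendritic segment. Vectorised.
#'
#' @param n_spines Spine count(s), >= 0.
#' @param segment_length_um Segment length(s) in micrometres, > 0.
#' @return Density in spines per micrometre.
#' @export
#' @examples
#' spine_density(10, 20) # 0.5
spine_density <- function(n_spines, segment_length_um) {
  if (any(!is.finite(segment_length_um)) || any(segment_length_um <= 0)) {
    abort("segment_length_um must be positive",
          class = "spinedyn_value_error")
  }
  if (any(n_spines < 0)) {
    abort("n_spines must be non-negative", class = "spinedyn_value_error")
  }
  n_spines / segment_length_um
}

#' Morphology-class fractions per group
#'
#' Tabulates manual morphology scores (mushroom / intermediate / filopodia)
#' into per-group class fractions. Fractions within a group sum to 1.
#'
#' @param scores A data frame with a `class` column (values among
#'   `mushroom`, `intermediate`, `filopodia`) and optional grouping columns.
#' @param ... Grouping columns (tidy-select), e.g. `genotype, age_group`.
#' @return Tibble with one row per group x class: `n`, `n_group`, `fraction`.
#' @export
#' @examples
#' scores <- tibble::tibble(
#'   genotype = rep("WT", 100),
#'   class = rep(c("mushroom", "intermediate", "filopodia"), c(54, 16, 30))
#' )
#' morphology_fractions(scores, genotype)
morphology_fractions <- function(scores, ...) {
  stopifnot(is.data.frame(scores), "class" %in% names(scores))
  classes <- c("mushroom", "intermediate", "filopodia")
  scores$class <- tolower(trimws(scores$class))
  if (any(!scores$class %in% classes)) {
    abort(paste0("unknown morphology class: ",
                 setdiff(unique(scores$class), classes)[1]),
          class = "spinedyn_value_error")
  }
  grouped <- scores |>
    dplyr::group_by(..., .data$class) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(n_group = sum(.data$n),
                  fraction = .data$n / .data$n_group) |>
    dplyr::ungroup()
  if (any(grouped$n_group == 0)) {
    abort("empty group", class = "spinedyn_value_error")
  }
  grouped
}
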