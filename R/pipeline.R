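#' Pipeline configuration
#'
#' Exactly one input source: either `input` (path to an existing track
#' table) or `sim_configs` (named list of [simulation_config()] objects, one
#' per genotype, to simulate a cohort). Analysis toggles flow into every
#' downstream stage and are echoed in the output manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param input Optional path to a track-table CSV.
#' @param sim_configs Optional named list of simulation configs.
#' @param compare Character vector of two genotype labels to compare with
#'   the extra sum-of-squares F test, or `NULL` to compare the first two
#'   genotypes present (skipped if only one).
#' @param include_filopodia,constrain_s0,weight_by_n Analysis toggles.
#' @param turnover_sessions Integer vector of two session days for the
#'   turnover stage, or `NULL` for the first two scheduled days.
#' @param seed Integer master seed (used only when simulating).
#' @param age_group Age-group label for simulated cohorts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, input = NULL, sim_configs = NULL,
                            compare = NULL, include_filopodia = FALSE,
                            constrain_s0 = FALSE, weight_by_n = FALSE,
                            turnover_sessions = NULL, seed = 1,
                            age_group = "adult") {
  if (is.null(input) == is.null(sim_configs)) {
    abort("exactly one of input / sim_configs must be given",
          class = "spinedyn_config_error")
  }
  cfg <- list(out_dir = out_dir, input = input, sim_configs = sim_configs,
              compare = compare, include_filopodia = include_filopodia,
              constrain_s0 = constrain_s0, weight_by_n = weight_by_n,
              turnover_sessions = turnover_sessions,
              seed = as.integer(seed), age_group = age_group)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full spine-dynamics pipeline
#'
#' simulate (or load) -> validate -> turnover -> filopodial fractions ->
#' survival curves -> decay fits (both constraint modes) -> classification
#' -> group comparison, writing each stage as a delimited table plus a JSON
#' summary and a manifest recording package version, seed and configuration.
#' Idempotent: the same config and seed reproduce byte-identical numeric
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)),
            class = "spinedyn_pipeline_error")
    })
  }

  tracks <- if (!is.null(config$input)) {
    stage("load", read_track_table(config$input))
  } else {
    tr <- stage("simulate",
                simulate_cohort(config$sim_configs, seed = config$seed,
                                age_group = config$age_group))
    write_track_table(tr, path("tracks.csv"))
    tr
  }

  report <- stage("validate", validate_tracks(tracks))
  if (nrow(report$issues) > 0) {
    readr::write_csv(report$issues, path("validation_issues.csv"),
                     progress = FALSE)
  }

  sessions <- config$turnover_sessions %||%
    head(sort(unique(tracks$session_day)), 2)
  turnover <- stage("turnover",
                    count_turnover(tracks, sessions[1], sessions[2],
                                   config$include_filopodia))
  readr::write_csv(turnover, path("turnover.csv"), progress = FALSE)

  filo <- stage("filopodia", filopodial_fraction(tracks))
  readr::write_csv(filo, path("filopodial_fraction.csv"), progress = FALSE)

  curves <- stage("survival",
                  survival_curves(tracks, config$include_filopodia))
  readr::write_csv(curves, path("survival_curves.csv"), progress = FALSE)

  min_sessions <- min(table(tracks$mouse_id[!duplicated(
    paste(tracks$mouse_id, tracks$session_day))]))
  classes <- NULL
  if (min_sessions >= 3) {
    classes <- stage("classify",
                     classify_spines(tracks, config$include_filopodia))
    readr::write_csv(classes, path("spine_classes.csv"), progress = FALSE)
  }

  genotypes <- unique(tracks$genotype)
  fits <- list()
  for (g in genotypes) {
    cg <- curves[curves$genotype == g, ]
    fits[[g]] <- list(
      free = glance(stage("fit", fit_decay(cg, constrain_s0 = FALSE,
                                           config$weight_by_n))),
      constrained = glance(stage("fit", fit_decay(cg, constrain_s0 = TRUE,
                                                  config$weight_by_n)))
    )
  }

  comparison <- NULL
  cmp_pair <- config$compare %||% head(genotypes, 2)
  if (length(cmp_pair) == 2 && all(cmp_pair %in% genotypes)) {
    comparison <- stage("compare", extra_sum_of_squares_f(
      curves[curves$genotype == cmp_pair[1], ],
      curves[curves$genotype == cmp_pair[2], ],
      constrain_s0 = config$constrain_s0,
      weight_by_n = config$weight_by_n
    ))
  }

  summary <- list(
    fits = fits,
    comparison = if (!is.null(comparison)) glance(comparison) else NULL,
    n_mice = length(unique(tracks$mouse_id)),
    turnover_sessions = sessions
  )
  jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  cfg_plain <- strip(cfg_for_hash)
  manifest <- list(
    package = "spinedyn",
    version = as.character(packageVersion("spinedyn")),
    seed = config$seed,
    config = cfg_plain,
    config_hash = rlang::hash(cfg_for_hash),
    artifacts = sort(unique(c(list.files(config$out_dir), "manifest.json")))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(tracks = tracks, validation = report, turnover = turnover,
                 filopodia = filo, curves = curves, classes = classes,
                 fits = fits, comparison = comparison, manifest = manifest))
}
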