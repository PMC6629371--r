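#' Imaging schedules used in the chronic-imaging design
#'
#' Adult mice were imaged on days 0, 1, 2, 7, 14, 21, 28 and 42 relative to
#' the first session; juveniles on days 0, 1 and 2 only.
#'
#' @param age_group `"adult"` or `"juvenile"`.
#' @return Integer vector of session days (day 0 first, strictly increasing).
#' @export
default_schedule <- function(age_group = c("adult", "juvenile")) {
  age_group <- match.arg(age_group)
  if (age_group == "adult") c(0L, 1L, 2L, 7L, 14L, 21L, 28L, 42L)
  else c(0L, 1L, 2L)
}

#' Configuration of the synthetic spine-kinetics generator
#'
#' The generator draws a day-0 protrusion pool and evolves it over an imaging
#' schedule under a two-population model: a fraction `sp` of day-0 spines is
#' permanent; the rest are impermanent with exponentially distributed
#' lifetimes of mean `tau` days. The lifetime clock is continuous and
#' observation is censored to the scheduled sessions (a spine dying on day 9
#' is last seen on day 7). Day-0 filopodia (fraction `f0` of the pool)
#' survive each session-to-session step independently with probability
#' `p_f`; once gone they stay gone. New features form as a homogeneous
#' Poisson process at rate `lambda` per day per 100 day-0 features and draw
#' the same permanent/impermanent fate; features formed after day 0 never
#' enter survival or classification. A dead impermanent day-0 spine may
#' reappear once (probability `p_rec`) after a single-session gap, with a
#' fresh exponential lifetime and no further recurrence. Each truly present
#' observation is independently mis-scored absent with probability `p_miss`.
#'
#' Defaults are the wild-type adult study conditions: 250 day-0 features,
#' `sp = 0.71`, `f0 = 0.15`, adult schedule. `tau = 5` days, `lambda = 5`
#' and `p_rec = 0.35` are model calibration choices (no measured values
#' exist for them); see the methods vignette.
#'
#' @param n_mice Mice per cohort (used by [simulate_cohort()]).
#' @param n_features0 Day-0 features per mouse (spines + filopodia).
#' @param sp Permanent fraction of day-0 spines, in `[0, 1]`.
#' @param tau Mean lifetime of impermanent spines, days (> 0).
#' @param f0 Day-0 filopodial fraction, in `[0, 1]`.
#' @param p_f Per-session filopodium survival probability, in `[0, 1]`.
#' @param lambda Formation rate: expected new features per day per 100 day-0
#'   features (>= 0).
#' @param p_rec Probability a dead impermanent spine recurs once, in `[0, 1]`.
#' @param p_miss Probability a truly present observation is scored absent.
#' @param schedule Integer session days, day 0 first, strictly increasing.
#' @param n_dendrites Number of dendritic segments per mouse.
#' @param dendrite_length_um Length of each segment, micrometres.
#' @param sp_kappa Optional Beta concentration for mouse-level heterogeneity:
#'   when non-`NULL`, each mouse draws its own permanent fraction from
#'   `Beta(sp * sp_kappa, (1 - sp) * sp_kappa)`. Default `NULL` (fixed `sp`).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_mice = 5,
                              n_features0 = 250,
                              sp = 0.71,
                              tau = 5,
                              f0 = 0.15,
                              p_f = 0.5,
                              lambda = 5,
                              p_rec = 0.35,
                              p_miss = 0,
                              schedule = default_schedule("adult"),
                              n_dendrites = 3,
                              dendrite_length_um = 140,
                              sp_kappa = NULL) {
  cfg <- list(
    n_mice = as.integer(n_mice), n_features0 = as.integer(n_features0),
    sp = sp, tau = tau, f0 = f0, p_f = p_f, lambda = lambda,
    p_rec = p_rec, p_miss = p_miss, schedule = as.integer(schedule),
    n_dendrites = as.integer(n_dendrites),
    dendrite_length_um = dendrite_length_um, sp_kappa = sp_kappa
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  probs <- c(sp = cfg$sp, f0 = cfg$f0, p_f = cfg$p_f,
             p_rec = cfg$p_rec, p_miss = cfg$p_miss)
  bad <- names(probs)[is.na(probs) | probs < 0 | probs > 1]
  if (length(bad) > 0) {
    abort(paste0("probability field(s) outside [0, 1]: ",
                 paste(bad, collapse = ", ")),
          class = "spinedyn_config_error")
  }
  if (!is.finite(cfg$tau) || cfg$tau <= 0) {
    abort("tau must be > 0", class = "spinedyn_config_error")
  }
  if (!is.finite(cfg$lambda) || cfg$lambda < 0) {
    abort("lambda must be >= 0", class = "spinedyn_config_error")
  }
  s <- cfg$schedule
  if (length(s) < 2 || s[1] != 0 || any(diff(s) <= 0)) {
    abort("schedule must start at 0, be strictly increasing, length >= 2",
          class = "spinedyn_config_error")
  }
  if (cfg$n_mice < 1 || cfg$n_features0 < 1 || cfg$n_dendrites < 1 ||
      cfg$dendrite_length_um <= 0) {
    abort("counts must be positive", class = "spinedyn_config_error")
  }
  invisible(cfg)
}

#' Simulate one mouse's track table
#'
#' Draws a full longitudinal annotation table for one animal under the model
#' described in [simulation_config()]. Fully reproducible: the same
#' `(config, seed)` pair yields a byte-identical table; the caller's RNG
#' state is left untouched.
#'
#' @param config A [simulation_config()].
#' @param mouse_id,genotype,age_group Labels for the output table.
#' @param seed Integer seed driving all randomness for this mouse.
#' @return A `spine_tracks` tibble.
#' @export
simulate_mouse <- function(config, mouse_id, genotype = "WT",
                           age_group = "adult", seed = 1) {
  validate_simulation_config(config)
  withr::local_seed(as.integer(seed))
  sched <- config$schedule
  n_s <- length(sched)
  n0 <- config$n_features0

  sp_mouse <- config$sp
  if (!is.null(config$sp_kappa)) {
    sp_mouse <- stats::rbeta(1, config$sp * config$sp_kappa,
                             (1 - config$sp) * config$sp_kappa)
  }

  is_filo <- runif(n0) < config$f0
  n_filo <- sum(is_filo)
  n_spine <- n0 - n_filo

  status <- matrix("absent", nrow = n0, ncol = n_s)
  kind <- ifelse(is_filo, "filopodia", "present")

  ## --- day-0 filopodia: chain survival, geometric in sessions -------------
  if (n_filo > 0) {
    surv_steps <- matrix(runif(n_filo * (n_s - 1)) < config$p_f,
                         nrow = n_filo)
    alive <- rep(TRUE, n_filo)
    status[is_filo, 1] <- "filopodia"
    for (k in seq_len(n_s - 1)) {
      alive <- alive & surv_steps[, k]
      status[which(is_filo)[alive], k + 1] <- "filopodia"
    }
  }

  ## --- day-0 spines: permanent / exponential death, single recurrence -----
  if (n_spine > 0) {
    idx <- which(!is_filo)
    permanent <- runif(n_spine) < sp_mouse
    death <- ifelse(permanent, Inf, rexp(n_spine, rate = 1 / config$tau))
    # alive at session day d iff death > d (continuous clock, censored view)
    for (k in seq_len(n_s)) {
      status[idx[death > sched[k]], k] <- "present"
    }
    # recurrence: first absent session k0; reappears at k0 + 1 with a fresh
    # lifetime started at that session's day, then dies for good
    first_absent <- vapply(seq_len(n_spine), function(i) {
      k <- which(sched >= death[i])[1]
      if (is.na(k)) n_s + 1L else k
    }, integer(1))
    can_recur <- !permanent & first_absent <= n_s - 1L
    recurs <- can_recur & runif(n_spine) < config$p_rec
    for (i in which(recurs)) {
      k1 <- first_absent[i] + 1L          # session of reappearance
      death2 <- sched[k1] + rexp(1, rate = 1 / config$tau)
      for (k in k1:n_s) {
        status[idx[i], k] <- if (death2 > sched[k]) "present" else "absent"
      }
    }
  }

  ## --- formation between sessions (never day-0 features) ------------------
  formed <- list()
  rate100 <- config$lambda * n0 / 100
  for (k in seq_len(n_s - 1)) {
    dt <- sched[k + 1] - sched[k]
    n_new <- rpois(1, rate100 * dt)
    if (n_new == 0) next
    t_form <- sched[k] + runif(n_new) * dt
    perm <- runif(n_new) < sp_mouse
    death <- ifelse(perm, Inf, t_form + rexp(n_new, rate = 1 / config$tau))
    st <- matrix("absent", nrow = n_new, ncol = n_s)
    for (j in seq_len(n_s)) {
      st[t_form <= sched[j] & death > sched[j], j] <- "present"
    }
    formed[[length(formed) + 1]] <- st
  }
  if (length(formed) > 0) {
    status <- rbind(status, do.call(rbind, formed))
  }

  ## --- observation noise ---------------------------------------------------
  if (config$p_miss > 0) {
    present_mask <- status != "absent"
    flip <- matrix(runif(length(status)) < config$p_miss, nrow = nrow(status))
    status[present_mask & flip] <- "absent"
  }

  ## drop features never observed (an unseen feature is never annotated)
  observed <- rowSums(status != "absent") > 0
  status <- status[observed, , drop = FALSE]
  n_feat <- nrow(status)

  ## --- assemble table ------------------------------------------------------
  dendrite <- sprintf("d%02d", 1 + (seq_len(n_feat) - 1) %% config$n_dendrites)
  x0 <- runif(n_feat, 0, config$dendrite_length_um)
  y0 <- runif(n_feat, -2, 2)
  z0 <- runif(n_feat, 0, 30)
  feature <- sprintf("f%05d", seq_len(n_feat))

  out <- tibble::tibble(
    mouse_id = mouse_id,
    genotype = genotype,
    age_group = age_group,
    dendrite_id = rep(dendrite, each = n_s),
    feature_id = rep(feature, each = n_s),
    session_day = rep(sched, times = n_feat),
    status = as.vector(t(status)),
    x_um = rep(x0, each = n_s),
    y_um = rep(y0, each = n_s),
    z_um = rep(z0, each = n_s)
  )
  out$x_um[out$status == "absent"] <- NA_real_
  out$y_um[out$status == "absent"] <- NA_real_
  out$z_um[out$status == "absent"] <- NA_real_
  as_spine_tracks(out)
}

#' Simulate a multi-genotype cohort
#'
#' Generates `n_mice` datasets per genotype with per-mouse sub-seeds derived
#' deterministically from the master seed, so a cohort is reproducible as a
#' whole and any single mouse can be regenerated in isolation.
#'
#' @param configs Named list of [simulation_config()] objects, one per
#'   genotype (names are the genotype labels).
#' @param seed Master integer seed.
#' @param age_group Age-group label stamped on all mice.
#' @return A single `spine_tracks` tibble covering the whole cohort; mouse
#'   ids are `"<genotype>_m<k>"`.
#' @export
simulate_cohort <- function(configs, seed = 1, age_group = "adult") {
  if (length(configs) < 1 || is.null(names(configs)) ||
      any(!nzchar(names(configs)))) {
    abort("configs must be a non-empty named list (names = genotypes)",
          class = "spinedyn_config_error")
  }
  if (anyDuplicated(names(configs))) {
    abort("duplicate genotype names", class = "spinedyn_config_error")
  }
  seed <- as.integer(seed)
  out <- list()
  g_i <- 0L
  for (g in names(configs)) {
    cfg <- configs[[g]]
    validate_simulation_config(cfg)
    for (i in seq_len(cfg$n_mice)) {
      sub_seed <- (seed + 104729L * g_i + 7919L * i) %% 2147483647L
      out[[length(out) + 1]] <- simulate_mouse(
        cfg, mouse_id = sprintf("%s_m%02d", g, i), genotype = g,
        age_group = age_group, seed = sub_seed
      )
    }
    g_i <- g_i + 1L
  }
  combined <- dplyr::bind_rows(out)
  if (anyDuplicated(unique(combined$mouse_id)) > 0) {
    abort("duplicate mouse ids in cohort", class = "spinedyn_config_error")
  }
  as_spine_tracks(combined)
}
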