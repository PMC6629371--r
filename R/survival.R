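#' Per-mouse spine survival curves
#'
#' For each mouse, S(t) is the fraction of day-0 spines consistently present
#' at every session up to and including day t, out of the spines initially
#' observed. A spine scored absent at any session is dead for the purpose of
#' S(t) from that session onward, even if it later reappears (recurrence is
#' handled by [classify_spines()], not here). S(0) = 1 by construction and
#' the curve is non-increasing.
#'
#' By default the day-0 cohort is spines only (`status == "present"` at day
#' 0); `include_filopodia = TRUE` admits day-0 filopodia as well, in which
#' case any non-absent status counts as presence. Features first observed
#' after day 0 never enter the curve.
#'
#' @param tracks A track table.
#' @param include_filopodia Admit day-0 filopodia into the cohort?
#' @return A `spine_survival` tibble: `mouse_id`, `genotype`, `age_group`,
#'   `time` (days), `survival`, `n_initial`.
#' @export
#' @examples
#' tracks <- simulate_mouse(simulation_config(), "m1", "WT", seed = 3)
#' survival_curves(tracks)
survival_curves <- function(tracks, include_filopodia = FALSE) {
  tracks <- as_spine_tracks(tracks)
  assert_complete_tracks(tracks)
  out <- lapply(split(tracks, tracks$mouse_id), function(tm) {
    sched <- mouse_schedule(tm)
    if (length(sched) < 2) {
      abort(paste0("mouse '", tm$mouse_id[1], "' has fewer than 2 sessions"),
            class = "spinedyn_value_error")
    }
    st <- status_matrix(tm, sched)
    day0 <- if (include_filopodia) st[, 1] != "absent" else
      st[, 1] == "present"
    if (sum(day0) == 0) {
      abort(paste0("mouse '", tm$mouse_id[1], "' has no day-0 spines"),
            class = "spinedyn_value_error")
    }
    present <- st[day0, , drop = FALSE] != "absent"
    # consistently present through session k = no absence at sessions 1..k
    consistent <- t(apply(present, 1, cumprod)) > 0
    tibble::tibble(
      mouse_id = tm$mouse_id[1],
      genotype = tm$genotype[1],
      age_group = tm$age_group[1],
      time = sched,
      survival = unname(colMeans(consistent)),
      n_initial = sum(day0)
    )
  })
  res <- dplyr::bind_rows(out)
  class(res) <- unique(c("spine_survival", class(res)))
  res
}

# internal: features x sessions status matrix for one mouse
status_matrix <- function(tm, sched = mouse_schedule(tm)) {
  tm <- dplyr::arrange(tm, .data$dendrite_id, .data$feature_id,
                       .data$session_day)
  n_s <- length(sched)
  matrix(tm$status, ncol = n_s, byrow = TRUE,
         dimnames = list(unique(paste(tm$dendrite_id, tm$feature_id)),
                         sched))
}

#' Classify day-0 spines as stable, recurrent or transient
#'
#' Day-0 spines observed at every session are stable; spines that disappear
#' and are seen again at a later session are recurrent; spines that
#' disappear and never reappear are transient. The three classes partition
#' the day-0 spine cohort. Requires at least three sessions (a reappearance
#' needs a session after the first absence).
#'
#' @inheritParams survival_curves
#' @return Tibble with one row per mouse: counts `n_stable`, `n_recurrent`,
#'   `n_transient`, the analysed cohort size `n_day0`, and the matching
#'   `f_stable`, `f_recurrent`, `f_transient` fractions (summing to 1).
#' @export
classify_spines <- function(tracks, include_filopodia = FALSE) {
  tracks <- as_spine_tracks(tracks)
  assert_complete_tracks(tracks)
  out <- lapply(split(tracks, tracks$mouse_id), function(tm) {
    sched <- mouse_schedule(tm)
    if (length(sched) < 3) {
      abort(paste0("mouse '", tm$mouse_id[1], "' has fewer than 3 sessions; ",
                   "recurrence is undefined"),
            class = "spinedyn_value_error")
    }
    st <- status_matrix(tm, sched)
    day0 <- if (include_filopodia) st[, 1] != "absent" else
      st[, 1] == "present"
    present <- st[day0, , drop = FALSE] != "absent"
    cls <- apply(present, 1, classify_status_row)
    tibble::tibble(
      mouse_id = tm$mouse_id[1],
      genotype = tm$genotype[1],
      age_group = tm$age_group[1],
      n_stable = sum(cls == "stable"),
      n_recurrent = sum(cls == "recurrent"),
      n_transient = sum(cls == "transient"),
      n_day0 = length(cls)
    )
  })
  res <- dplyr::bind_rows(out)
  res$f_stable <- res$n_stable / res$n_day0
  res$f_recurrent <- res$n_recurrent / res$n_day0
  res$f_transient <- res$n_transient / res$n_day0
  res
}

# internal: classify one logical presence vector (day-0 feature)
classify_status_row <- function(present) {
  if (all(present)) return("stable")
  first_gone <- which(!present)[1]
  if (any(present[seq_along(present) > first_gone])) "recurrent"
  else "transient"
}

#' Fit the single-phase exponential decay stability model
#'
#' Least-squares fit of \deqn{S(t) = S_p + S_i e^{-t/\tau}} to pooled
#' per-mouse survival points, where `Sp` and `Si` are the permanent and
#' impermanent spine fractions and `tau` (days) is the characteristic
#' lifespan of impermanent spines. All points are pooled with equal weight
#' (curves, not spines, are the unit) unless `weight_by_n = TRUE`, which
#' weights each point by its curve's day-0 spine count.
#'
#' Parameters are box-constrained (`Sp`, `Si` in `[0, 1]`; `tau` in
#' `(0, 10 t_max]`) and optimised by multi-start bounded quasi-Newton
#' descent with starts `Sp0 = min(S)`, `Si0 = 1 - Sp0` and
#' `tau0` in `{t_max/4, t_max/2, t_max}`; the best residual sum of squares
#' wins (relative tolerance 1e-8). With `constrain_s0 = TRUE` the model is
#' reparameterised with `Si = 1 - Sp` (two free parameters), enforcing
#' S(0) = 1 exactly.
#'
#' @param curves A `spine_survival` tibble (or any data frame with `time`,
#'   `survival` and, for weighting, `n_initial` columns).
#' @param constrain_s0 Force `Sp + Si = 1`? Default `FALSE` (3 free
#'   parameters, as a generic one-phase-decay fit).
#' @param weight_by_n Weight points by day-0 spine counts? Default `FALSE`.
#' @return A `decay_fit` object with elements `sp`, `si`, `tau`, `ss`, `df`,
#'   `n_points`, `converged`, `constrained`, `weighted`.
#' @export
#' @examples
#' tracks <- simulate_cohort(list(WT = simulation_config(n_mice = 3)), seed = 1)
#' fit <- fit_decay(survival_curves(tracks))
#' tidy(fit)
#' glance(fit)
fit_decay <- function(curves, constrain_s0 = FALSE, weight_by_n = FALSE) {
  stopifnot(is.data.frame(curves),
            all(c("time", "survival") %in% names(curves)))
  t <- as.numeric(curves$time)
  s <- as.numeric(curves$survival)
  w <- if (weight_by_n) as.numeric(curves$n_initial) else rep(1, length(s))
  keep <- is.finite(t) & is.finite(s)
  t <- t[keep]; s <- s[keep]; w <- w[keep]
  if (length(t) < 4 || length(unique(t[t > 0])) < 2) {
    abort("need >= 4 pooled points with >= 2 distinct positive times",
          class = "spinedyn_value_error")
  }
  if (sd(s) == 0) {
    abort("all survival values identical: tau is unidentifiable",
          class = "spinedyn_degenerate_error")
  }
  t_max <- max(t)
  n_free <- if (constrain_s0) 2L else 3L

  ssq <- function(par) {
    sp <- par[1]
    si <- if (constrain_s0) 1 - sp else par[2]
    tau <- par[length(par)]
    sum(w * (s - (sp + si * exp(-t / tau)))^2)
  }

  sp0 <- min(s)
  starts <- lapply(c(t_max / 4, t_max / 2, t_max), function(tau0) {
    if (constrain_s0) c(sp0, tau0) else c(sp0, 1 - sp0, tau0)
  })
  lower <- if (constrain_s0) c(0, 1e-6) else c(0, 0, 1e-6)
  upper <- if (constrain_s0) c(1, 10 * t_max) else c(1, 1, 10 * t_max)

  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, ssq, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 10, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value * (1 - 1e-8)) best <- fit
  }
  if (is.null(best)) {
    return(new_decay_fit(NA, NA, NA, NA, length(t) - n_free, length(t),
                         FALSE, constrain_s0, weight_by_n))
  }
  # polish: bounded refinement from the winning start
  polish <- tryCatch(
    optim(best$par, ssq, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(factr = 1, pgtol = 1e-14, maxit = 1000)),
    error = function(e) best
  )
  if (polish$value <= best$value) best <- polish

  sp <- best$par[1]
  si <- if (constrain_s0) 1 - sp else best$par[2]
  tau <- best$par[length(best$par)]
  new_decay_fit(sp, si, tau, best$value, length(t) - n_free, length(t),
                best$convergence == 0, constrain_s0, weight_by_n)
}

new_decay_fit <- function(sp, si, tau, ss, df, n_points, converged,
                          constrained, weighted) {
  structure(
    list(sp = sp, si = si, tau = tau, ss = ss, df = df, n_points = n_points,
         converged = converged, constrained = constrained,
         weighted = weighted),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Single-phase exponential decay fit: S(t) = Sp + Si * exp(-t/tau)\n")
  cat(sprintf("  Sp  (permanent fraction)   %.4f\n", x$sp))
  cat(sprintf("  Si  (impermanent fraction) %.4f%s\n", x$si,
              if (x$constrained) "  [constrained: Si = 1 - Sp]" else ""))
  cat(sprintf("  tau (lifespan, days)       %.3f\n", x$tau))
  cat(sprintf("  SS %.6g on %d df (%d points)%s\n", x$ss, x$df, x$n_points,
              if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}

#' @rdname fit_decay
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sp", "si", "tau"),
    estimate = c(x$sp, x$si, x$tau)
  )
}

#' @rdname fit_decay
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    sp = x$sp, si = x$si, tau = x$tau, ss = x$ss, df = x$df,
    n_points = x$n_points, converged = x$converged,
    constrained = x$constrained, weighted = x$weighted
  )
}

#' Predict survival from a decay fit
#'
#' @param object A `decay_fit`.
#' @param newdata Optional data frame with a `time` column; defaults to the
#'   times 0..t implied by nothing — supply explicitly.
#' @param ... Unused.
#' @return Numeric vector of fitted S(t).
#' @export
predict.decay_fit <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata), "time" %in% names(newdata))
  object$sp + object$si * exp(-newdata$time / object$tau)
}

#' Extra sum-of-squares F statistic from residual sums of squares
#'
#' The nested-model F statistic
#' `((ss_null - ss_alt) / (df_null - df_alt)) / (ss_alt / df_alt)` and its
#' upper-tail p-value. Exposed separately so the formula can be applied to
#' any pair of nested least-squares fits.
#'
#' @param ss_null,ss_alt Residual sums of squares of the nested (shared) and
#'   full (separate) models; `ss_null >= ss_alt`.
#' @param df_null,df_alt Residual degrees of freedom; `df_null > df_alt`.
#' @return A list with `f_statistic`, `df_numerator`, `df_denominator`,
#'   `p_value`.
#' @export
#' @examples
#' ess_f_statistic(10, 8, 13, 10)$f_statistic # 0.8333...
ess_f_statistic <- function(ss_null, ss_alt, df_null, df_alt) {
  stopifnot(df_null > df_alt, df_alt > 0)
  df_num <- df_null - df_alt
  if (ss_alt <= 1e-12) {
    return(list(f_statistic = Inf, df_numerator = df_num,
                df_denominator = df_alt, p_value = 0))
  }
  f_stat <- ((ss_null - ss_alt) / df_num) / (ss_alt / df_alt)
  list(f_statistic = f_stat, df_numerator = df_num,
       df_denominator = df_alt,
       p_value = pf(f_stat, df_num, df_alt, lower.tail = FALSE))
}

#' Extra sum-of-squares F test between two groups' decay fits
#'
#' Nested-model comparison of survival dynamics between two groups of mice
#' (e.g. genotypes). The null model fits one shared `(Sp, Si, tau)` decay to
#' both groups' pooled points; the alternative fits each group separately.
#' \deqn{F = \frac{(SS_{null} - SS_{alt}) / (df_{null} - df_{alt})}
#'            {SS_{alt} / df_{alt}}}
#' with `SS_alt = SS_a + SS_b`, `df_alt = df_a + df_b`, and the p-value is
#' the upper tail of the F distribution on
#' `(df_null - df_alt, df_alt)` degrees of freedom.
#'
#' @param curves_a,curves_b `spine_survival` tibbles for the two groups.
#' @param constrain_s0,weight_by_n Passed to [fit_decay()].
#' @return A `decay_comparison` object: `f_statistic`, `df_numerator`,
#'   `df_denominator`, `p_value`, `ss_null`, `ss_alt`, `degenerate` (TRUE
#'   when `ss_alt = 0` and F is infinite), plus the three fits.
#' @export
extra_sum_of_squares_f <- function(curves_a, curves_b, constrain_s0 = FALSE,
                                   weight_by_n = FALSE) {
  fit_a <- fit_decay(curves_a, constrain_s0, weight_by_n)
  fit_b <- fit_decay(curves_b, constrain_s0, weight_by_n)
  pooled <- dplyr::bind_rows(
    curves_a[intersect(names(curves_a), c("time", "survival", "n_initial"))],
    curves_b[intersect(names(curves_b), c("time", "survival", "n_initial"))]
  )
  fit_null <- fit_decay(pooled, constrain_s0, weight_by_n)

  ss_alt <- fit_a$ss + fit_b$ss
  df_alt <- fit_a$df + fit_b$df
  ss_null <- max(fit_null$ss, ss_alt)  # nested: exact math guarantees >=
  degenerate <- ss_alt <= 1e-12
  ft <- ess_f_statistic(ss_null, ss_alt, fit_null$df, df_alt)

  structure(
    list(f_statistic = ft$f_statistic, df_numerator = ft$df_numerator,
         df_denominator = ft$df_denominator, p_value = ft$p_value,
         ss_null = ss_null,
         ss_alt = ss_alt, degenerate = degenerate,
         fit_null = fit_null, fit_a = fit_a, fit_b = fit_b),
    class = "decay_comparison"
  )
}

#' @export
print.decay_comparison <- function(x, ...) {
  cat("Extra sum-of-squares F test (shared vs separate decay fits)\n")
  cat(sprintf("  F(%d, %d) = %.4f, p = %.4g%s\n", x$df_numerator,
              x$df_denominator, x$f_statistic, x$p_value,
              if (x$degenerate) "  [degenerate: perfect fits]" else ""))
  cat(sprintf("  SS null %.6g | SS alt %.6g\n", x$ss_null, x$ss_alt))
  cat(sprintf("  group A: Sp = %.3f, tau = %.2f | group B: Sp = %.3f, tau = %.2f\n",
              x$fit_a$sp, x$fit_a$tau, x$fit_b$sp, x$fit_b$tau))
  invisible(x)
}

#' @rdname extra_sum_of_squares_f
#' @param x A `decay_comparison` object.
#' @param ... Unused.
#' @method tidy decay_comparison
#' @export
tidy.decay_comparison <- function(x, ...) {
  tibble::tibble(
    group = c("null", "a", "b"),
    sp = c(x$fit_null$sp, x$fit_a$sp, x$fit_b$sp),
    si = c(x$fit_null$si, x$fit_a$si, x$fit_b$si),
    tau = c(x$fit_null$tau, x$fit_a$tau, x$fit_b$tau),
    ss = c(x$fit_null$ss, x$fit_a$ss, x$fit_b$ss),
    df = c(x$fit_null$df, x$fit_a$df, x$fit_b$df)
  )
}

#' @rdname extra_sum_of_squares_f
#' @method glance decay_comparison
#' @export
glance.decay_comparison <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic, df_numerator = x$df_numerator,
    df_denominator = x$df_denominator, p_value = x$p_value,
    ss_null = x$ss_null, ss_alt = x$ss_alt, degenerate = x$degenerate
  )
}
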