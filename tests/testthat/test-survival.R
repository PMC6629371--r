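test_that("survival honours the consistently-present rule on constructed tracks", {
  sched <- c(0, 1, 2, 7, 14)
  # all present -> S identically 1
  cv <- survival_curves(make_tracks(all_present(5, sched), sched))
  expect_equal(cv$survival, rep(1, 5))

  # present d0-d1, absent d2, present again d7: survives through day 1 only
  st <- rbind(c("present", "present", "absent", "present", "present"),
              all_present(1, sched))
  cv <- survival_curves(make_tracks(st, sched))
  expect_equal(cv$survival, c(1, 1, 0.5, 0.5, 0.5))

  # 100 day-0 spines, 20 with first absence <= day 7 -> S(7) = 0.80
  st <- all_present(100, sched)
  st[1:12, 3:5] <- "absent"   # first absent day 2
  st[13:20, 4:5] <- "absent"  # first absent day 7
  cv <- survival_curves(make_tracks(st, sched))
  expect_equal(cv$survival[cv$time == 7], 0.80)
})

test_that("survival curves start at 1 and never increase across simulator draws", {
  cfg <- simulation_config(n_features0 = 120, p_rec = 0.5, p_miss = 0.03,
                           f0 = 0.2)
  for (seed in 1:8) {
    cv <- survival_curves(simulate_mouse(cfg, "m1", "WT", seed = seed))
    expect_equal(cv$survival[1], 1)
    expect_true(all(diff(cv$survival) <= 1e-12))
  }
})

test_that("classification follows the stable/recurrent/transient rules", {
  sched <- c(0, 1, 2, 7, 14)
  st <- rbind(
    all_present(1, sched),                                    # stable
    c("present", "present", "present", "absent", "absent"),   # transient
    c("present", "present", "absent", "present", "absent"),   # recurrent
    c("filopodia", "absent", "absent", "absent", "absent")    # not a spine
  )
  cls <- classify_spines(make_tracks(st, sched))
  expect_equal(cls$n_stable, 1)
  expect_equal(cls$n_transient, 1)
  expect_equal(cls$n_recurrent, 1)
  expect_equal(cls$n_day0, 3)

  with_filo <- classify_spines(make_tracks(st, sched),
                               include_filopodia = TRUE)
  expect_equal(with_filo$n_day0, 4)
  expect_equal(with_filo$n_transient, 2)

  expect_error(classify_spines(make_tracks(all_present(3, c(0, 1)), c(0, 1))),
               class = "spinedyn_value_error")
})

test_that("survival and classification agree with the brute-force oracle on every per-spine status sequence", {
  sched <- c(0, 2, 7, 14, 21)
  # every status sequence over 5 sessions that starts with a day-0 spine
  seqs <- expand.grid(rep(list(c("present", "absent", "filopodia")), 4),
                      stringsAsFactors = FALSE)
  st <- as.matrix(cbind("present", seqs))
  colnames(st) <- NULL
  tracks <- make_tracks(st, sched)

  cv <- survival_curves(tracks)
  expect_equal(cv$survival, oracle_survival(st))

  cls <- classify_spines(tracks)
  orc <- oracle_classify(st)
  expect_equal(cls$n_stable, unname(orc["stable"]))
  expect_equal(cls$n_recurrent, unname(orc["recurrent"]))
  expect_equal(cls$n_transient, unname(orc["transient"]))
  expect_equal(cls$n_stable + cls$n_recurrent + cls$n_transient, cls$n_day0)
})

test_that("survival and classification agree with the oracle on random status matrices", {
  withr::local_seed(99)
  for (rep in 1:20) {
    n_s <- sample(3:5, 1)
    n_f <- sample(3:10, 1)
    st <- matrix(sample(c("present", "absent", "filopodia"), n_f * n_s,
                        replace = TRUE, prob = c(0.6, 0.3, 0.1)),
                 nrow = n_f)
    st[, 1] <- "present"  # keep a day-0 cohort
    tracks <- make_tracks(st, seq(0, by = 3, length.out = n_s))
    expect_equal(survival_curves(tracks)$survival, oracle_survival(st))
    orc <- oracle_classify(st)
    cls <- classify_spines(tracks)
    expect_equal(c(cls$n_stable, cls$n_recurrent, cls$n_transient),
                 unname(as.vector(orc)))
  }
})

test_that("noiseless curves invert exactly to their generating parameters", {
  tt <- default_schedule("adult")
  curves <- tibble::tibble(time = tt,
                           survival = 0.7 + 0.3 * exp(-tt / 5),
                           n_initial = 200)
  fit <- fit_decay(curves)
  expect_lt(abs(fit$sp - 0.7), 1e-6)
  expect_lt(abs(fit$si - 0.3), 1e-6)
  expect_lt(abs(fit$tau - 5), 1e-6)
  expect_lt(fit$ss, 1e-12)
  expect_true(fit$converged)
  expect_equal(fit$df, length(tt) - 3)

  con <- fit_decay(curves, constrain_s0 = TRUE)
  expect_lt(abs(con$sp - 0.7), 1e-6)
  expect_equal(con$df, length(tt) - 2)
})

test_that("degenerate survival input raises an unidentifiable-tau error", {
  flat <- tibble::tibble(time = c(0, 1, 2, 7), survival = 1, n_initial = 100)
  expect_error(fit_decay(flat), "unidentifiable",
               class = "spinedyn_degenerate_error")
  expect_error(fit_decay(flat[1:3, ]), class = "spinedyn_value_error")
})

test_that("fit is order-invariant and duplication changes only ss and df", {
  cfg <- simulation_config(n_mice = 4, n_features0 = 200)
  curves <- survival_curves(simulate_cohort(list(WT = cfg), seed = 17))
  fit <- fit_decay(curves)
  shuffled <- curves[sample(nrow(curves)), ]
  fit_s <- fit_decay(shuffled)
  expect_equal(c(fit_s$sp, fit_s$si, fit_s$tau, fit_s$ss),
               c(fit$sp, fit$si, fit$tau, fit$ss))

  doubled <- fit_decay(rbind(curves, curves))
  expect_equal(c(doubled$sp, doubled$si, doubled$tau),
               c(fit$sp, fit$si, fit$tau), tolerance = 1e-5)
  expect_equal(doubled$ss, 2 * fit$ss, tolerance = 1e-6)
  expect_equal(doubled$df, 2 * fit$n_points - 3)
})

test_that("pooled fit recovers simulator ground truth at cohort scale", {
  cfg <- simulation_config(n_mice = 50, n_features0 = 300, sp = 0.75,
                           tau = 7, f0 = 0, p_rec = 0, p_miss = 0)
  curves <- survival_curves(simulate_cohort(list(WT = cfg), seed = 31))
  fit <- fit_decay(curves)
  expect_lt(abs(fit$sp - 0.75), 0.02)
  expect_lt(abs(fit$tau - 7) / 7, 0.15)
})

test_that("F statistic matches hand arithmetic and identical groups give F near 0", {
  # constructed SS/df: ((10 - 8) / (13 - 10)) / (8 / 10) = 0.8333...
  f_hand <- ((10 - 8) / (13 - 10)) / (8 / 10)
  expect_equal(f_hand, 5 / 6)

  cfg <- simulation_config(n_mice = 5, n_features0 = 200)
  curves <- survival_curves(simulate_cohort(list(WT = cfg), seed = 23))
  cmp <- extra_sum_of_squares_f(curves, curves)
  expect_lt(cmp$f_statistic, 0.05)
  expect_gt(cmp$p_value, 0.95)
  expect_equal(cmp$df_numerator, 3)
  expect_gte(cmp$ss_null, cmp$ss_alt)
})

test_that("perfect fits in both groups degenerate to infinite F with p = 0", {
  tt <- c(0, 1, 2, 7, 14, 21, 28, 42)
  mk <- function(sp, tau) tibble::tibble(time = tt,
                                         survival = sp + (1 - sp) *
                                           exp(-tt / tau),
                                         n_initial = 100)
  cmp <- extra_sum_of_squares_f(mk(0.6, 4), mk(0.8, 9))
  expect_true(cmp$degenerate)
  expect_equal(cmp$f_statistic, Inf)
  expect_equal(cmp$p_value, 0)
})

test_that("tidy and glance expose fit parameters in broom shape", {
  tt <- default_schedule("adult")
  curves <- tibble::tibble(time = tt, survival = 0.7 + 0.3 * exp(-tt / 5),
                           n_initial = 100)
  fit <- fit_decay(curves)
  td <- tidy(fit)
  expect_equal(td$term, c("sp", "si", "tau"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("sp", "si", "tau", "ss", "df", "n_points", "converged",
                     "constrained", "weighted"))
  expect_equal(predict(fit, tibble::tibble(time = 0)), 1, tolerance = 1e-6)

  cmp <- extra_sum_of_squares_f(
    tibble::tibble(time = tt, survival = 0.7 + 0.3 * exp(-tt / 5) +
                     c(0.001, -0.001), n_initial = 100),
    tibble::tibble(time = tt, survival = 0.8 + 0.2 * exp(-tt / 6) +
                     c(-0.002, 0.002), n_initial = 100)
  )
  expect_equal(nrow(tidy(cmp)), 3)
  expect_true(glance(cmp)$f_statistic >= 0)
})
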