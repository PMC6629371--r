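# Independent brute-force oracles, written directly from the scoring rules
# and deliberately naive (loops, no shared code with the package).

# Survival: S(t) = (# day-0 spines consistently present to t) /
# (# day-0 spines). `status` is a features x sessions character matrix;
# day-0 cohort is the set of features with status "present" in column 1.
oracle_survival <- function(status) {
  day0 <- which(status[, 1] == "present")
  n0 <- length(day0)
  s <- numeric(ncol(status))
  for (k in seq_len(ncol(status))) {
    n_surv <- 0
    for (i in day0) {
      consistently <- TRUE
      for (j in 1:k) {
        if (status[i, j] == "absent") consistently <- FALSE
      }
      if (consistently) n_surv <- n_surv + 1
    }
    s[k] <- n_surv / n0
  }
  s
}

# Stable / recurrent / transient, per day-0 spine:
# observed at all time points -> stable; disappeared then observed again ->
# recurrent; disappeared and never reappeared -> transient.
oracle_classify <- function(status) {
  day0 <- which(status[, 1] == "present")
  out <- character(length(day0))
  for (ii in seq_along(day0)) {
    seen <- status[day0[ii], ] != "absent"
    if (all(seen)) {
      out[ii] <- "stable"
    } else {
      gone <- which(!seen)[1]
      reappeared <- FALSE
      for (j in seq_along(seen)) {
        if (j > gone && seen[j]) reappeared <- TRUE
      }
      out[ii] <- if (reappeared) "recurrent" else "transient"
    }
  }
  table(factor(out, levels = c("stable", "recurrent", "transient")))
}

# Dense-sampling Sholl oracle: walk every segment in steps of `step` um and
# count sign changes of (distance from centre - r) along the samples.
oracle_sholl <- function(trace, radii, mode = "3d", step = 0.01) {
  root <- trace[trace$parent == -1, ]
  centre <- c(root$x, root$y, root$z)
  if (mode == "2d") centre[3] <- 0
  counts <- integer(length(radii))
  children <- trace[trace$parent != -1, ]
  for (i in seq_len(nrow(children))) {
    par_row <- trace[trace$id == children$parent[i], ]
    p1 <- c(par_row$x, par_row$y, par_row$z)
    p2 <- c(children$x[i], children$y[i], children$z[i])
    if (mode == "2d") { p1[3] <- 0; p2[3] <- 0 }
    len <- sqrt(sum((p2 - p1)^2))
    n_samp <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = n_samp)
    d <- sqrt(colSums((outer(p2 - p1, tt) + p1 - centre)^2))
    for (k in seq_along(radii)) {
      sgn <- sign(d - radii[k])
      counts[k] <- counts[k] + sum(sgn[-1] * sgn[-length(sgn)] < 0)
    }
  }
  counts
}
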