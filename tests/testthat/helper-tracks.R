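# Build a track table from a features x sessions status matrix.
# Rows of `status` are features, columns are the scheduled days.
make_tracks <- function(status, schedule, mouse = "m1", genotype = "WT",
                        age_group = "adult", dendrite = "d01") {
  status <- as.matrix(status)
  n_f <- nrow(status)
  n_s <- ncol(status)
  stopifnot(n_s == length(schedule))
  tibble::tibble(
    mouse_id = mouse,
    genotype = genotype,
    age_group = age_group,
    dendrite_id = dendrite,
    feature_id = sprintf("f%05d", rep(seq_len(n_f), each = n_s)),
    session_day = rep(as.integer(schedule), times = n_f),
    status = as.vector(t(status)),
    x_um = ifelse(as.vector(t(status)) == "absent", NA_real_, 1),
    y_um = ifelse(as.vector(t(status)) == "absent", NA_real_, 2),
    z_um = ifelse(as.vector(t(status)) == "absent", NA_real_, 3)
  )
}

# Status matrix of n features present at every session.
all_present <- function(n_features, schedule) {
  matrix("present", nrow = n_features, ncol = length(schedule))
}
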