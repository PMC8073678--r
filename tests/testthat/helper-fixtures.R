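# Fixture builders shared across test files.

# A hand-specified series: constant confidence unless given.
make_series <- function(au12, au06 = rep(0, length(au12)),
                        confidence = rep(0.95, length(au12)),
                        fps = 25, subject_id = "S1") {
  n <- length(au12)
  au_frame_series(subject_id, (seq_len(n) - 1) / fps, confidence,
                  au12, au06, fps = fps)
}

# Write a minimal OpenFace-dialect CSV from explicit columns.
write_openface_fixture <- function(path, timestamp, AU12_r, AU06_r,
                                   confidence = rep(0.95, length(timestamp)),
                                   extra = NULL, drop = NULL) {
  df <- data.frame(frame = seq_along(timestamp), timestamp = timestamp,
                   confidence = confidence, success = 1L,
                   AU06_r = AU06_r, AU12_r = AU12_r, check.names = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  if (!is.null(drop)) df <- df[, setdiff(names(df), drop), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A feature-level cohort without running the pipeline: every DV drawn
# normal, with an optional additive group shift applied to chosen DVs.
make_feature_cohort <- function(n_asd = 15, n_td = 15, shift = c(),
                                seed = NULL, dv_sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_asd + n_td
  grp <- rep(c("ASD", "TD"), c(n_asd, n_td))
  dvs <- c("dur_SI", "dur_SO", "freq_SI", "freq_SO", "int_SI_au12",
           "int_SO_au12", "int_SO_au06")
  d <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    group = grp,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.85, 0.15)),
    age_months = round(stats::rnorm(n, 8.5, 1.4), 1),
    iq = round(stats::rnorm(n, 85, 15)),
    n_events_SI = 5L, n_events_SO = 5L,
    usable_seconds = 120)
  base <- c(dur_SI = 2, dur_SO = 2, freq_SI = 6, freq_SO = 5,
            int_SI_au12 = 3, int_SO_au12 = 3, int_SO_au06 = 2.5)
  for (dv in dvs) {
    mu <- rep(base[[dv]], n)
    if (dv %in% names(shift)) mu[grp == "ASD"] <- mu[grp == "ASD"] + shift[[dv]]
    d[[dv]] <- stats::rnorm(n, mu, dv_sd)
  }
  d
}
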