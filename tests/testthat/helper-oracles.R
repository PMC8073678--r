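# Independent reference implementations used as oracles. These stay
# deliberately naive (frame-by-frame scans, textbook formulas) and share
# no code with the package internals they check.

# Frame-scan reference for the detect -> filter -> classify chain,
# operating on already-smoothed signals.
brute_force_events <- function(au12_s, au06_s, valid, fps, tau = 0.5,
                               min_s = 1.0, overlap_thr = 0.5) {
  n <- length(au12_s)
  runs_of <- function(active) {
    out <- list()
    start <- NA_integer_
    for (i in seq_len(n)) {
      if (active[i] && is.na(start)) start <- i
      if (!active[i] && !is.na(start)) {
        out[[length(out) + 1L]] <- c(start, i - 1L)
        start <- NA_integer_
      }
    }
    if (!is.na(start)) out[[length(out) + 1L]] <- c(start, n)
    out
  }
  r12 <- runs_of(au12_s >= tau & valid)
  r06 <- runs_of(au06_s >= tau & valid)
  cov06 <- rep(FALSE, n)
  for (r in r06) cov06[r[1]:r[2]] <- TRUE
  rows <- list()
  for (r in r12) {
    len <- r[2] - r[1] + 1L
    if (len / fps < min_s) next
    idx <- r[1]:r[2]
    ov <- sum(cov06[idx]) / len
    rows[[length(rows) + 1L]] <- data.frame(
      start_idx = r[1], end_idx = r[2],
      smile_type = if (ov >= overlap_thr) "SO" else "SI",
      duration_s = len / fps,
      mean_au12 = mean(au12_s[idx]), mean_au06 = mean(au06_s[idx]),
      au06_overlap_frac = ov)
  }
  if (length(rows) == 0L) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      smile_type = character(), duration_s = numeric(),
                      mean_au12 = numeric(), mean_au06 = numeric(),
                      au06_overlap_frac = numeric()))
  }
  do.call(rbind, rows)
}

# The package's chain on the same pre-smoothed inputs, reshaped to match
# the oracle's output columns.
chain_events <- function(au12_s, au06_s, valid, fps, tau = 0.5,
                         min_s = 1.0, overlap_thr = 0.5) {
  ts <- (seq_along(au12_s) - 1) / fps
  iv12 <- detect_active_intervals(au12_s, valid, tau)
  iv06 <- detect_active_intervals(au06_s, valid, tau)
  iv12 <- filter_min_duration(iv12, fps, min_s)
  ev <- classify_smiles(iv12, iv06, fps, ts, au12_s, au06_s, overlap_thr)
  as.data.frame(ev[, c("start_idx", "end_idx", "smile_type", "duration_s",
                       "mean_au12", "mean_au06", "au06_overlap_frac")])
}

# Textbook two-sample Hotelling T^2 and its F transform.
hotelling_F <- function(y, g) {
  g <- factor(g)
  lv <- levels(g)
  y1 <- y[g == lv[1], , drop = FALSE]
  y2 <- y[g == lv[2], , drop = FALSE]
  n1 <- nrow(y1); n2 <- nrow(y2); p <- ncol(y)
  d <- colMeans(y1) - colMeans(y2)
  S <- ((n1 - 1) * stats::cov(y1) + (n2 - 1) * stats::cov(y2)) / (n1 + n2 - 2)
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S) %*% d)
  list(F = (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * T2,
       df1 = p, df2 = n1 + n2 - p - 1)
}

# Random piecewise trace for oracle-equivalence checks: a handful of
# rectangular/noisy activation stretches on each AU plus a random
# validity mask.
random_trace <- function(n) {
  sig <- function() {
    x <- abs(stats::rnorm(n, 0, 0.3))
    for (k in seq_len(sample(0:4, 1))) {
      len <- sample(1:max(2, n %/% 3), 1)
      s0 <- sample(1:max(1, n - len), 1)
      x[s0:(s0 + len - 1)] <- x[s0:(s0 + len - 1)] + stats::runif(1, 0.3, 3)
    }
    pmin(x, 5)
  }
  list(au12 = sig(), au06 = sig(),
       valid = stats::runif(n) > 0.1,
       fps = sample(c(12.5, 25, 30), 1),
       tau = stats::runif(1, 0.2, 1.5))
}
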