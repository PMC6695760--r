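# Independent brute-force oracles used to freeze expected values.

# double-loop time-averaged MSD: average over every pair exactly k frames apart
msd_oracle <- function(frame, x, y, max_lag, dt) {
  out <- data.frame(lag_frames = integer(0), msd_um2 = numeric(0),
                    n_pairs = integer(0))
  for (k in seq_len(max_lag)) {
    acc <- c()
    for (i in seq_along(frame)) for (j in seq_along(frame)) {
      if (frame[j] - frame[i] == k)
        acc <- c(acc, (x[j] - x[i])^2 + (y[j] - y[i])^2)
    }
    if (length(acc))
      out <- rbind(out, data.frame(lag_frames = k, msd_um2 = mean(acc),
                                   n_pairs = length(acc)))
  }
  out$lag_s <- out$lag_frames * dt
  out
}

# all-pairs maximum distance
motion_range_oracle <- function(x, y) {
  best <- 0
  for (i in seq_along(x)) for (j in seq_along(x))
    best <- max(best, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
  best
}

# random short trajectory, possibly with missing frames (gaps)
random_trajectory <- function(n, with_gaps = FALSE, dt = 0.15) {
  frames <- seq_len(n + if (with_gaps) 3L else 0L)
  if (with_gaps) frames <- sort(sample(frames, n))
  d <- data.frame(frame = frames,
                  x_um = cumsum(stats::rnorm(n, 0, 0.05)),
                  y_um = cumsum(stats::rnorm(n, 0, 0.05)),
                  intensity = 1)
  attr(d, "frame_interval_s") <- dt
  d
}

# render one synthetic Gaussian spot on a constant background (no noise
# unless sd > 0); pixel centres at integer coordinates
synthetic_spot_frame <- function(ny, nx, x0, y0, amplitude, sigma,
                                 background = 10, noise_sd = 0) {
  xs <- seq_len(nx); ys <- seq_len(ny)
  gx <- exp(-(xs - x0)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y0)^2 / (2 * sigma^2))
  img <- background + amplitude * outer(gy, gx)
  if (noise_sd > 0) img <- img + matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
  img
}
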