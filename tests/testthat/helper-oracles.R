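# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# quartile by explicit linear interpolation of order statistics
# (h = (n - 1) p + 1, interpolate between floor and ceiling order stats)
oracle_quartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_outlier_mask <- function(x, w = 2) {
  q1 <- oracle_quartile(x, 0.25); q3 <- oracle_quartile(x, 0.75)
  iqr <- q3 - q1
  x > q3 + w * iqr | x < q1 - w * iqr
}

# OLS and adjusted R^2 via explicit normal equations
oracle_ols_radj <- function(X, y) {
  A <- cbind(1, X)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  res <- y - A %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  n <- length(y); p <- ncol(X)
  r2adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sqrt(abs(r2adj))
}

# one-sided Hann PSD band power by direct DFT summation (no fft())
oracle_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  xw <- x * w
  nf <- floor(n / 2)
  df <- rate / n
  total <- 0
  for (k in seq_len(nf)) {
    f <- k * df
    if (f >= lo && f < hi) {
      cs <- sum(xw * cos(-2 * pi * k * (0:(n - 1)) / n))
      sn <- sum(xw * sin(-2 * pi * k * (0:(n - 1)) / n))
      p <- (cs^2 + sn^2) * 2 / (rate * sum(w^2))
      if (k == nf && n %% 2 == 0) p <- p / 2
      total <- total + p
    }
  }
  total * df
}

oracle_boxplot_median <- function(x) oracle_quartile(x, 0.5)

# dominant frequency of a series by periodogram argmax (plain fft)
oracle_peak_freq <- function(x, rate) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2)]
  which.max(sp) * rate / n
}

# small deterministic feature/target tables for table-assembly tests
make_toy_tables <- function(n_subjects = 3) {
  labs <- c("Baseline", "Rest", "Task1", "Rest", "Task2", "Rest", "Task1R")
  feats <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject = sprintf("S%02d", s), episode = seq_along(labs),
               label = labs,
               hr_mean = 60 + s + seq_along(labs),
               hr_std = 1, hr_max = 80, hr_min = 55,
               hrv_mean = 0.5, hrv_std = 0.05, hrv_max = 0.8, hrv_min = 0.2,
               br_mean = 14 - s)
  }))
  targs <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    data.frame(subject = sprintf("S%02d", s),
               episode = c(3, 5, 7), label = c("Task1", "Task2", "Task1R"),
               nasa_tlx_avg = 40 + 5 * s + c(0, 10, -5),
               reaction_time = 0.4 + 0.01 * s,
               non_response_rate = 0.1,
               completion_time = 300 + 10 * s)
  }))
  list(features = feats, targets = targs)
}
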