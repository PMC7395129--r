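#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor cor.test fft ks.test lm mad median
#'   pf pnorm quantile rbinom rexp rlnorm rnorm rpois runif sd var
#'   wilcox.test nextn convolve fivenum qlogis plogis
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb the global stream.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, force(code))
}

#' Derive a child seed from a parent seed and a stream label
#'
#' Deterministic fan-out of one global seed into per-stage / per-subject
#' streams. Kept below 2^31 so the result is a valid integer seed.
#'
#' @param seed parent integer seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483563L
  as.integer(h) + 1L
}

## Hann taper of length n (periodic-symmetric form used for PSD estimation)
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

#' One-sided Hann-tapered periodogram
#'
#' Power spectral density estimate of a uniformly sampled series: the series
#' is mean-removed, multiplied by a Hann taper, and the squared FFT modulus
#' is scaled so that `sum(psd) * df` equals the tapered series' variance
#' (one-sided convention, DC bin excluded from band integrals downstream).
#'
#' @param x numeric series.
#' @param rate sampling rate in Hz.
#' @return list with `freq` (Hz, excluding DC) and `psd` (power per Hz).
#' @export
periodogram_hann <- function(x, rate) {
  n <- length(x)
  if (n < 4) stopf("periodogram needs at least 4 samples")
  x <- x - mean(x)
  w <- hann_window(n)
  xf <- fft(x * w)
  nf <- floor(n / 2)
  df <- rate / n
  # one-sided PSD; factor 2 for all bins except DC (and Nyquist if present)
  p <- (Mod(xf[2:(nf + 1)])^2) * 2 / (rate * sum(w^2))
  if (n %% 2 == 0) p[nf] <- p[nf] / 2
  list(freq = (1:nf) * df, psd = p)
}

## integral of a periodogram over [lo, hi): sum of bin powers times df
band_power <- function(pg, lo, hi) {
  df <- pg$freq[1]
  sel <- pg$freq >= lo & pg$freq < hi
  sum(pg$psd[sel]) * df
}

## sample excess kurtosis (moment estimator), delegated to e1071
excess_kurtosis <- function(x) e1071::kurtosis(x, type = 1)

## draw from Normal(mean, sd) truncated to [lo, hi] by rejection
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

## clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
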