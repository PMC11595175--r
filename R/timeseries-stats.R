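# Autocorrelation-corrected statistics for per-frame observables.
#
# The statistical uncertainty of a trajectory average is the standard
# deviation divided by the square root of the number of independent
# observations, estimated as the series length divided by the integrated
# autocorrelation time tau.  tau is estimated with the self-consistent
# windowing rule (window W = smallest W >= c * tau(W), c = 5), the standard
# stable estimator for MD observables.

#' Integrated autocorrelation time of a series
#'
#' tau = 1 + 2 * sum_{k=1..W} rho(k) with the self-consistent window
#' W = min { W : W >= c * tau(W) }, clipped to [1, n/2].  A constant series
#' has tau defined as 1 (with a warning).
#'
#' @param series numeric vector of at least 10 frames.
#' @param c window factor (default 5).
#' @return tau in frames (>= 1).
#' @export
autocorrelation_time <- function(series, c = 5) {
  n <- length(series)
  if (n < 10) stop("need at least 10 frames to estimate tau, got ", n)
  if (stats::sd(series) == 0) {
    warning("constant series; tau defined as 1")
    return(1)
  }
  # grow the acf window geometrically until the self-consistent W fits in it
  lag_max <- min(200L, n - 1)
  repeat {
    rho <- as.numeric(stats::acf(series, lag.max = lag_max, plot = FALSE,
                                 demean = TRUE)$acf)[-1]
    tau_w <- 1 + 2 * cumsum(rho)
    W <- NA_integer_
    for (w in seq_along(tau_w)) {
      if (w >= c * tau_w[w]) { W <- w; break }
    }
    if (!is.na(W) || lag_max >= floor(n / 2)) break
    lag_max <- min(floor(n / 2), lag_max * 4L)
  }
  if (is.na(W)) W <- length(tau_w)
  tau <- tau_w[W]
  min(max(tau, 1), n / 2)
}

#' Mean, SD and autocorrelation-corrected SEM of a series
#'
#' @param series numeric vector (n >= 10 for a tau estimate; constant series
#'   get tau = 1 and sem = 0).
#' @return object of class `series_stats`: `n`, `mean`, `sd` (unbiased),
#'   `tau_frames`, `n_eff = n / tau`, `sem = sd / sqrt(n_eff)`.
#' @export
series_stats <- function(series) {
  n <- length(series)
  s <- stats::sd(series)
  tau <- if (s == 0) 1 else autocorrelation_time(series)
  n_eff <- n / tau
  structure(
    list(n = n, mean = mean(series), sd = if (is.na(s)) 0 else s,
         tau_frames = tau, n_eff = n_eff,
         sem = if (is.na(s) || s == 0) 0 else s / sqrt(n_eff)),
    class = "series_stats"
  )
}

#' @export
print.series_stats <- function(x, ...) {
  cat(sprintf("series_stats: n=%d mean=%.4g sd=%.4g tau=%.2f n_eff=%.1f sem=%.4g\n",
              x$n, x$mean, x$sd, x$tau_frames, x$n_eff, x$sem))
  invisible(x)
}

#' Block-averaged SEM (cross-check estimator)
#'
#' Splits the series into contiguous blocks and reports the SEM of the block
#' means.  With block length well above tau this is an independent route to
#' the same uncertainty as [series_stats()].
#'
#' @param series numeric vector.
#' @param block_frames block length in frames.
#' @return SEM of the mean.
#' @export
block_sem <- function(series, block_frames) {
  n_blocks <- floor(length(series) / block_frames)
  if (n_blocks < 2) stop("need at least 2 blocks; shorten block_frames")
  use <- series[seq_len(n_blocks * block_frames)]
  means <- colMeans(matrix(use, nrow = block_frames))
  stats::sd(means) / sqrt(n_blocks)
}
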