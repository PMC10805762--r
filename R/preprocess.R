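#' Construct a multichannel recording object
#'
#' @param samples channels x time matrix of voltages.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param channel_ids optional channel id strings.
#' @return object of class `recording`.
#' @export
recording <- function(samples, sample_rate, channel_ids = NULL) {
  samples <- as.matrix(samples)
  stopifnot(sample_rate > 0, all(is.finite(samples)))
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%03d", seq_len(nrow(samples)))
  }
  rownames(samples) <- channel_ids
  structure(list(samples = samples, sample_rate = sample_rate,
                 channel_ids = channel_ids),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels x %d samples at %g Hz\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate))
  invisible(x)
}

#' The canonical frequency-band table
#'
#' delta 1-3, theta 4-7, alpha 8-12, beta 13-30, gamma 31-50,
#' high-gamma 70-150 Hz.
#'
#' @return data frame with columns band, lo_hz, hi_hz.
#' @export
band_table <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma",
                      "high-gamma"),
             lo_hz = c(1, 4, 8, 13, 31, 70),
             hi_hz = c(3, 7, 12, 30, 50, 150),
             stringsAsFactors = FALSE)
}

#' Preprocess a raw multichannel LFP recording
#'
#' Common average referencing, notch filtering at 60 Hz and its
#' harmonics below the low-pass corner (60, 120 Hz), band-pass
#' filtering 0.1-170 Hz, and downsampling to three times the low-pass
#' cutoff (510 Hz).
#'
#' @param raw a `recording` with sample_rate >= 1020 Hz and at least 2
#'   channels.
#' @param notch_hz fundamental line frequency (default 60).
#' @param band passband edges in Hz (default c(0.1, 170)).
#' @return a `recording` at 510 Hz with per-timepoint channel mean ~ 0.
#' @export
preprocess_lfp <- function(raw, notch_hz = 60, band = c(0.1, 170)) {
  if (nrow(raw$samples) < 2) {
    stop("common-average referencing needs at least 2 channels")
  }
  fs <- raw$sample_rate
  if (fs < 2 * 3 * band[2]) {
    stop("sample rate must be at least 1020 Hz so 510 Hz is a downsample")
  }
  x <- raw$samples
  # common average reference: remove the per-timepoint channel mean
  x <- sweep(x, 2, colMeans(x))

  nyq <- fs / 2
  harmonics <- seq(notch_hz, band[2], by = notch_hz)
  filters <- lapply(harmonics, function(f) {
    signal::butter(2, c(f - 2, f + 2) / nyq, type = "stop")
  })
  # the band corners sit at very different fractions of Nyquist, so a
  # single IIR band-pass is ill-conditioned; cascade a low-order
  # high-pass with an order-4 low-pass instead
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")

  x <- t(apply(x, 1, function(ch) {
    for (flt in filters) ch <- signal::filtfilt(flt, ch)
    signal::filtfilt(lp, signal::filtfilt(hp, ch))
  }))

  target <- 3 * band[2]  # 510 Hz
  t_in <- (seq_len(ncol(x)) - 1) / fs
  n_out <- floor(max(t_in) * target) + 1
  t_out <- (seq_len(n_out) - 1) / target
  y <- t(apply(x, 1, function(ch) {
    stats::approx(t_in, ch, xout = t_out)$y
  }))
  recording(y, target, channel_ids = raw$channel_ids)
}

#' Band power via a Gaussian filter bank
#'
#' Power in a canonical band is the analytic amplitude averaged over
#' eight Gaussian band-pass filters whose center frequencies increase
#' logarithmically across the band. Filters are applied in the
#' frequency domain; adjacent filters cross at half power, and the
#' analytic amplitude is the modulus of the analytic signal obtained by
#' retaining (doubled) positive frequencies only.
#'
#' @param rec a `recording`.
#' @param band band name from [band_table()].
#' @param n_filters number of sub-band filters (default 8).
#' @return object of class `band_power_series`: `power` (channels x
#'   time, nonnegative), `band`, `edges_hz`, `sample_rate`.
#' @export
band_power <- function(rec, band, n_filters = 8L) {
  tab <- band_table()
  row <- tab[tab$band == band, ]
  if (nrow(row) == 0) {
    stop("unknown band '", band, "'; see band_table()")
  }
  if (rec$sample_rate <= 2 * row$hi_hz) {
    stop(sprintf("sample rate %g Hz too low for band %s (needs > %g Hz)",
                 rec$sample_rate, band, 2 * row$hi_hz))
  }
  centers <- exp(seq(log(row$lo_hz), log(row$hi_hz), length.out = n_filters))
  # half-power crossing at the geometric midpoint between neighbours
  mids <- sqrt(centers[-1] * centers[-n_filters])
  half_dist <- c(mids[1] - centers[1],
                 pmin(centers[-1] - mids, c(mids[-1], Inf) - centers[-1]))
  half_dist[n_filters] <- centers[n_filters] - mids[n_filters - 1]
  sigma <- abs(half_dist) / sqrt(2 * log(2))

  n <- ncol(rec$samples)
  freqs <- (seq_len(n) - 1) / n * rec$sample_rate
  pos <- freqs <= rec$sample_rate / 2
  power <- matrix(0, nrow(rec$samples), n,
                  dimnames = list(rec$channel_ids, NULL))
  for (ch in seq_len(nrow(rec$samples))) {
    X <- stats::fft(rec$samples[ch, ])
    amp <- 0
    for (k in seq_len(n_filters)) {
      W <- exp(-(freqs - centers[k])^2 / (2 * sigma[k]^2))
      W[!pos] <- 0                       # analytic: kill negative freqs
      W[pos & freqs > 0] <- 2 * W[pos & freqs > 0]
      analytic <- stats::fft(X * W, inverse = TRUE) / n
      amp <- amp + Mod(analytic)
    }
    power[ch, ] <- amp / n_filters
  }
  structure(list(power = power, band = band,
                 edges_hz = c(row$lo_hz, row$hi_hz),
                 sample_rate = rec$sample_rate),
            class = "band_power_series")
}

#' @export
print.band_power_series <- function(x, ...) {
  cat(sprintf("Band power (%s, %g-%g Hz): %d channels x %d samples at %g Hz\n",
              x$band, x$edges_hz[1], x$edges_hz[2], nrow(x$power),
              ncol(x$power), x$sample_rate))
  invisible(x)
}

# extract tokens x time epochs from one channel's series
epoch_matrix <- function(x, rate, onsets_s, pre_ms = 100, post_ms = 500) {
  n_pre <- round(pre_ms / 1000 * rate)
  n_post <- round(post_ms / 1000 * rate)
  idx0 <- round(onsets_s * rate)         # sample index of onset (0-based)
  if (any(idx0 - n_pre < 0) || any(idx0 + n_post > length(x))) {
    stop("event window extends outside the series")
  }
  ep <- t(vapply(idx0, function(i) x[(i - n_pre + 1):(i + n_post)],
                 numeric(n_pre + n_post)))
  attr(ep, "n_pre") <- n_pre
  ep
}

#' Segment a band-power series into baseline-z-scored peri-token epochs
#'
#' Epochs run from 100 ms before to 500 ms after each token onset; each
#' epoch is z-scored relative to the mean and SD of its own 100 ms
#' pre-onset baseline.
#'
#' @param power a `band_power_series` (or plain channels x time matrix;
#'   then supply `rate`).
#' @param onsets_s token onset times in seconds.
#' @param labels condition label per token.
#' @param channel channel index or id to epoch.
#' @param rate sample rate, when `power` is a bare matrix.
#' @param pre_ms,post_ms epoch extent in ms.
#' @return object of class `epoch_set`: `epochs` (tokens x time),
#'   `times_ms`, `labels`, `zscored = TRUE`.
#' @export
epoch_and_zscore <- function(power, onsets_s, labels = NULL, channel = 1L,
                             rate = NULL, pre_ms = 100, post_ms = 500) {
  if (inherits(power, "band_power_series")) {
    x <- power$power[channel, ]
    rate <- power$sample_rate
  } else {
    if (is.null(rate)) stop("rate required for a bare matrix")
    x <- if (is.matrix(power)) power[channel, ] else power
  }
  ep <- epoch_matrix(x, rate, onsets_s, pre_ms, post_ms)
  n_pre <- attr(ep, "n_pre")
  base <- ep[, seq_len(n_pre), drop = FALSE]
  mu <- rowMeans(base)
  sdv <- apply(base, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("zero baseline SD for token(s) ",
         paste(which(sdv == 0), collapse = ", "))
  }
  z <- (ep - mu) / sdv
  times_ms <- (seq_len(ncol(ep)) - n_pre - 0.5) / rate * 1000
  structure(list(epochs = z, times_ms = times_ms,
                 labels = labels, n_pre = n_pre, rate = rate,
                 zscored = TRUE),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d tokens x %d samples (%.0f..%.0f ms)%s\n",
              nrow(x$epochs), ncol(x$epochs), min(x$times_ms),
              max(x$times_ms), if (isTRUE(x$zscored)) ", z-scored" else ""))
  invisible(x)
}

#' Flag speech-responsive channels
#'
#' For each channel, 500 ms silent epochs are compared against an equal
#' number of speech epochs with a sliding-window two-sample t-test over
#' nine 100 ms windows with 50 ms overlap. Epochs are baselined by
#' subtracting the mean of the 100 ms preceding onset; within each
#' window, values per token are averaged over time. A channel is
#' responsive if at least one window's test has p < alpha.
#'
#' @param power a `band_power_series` (or channels x time matrix with
#'   `rate`).
#' @param silent_onsets_s,speech_onsets_s equal-length onset vectors.
#' @param alpha significance level per window (default 0.05; no
#'   multiple-window correction, by design).
#' @param rate sample rate when `power` is a bare matrix.
#' @return logical vector, one flag per channel; attribute `p_min`
#'   carries each channel's smallest window p-value.
#' @export
speech_responsive <- function(power, silent_onsets_s, speech_onsets_s,
                              alpha = 0.05, rate = NULL) {
  if (inherits(power, "band_power_series")) {
    mat <- power$power
    rate <- power$sample_rate
  } else {
    if (is.null(rate)) stop("rate required for a bare matrix")
    mat <- as.matrix(power)
  }
  if (length(silent_onsets_s) != length(speech_onsets_s)) {
    stop("silent and speech epoch counts must be equal")
  }
  if (length(silent_onsets_s) < 2) stop("need at least 2 epochs per group")
  wins <- window_indices(rate)
  flags <- logical(nrow(mat))
  p_min <- numeric(nrow(mat))
  for (ch in seq_len(nrow(mat))) {
    sil <- epoch_matrix(mat[ch, ], rate, silent_onsets_s)
    spe <- epoch_matrix(mat[ch, ], rate, speech_onsets_s)
    n_pre <- attr(sil, "n_pre")
    sil <- sil - rowMeans(sil[, seq_len(n_pre), drop = FALSE])
    spe <- spe - rowMeans(spe[, seq_len(n_pre), drop = FALSE])
    ps <- vapply(wins, function(w) {
      a <- rowMeans(sil[, n_pre + w, drop = FALSE])
      b <- rowMeans(spe[, n_pre + w, drop = FALSE])
      if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
      stats::t.test(a, b)$p.value
    }, numeric(1))
    flags[ch] <- any(ps < alpha)
    p_min[ch] <- min(ps)
  }
  names(flags) <- rownames(mat)
  attr(flags, "p_min") <- p_min
  flags
}
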