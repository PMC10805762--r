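# pairwise average of consecutive rows (margin 1) or columns (margin 2),
# dropping a trailing odd element
pair_avg <- function(m, margin) {
  n <- dim(m)[margin]
  k <- n %/% 2
  if (margin == 1) {
    (m[seq(1, 2 * k, by = 2), , drop = FALSE] +
       m[seq(2, 2 * k, by = 2), , drop = FALSE]) / 2
  } else {
    (m[, seq(1, 2 * k, by = 2), drop = FALSE] +
       m[, seq(2, 2 * k, by = 2), drop = FALSE]) / 2
  }
}

#' Compute the 16-bin analysis spectrogram of a waveform
#'
#' The waveform is resampled to 16 kHz, cut into consecutive 128-sample
#' (8 ms) Hann-windowed segments, and Fourier transformed, yielding 65
#' one-sided frequency bins per segment. The DC bin is dropped, the
#' remaining 64 bins are log transformed (log(x + 1e-10) guards silent
#' frames) and pairwise-averaged twice in frequency (64 -> 32 -> 16),
#' and the time axis is pairwise-averaged three times, so each final
#' time bin spans 64 ms and the bin rate is 15.625 Hz.
#'
#' @param waveform numeric samples.
#' @param sample_rate input rate in Hz; resampled to 16 kHz if needed.
#' @return object of class `binned_spectrogram`: `values` (16 x T log
#'   power, frequency low -> high), `bin_starts` (s), `bin_duration`
#'   (0.064 s), `bin_rate` (15.625 Hz).
#' @export
compute_spectrogram <- function(waveform, sample_rate) {
  target <- 16000
  x <- waveform
  if (sample_rate != target) {
    t_in <- (seq_along(x) - 1) / sample_rate
    n_out <- floor(max(t_in) * target) + 1
    x <- stats::approx(t_in, x, xout = (seq_len(n_out) - 1) / target)$y
  }
  seg_len <- 128L
  n_seg <- length(x) %/% seg_len
  if (n_seg < 1) stop("waveform shorter than one 128-sample segment")
  frames <- matrix(x[seq_len(n_seg * seg_len)], nrow = seg_len)
  win <- 0.5 * (1 - cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1)))  # Hann
  spec <- Mod(stats::mvfft(frames * win))^2
  spec <- spec[1:65, , drop = FALSE]       # one-sided, 65 bins
  spec <- spec[-1, , drop = FALSE]         # drop DC -> 64 bins
  spec <- log(spec + 1e-10)
  spec <- pair_avg(pair_avg(spec, 1), 1)   # 64 -> 32 -> 16 frequency bins
  for (i in 1:3) spec <- pair_avg(spec, 2) # 8 ms -> 64 ms time bins
  bin_dur <- seg_len / target * 8          # 0.064 s
  structure(list(values = spec,
                 bin_starts = (seq_len(ncol(spec)) - 1) * bin_dur,
                 bin_duration = bin_dur,
                 bin_rate = 1 / bin_dur),
            class = "binned_spectrogram")
}

#' @export
print.binned_spectrogram <- function(x, ...) {
  cat(sprintf("Binned spectrogram: %d freq bins x %d time bins at %g Hz\n",
              nrow(x$values), ncol(x$values), x$bin_rate))
  invisible(x)
}

#' Map a spectrogram to overlapping preceding-context chunks
#'
#' From the sixteenth time bin onward, each bin is mapped to the
#' 16 x 16 chunk (1024 ms) of spectrogram ending at and including that
#' bin, time columns ordered oldest to newest.
#'
#' @param spec a `binned_spectrogram`.
#' @return object of class `context_chunks`: `chunks` (N x 16 x 16
#'   array), `target_bin` (index of each chunk's final bin),
#'   `bin_starts`, `bin_duration`. N = T - 15; an empty series (with a
#'   warning) if T < 16.
#' @export
chunk_context <- function(spec) {
  T_bins <- ncol(spec$values)
  n_ctx <- 16L
  N <- T_bins - n_ctx + 1L
  if (N < 1L) {
    warning("spectrogram has fewer than 16 bins; no chunks")
    N <- 0L
  }
  chunks <- array(0, dim = c(N, nrow(spec$values), n_ctx))
  for (i in seq_len(N)) chunks[i, , ] <- spec$values[, i:(i + n_ctx - 1L)]
  structure(list(chunks = chunks,
                 target_bin = if (N > 0) (n_ctx:T_bins) else integer(0),
                 bin_starts = spec$bin_starts,
                 bin_duration = spec$bin_duration),
            class = "context_chunks")
}

#' Average a response series onto spectrogram time bins
#'
#' For each spectrogram bin, the response samples falling inside that
#' bin are averaged; at 510 Hz versus 15.625 Hz bins each average is
#' over 32 or 33 samples.
#'
#' @param response numeric series.
#' @param rate response sample rate in Hz.
#' @param spec a `binned_spectrogram` (supplies the bin grid).
#' @return numeric vector, one averaged value per bin; attribute
#'   `n_samples` holds the per-bin sample counts.
#' @export
align_response <- function(response, rate, spec) {
  stops <- spec$bin_starts + spec$bin_duration
  if (length(response) < floor(max(stops) * rate)) {
    stop("response does not cover all spectrogram bins")
  }
  t_samp <- (seq_along(response) - 1) / rate
  bin <- findInterval(t_samp, c(spec$bin_starts, max(stops)))
  keep <- bin >= 1 & bin <= length(spec$bin_starts) & t_samp < max(stops)
  f <- factor(bin[keep], levels = seq_along(spec$bin_starts))
  means <- as.numeric(tapply(response[keep], f, mean))
  counts <- as.integer(table(f))
  structure(means, n_samples = counts)
}

#' Keep only the most recent half of each context chunk
#'
#' Retains the 8 newest time columns of each 16 x 16 chunk (the 512 ms
#' preceding the target bin) and flattens to 128 features per chunk
#' (frequency index fastest).
#'
#' @param chunks a `context_chunks`.
#' @return N x 128 feature matrix.
#' @export
truncate_recent <- function(chunks) {
  N <- dim(chunks$chunks)[1]
  n_f <- dim(chunks$chunks)[2]
  keep <- (dim(chunks$chunks)[3] - 7L):dim(chunks$chunks)[3]
  out <- matrix(0, N, n_f * length(keep))
  for (i in seq_len(N)) out[i, ] <- as.vector(chunks$chunks[i, , keep])
  colnames(out) <- paste0("s_", seq_len(ncol(out)))
  out
}

#' Flatten full context chunks to a feature matrix
#'
#' @param chunks a `context_chunks`.
#' @return N x 256 matrix (frequency index fastest within each time
#'   column).
#' @export
flatten_chunks <- function(chunks) {
  N <- dim(chunks$chunks)[1]
  out <- matrix(0, N, prod(dim(chunks$chunks)[2:3]))
  for (i in seq_len(N)) out[i, ] <- as.vector(chunks$chunks[i, , ])
  out
}

#' Restore a flattened chunk to its frequency x time block
#'
#' Inverse of the flattening used by [truncate_recent()] and
#' [flatten_chunks()].
#'
#' @param v flattened feature vector.
#' @param n_freq number of frequency rows (default 16).
#' @return n_freq x (length(v)/n_freq) matrix.
#' @export
unflatten_chunk <- function(v, n_freq = 16L) {
  matrix(v, nrow = n_freq)
}
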