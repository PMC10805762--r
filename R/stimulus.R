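#' Synthesize a labeled speech-like excerpt
#'
#' Concatenates phone tokens into a waveform with a time-aligned interval
#' track. Each token is white noise spectrally shaped by its surface
#' class's 16-band prototype (FFT-domain gain, amplitude ramps at the
#' edges), separated by short silent gaps labeled with the inventory's
#' silence phone. Consecutive tokens are grouped into pseudo-words of
#' 1-3 phones for the word column of the track.
#'
#' Under `language_tag = "foreign"` the label-to-acoustics mapping is
#' permuted: a token labeled with phone p is rendered with the prototype
#' of a permuted phone's surface class, so labels no longer predict the
#' acoustics under the native grammar (the permutation moves at least
#' half of the phones). The permutation used is stored in the
#' `label_map` attribute.
#'
#' @param inventory a `phone_inventory`.
#' @param n_tokens number of phone tokens (>= 1).
#' @param duration_s optional target duration; the excerpt is padded
#'   with trailing silence up to this length if shorter.
#' @param language_tag "native" or "foreign".
#' @param seed integer seed.
#' @param sample_rate waveform sample rate in Hz (default 16000, the
#'   rate the spectrogram front end expects).
#' @param excerpt_id identifier recorded in the interval track.
#' @param gap_range range of inter-token silent gaps, seconds.
#' @return an object of class `labeled_stimulus`: `waveform`,
#'   `sample_rate`, `intervals` (start_s, stop_s, phone, word,
#'   excerpt_id), `language_tag`.
#' @export
synthesize_excerpt <- function(inventory, n_tokens, duration_s = NULL,
                               language_tag = c("native", "foreign"),
                               seed = 1L, sample_rate = 16000,
                               excerpt_id = "exc1",
                               gap_range = c(0.02, 0.08)) {
  language_tag <- match.arg(language_tag)
  if (length(inventory$phones) == 0) stop("empty inventory")
  if (n_tokens < 1) stop("n_tokens must be >= 1")
  set.seed(derive_seed(seed, paste0("excerpt_", excerpt_id)))

  sp <- speech_phones(inventory)
  # foreign grammar: permuted phone -> surface mapping (>= half displaced)
  label_map <- stats::setNames(sp, sp)
  if (language_tag == "foreign") {
    repeat {
      perm <- sample(sp)
      if (mean(perm != sp) >= 0.5) break
    }
    label_map <- stats::setNames(perm, sp)
  }

  phones <- sample(sp, n_tokens, replace = TRUE)
  words <- make_words(phones)

  lead <- 0.1
  t_cursor <- lead
  pieces <- list(numeric(round(lead * sample_rate)))
  rows <- list(data.frame(start_s = 0, stop_s = lead,
                          phone = inventory$silence_phone,
                          word = "", excerpt_id = excerpt_id))
  for (i in seq_len(n_tokens)) {
    dr <- inventory$duration_range[phones[i], ] / 1000
    dur <- stats::runif(1, dr[1], dr[2])
    n <- max(32L, round(dur * sample_rate))
    cls <- inventory$surface_class[[label_map[[phones[i]]]]]
    tok <- shaped_noise(n, inventory$prototype[, cls], sample_rate)
    pieces[[length(pieces) + 1L]] <- tok
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = t_cursor, stop_s = t_cursor + n / sample_rate,
      phone = phones[i], word = words[i], excerpt_id = excerpt_id)
    t_cursor <- t_cursor + n / sample_rate
    if (i < n_tokens) {
      gap <- stats::runif(1, gap_range[1], gap_range[2])
      g <- round(gap * sample_rate)
      pieces[[length(pieces) + 1L]] <- numeric(g)
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = t_cursor, stop_s = t_cursor + g / sample_rate,
        phone = inventory$silence_phone, word = "", excerpt_id = excerpt_id)
      t_cursor <- t_cursor + g / sample_rate
    }
  }
  wav <- unlist(pieces, use.names = FALSE)
  iv <- do.call(rbind, rows)

  if (!is.null(duration_s) && length(wav) < duration_s * sample_rate) {
    extra <- round(duration_s * sample_rate) - length(wav)
    iv <- rbind(iv, data.frame(start_s = t_cursor,
                               stop_s = t_cursor + extra / sample_rate,
                               phone = inventory$silence_phone,
                               word = "", excerpt_id = excerpt_id))
    wav <- c(wav, numeric(extra))
  }
  iv$stop_s <- pmin(iv$stop_s, length(wav) / sample_rate)

  structure(list(waveform = wav, sample_rate = sample_rate,
                 intervals = iv, language_tag = language_tag),
            class = "labeled_stimulus",
            label_map = label_map)
}

# white noise shaped in the FFT domain by a 16-band power envelope
# (bands tile 0-8 kHz in 500 Hz steps, matching the spectrogram's
# 16 averaged frequency bins), with raised-cosine on/off ramps
shaped_noise <- function(n, prototype, sample_rate) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * sample_rate
  f <- pmin(f, sample_rate - f)          # fold to 0..Nyquist
  band <- pmin(pmax(ceiling(f / 500), 1L), 16L)
  gain <- sqrt(prototype[band])
  x <- Re(stats::fft(X * gain, inverse = TRUE)) / n
  ramp_n <- min(round(0.01 * sample_rate), floor(n / 4))
  if (ramp_n > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    x[seq_len(ramp_n)] <- x[seq_len(ramp_n)] * ramp
    x[n + 1 - seq_len(ramp_n)] <- x[n + 1 - seq_len(ramp_n)] * ramp
  }
  0.1 * x / max(stats::sd(x), 1e-12)
}

# group consecutive tokens into pseudo-words of 1-3 phones
make_words <- function(phones) {
  n <- length(phones)
  words <- character(n)
  i <- 1L; w <- 0L
  while (i <= n) {
    w <- w + 1L
    len <- min(sample(1:3, 1), n - i + 1L)
    idx <- i:(i + len - 1L)
    words[idx] <- sprintf("w%03d_%s", w, paste(phones[idx], collapse = ""))
    i <- i + len
  }
  words
}

#' @export
print.labeled_stimulus <- function(x, ...) {
  cat(sprintf("Labeled stimulus: %.2f s at %d Hz, %d intervals (%s)\n",
              length(x$waveform) / x$sample_rate, x$sample_rate,
              nrow(x$intervals), x$language_tag))
  invisible(x)
}
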