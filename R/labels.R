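#' Per-bin phone-label proportion features
#'
#' One-hot phone labels are averaged onto the spectrogram time grid: the
#' value of each label feature in a bin is the proportion of that bin's
#' duration occupied by the label, so every feature vector is
#' nonnegative and sums to 1 when the intervals tile the audio. Bin
#' time not covered by any interval is assigned to the silence label.
#'
#' @param intervals interval data frame (start_s, stop_s, phone).
#' @param spec a `binned_spectrogram` supplying the bin grid, or NULL if
#'   `bin_starts`/`bin_duration` are given directly.
#' @param vocabulary ordered label vocabulary; defaults to the sorted
#'   unique phones in `intervals`.
#' @param silence label used for uncovered time (must be in the
#'   vocabulary if any bin is partially uncovered).
#' @param bin_starts,bin_duration explicit bin grid (seconds).
#' @return T x V matrix of proportions with vocabulary column names,
#'   class `label_track`.
#' @export
label_features <- function(intervals, spec = NULL, vocabulary = NULL,
                           silence = "sil", bin_starts = NULL,
                           bin_duration = NULL) {
  if (!is.null(spec)) {
    bin_starts <- spec$bin_starts
    bin_duration <- spec$bin_duration
  }
  if (is.null(vocabulary)) vocabulary <- sort(unique(intervals$phone))
  stops <- bin_starts + bin_duration
  out <- matrix(0, length(bin_starts), length(vocabulary),
                dimnames = list(NULL, vocabulary))
  for (i in seq_len(nrow(intervals))) {
    ph <- intervals$phone[i]
    if (!ph %in% vocabulary) next
    ov <- pmax(0, pmin(stops, intervals$stop_s[i]) -
                 pmax(bin_starts, intervals$start_s[i]))
    out[, ph] <- out[, ph] + ov / bin_duration
  }
  short <- which(rowSums(out) < 1 - 1e-9)
  if (length(short)) {
    if (!silence %in% vocabulary) {
      stop("bin(s) ", paste(utils::head(short, 5), collapse = ", "),
           " overlap no interval and no silence label is available")
    }
    out[short, silence] <- out[short, silence] + 1 - rowSums(out)[short]
  }
  out <- out / rowSums(out)   # guard accumulated float error
  class(out) <- c("label_track", class(out))
  out
}

#' Deterministic 8-bit code book for a label vocabulary
#'
#' The vocabulary is sorted lexicographically and label i (0-based, in
#' sorted order) is assigned the 8-bit binary representation of i.
#'
#' @param vocabulary character vector of labels (at most 256).
#' @return V x 8 binary matrix with label row names (most significant
#'   bit first).
#' @export
phone_code_book <- function(vocabulary) {
  vocab <- sort(unique(vocabulary))
  if (length(vocab) > 256) stop("code space exhausted: > 256 labels")
  codes <- t(vapply(seq_along(vocab) - 1L, function(i) {
    as.integer(intToBits(i))[8:1]
  }, integer(8)))
  rownames(codes) <- vocab
  codes
}

#' Embed phone-label codes into context chunks for MNE fitting
#'
#' Each 16 x 16 chunk receives a 16-bit label: the 8-bit code of the
#' phone occupying the plurality of the chunk's 1024 ms window,
#' concatenated with the runner-up's code (or with itself when the
#' window holds a single label). The chunk's mean m and standard
#' deviation sd are computed before replacement, and the
#' highest-frequency row is overwritten with m - sd for 0 bits and
#' m + sd for 1 bits, so the embedding minimally perturbs the chunk's
#' variance and covariance structure. Plurality ties break toward the
#' label with the earlier onset within the window.
#'
#' @param chunks a `context_chunks`.
#' @param intervals interval data frame.
#' @param code_book code book from [phone_code_book()].
#' @param silence label for uncovered time.
#' @return object of class `mne_feature_series`: `X` (N x 256 flattened
#'   features), `labeled = TRUE`, `codes` (N x 16 bit matrix),
#'   `labels` (N x 2 plurality / runner-up).
#' @export
label_embed_chunks <- function(chunks, intervals, code_book,
                               silence = "sil") {
  N <- dim(chunks$chunks)[1]
  n_freq <- dim(chunks$chunks)[2]
  n_ctx <- dim(chunks$chunks)[3]
  vocab <- rownames(code_book)
  X <- matrix(0, N, n_freq * n_ctx)
  codes <- matrix(0L, N, 16)
  labs <- matrix("", N, 2)
  for (i in seq_len(N)) {
    w_start <- chunks$bin_starts[chunks$target_bin[i] - n_ctx + 1L]
    w_stop <- chunks$bin_starts[chunks$target_bin[i]] + chunks$bin_duration
    occ <- stats::setNames(numeric(length(vocab)), vocab)
    onset <- stats::setNames(rep(Inf, length(vocab)), vocab)
    for (j in seq_len(nrow(intervals))) {
      ph <- intervals$phone[j]
      if (!ph %in% vocab) next
      ov <- max(0, min(w_stop, intervals$stop_s[j]) -
                  max(w_start, intervals$start_s[j]))
      if (ov > 0) {
        occ[ph] <- occ[ph] + ov
        onset[ph] <- min(onset[ph], max(intervals$start_s[j], w_start))
      }
    }
    if (sum(occ) < (w_stop - w_start) - 1e-9 && silence %in% vocab) {
      occ[silence] <- occ[silence] + (w_stop - w_start) - sum(occ)
      onset[silence] <- min(onset[silence], w_start)
    }
    present <- names(occ)[occ > 0]
    ord <- present[order(-occ[present], onset[present])]
    plur <- ord[1]
    runner <- if (length(ord) > 1) ord[2] else ord[1]
    bits <- c(code_book[plur, ], code_book[runner, ])
    chunk <- chunks$chunks[i, , ]
    m <- mean(chunk); sdv <- stats::sd(as.vector(chunk))
    chunk[n_freq, ] <- m + (2 * bits - 1) * sdv  # top (highest-freq) row
    X[i, ] <- as.vector(chunk)
    codes[i, ] <- bits
    labs[i, ] <- c(plur, runner)
  }
  structure(list(X = X, labeled = TRUE, codes = codes, labels = labs),
            class = "mne_feature_series")
}

#' @export
print.mne_feature_series <- function(x, ...) {
  cat(sprintf("MNE feature series: %d chunks x %d features%s\n",
              nrow(x$X), ncol(x$X),
              if (isTRUE(x$labeled)) " (labeled)" else ""))
  invisible(x)
}
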