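#' Define a three-role comparison for site classification
#'
#' A comparison names an anchor phone set A (the acoustically distinct
#' form), a cognate set Bx (sharing underlying category with A) and a
#' contrast set By. For the coronal-tap comparison, A = surface [t],
#' Bx = tap /t/, By = tap /d/; the morphological comparisons reuse the
#' same machinery with the word-final non-past/non-plural form as
#' anchor and the two allomorphs as Bx/By.
#'
#' @param name comparison name ("tap", "past", "plural", ...).
#' @param A,Bx,By character vectors of phone labels per role.
#' @return object of class `comparison_spec`.
#' @export
comparison_spec <- function(name, A, Bx, By) {
  roles <- list(A = A, Bx = Bx, By = By)
  if (anyDuplicated(unlist(roles))) stop("roles must be distinct phone sets")
  structure(list(name = name, roles = roles), class = "comparison_spec")
}

#' The coronal-tap comparison for a synthetic inventory
#'
#' @param inventory a `phone_inventory` from [make_inventory()].
#' @return a `comparison_spec` with A = surface [t], Bx = tap /t/,
#'   By = tap /d/.
#' @export
tap_comparison <- function(inventory) {
  comparison_spec("tap", A = "T", Bx = "dxT", By = "dxD")
}

# role factor (A/Bx/By, NA elsewhere) for a token phone vector
role_of <- function(phones, spec) {
  out <- rep(NA_character_, length(phones))
  for (r in names(spec$roles)) out[phones %in% spec$roles[[r]]] <- r
  factor(out, levels = c("A", "Bx", "By"))
}

#' Precompute per-token window values for every channel
#'
#' Extracts a baseline-z-scored epoch around every non-silence token
#' onset for every channel and averages it within the nine sliding
#' windows, yielding the tokens x windows x channels array that both
#' the real comparisons and the permutation null draw from. Tokens
#' whose epoch would leave the series, or with a degenerate (zero-SD)
#' baseline, are dropped.
#'
#' @param power channels x time matrix (or `band_power_series`).
#' @param rate sample rate in Hz (taken from the series if given one).
#' @param intervals interval data frame with start_s, stop_s, phone.
#' @param silence silence label to exclude.
#' @return object of class `token_windows`: `winvals` (tokens x 9 x
#'   channels), `phone` per token, `onsets_s`, `channel_ids`.
#' @export
token_window_values <- function(power, rate = NULL, intervals,
                                silence = "sil") {
  if (inherits(power, "band_power_series")) {
    rate <- power$sample_rate
    power <- power$power
  }
  power <- as.matrix(power)
  tok <- intervals[intervals$phone != silence, , drop = FALSE]
  n_pre <- round(0.1 * rate)
  n_post <- round(0.5 * rate)
  idx0 <- round(tok$start_s * rate)
  ok <- idx0 - n_pre >= 0 & idx0 + n_post <= ncol(power)
  tok <- tok[ok, , drop = FALSE]
  idx0 <- idx0[ok]
  wins <- window_indices(rate)
  winvals <- array(NA_real_, c(nrow(tok), length(wins), nrow(power)))
  keep <- rep(TRUE, nrow(tok))
  for (ch in seq_len(nrow(power))) {
    x <- power[ch, ]
    ep <- t(vapply(idx0, function(i) x[(i - n_pre + 1):(i + n_post)],
                   numeric(n_pre + n_post)))
    base <- ep[, seq_len(n_pre), drop = FALSE]
    mu <- rowMeans(base)
    sdv <- apply(base, 1, stats::sd)
    keep <- keep & sdv > 0
    z <- (ep - mu) / pmax(sdv, 1e-300)
    for (w in seq_along(wins)) {
      winvals[, w, ch] <- rowMeans(z[, n_pre + wins[[w]], drop = FALSE])
    }
  }
  if (!all(keep)) {
    winvals <- winvals[keep, , , drop = FALSE]
    tok <- tok[keep, , drop = FALSE]
  }
  structure(list(winvals = winvals, phone = tok$phone,
                 onsets_s = tok$start_s,
                 channel_ids = rownames(power)),
            class = "token_windows")
}

# vectorized surface/underlying classification over channels given a
# token subset and role assignment; returns per-channel flags
classify_channels <- function(tw, roles, alpha = 0.05) {
  sel <- !is.na(roles)
  roles <- droplevels(roles[sel])
  n_ch <- dim(tw$winvals)[3]
  n_win <- dim(tw$winvals)[2]
  surf <- matrix(FALSE, n_win, n_ch)
  under <- matrix(FALSE, n_win, n_ch)
  for (w in seq_len(n_win)) {
    vals <- tw$winvals[sel, w, , drop = TRUE]
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = n_ch)
    va <- vect_anova(vals, roles)
    gate <- va$p < alpha
    pABx <- va$tukey["A-Bx", ]
    pABy <- va$tukey["A-By", ]
    pBxBy <- va$tukey["Bx-By", ]
    surf[w, ] <- gate & pABx < alpha & pABy < alpha & pBxBy >= alpha
    under[w, ] <- gate & pBxBy < alpha & pABy < alpha & pABx >= alpha
  }
  first_win <- function(m) {
    apply(m, 2, function(col) if (any(col)) which(col)[1] else NA_integer_)
  }
  data.frame(channel = tw$channel_ids %||% seq_len(n_ch),
             surface = apply(surf, 2, any),
             underlying = apply(under, 2, any),
             first_surface_window = first_win(surf),
             first_underlying_window = first_win(under),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify channels as surface vs. underlying responders
#'
#' Applies the three-way decision templates window by window: a channel
#' is a surface site if some window shows significant A-Bx and A-By
#' differences with no Bx-By difference, and an underlying site if some
#' window shows significant By-Bx and By-A differences with no A-Bx
#' difference (Tukey tests gated by a significant window ANOVA). The
#' two flags are independent: a channel may be both.
#'
#' @param tw a `token_windows` (see [token_window_values()]).
#' @param spec a `comparison_spec`.
#' @param alpha significance level (default 0.05).
#' @return data frame: channel, surface, underlying, first significant
#'   window per pattern.
#' @export
classify_sites <- function(tw, spec, alpha = 0.05) {
  roles <- role_of(tw$phone, spec)
  if (any(table(roles) < 2)) {
    stop("comparison '", spec$name, "': every role needs >= 2 tokens")
  }
  classify_channels(tw, roles, alpha)
}

#' Classify a single channel from sliding-window statistics
#'
#' Single-channel counterpart of [classify_sites()] operating on a
#' `window_stats` table from [sliding_anova()] (whose Tukey columns are
#' already ANOVA-gated: NA entries count as non-significant).
#'
#' @param stats a `window_stats` data frame.
#' @param alpha significance level (default 0.05).
#' @return list with `surface`, `underlying`, and first significant
#'   window index per pattern (NA if none).
#' @export
classify_site <- function(stats, alpha = 0.05) {
  sig <- function(p) !is.na(p) & p < alpha
  nsig <- function(p) is.na(p) | p >= alpha
  surf <- sig(stats[["A-Bx"]]) & sig(stats[["A-By"]]) &
    nsig(stats[["Bx-By"]])
  under <- sig(stats[["Bx-By"]]) & sig(stats[["A-By"]]) &
    nsig(stats[["A-Bx"]])
  list(surface = any(surf), underlying = any(under),
       first_surface_window = if (any(surf)) which(surf)[1] else NA_integer_,
       first_underlying_window = if (any(under)) which(under)[1] else
         NA_integer_)
}

#' Permutation null over arbitrary phone pairs
#'
#' For each draw, an arbitrary pair of phones (A, B) is chosen from the
#' recorded data, B's tokens are split arbitrarily into two halves
#' (Bx, By), the full surface/underlying classification is run over
#' every channel, and the resulting (surface count, underlying count)
#' pair is recorded. Because the null is generated from the same
#' recorded responses as the real comparison, spatially correlated
#' activity is preserved in it. Draws with too few tokens are
#' resampled.
#'
#' @param tw a `token_windows` over all phones.
#' @param n_draws number of null draws (default 1000).
#' @param seed integer seed.
#' @param alpha significance level used inside each draw.
#' @param min_tokens minimum token count per role.
#' @return object of class `null_distribution`: data frame `draws`
#'   (surface_n, underlying_n), `n_draws`, `n_channels`.
#' @export
permutation_null <- function(tw, n_draws = 1000L, seed = 1L, alpha = 0.05,
                             min_tokens = 8L) {
  set.seed(derive_seed(seed, "perm_null"))
  counts <- table(tw$phone)
  a_pool <- names(counts)[counts >= min_tokens]
  b_pool <- names(counts)[counts >= 2 * min_tokens]
  if (length(a_pool) < 2 || length(b_pool) < 1) {
    stop("not enough phones with sufficient tokens for the null")
  }
  n_ch <- dim(tw$winvals)[3]
  draws <- matrix(NA_integer_, n_draws, 2)
  for (d in seq_len(n_draws)) {
    repeat {
      B <- sample(b_pool, 1)
      A <- sample(setdiff(a_pool, B), 1)
      roles <- rep(NA_character_, length(tw$phone))
      roles[tw$phone == A] <- "A"
      b_idx <- which(tw$phone == B)
      half <- sample(b_idx, floor(length(b_idx) / 2))
      roles[half] <- "Bx"
      roles[setdiff(b_idx, half)] <- "By"
      roles <- factor(roles, levels = c("A", "Bx", "By"))
      if (all(table(roles) >= 2)) break
    }
    if (n_ch == 0) {
      draws[d, ] <- c(0L, 0L)
    } else {
      cl <- classify_channels(tw, roles, alpha)
      draws[d, ] <- c(sum(cl$surface), sum(cl$underlying))
    }
  }
  structure(list(draws = data.frame(surface_n = draws[, 1],
                                    underlying_n = draws[, 2]),
                 n_draws = n_draws, n_channels = n_ch),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation null: %d draws over %d channels\n",
              x$n_draws, x$n_channels))
  cat(sprintf("  surface counts: median %g, underlying counts: median %g\n",
              stats::median(x$draws$surface_n),
              stats::median(x$draws$underlying_n)))
  invisible(x)
}

#' Joint tail probability of an observed (surface, underlying) pair
#'
#' The plain proportion of null draws with at least as many surface
#' sites and at least as many underlying sites as observed.
#'
#' @param null a `null_distribution`.
#' @param observed length-2 numeric (surface count, underlying count).
#' @return proportion in [0, 1].
#' @export
joint_tail_probability <- function(null, observed) {
  if (null$n_draws == 0) stop("empty null distribution")
  mean(null$draws$surface_n >= observed[1] &
         null$draws$underlying_n >= observed[2])
}

#' Is an observed count pair inside the null's joint 95% region?
#'
#' An observation is called inside the region when its joint tail
#' probability under the null is at least 1 - level, i.e. it is not in
#' the extreme upper-right 5% of the null mass.
#'
#' @param null a `null_distribution`.
#' @param observed length-2 numeric (surface count, underlying count).
#' @param level region mass (default 0.95).
#' @return logical.
#' @export
in_null_region <- function(null, observed, level = 0.95) {
  joint_tail_probability(null, observed) >= 1 - level
}
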