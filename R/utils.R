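#' Derive a stage-specific sub-seed from a root seed
#'
#' Every stochastic stage of the pipeline receives its own deterministic
#' sub-seed derived from a single root seed, so whole-pipeline runs are
#' reproducible from one integer while stages remain independently
#' re-runnable.
#'
#' @param seed integer root seed.
#' @param stage character stage tag.
#' @param index optional integer (e.g., a repetition counter).
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (abs(seed) %% 2147483647) * 69069 + h * 7919 + index * 104729
  as.integer(val %% 2147483646L + 1L)
}

#' Logistic (inverse-logit) function
#' @param z numeric vector.
#' @return 1 / (1 + exp(-z)).
#' @keywords internal
logistic <- function(z) stats::plogis(z)

#' Fisher Z transform of a correlation coefficient
#'
#' atanh of r, with r clipped to +/- (1 - 1e-6) so that perfect
#' correlations map to a large finite value rather than +/-Inf.
#'
#' @param r numeric vector of correlations in [-1, 1].
#' @return atanh of the clipped r.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -1 + 1e-6), 1 - 1e-6))
}

#' The sliding analysis-window grid
#'
#' 100 ms windows with 50 ms overlap tiling the 500 ms after onset:
#' starts 0, 50, ..., 400 ms — exactly nine windows.
#'
#' @param span_ms,win_ms,step_ms grid geometry in ms.
#' @return data frame with window, start_ms, stop_ms.
#' @export
window_grid <- function(span_ms = 500, win_ms = 100, step_ms = 50) {
  starts <- seq(0, span_ms - win_ms, by = step_ms)
  data.frame(window = seq_along(starts), start_ms = starts,
             stop_ms = starts + win_ms)
}

# index ranges (1-based, relative to a series starting at t = 0) for the
# sliding windows at a given sample rate
window_indices <- function(rate, span_ms = 500, win_ms = 100, step_ms = 50) {
  grid <- window_grid(span_ms, win_ms, step_ms)
  lapply(seq_len(nrow(grid)), function(i) {
    a <- floor(grid$start_ms[i] / 1000 * rate) + 1L
    b <- floor(grid$stop_ms[i] / 1000 * rate)
    a:b
  })
}
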