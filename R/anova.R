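# vectorized one-way ANOVA (3+ groups) with Tukey HSD post hoc,
# computed column-wise over a tokens x channels value matrix.
# Closed forms (group sums of squares + ptukey) keep the 1000-draw
# permutation null tractable; aov()/TukeyHSD() are the test oracle.
vect_anova <- function(vals, groups) {
  vals <- as.matrix(vals)
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  k <- length(lev)
  n_g <- as.numeric(table(groups))
  n <- nrow(vals)
  if (any(n_g < 2)) stop("each group needs at least 2 tokens")
  sums <- rowsum(vals, groups)                 # k x C
  means <- sums / n_g
  grand <- colSums(sums) / n
  ssb <- colSums(n_g * (means - matrix(grand, k, ncol(vals),
                                       byrow = TRUE))^2)
  sst <- colSums(vals^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  df_b <- k - 1
  df_w <- n - k
  msw <- ssw / df_w
  F_stat <- ifelse(msw > 0, (ssb / df_b) / msw, Inf)
  p <- stats::pf(F_stat, df_b, df_w, lower.tail = FALSE)

  pairs <- utils::combn(lev, 2)
  tukey <- matrix(NA_real_, ncol(pairs), ncol(vals))
  rownames(tukey) <- paste(pairs[1, ], pairs[2, ], sep = "-")
  for (j in seq_len(ncol(pairs))) {
    i1 <- match(pairs[1, j], lev); i2 <- match(pairs[2, j], lev)
    se <- sqrt(msw / 2 * (1 / n_g[i1] + 1 / n_g[i2]))
    q <- abs(means[i1, ] - means[i2, ]) / se
    tukey[j, ] <- stats::ptukey(q, k, df_w, lower.tail = FALSE)
    tukey[j, se == 0] <- ifelse(
      abs(means[i1, se == 0] - means[i2, se == 0]) > 0, 0, 1)
  }
  list(F_stat = F_stat, p = p, tukey = tukey, df_w = df_w, levels = lev)
}

#' Sliding-window one-way ANOVA with Tukey post hoc over an epoch set
#'
#' Token epochs grouped into three roles (anchor A, cognate Bx,
#' contrast By) are compared in nine 100 ms windows with 50 ms overlap
#' spanning the 500 ms after onset. Within each window, each token's
#' values are averaged over time; a one-way ANOVA across roles is
#' computed per window, and Tukey HSD pairwise p-values are reported
#' only for windows whose ANOVA p falls below `alpha` (post hoc tests
#' are ANOVA-gated).
#'
#' @param epochs an `epoch_set` (z-scored) or a tokens x time matrix
#'   whose columns start at epoch onset minus the baseline.
#' @param roles factor of role labels per token (3 levels, each with at
#'   least 2 tokens).
#' @param alpha ANOVA gate for the post hoc tests (default 0.05).
#' @return object of class `window_stats`: data frame with window,
#'   start_ms, F, p and one Tukey p column per role pair (NA where the
#'   ANOVA was not significant).
#' @export
sliding_anova <- function(epochs, roles, alpha = 0.05) {
  if (!inherits(epochs, "epoch_set")) {
    stop("epochs must be an epoch_set (see epoch_and_zscore)")
  }
  if (!isTRUE(epochs$zscored)) stop("epochs must be z-scored")
  roles <- droplevels(as.factor(roles))
  if (nlevels(roles) != 3) stop("exactly three roles are required")
  if (any(table(roles) < 2)) stop("every role needs at least 2 tokens")
  wins <- window_indices(epochs$rate)
  n_pre <- epochs$n_pre
  grid <- window_grid()
  res <- lapply(seq_along(wins), function(w) {
    vals <- rowMeans(epochs$epochs[, n_pre + wins[[w]], drop = FALSE])
    va <- vect_anova(matrix(vals, ncol = 1), roles)
    tk <- va$tukey[, 1]
    if (va$p[1] >= alpha) tk[] <- NA_real_
    c(F = va$F_stat[1], p = va$p[1], tk)
  })
  out <- cbind(grid[, c("window", "start_ms")],
               do.call(rbind, res))
  class(out) <- c("window_stats", class(out))
  out
}
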