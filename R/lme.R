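#' Build the seven-design encoding family
#'
#' From bin-aligned spectrographic (s1, 128 columns) and phone-label
#' (p1) feature blocks, constructs the seven fixed-effect designs:
#' s1, p1, s1p1 (both), plus shuffle controls s2/p2 (rows permuted
#' within excerpts) and s3/p3 (rows permuted across the session).
#'
#' @param s1 N x 128 spectrographic feature matrix.
#' @param p1 N x V label feature matrix.
#' @param excerpt_id length-N excerpt identifier.
#' @param seed integer seed for the shuffles.
#' @return named list of 7 `design_spec` objects (fields: id, X,
#'   blocks, seed).
#' @export
build_designs <- function(s1, p1, excerpt_id, seed = 1L) {
  s1 <- as.matrix(s1); p1 <- as.matrix(p1)
  if (nrow(s1) != nrow(p1)) stop("s1 and p1 are not bin-aligned")
  if (length(excerpt_id) != nrow(s1)) stop("excerpt_id length mismatch")
  colnames(s1) <- paste0("s", seq_len(ncol(s1)))
  colnames(p1) <- paste0("p", seq_len(ncol(p1)))
  mk <- function(id, X, blocks) {
    structure(list(id = id, X = X, blocks = blocks, seed = seed),
              class = "design_spec")
  }
  s2 <- shuffle_features(s1, "within_excerpt", excerpt_id,
                         seed = derive_seed(seed, "s2"))
  s3 <- shuffle_features(s1, "session", seed = derive_seed(seed, "s3"))
  p2 <- shuffle_features(p1, "within_excerpt", excerpt_id,
                         seed = derive_seed(seed, "p2"))
  p3 <- shuffle_features(p1, "session", seed = derive_seed(seed, "p3"))
  list(s1 = mk("s1", s1, "s"),
       p1 = mk("p1", p1, "p"),
       s1p1 = mk("s1p1", cbind(s1, p1), c("s", "p")),
       s2 = mk("s2", s2, "s-shuffled-excerpt"),
       p2 = mk("p2", p2, "p-shuffled-excerpt"),
       s3 = mk("s3", s3, "s-shuffled-session"),
       p3 = mk("p3", p3, "p-shuffled-session"))
}

# drop aliased columns so lmer's fixed-effect matrix stays full rank:
# label blocks sum to 1 and so are collinear with the intercept, and
# constant columns can arise in tiny designs. Pivoted QR against the
# intercept identifies an independent column subset, keeping parameter
# counts well-defined.
drop_aliased <- function(X) {
  qrX <- qr(cbind(1, X))
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  keep <- keep[keep > 1] - 1L
  X[, keep, drop = FALSE]
}

#' Fit one mixed-effects encoding model
#'
#' Fits response ~ features + (1 | channel) + (1 | speaker) by maximum
#' likelihood (not REML, so AICs are comparable across fixed-effect
#' sets). Random effects are intercepts only. The parameter count k is
#' the number of fixed effects plus the two random-intercept variances
#' plus the residual variance.
#'
#' @param design a `design_spec` (or bare feature matrix).
#' @param response numeric response, stacked bins within channels:
#'   channels x bins matrix or a vector ordered bin-fastest.
#' @param channel factor of channel ids per stacked row (recycled from
#'   a matrix response if NULL).
#' @param speaker factor of excerpt speakers per bin (recycled across
#'   channels).
#' @return object of class `lme_fit`: `fit` (the lmer model), `id`,
#'   `log_lik`, `k`, `aic`, `converged`, `singular`.
#' @export
fit_lme <- function(design, response, channel = NULL, speaker = NULL) {
  X <- if (inherits(design, "design_spec")) design$X else as.matrix(design)
  id <- if (inherits(design, "design_spec")) design$id else "design"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.matrix(response)) {
    n_ch <- nrow(response)
    if (is.null(channel)) {
      channel <- factor(rep(rownames(response) %||%
                              seq_len(n_ch), each = ncol(response)))
    }
    if (!is.null(speaker)) speaker <- rep(speaker, times = n_ch)
    Xs <- X[rep(seq_len(nrow(X)), times = n_ch), , drop = FALSE]
    y <- as.numeric(t(response))
  } else {
    y <- response
    Xs <- X
  }
  if (is.null(channel) || is.null(speaker)) {
    stop("channel and speaker grouping factors are required")
  }
  channel <- as.factor(channel); speaker <- as.factor(speaker)
  if (nlevels(channel) < 2 || nlevels(speaker) < 2) {
    stop("grouping factors need at least 2 levels each")
  }
  Xs <- drop_aliased(Xs)
  df <- data.frame(y = y, channel = channel, speaker = speaker)
  df <- cbind(df, as.data.frame(Xs))
  fixed <- paste(colnames(Xs), collapse = " + ")
  form <- stats::as.formula(paste(
    "y ~", fixed, "+ (1 | channel) + (1 | speaker)"))
  converged <- TRUE
  fit <- suppressMessages(withCallingHandlers(
    lme4::lmer(form, data = df, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }))
  ll <- as.numeric(stats::logLik(fit))
  k <- length(lme4::fixef(fit)) + 2L + 1L
  structure(list(fit = fit, id = id, log_lik = ll, k = k,
                 aic = 2 * k - 2 * ll,
                 converged = converged,
                 singular = lme4::isSingular(fit)),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("LME fit '%s': k = %d, lnL = %.2f, AIC = %.2f%s\n",
              x$id, x$k, x$log_lik, x$aic,
              if (!x$converged) " (convergence flagged)" else ""))
  invisible(x)
}

#' Akaike information criterion of a fit
#'
#' AIC = 2k - 2 ln(L), where k is the number of estimated parameters
#' and L the maximized likelihood.
#'
#' @param fit an `lme_fit`, or NULL when `k` and `log_lik` are given
#'   directly.
#' @param k,log_lik explicit parameter count and log-likelihood.
#' @return the AIC value.
#' @export
aic_value <- function(fit = NULL, k = fit$k, log_lik = fit$log_lik) {
  if (is.null(k) || is.null(log_lik)) stop("missing likelihood or k")
  2 * k - 2 * log_lik
}

#' Rank a model family by AIC and Akaike weights
#'
#' For each model i, dAIC_i = AIC_i - AIC_min, the relative likelihood
#' is exp((AIC_min - AIC_i) / 2), and the Akaike weight normalizes the
#' relative likelihoods to sum to 1.
#'
#' @param fits named list of `lme_fit` objects, or a named numeric
#'   vector of AIC values.
#' @return object of class `model_ranking`: data frame with model,
#'   aic, delta_aic, rel_likelihood, akaike_weight, ordered best first.
#' @export
rank_models <- function(fits) {
  if (is.list(fits)) {
    aics <- vapply(fits, function(f) f$aic, numeric(1))
    if (is.null(names(aics))) {
      names(aics) <- vapply(fits, function(f) f$id, "")
    }
  } else {
    aics <- fits
  }
  if (length(aics) < 2) stop("need at least 2 fits to rank")
  delta <- aics - min(aics)
  rel <- exp(-delta / 2)
  out <- data.frame(model = names(aics), aic = aics, delta_aic = delta,
                    rel_likelihood = rel,
                    akaike_weight = rel / sum(rel),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$aic), ]
  rownames(out) <- NULL
  class(out) <- c("model_ranking", class(out))
  out
}

#' Predicted-recorded correlations for an encoding fit
#'
#' Reconstructs the within-sample prediction from the fixed effects
#' plus the estimated random intercepts of each channel and speaker,
#' and correlates it with the recorded response per channel: an
#' overall Pearson r (with its Fisher Z) and a sliding-window r series
#' (500 ms windows, 50% overlap, on the bin time base).
#'
#' @param lfit an `lme_fit`.
#' @param response channels x bins response matrix used in the fit.
#' @param bin_rate bin rate in Hz (default 15.625).
#' @param window_ms sliding-window length (default 500).
#' @return object of class `prediction_record`: `per_channel` data
#'   frame (channel, r, z), `windowed` matrix (channels x windows),
#'   `window_starts_s`.
#' @export
predict_and_correlate <- function(lfit, response, bin_rate = 15.625,
                                  window_ms = 500) {
  pred <- stats::predict(lfit$fit)   # conditional on random intercepts
  n_ch <- nrow(response)
  n_bin <- ncol(response)
  pred <- matrix(pred, nrow = n_ch, byrow = TRUE)
  win_len <- max(2L, round(window_ms / 1000 * bin_rate))
  step <- max(1L, floor(win_len / 2))
  starts <- seq(1L, max(1L, n_bin - win_len + 1L), by = step)
  per_channel <- data.frame(channel = rownames(response) %||% seq_len(n_ch),
                            r = NA_real_, z = NA_real_,
                            stringsAsFactors = FALSE)
  windowed <- matrix(NA_real_, n_ch, length(starts))
  for (ch in seq_len(n_ch)) {
    if (stats::sd(pred[ch, ]) == 0 || stats::sd(response[ch, ]) == 0) {
      stop("zero-variance prediction or response for channel ", ch)
    }
    r <- stats::cor(pred[ch, ], response[ch, ])
    per_channel$r[ch] <- r
    per_channel$z[ch] <- fisher_z(r)
    for (w in seq_along(starts)) {
      idx <- starts[w]:min(n_bin, starts[w] + win_len - 1L)
      sp <- stats::sd(pred[ch, idx]); sr <- stats::sd(response[ch, idx])
      windowed[ch, w] <- if (sp > 0 && sr > 0) {
        stats::cor(pred[ch, idx], response[ch, idx])
      } else NA_real_
    }
  }
  structure(list(per_channel = per_channel, windowed = windowed,
                 window_starts_s = (starts - 1) / bin_rate),
            class = "prediction_record")
}

# shared meta-model fitter: Z ~ <terms> + (1 | subject) + (1 | channel),
# ML fit, with guards for single-level grouping factors
fit_meta_family <- function(records, formulas) {
  records$subject <- as.factor(records$subject)
  records$channel <- as.factor(records$channel)
  re <- c()
  if (nlevels(records$subject) > 1) re <- c(re, "(1 | subject)")
  if (nlevels(records$channel) > 1) re <- c(re, "(1 | channel)")
  if (length(re) == 0) stop("need at least one multi-level grouping factor")
  fits <- lapply(names(formulas), function(nm) {
    rhs <- paste(c(formulas[[nm]], re), collapse = " + ")
    converged <- TRUE
    fit <- suppressMessages(withCallingHandlers(
      lme4::lmer(stats::as.formula(paste("z ~", rhs)), data = records,
                 REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }))
    ll <- as.numeric(stats::logLik(fit))
    k <- attr(stats::logLik(fit), "df")
    structure(list(fit = fit, id = nm, log_lik = ll, k = k,
                   aic = 2 * k - 2 * ll, converged = converged,
                   singular = lme4::isSingular(fit)),
              class = "lme_fit")
  })
  names(fits) <- names(formulas)
  list(fits = fits, ranking = rank_models(fits))
}

#' Language-knowledge contrast over encoding-fit quality
#'
#' Fits the three-member meta-model family on per-channel Fisher-Z
#' prediction quality: (1) z ~ model + band, (2) + lang, (3) + lang +
#' lang:model, each with subject and channel random intercepts, and
#' ranks them by AIC. A first-ranked interaction model indicates that
#' the benefit of phone-label features depends on whether the listener
#' knows the language of the excerpt.
#'
#' @param records data frame with columns z, model, band, lang,
#'   subject, channel, spanning both language tags.
#' @return list with `fits` and `ranking` (a `model_ranking`).
#' @export
language_contrast <- function(records) {
  need <- c("z", "model", "band", "lang", "subject", "channel")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(records$lang)) < 2) {
    stop("records must span both language tags")
  }
  base <- "model"
  if (length(unique(records$band)) > 1) base <- c(base, "band")
  fit_meta_family(records, list(
    base = base,
    lang = c(base, "lang"),
    lang_x_model = c(base, "lang", "lang:model")))
}
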