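#' Construct a Maximum Noise Entropy stimulus-response model
#'
#' An MNE model maps a stimulus feature vector s to a response
#' probability through a logistic function,
#' P(y | s) = 1 / (1 + exp(-z(s))) with z(s) = a + h's + s'Js:
#' `a` sets the mean unit response, the linear kernel `h` captures the
#' response constrained by the stimulus variance, and the symmetric
#' quadratic kernel `J` the response constrained by the stimulus
#' covariance. A first-order model has no quadratic term.
#'
#' @param a scalar offset.
#' @param h numeric linear kernel of length D.
#' @param J optional D x D quadratic kernel; must be symmetric. NULL for
#'   a first-order model.
#' @param feature_set optional tag describing the feature space the
#'   model is defined over (e.g., "spectrogram", "labeled-spectrogram").
#' @return object of class `mne_model` with fields `a`, `h`, `J`,
#'   `order` (1 or 2) and `feature_set`.
#' @export
mne_model <- function(a, h, J = NULL, feature_set = "spectrogram") {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(h))
  order <- 1L
  if (!is.null(J)) {
    J <- as.matrix(J)
    stopifnot(nrow(J) == length(h), ncol(J) == length(h))
    if (max(abs(J - t(J))) > 1e-8 * max(1, max(abs(J)))) {
      stop("J must be symmetric")
    }
    J <- (J + t(J)) / 2   # exact symmetry to machine precision
    order <- 2L
  }
  structure(list(a = a, h = as.numeric(h), J = J, order = order,
                 feature_set = feature_set),
            class = "mne_model")
}

#' @export
print.mne_model <- function(x, ...) {
  cat(sprintf("MNE model: order %d, D = %d (%s)\n", x$order,
              length(x$h), x$feature_set))
  invisible(x)
}

#' Evaluate an MNE model's response probability
#'
#' Computes P(y | s) = logistic(a + h's + s'Js) for one or more feature
#' vectors. First-order models ignore the quadratic term.
#'
#' @param model an `mne_model`.
#' @param s a feature vector of length D or an N x D matrix of feature
#'   rows.
#' @param order evaluation order, defaulting to the model's own; an
#'   order-2 model can be evaluated at order 1 (linear features only).
#' @return numeric vector of probabilities in (0, 1).
#' @export
mne_response <- function(model, s, order = model$order) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  if (!all(is.finite(s))) stop("non-finite stimulus features")
  if (ncol(s) != length(model$h)) {
    stop(sprintf("feature dimension mismatch: model D = %d, input D = %d",
                 length(model$h), ncol(s)))
  }
  z <- model$a + as.numeric(s %*% model$h)
  if (order == 2L) {
    if (is.null(model$J)) stop("order-2 evaluation of an order-1 model")
    z <- z + rowSums((s %*% model$J) * s)
  }
  logistic(z)
}

#' Predicted response series from an MNE model
#'
#' @param object an `mne_model`.
#' @param features N x D feature matrix.
#' @param order 1 for linear-only prediction (z = a + h's), 2 for the
#'   complete model; defaults to the model's order.
#' @param ... unused.
#' @return numeric vector of N probabilities.
#' @export
predict.mne_model <- function(object, features, order = object$order, ...) {
  mne_response(object, features, order = order)
}

#' Robust min-max normalization of a response series to [0, 1]
#'
#' Maps a continuous per-bin response onto the probability scale the
#' logistic log loss expects: values are scaled between the series' 1st
#' and 99th percentiles and clipped, so isolated outliers do not
#' compress the usable range. Affine transforms of the input give
#' identical output.
#'
#' @param x numeric series.
#' @return numeric series in [0, 1].
#' @export
normalize_response <- function(x) {
  if (stats::sd(x) == 0) stop("constant response series cannot be normalized")
  q <- stats::quantile(x, c(0.01, 0.99), names = FALSE, type = 7)
  if (q[2] <= q[1]) q <- range(x)
  pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
}

# --- parameter packing -------------------------------------------------

# order-2 parameters are (a, h, upper triangle of J incl. diagonal);
# J is reconstructed exactly symmetric
pack_theta <- function(a, h, J = NULL) {
  if (is.null(J)) c(a, h) else c(a, h, J[upper.tri(J, diag = TRUE)])
}

unpack_theta <- function(theta, D, order) {
  a <- theta[1]
  h <- theta[2:(D + 1)]
  J <- NULL
  if (order == 2L) {
    J <- matrix(0, D, D)
    J[upper.tri(J, diag = TRUE)] <- theta[-(1:(D + 1))]
    J <- J + t(J) - diag(diag(J))
  }
  list(a = a, h = h, J = J)
}

# mean cross-entropy between response y in [0,1] and logistic(z)
mne_loss <- function(theta, X, y, D, order) {
  par <- unpack_theta(theta, D, order)
  z <- par$a + as.numeric(X %*% par$h)
  if (order == 2L) z <- z + rowSums((X %*% par$J) * X)
  p <- pmin(pmax(logistic(z), 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

mne_grad <- function(theta, X, y, D, order) {
  par <- unpack_theta(theta, D, order)
  z <- par$a + as.numeric(X %*% par$h)
  if (order == 2L) z <- z + rowSums((X %*% par$J) * X)
  r <- (logistic(z) - y) / length(y)
  g_a <- sum(r)
  g_h <- as.numeric(crossprod(X, r))
  if (order == 1L) return(c(g_a, g_h))
  M <- crossprod(X, r * X)              # sum_n r_n s_i s_j
  G <- M + t(M) - diag(diag(M))         # d z / d J_ij (i<j) doubles up
  c(g_a, g_h, G[upper.tri(G, diag = TRUE)])
}

#' Fit an MNE model by jackknifed conjugate-gradient descent
#'
#' Minimizes the logistic log loss between the response and the model
#' output with a nonlinear conjugate-gradient optimizer and analytic
#' gradients. The bins are split into `folds` contiguous temporal
#' batches; for each jackknife, the held-out batch monitors the test
#' loss. One "epoch" is a block of `cg_iter` CG iterations; if the test
#' loss has not decreased for `patience` consecutive epochs, training
#' for that fold halts and the weights at the best test loss are kept.
#' The final model averages the four folds' weights.
#'
#' @param features N x D feature matrix.
#' @param response length-N response in [0, 1] (see
#'   [normalize_response()]).
#' @param order 1 (linear) or 2 (linear + quadratic).
#' @param folds number of jackknife batches (default 4).
#' @param patience early-stopping patience, in epochs (default 10).
#' @param max_epochs hard cap on epochs per fold.
#' @param cg_iter CG iterations per epoch (default 20).
#' @param feature_set tag stored on the fitted model.
#' @param verbose print per-fold progress.
#' @return object of class `mne_jackknife`: `model` (fold-averaged
#'   `mne_model`), `fold_models`, `stop_epoch`, `test_loss` traces, and
#'   the fold index of each bin.
#' @export
fit_mne <- function(features, response, order = 2L, folds = 4L,
                    patience = 10L, max_epochs = 300L, cg_iter = 20L,
                    feature_set = "spectrogram", verbose = FALSE) {
  X <- as.matrix(features)
  y <- as.numeric(response)
  N <- nrow(X); D <- ncol(X)
  if (length(y) != N) stop("features and response lengths differ")
  if (any(y < 0 | y > 1)) stop("response must lie in [0, 1]")
  n_par <- if (order == 2L) 1 + D + D * (D + 1) / 2 else 1 + D
  if (N < 4 * (D + 1)) {
    stop(sprintf("too few bins (N = %d) for D = %d", N, D))
  }

  fold_id <- cut(seq_len(N), folds, labels = FALSE)  # contiguous quarters
  fold_models <- vector("list", folds)
  stop_epoch <- integer(folds)
  traces <- vector("list", folds)

  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    theta <- numeric(n_par)           # zeros: deterministic, unbiased start
    best <- list(loss = Inf, theta = theta)
    bad <- 0L; trace <- numeric(0)
    prev_train <- Inf
    for (epoch in seq_len(max_epochs)) {
      opt <- stats::optim(theta, mne_loss, mne_grad, X = Xtr, y = ytr,
                          D = D, order = order, method = "CG",
                          control = list(maxit = cg_iter))
      theta <- opt$par
      te <- mne_loss(theta, Xte, yte, D, order)
      trace <- c(trace, te)
      if (te < best$loss - 1e-12) {
        best <- list(loss = te, theta = theta)
        bad <- 0L
      } else {
        bad <- bad + 1L
      }
      converged_train <- prev_train - opt$value < 1e-11
      prev_train <- opt$value
      if (bad >= patience || converged_train) break
    }
    stop_epoch[f] <- length(trace)
    traces[[f]] <- trace
    par <- unpack_theta(best$theta, D, order)
    fold_models[[f]] <- mne_model(par$a, par$h, par$J,
                                  feature_set = feature_set)
    if (verbose) {
      message(sprintf("fold %d: %d epochs, test loss %.6f", f,
                      stop_epoch[f], best$loss))
    }
  }

  avg <- Reduce(`+`, lapply(fold_models, function(m) {
    pack_theta(m$a, m$h, m$J)
  })) / folds
  par <- unpack_theta(avg, D, order)
  structure(list(model = mne_model(par$a, par$h, par$J,
                                   feature_set = feature_set),
                 fold_models = fold_models,
                 stop_epoch = stop_epoch,
                 test_loss = traces,
                 fold_id = fold_id,
                 order = order),
            class = "mne_jackknife")
}

#' @export
print.mne_jackknife <- function(x, ...) {
  cat(sprintf("Jackknifed MNE fit: order %d, D = %d, %d folds, epochs: %s\n",
              x$order, length(x$model$h), length(x$fold_models),
              paste(x$stop_epoch, collapse = "/")))
  invisible(x)
}

#' Eigendecomposition of a second-order MNE model's quadratic kernel
#'
#' The eigenvectors of J are the model's receptive fields; eigenvalues
#' are returned in ascending order, with the threshold delimiting the
#' top 5% of eigenvalue magnitudes (the fields outside the bulk).
#'
#' @param model an order-2 `mne_model`.
#' @return object of class `rf_decomposition`: `values` (ascending),
#'   `vectors` (columns matching `values`), `magnitude_threshold`.
#' @export
decompose <- function(model) {
  if (model$order != 2L || is.null(model$J)) {
    stop("receptive-field decomposition requires an order-2 model")
  }
  e <- eigen(model$J, symmetric = TRUE)
  ord <- order(e$values)                # ascending
  structure(list(values = e$values[ord],
                 vectors = e$vectors[, ord, drop = FALSE],
                 magnitude_threshold =
                   stats::quantile(abs(e$values), 0.95, names = FALSE)),
            class = "rf_decomposition")
}

#' Extract extreme receptive fields from a decomposition
#'
#' Convenience accessor for the fields at the most negative or most
#' positive eigenvalues, reshaped to frequency x time when the feature
#' dimension is a perfect square or a declared chunk shape.
#'
#' @param dec an `rf_decomposition`.
#' @param which "negative" or "positive".
#' @param n number of fields (default 6).
#' @param shape optional c(freq, time) to reshape each field; defaults
#'   to c(16, D / 16) when D is a multiple of 16.
#' @return list of matrices (or vectors if no shape applies).
#' @export
rf_fields <- function(dec, which = c("negative", "positive"), n = 6,
                      shape = NULL) {
  which <- match.arg(which)
  D <- nrow(dec$vectors)
  idx <- if (which == "negative") seq_len(min(n, D)) else
    rev(seq(D, by = -1, length.out = min(n, D)))
  if (is.null(shape) && D %% 16 == 0) shape <- c(16, D / 16)
  lapply(idx, function(i) {
    v <- dec$vectors[, i]
    if (!is.null(shape)) matrix(v, shape[1], shape[2]) else v
  })
}

#' Spectrum- or kernel-preserving shuffle controls for an MNE model
#'
#' Linear control: the entries of h are permuted. Quadratic control: J
#' is eigendecomposed, the eigenvalues are permuted over the fixed
#' eigenvectors, and J is recomposed (h is permuted as well). Either way
#' the multiset of weights (and for J the eigenvalue spectrum and the
#' receptive fields themselves) is preserved; only their assignment is
#' randomized, giving a deliberately strong chance-level control.
#'
#' @param model an `mne_model`.
#' @param part "linear" or "quadratic".
#' @param seed integer seed.
#' @return a shuffled `mne_model` of the same order.
#' @export
shuffle_control <- function(model, part = c("linear", "quadratic"),
                            seed = 1L) {
  part <- match.arg(part)
  set.seed(derive_seed(seed, paste0("shuffle_", part)))
  if (part == "linear") {
    return(mne_model(model$a, sample(model$h), model$J,
                     feature_set = model$feature_set))
  }
  if (model$order != 2L) {
    stop("quadratic shuffle requires an order-2 model")
  }
  e <- eigen(model$J, symmetric = TRUE)
  lam <- sample(e$values)
  J <- e$vectors %*% (lam * t(e$vectors))
  J <- (J + t(J)) / 2
  mne_model(model$a, sample(model$h), J, feature_set = model$feature_set)
}

#' Fisher-Z prediction quality of a predicted response
#'
#' Pearson correlation between predicted and recorded series,
#' variance-stabilized by the Fisher Z transform (r clipped away from
#' +/-1 so Z stays finite).
#'
#' @param predicted,recorded equal-length numeric series.
#' @return list with `r` and `z`.
#' @export
evaluate_prediction <- function(predicted, recorded) {
  if (length(predicted) != length(recorded)) stop("length mismatch")
  if (stats::sd(predicted) == 0 || stats::sd(recorded) == 0) {
    stop("zero-variance series: correlation undefined")
  }
  r <- stats::cor(predicted, recorded)
  list(r = r, z = fisher_z(r))
}
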