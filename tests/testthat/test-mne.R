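mk_truth <- function(D = 8, seed = 3, rank = 3) {
  set.seed(seed)
  h <- rnorm(D, 0, 0.5)
  V <- qr.Q(qr(matrix(rnorm(D * D), D)))
  lam <- numeric(D)
  lam[1:rank] <- c(0.45, -0.3, 0.2)[1:rank]
  J <- V %*% (lam * t(V)); J <- (J + t(J)) / 2
  list(model = mne_model(-0.2, h, J), h = h, V = V, lam = lam)
}

test_that("the logistic response law matches closed forms", {
  D <- 4
  expect_equal(mne_response(mne_model(0, rep(0, D)), rnorm(D)), 0.5)
  expect_equal(mne_response(mne_model(1, rep(0, D)), rnorm(D)),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(1 / (1 + exp(-1)), 5), 0.73106)
  # e1 with J = I: z = 1
  m <- mne_model(0, rep(0, D), diag(D))
  expect_equal(mne_response(m, c(1, 0, 0, 0)), 1 / (1 + exp(-1)))
  expect_error(mne_response(m, rnorm(3)), "dimension")
  expect_error(mne_response(m, c(NA, 1, 1, 1)), "finite")
  expect_error(mne_model(0, rep(0, 3), matrix(rnorm(9), 3)), "symmetric")
  # order-1 models have no quadratic term
  m1 <- mne_model(0.5, rep(1, 2))
  expect_equal(m1$order, 1L)
  expect_null(m1$J)
})

test_that("response normalization is robust, affine-invariant min-max", {
  x <- seq(0, 1, length.out = 200)
  nx <- normalize_response(x)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), 1)
  # affine invariance
  expect_equal(normalize_response(3 * x - 7), nx)
  # outliers clip to 1 rather than compressing the scale
  y <- c(rep(seq(0, 1, length.out = 99), 3), 100)
  ny <- normalize_response(y)
  expect_equal(ny[length(ny)], 1)
  q <- stats::quantile(y, c(0.01, 0.99), names = FALSE)
  expect_equal(ny[5], min(max((y[5] - q[1]) / (q[2] - q[1]), 0), 1))
  expect_error(normalize_response(rep(2, 10)), "constant")
})

test_that("jackknifed fitting recovers planted second-order structure", {
  tr <- mk_truth(D = 8, seed = 5)
  set.seed(6)
  N <- 6000
  X <- matrix(rnorm(N * 8), N, 8)
  y <- mne_response(tr$model, X)      # noiseless
  jk <- fit_mne(X, y, order = 2, max_epochs = 150)
  expect_equal(length(jk$fold_models), 4)
  # averaged weights equal the mean of the fold weights
  avg_h <- Reduce(`+`, lapply(jk$fold_models, `[[`, "h")) / 4
  expect_equal(jk$model$h, avg_h)
  avg_J <- Reduce(`+`, lapply(jk$fold_models, `[[`, "J")) / 4
  expect_equal(jk$model$J, avg_J)
  # folds partition the bins into contiguous quarters
  expect_equal(as.vector(table(jk$fold_id)), rep(N / 4, 4))
  expect_true(all(diff(jk$fold_id) >= 0))
  # recovery
  expect_gt(cor(jk$model$h, tr$h), 0.95)
  dec <- decompose(jk$model)
  i_hat <- which.max(abs(dec$values))
  v_true <- tr$V[, which.max(abs(tr$lam))]
  expect_gt(abs(sum(dec$vectors[, i_hat] * v_true)), 0.9)
  # J is exactly symmetric
  expect_identical(jk$model$J, t(jk$model$J))
})

test_that("a constant 0.5 response shrinks the kernels toward zero", {
  set.seed(7)
  N <- 3000; D <- 6
  X <- matrix(rnorm(N * D), N, D)
  flat <- fit_mne(X, rep(0.5, N), order = 2, max_epochs = 60)
  tr <- mk_truth(D = 6, seed = 8, rank = 3)
  y <- mne_response(tr$model, X)
  sig <- fit_mne(X, y, order = 2, max_epochs = 60)
  expect_lt(sqrt(sum(flat$model$h^2)), 0.1 * sqrt(sum(sig$model$h^2)))
  expect_lt(sqrt(sum(flat$model$J^2)), 0.1 * sqrt(sum(sig$model$J^2)))
})

test_that("fitting input contracts are enforced", {
  X <- matrix(rnorm(200), 50, 4)
  expect_error(fit_mne(X, rep(0.5, 10)), "length")
  expect_error(fit_mne(X, rep(2, 50)), "0, 1")
  expect_error(fit_mne(matrix(rnorm(40), 10, 4), rep(0.5, 10)),
               "too few bins")
})

test_that("receptive-field decomposition satisfies the spectral theorem", {
  expect_error(decompose(mne_model(0, rep(0, 4))), "order-2")
  m_id <- mne_model(0, rep(0, 5), diag(5))
  expect_equal(decompose(m_id)$values, rep(1, 5))
  # rank-1 oracle: J = lam v v'
  set.seed(9)
  v <- rnorm(16 * 16); v <- v / sqrt(sum(v^2))
  J <- 3 * tcrossprod(v)
  dec <- decompose(mne_model(0, numeric(256), J))
  expect_equal(max(dec$values), 3, tolerance = 1e-8)
  v_hat <- dec$vectors[, which.max(dec$values)]
  expect_equal(abs(sum(v_hat * v)), 1, tolerance = 1e-8)
  # reconstruction: sum_i lam_i v_i v_i' = J
  recon <- dec$vectors %*% (dec$values * t(dec$vectors))
  expect_lt(max(abs(recon - J)), 1e-8)
  # ascending order and 95% magnitude threshold
  expect_true(all(diff(dec$values) >= -1e-12))
  expect_equal(dec$magnitude_threshold,
               stats::quantile(abs(dec$values), 0.95, names = FALSE))
  flds <- rf_fields(dec, "positive", n = 6)
  expect_length(flds, 6)
  expect_equal(dim(flds[[1]]), c(16, 16))
})

test_that("prediction order selects terms with the expected identities", {
  tr <- mk_truth(D = 8, seed = 10)
  X <- matrix(rnorm(50 * 8), 50, 8)
  # order-1 prediction of a J = 0 model equals the order-2 prediction
  m0 <- mne_model(tr$model$a, tr$model$h, matrix(0, 8, 8))
  expect_equal(predict(m0, X, order = 1), predict(m0, X, order = 2))
  # order-2 minus order-1 log odds = s'Js per bin
  p2 <- predict(tr$model, X, order = 2)
  p1 <- predict(tr$model, X, order = 1)
  lo <- function(p) log(p / (1 - p))
  expect_equal(lo(p2) - lo(p1), rowSums((X %*% tr$model$J) * X),
               tolerance = 1e-9)
})

test_that("an order-2 fit attains at least the order-1 training loss", {
  tr <- mk_truth(D = 6, seed = 12, rank = 3)
  set.seed(13)
  X <- matrix(rnorm(4000 * 6), 4000, 6)
  y <- mne_response(tr$model, X)
  f1 <- fit_mne(X, y, order = 1, max_epochs = 80)
  f2 <- fit_mne(X, y, order = 2, max_epochs = 80)
  loss <- function(m, order) {
    p <- pmin(pmax(predict(m, X, order = order), 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  expect_lte(loss(f2$model, 2), loss(f1$model, 1) + 1e-8)
})

test_that("shuffle controls preserve multisets and degrade predictions", {
  tr <- mk_truth(D = 8, seed = 14)
  # all-equal h: linear shuffle is a no-op
  m_eq <- mne_model(0, rep(0.3, 4))
  expect_equal(shuffle_control(m_eq, "linear", seed = 2)$h, m_eq$h)
  expect_error(shuffle_control(mne_model(0, rep(1, 3)), "quadratic"),
               "order-2")
  # spectrum is preserved by the eigenvalue shuffle
  sh <- shuffle_control(tr$model, "quadratic", seed = 3)
  expect_equal(sort(eigen(sh$J, symmetric = TRUE)$values),
               sort(eigen(tr$model$J, symmetric = TRUE)$values),
               tolerance = 1e-9)
  expect_setequal(round(sh$h, 12), round(tr$model$h, 12))
  # planted structure: shuffled prediction quality is lower
  set.seed(15)
  X <- matrix(rnorm(4000 * 8), 4000, 8)
  y <- mne_response(tr$model, X)
  z_true <- evaluate_prediction(predict(tr$model, X), y)$z
  worse <- vapply(1:20, function(s) {
    shf <- shuffle_control(tr$model, "quadratic", seed = s)
    evaluate_prediction(predict(shf, X), y)$z < z_true
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("prediction quality evaluation applies the Fisher transform", {
  x <- rnorm(100)
  expect_equal(evaluate_prediction(x, x)$r, 1)
  expect_true(is.finite(evaluate_prediction(x, x)$z))
  expect_equal(evaluate_prediction(x, -x)$r, -1)
  expect_equal(evaluate_prediction(x, x + 0)$z, fisher_z(1))
  expect_equal(round(atanh(0.3), 5), 0.30952)
  expect_error(evaluate_prediction(x, rep(1, 100)), "zero-variance")
  expect_error(evaluate_prediction(x, rnorm(50)), "length")
})

test_that("the main meta-family detects a planted order-by-label interaction", {
  set.seed(18)
  g <- expand.grid(model = c("linear", "quadratic"),
                   label = c("plain", "labeled"),
                   shuffle = c("true", "shuffled"),
                   band = c("delta", "high-gamma"),
                   subject = paste0("S", 1:4),
                   channel = paste0("c", 1:10))
  g$channel <- paste(g$subject, g$channel)
  base_z <- 0.4 - 0.15 * (g$shuffle == "shuffled")
  g$z <- base_z + 0.2 * (g$model == "quadratic" & g$label == "labeled") +
    rnorm(nrow(g), 0, 0.08)
  res <- fit_quality_meta(g, "main")
  expect_equal(nrow(res$ranking), 5)
  expect_equal(res$ranking$model[1], "interaction")

  # structureless records: no augmented model wins by much
  g$z <- 0.4 + rnorm(nrow(g), 0, 0.08)
  res0 <- fit_quality_meta(g, "main")
  expect_lt(min(res0$fits$add_model$aic, res0$fits$interaction$aic) -
              res0$fits$baseline$aic, 10)
  expect_gt(res0$fits$interaction$aic - res0$fits$baseline$aic, -10)

  # language family has six members and needs both language tags
  g2 <- expand.grid(model = c("linear", "quadratic"),
                    label = c("plain", "labeled"),
                    lang = c("native", "foreign"),
                    band = c("delta", "high-gamma"),
                    subject = paste0("S", 1:4),
                    channel = paste0("c", 1:10))
  g2$channel <- paste(g2$subject, g2$channel)
  g2$z <- 0.4 + 0.25 * (g2$label == "labeled" & g2$lang == "native") +
    rnorm(nrow(g2), 0, 0.08)
  res_l <- fit_quality_meta(g2, "language")
  expect_equal(nrow(res_l$ranking), 6)
  expect_true(res_l$ranking$model[1] %in%
                c("lang_x_label", "lang_x_both", "full"))
  expect_error(fit_quality_meta(g2[, setdiff(names(g2), "lang")],
                                "language"), "columns")
})
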