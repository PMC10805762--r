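# compact synthetic encoding problem shared across blocks
mk_encoding <- function(n_bins = 200, n_ch = 6, vocab = 5, seed = 31,
                        driver = c("both", "labels", "spectro"),
                        noise = 0.5) {
  driver <- match.arg(driver)
  set.seed(seed)
  s1 <- matrix(rnorm(n_bins * 128), n_bins, 128)
  p_raw <- t(stats::rmultinom(n_bins, 1, rep(1 / vocab, vocab)))
  p1 <- p_raw + matrix(stats::runif(n_bins * vocab, 0, 0.05),
                       n_bins, vocab)
  p1 <- p1 / rowSums(p1)
  colnames(p1) <- paste0("p", seq_len(vocab))
  excerpt <- rep(c("e1", "e2"), c(n_bins %/% 2, n_bins - n_bins %/% 2))
  beta_s <- rnorm(128, 0, 0.12)
  beta_p <- rnorm(vocab, 0, 2)
  mu <- switch(driver,
               both = as.numeric(s1 %*% beta_s + p1 %*% beta_p),
               labels = as.numeric(p1 %*% beta_p),
               spectro = as.numeric(s1 %*% beta_s))
  resp <- matrix(0, n_ch, n_bins,
                 dimnames = list(sprintf("c%02d", 1:n_ch), NULL))
  ch_int <- rnorm(n_ch, 0, 0.5)
  for (k in seq_len(n_ch)) {
    resp[k, ] <- mu + ch_int[k] + rnorm(n_bins, 0, noise)
  }
  list(s1 = s1, p1 = p1, excerpt = excerpt, resp = resp,
       speaker = ifelse(excerpt == "e1", "spk1", "spk2"),
       beta_s = beta_s, beta_p = beta_p)
}

test_that("the design family has seven members with the right structure", {
  enc <- mk_encoding(n_bins = 60, seed = 1)
  designs <- build_designs(enc$s1, enc$p1, enc$excerpt, seed = 2)
  expect_setequal(names(designs),
                  c("s1", "p1", "s1p1", "s2", "p2", "s3", "p3"))
  expect_length(designs, 7)
  expect_equal(ncol(designs$s1p1$X), 128 + ncol(enc$p1))
  # s2 is a within-excerpt permutation of s1: identical row multisets
  # per excerpt
  for (e in unique(enc$excerpt)) {
    rows <- enc$excerpt == e
    a <- designs$s1$X[rows, , drop = FALSE]
    b <- designs$s2$X[rows, , drop = FALSE]
    expect_equal(a[do.call(order, as.data.frame(a)), ],
                 b[do.call(order, as.data.frame(b)), ],
                 ignore_attr = TRUE)
  }
  expect_error(build_designs(enc$s1[1:10, ], enc$p1, enc$excerpt),
               "aligned")
})

test_that("mixed-model fits recover planted coefficients", {
  enc <- mk_encoding(n_bins = 300, n_ch = 20, driver = "labels",
                     noise = 0.4, seed = 7)
  fit <- fit_lme(enc$p1, enc$resp, speaker = enc$speaker)
  expect_true(fit$converged || !fit$singular)
  fe <- lme4::fixef(fit$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit$fit))))
  # label block is sum-to-one so effects are identified relative to the
  # dropped column; compare contrasts against the generator
  kept <- names(fe)[-1]
  idx <- as.integer(sub("^p", "", kept))
  dropped <- setdiff(seq_along(enc$beta_p), idx)[1]
  target <- enc$beta_p[idx] - enc$beta_p[dropped]
  within <- abs(fe[kept] - target) <= 2 * se[kept]
  expect_gte(mean(within), 0.9)
})

test_that("parameter bookkeeping: one more column adds exactly one to k", {
  enc <- mk_encoding(n_bins = 120, n_ch = 4, seed = 9)
  X1 <- enc$s1[, 1:5]
  X2 <- enc$s1[, 1:6]
  f1 <- fit_lme(X1, enc$resp, speaker = enc$speaker)
  f2 <- fit_lme(X2, enc$resp, speaker = enc$speaker)
  expect_equal(f2$k - f1$k, 1L)
  # k = fixed effects + 2 variance components + residual, matching the
  # likelihood bookkeeping lme4 itself reports
  expect_equal(f1$k, attr(stats::logLik(f1$fit), "df"))
})

test_that("AIC arithmetic matches its closed form", {
  expect_equal(aic_value(k = 2, log_lik = -10), 24)
  expect_equal(aic_value(k = 0, log_lik = 0), 0)
  # equal likelihoods, k differing by 1: AIC differs by exactly 2
  expect_equal(aic_value(k = 5, log_lik = -3) -
                 aic_value(k = 4, log_lik = -3), 2)
  expect_error(aic_value(k = 2, log_lik = NULL), "missing")
})

test_that("model ranking yields normalized Akaike weights", {
  rk <- rank_models(c(m1 = 100, m2 = 100))
  expect_equal(rk$akaike_weight, c(0.5, 0.5))
  expect_equal(rk$delta_aic[1], 0)

  rk2 <- rank_models(c(a = 10, b = 12))
  expect_equal(rk2$rel_likelihood[2], exp(-1), tolerance = 1e-12)
  expect_equal(sum(rk2$akaike_weight), 1)

  rk3 <- rank_models(c(best = 0, worse = 200))
  expect_gt(rk3$akaike_weight[1], 0.9999)
  # ranking invariant to adding a constant to all AICs
  rk4 <- rank_models(c(best = 1000, worse = 1200))
  expect_equal(rk3$akaike_weight, rk4$akaike_weight)
  expect_equal(rk3$model, rk4$model)
})

test_that("shuffled designs never beat the generating feature set", {
  enc <- mk_encoding(n_bins = 240, n_ch = 5, driver = "spectro",
                     seed = 11)
  designs <- build_designs(enc$s1, enc$p1, enc$excerpt, seed = 11)
  fits <- lapply(designs[c("s1", "s2", "s3")], fit_lme,
                 response = enc$resp, speaker = enc$speaker)
  expect_lt(fits$s1$aic, fits$s2$aic)
  expect_lt(fits$s1$aic, fits$s3$aic)
})

test_that("predictions correlate with the response per channel", {
  enc <- mk_encoding(n_bins = 180, n_ch = 5, driver = "labels", seed = 13)
  fit <- fit_lme(enc$p1, enc$resp, speaker = enc$speaker)
  pr <- predict_and_correlate(fit, enc$resp)
  expect_equal(nrow(pr$per_channel), 5)
  expect_true(all(pr$per_channel$r > 0.5))
  expect_true(all(is.finite(pr$per_channel$z)))
  expect_true(ncol(pr$windowed) > 1)
  # closed forms of the Fisher transform
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(round(atanh(0.5), 4), 0.5493)
  expect_true(is.finite(fisher_z(1)))
  # degenerate: constant response errors
  resp0 <- enc$resp
  resp0[2, ] <- 1
  fit0 <- fit_lme(enc$p1, resp0, speaker = enc$speaker)
  expect_error(predict_and_correlate(fit0, resp0), "zero-variance")
})

test_that("the language meta-family prefers the interaction only when planted", {
  set.seed(17)
  g <- expand.grid(model = c("s1", "p1", "s1p1"),
                   band = c("delta", "theta"),
                   lang = c("native", "foreign"),
                   subject = paste0("S", 1:4),
                   channel = paste0("c", 1:12))
  g$channel <- paste(g$subject, g$channel)
  g$z <- 0.3 + 0.1 * (g$model != "p1") +
    0.25 * (g$model %in% c("p1", "s1p1") & g$lang == "native") +
    rnorm(nrow(g), 0, 0.08)
  res <- language_contrast(g)
  expect_equal(nrow(res$ranking), 3)
  expect_equal(res$ranking$model[1], "lang_x_model")

  # permuted language tags: lang terms no longer preferred
  gp <- g
  gp$lang <- sample(gp$lang)
  gp$z <- 0.3 + 0.1 * (gp$model != "p1") + rnorm(nrow(gp), 0, 0.08)
  resp <- language_contrast(gp)
  base_aic <- resp$fits$base$aic
  expect_lt(abs(min(resp$fits$lang$aic, resp$fits$lang_x_model$aic) -
                  base_aic), 10)
  expect_error(language_contrast(g[g$lang == "native", ]), "both language")
})
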