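test_that("spectrogram pipeline yields 16 bins at 15.625 Hz", {
  spec <- fx_spectrogram()
  expect_equal(nrow(spec$values), 16)
  expect_equal(spec$bin_rate, 15.625)
  expect_equal(spec$bin_duration, 0.064)
  expect_error(compute_spectrogram(rnorm(64), 16000), "shorter")
  # shape law: T = floor(d / 64 ms) up to the trailing-odd-bin drops
  d <- length(fx_stimulus()$waveform) / 16000
  expect_lte(abs(ncol(spec$values) - floor(d / 0.064)), 1)
})

test_that("spectral energy lands in the frequency row containing the tone", {
  sr <- 16000
  t <- seq(0, 2, by = 1 / sr)
  x <- sin(2 * pi * 1000 * t)
  spec <- compute_spectrogram(x, sr)
  got_row <- which.max(rowMeans(spec$values))
  # oracle: direct DFT of one Hann-windowed 128-sample segment with the
  # identical 64 -> 32 -> 16 pairwise frequency averaging
  seg <- x[1:128]
  win <- 0.5 * (1 - cos(2 * pi * (0:127) / 127))
  P <- (Mod(stats::fft(seg * win))^2)[2:65]
  lp <- log(P + 1e-10)
  for (i in 1:2) {
    k <- length(lp) %/% 2
    lp <- (lp[seq(1, 2 * k, 2)] + lp[seq(2, 2 * k, 2)]) / 2
  }
  expect_equal(got_row, which.max(lp))
  # 1 kHz occupies 500 Hz-wide averaged row 2 (rows span 4 DFT bins of
  # 125 Hz each)
  expect_equal(got_row, 2)
})

test_that("context chunking maps each bin from the 16th onward to a 1024 ms chunk", {
  mk_spec <- function(T_bins) {
    structure(list(values = matrix(seq_len(16 * T_bins), 16),
                   bin_starts = (seq_len(T_bins) - 1) * 0.064,
                   bin_duration = 0.064, bin_rate = 15.625),
              class = "binned_spectrogram")
  }
  expect_equal(dim(chunk_context(mk_spec(16))$chunks)[1], 1)
  expect_warning(ch15 <- chunk_context(mk_spec(15)), "fewer than 16")
  expect_equal(dim(ch15$chunks)[1], 0)
  # oracle: enumerate valid chunk end indices 16..100
  expect_equal(dim(chunk_context(mk_spec(100))$chunks)[1],
               length(16:100))
  # chunk i spans bins i..i+15, oldest to newest
  ch <- chunk_context(mk_spec(20))
  expect_equal(ch$chunks[3, , ], mk_spec(20)$values[, 3:18])
  expect_equal(ch$target_bin, 16:20)
})

test_that("response alignment averages 32-33 samples per 510 Hz bin", {
  spec <- list(bin_starts = (0:49) * 0.064, bin_duration = 0.064)
  class(spec) <- "binned_spectrogram"
  n <- ceiling(50 * 0.064 * 510)
  const <- align_response(rep(3.3, n), 510, spec)
  expect_equal(as.numeric(const), rep(3.3, 50))
  expect_true(all(attr(const, "n_samples") %in% c(32L, 33L)))
  # ramp oracle: per-bin means equal arithmetic means of member samples
  ramp <- seq_len(n) - 1
  got <- align_response(ramp, 510, spec)
  t_samp <- (seq_len(n) - 1) / 510
  for (b in c(1, 17, 50)) {
    members <- ramp[t_samp >= spec$bin_starts[b] &
                      t_samp < spec$bin_starts[b] + 0.064]
    expect_equal(got[b], mean(members))
  }
  expect_error(align_response(rep(1, 100), 510, spec), "cover")
})

test_that("recent-context truncation keeps the newest 8 columns of each chunk", {
  # chunk with time columns tagged 1..16: tags 9..16 survive
  tagged <- structure(list(chunks = array(rep(1:16, each = 16),
                                          c(1, 16, 16)),
                           target_bin = 16L,
                           bin_starts = (0:15) * 0.064,
                           bin_duration = 0.064),
                      class = "context_chunks")
  out <- truncate_recent(tagged)
  expect_equal(ncol(out), 128)
  expect_equal(unique(as.vector(unflatten_chunk(out[1, ]))),
               as.numeric(9:16))
  # flatten/unflatten round trip restores the 16 x 8 block
  ch <- fx_chunks()
  flat <- truncate_recent(ch)
  block <- ch$chunks[5, , 9:16]
  expect_equal(unflatten_chunk(flat[5, ]), unname(block))
  expect_equal(flatten_chunks(ch)[3, ], as.vector(ch$chunks[3, , ]))
})

test_that("label features are per-bin time proportions summing to one", {
  iv <- data.frame(start_s = c(0, 0.048, 0.112),
                   stop_s = c(0.048, 0.112, 0.128),
                   phone = c("aa", "bb", "aa"))
  lf <- label_features(iv, bin_starts = c(0, 0.064), bin_duration = 0.064,
                       vocabulary = c("aa", "bb"))
  # bin 1 split 75%/25% between aa and bb
  expect_equal(lf[1, ], c(aa = 0.75, bb = 0.25))
  expect_equal(rowSums(lf), c(1, 1))
  # bin fully inside one phone: indicator vector
  lf2 <- label_features(data.frame(start_s = 0, stop_s = 1, phone = "aa"),
                        bin_starts = 0.2, bin_duration = 0.064,
                        vocabulary = c("aa", "bb"))
  expect_equal(lf2[1, ], c(aa = 1, bb = 0))
  # uncovered time requires a silence label
  gap <- data.frame(start_s = 0, stop_s = 0.01, phone = "aa")
  expect_error(label_features(gap, bin_starts = 0, bin_duration = 0.064,
                              vocabulary = c("aa", "bb")), "silence")
  lf3 <- label_features(gap, bin_starts = 0, bin_duration = 0.064,
                        vocabulary = c("aa", "sil"))
  expect_equal(sum(lf3[1, ]), 1)
  # full stimulus: every vector sums to 1
  stim <- fx_stimulus()
  full <- label_features(stim$intervals, fx_spectrogram())
  expect_true(all(abs(rowSums(full) - 1) < 1e-9))
  expect_true(all(full >= 0))
})

test_that("code book assigns distinct 8-bit codes in lexicographic order", {
  cb <- phone_code_book(c("b", "a", "c"))
  expect_equal(rownames(cb), c("a", "b", "c"))
  expect_equal(cb["a", ], c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(cb["c", ], c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L))
  expect_error(phone_code_book(sprintf("L%03d", 1:257)), "exhausted")
})

test_that("label embedding replaces the top row with the m +/- sd bit code", {
  # one chunk fully inside a single phone -> code concatenated with itself
  vals <- matrix(rnorm(256), 16)
  spec <- structure(list(values = vals, bin_starts = (0:15) * 0.064,
                         bin_duration = 0.064, bin_rate = 15.625),
                    class = "binned_spectrogram")
  ch <- chunk_context(spec)
  iv <- data.frame(start_s = 0, stop_s = 1.1, phone = "zz")
  cb <- phone_code_book(c("aa", "bb", "zz"))
  emb <- label_embed_chunks(ch, iv, cb)
  expect_equal(emb$codes[1, ], rep(cb["zz", ], 2))  # code twice: 00000010
  expect_equal(emb$labels[1, ], c("zz", "zz"))
  # replacement confined to the highest-frequency row, with values at
  # the chunk's pre-replacement mean +/- SD
  chunk0 <- ch$chunks[1, , ]
  back <- unflatten_chunk(emb$X[1, ])
  expect_equal(back[1:15, ], chunk0[1:15, ])
  m <- mean(chunk0); sdv <- stats::sd(as.vector(chunk0))
  expect_setequal(round(unique(back[16, ]), 10),
                  round(c(m - sdv, m + sdv), 10))
  expect_lte(sum(back != chunk0), 16)

  # sd = 0 chunk: replaced row constant at the mean
  flatspec <- structure(list(values = matrix(2, 16, 16),
                             bin_starts = (0:15) * 0.064,
                             bin_duration = 0.064, bin_rate = 15.625),
                        class = "binned_spectrogram")
  embf <- label_embed_chunks(chunk_context(flatspec), iv, cb)
  expect_equal(unique(unflatten_chunk(embf$X[1, ])[16, ]), 2)

  # explicit bit-mapping: m = 0, sd = 1, code 01010110 twice
  half <- c(0, 1, 0, 1, 0, 1, 1, 0)
  expect_equal(2 * c(half, half) - 1,
               c(-1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1, 1, -1, 1, 1, -1))
})

test_that("plurality and runner-up labels come from window occupancy", {
  vals <- matrix(rnorm(16 * 18), 16)
  spec <- structure(list(values = vals, bin_starts = (0:17) * 0.064,
                         bin_duration = 0.064, bin_rate = 15.625),
                    class = "binned_spectrogram")
  ch <- chunk_context(spec)
  # window 1 covers 0 .. 1.024 s: aa occupies 0.6 s, bb 0.3, cc 0.124
  iv <- data.frame(start_s = c(0, 0.6, 0.9),
                   stop_s = c(0.6, 0.9, 1.3),
                   phone = c("aa", "bb", "cc"))
  cb <- phone_code_book(c("aa", "bb", "cc"))
  emb <- label_embed_chunks(ch, iv, cb)
  expect_equal(emb$labels[1, ], c("aa", "bb"))
  expect_equal(emb$codes[1, ], c(cb["aa", ], cb["bb", ]))
})

test_that("shuffling permutes rows within the stated unit, preserving marginals", {
  X <- matrix(seq_len(40), 10, 4)
  expect_equal(unname(shuffle_features(X[1, , drop = FALSE], "session",
                                       seed = 1)),
               X[1, , drop = FALSE], ignore_attr = TRUE)
  exc <- rep(c("e1", "e2"), each = 5)
  sx <- shuffle_features(X, "within_excerpt", exc, seed = 3)
  perm <- attr(sx, "permutation")
  expect_true(all(perm[1:5] %in% 1:5) && all(perm[6:10] %in% 6:10))
  for (j in 1:4) expect_setequal(sx[, j], X[, j])
  expect_error(shuffle_features(X, "within_excerpt"), "excerpt_id")
  # session shuffles cross excerpt boundaries with positive probability
  crossed <- vapply(1:20, function(s) {
    p <- attr(shuffle_features(X, "session", seed = s), "permutation")
    any(p[1:5] > 5)
  }, logical(1))
  expect_true(any(crossed))
  # determinism
  expect_identical(shuffle_features(X, "session", seed = 5),
                   shuffle_features(X, "session", seed = 5))
})
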