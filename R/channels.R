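#' Declare a ground-truth synthetic channel
#'
#' Bundles an MNE generator with its selectivity label so downstream
#' classifiers and encoders can be scored against known truth.
#'
#' @param id channel id string.
#' @param selectivity one of "surface", "underlying", "acoustic",
#'   "null".
#' @param generator an `mne_model` over a declared feature set.
#' @param noise_sd additive Gaussian response noise SD (>= 0).
#' @param band_profile optional named per-band gain vector.
#' @return object of class `ground_truth_channel`.
#' @export
ground_truth_channel <- function(id, selectivity, generator, noise_sd = 0,
                                 band_profile = NULL) {
  stopifnot(noise_sd >= 0)
  selectivity <- match.arg(selectivity,
                           c("surface", "underlying", "acoustic", "null"))
  structure(list(id = id, selectivity = selectivity, generator = generator,
                 noise_sd = noise_sd, band_profile = band_profile),
            class = "ground_truth_channel")
}

#' Simulate a channel's response to a feature series
#'
#' The response at each time bin is logistic(z(s)) under the channel's
#' MNE generator plus Gaussian noise, clipped to [0, 1]. With zero noise
#' the exact logistic surface is reproduced.
#'
#' @param features N x D feature matrix (bins x features).
#' @param truth a `ground_truth_channel`.
#' @param seed integer seed for the noise draw.
#' @return numeric response series of length N in [0, 1].
#' @export
simulate_channel <- function(features, truth, seed = 1L) {
  if (is.null(dim(features))) features <- matrix(features, ncol = 1)
  if (ncol(features) != length(truth$generator$h)) {
    stop("feature dimension does not match the channel's generator")
  }
  resp <- mne_response(truth$generator, features)
  if (truth$noise_sd > 0) {
    set.seed(derive_seed(seed, paste0("chan_", truth$id)))
    resp <- resp + stats::rnorm(length(resp), 0, truth$noise_sd)
  }
  pmin(pmax(resp, 0), 1)
}

# per-sample one-hot phone indicator track at an arbitrary rate
phone_indicator <- function(intervals, rate, n_samples, silence = "sil") {
  t_mid <- (seq_len(n_samples) - 0.5) / rate
  lab <- rep(silence, n_samples)
  for (i in seq_len(nrow(intervals))) {
    sel <- t_mid >= intervals$start_s[i] & t_mid < intervals$stop_s[i]
    lab[sel] <- intervals$phone[i]
  }
  lab
}

#' Plant an ensemble of ground-truth channels over a stimulus
#'
#' Simulates a multichannel recording in which each channel's
#' selectivity is known. Surface-selective channels respond whenever the
#' current phone's surface acoustic class is the neutralized tap;
#' underlying-selective channels respond to the underlying /d/ category
#' (so the two tap phones are driven apart while tap /t/ patterns with
#' surface [t]); acoustic channels respond to any non-silence;
#' null channels carry noise only. Responses are generated at
#' `rate` Hz from per-sample label indicator features through each
#' channel's logistic generator.
#'
#' @param inventory a `phone_inventory`.
#' @param n_surface,n_underlying,n_null,n_acoustic channel counts per
#'   selectivity class (>= 0).
#' @param stimulus optional `labeled_stimulus`; one is synthesized from
#'   the inventory (240 tokens) if missing.
#' @param seed integer seed.
#' @param rate response sample rate in Hz (default 510, matching the
#'   preprocessed LFP rate).
#' @param noise_sd response noise SD.
#' @param gain logistic gain of the selective response.
#' @param baseline logistic offset a.
#' @return object of class `planted_ensemble`: `recording` (channels x
#'   samples), `sample_rate`, `channels` (list of
#'   `ground_truth_channel`), `truth` (data frame id x selectivity),
#'   `stimulus`.
#' @export
plant_ensemble <- function(inventory, n_surface = 0L, n_underlying = 0L,
                           n_null = 0L, n_acoustic = 0L, stimulus = NULL,
                           seed = 1L, rate = 510, noise_sd = 0.15,
                           gain = 2, baseline = -1) {
  stopifnot(n_surface >= 0, n_underlying >= 0, n_null >= 0, n_acoustic >= 0)
  if (is.null(stimulus)) {
    stimulus <- synthesize_excerpt(inventory, n_tokens = 240,
                                   seed = derive_seed(seed, "ens_stim"))
  }
  n_samples <- ceiling(length(stimulus$waveform) /
                         stimulus$sample_rate * rate)
  lab <- phone_indicator(stimulus$intervals, rate, n_samples,
                         inventory$silence_phone)
  drive <- list(
    surface = as.numeric(inventory$surface_class[lab] == "tap"),
    underlying = as.numeric(inventory$underlying_class[lab] == "d"),
    acoustic = as.numeric(lab != inventory$silence_phone),
    null = rep(0, n_samples))

  spec <- rep(c("surface", "underlying", "null", "acoustic"),
              c(n_surface, n_underlying, n_null, n_acoustic))
  channels <- vector("list", length(spec))
  rec <- matrix(0, nrow = length(spec), ncol = n_samples)
  for (k in seq_along(spec)) {
    id <- sprintf("ch%03d_%s", k, spec[k])
    gen <- mne_model(baseline, gain,
                     feature_set = paste0("label:", spec[k]))
    truth <- ground_truth_channel(id, spec[k], gen, noise_sd = noise_sd)
    channels[[k]] <- truth
    rec[k, ] <- simulate_channel(matrix(drive[[spec[k]]], ncol = 1), truth,
                                 seed = derive_seed(seed, "ens", k))
  }
  rownames(rec) <- vapply(channels, `[[`, "", "id")
  structure(list(recording = rec, sample_rate = rate, channels = channels,
                 truth = data.frame(
                   id = rownames(rec),
                   selectivity = spec,
                   stringsAsFactors = FALSE),
                 stimulus = stimulus),
            class = "planted_ensemble")
}

#' @export
print.planted_ensemble <- function(x, ...) {
  cat(sprintf("Planted ensemble: %d channels x %d samples at %g Hz\n",
              nrow(x$recording), ncol(x$recording), x$sample_rate))
  print(table(x$truth$selectivity))
  invisible(x)
}

#' Upsample a planted ensemble to a pseudo-LFP recording
#'
#' Produces a voltage-like multichannel recording for the preprocessing
#' front end. Each channel's response series is linearly interpolated
#' onto the target rate and used as the amplitude envelope of broadband
#' carrier noise (plus a floor of unmodulated noise), so the planted
#' response reappears as band power — the quantity the responsiveness
#' test and the evoked-response analyses measure — rather than as a DC
#' offset the 0.1 Hz high-pass would remove.
#'
#' @param ensemble a `planted_ensemble`.
#' @param rate target sample rate in Hz (default 1020, so the
#'   preprocessing chain performs a genuine downsample to 510 Hz).
#' @param noise_sd SD of the unmodulated noise floor.
#' @param seed integer seed.
#' @return a `recording` object (see [recording()]).
#' @export
ensemble_to_lfp <- function(ensemble, rate = 1020, noise_sd = 0.05,
                            seed = 1L) {
  set.seed(derive_seed(seed, "lfp_noise"))
  n_in <- ncol(ensemble$recording)
  t_in <- (seq_len(n_in) - 1) / ensemble$sample_rate
  n_out <- ceiling(max(t_in) * rate)
  t_out <- (seq_len(n_out) - 1) / rate
  out <- t(apply(ensemble$recording, 1, function(x) {
    env <- stats::approx(t_in, x, xout = t_out, rule = 2)$y
    env * stats::rnorm(n_out) + stats::rnorm(n_out, 0, noise_sd)
  }))
  recording(out, rate, channel_ids = rownames(ensemble$recording))
}
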