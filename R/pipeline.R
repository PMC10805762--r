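#' Build and validate a pipeline run configuration
#'
#' A single root seed drives every stochastic stage through derived,
#' logged sub-seeds. The "desk" preset bounds problem sizes for
#' single-machine runs (feature dimension <= 64, permutation draws
#' <= 200); "full" lifts those bounds.
#'
#' @param seed integer root seed.
#' @param bands character vector of band names (see [band_table()]).
#' @param preset "desk" or "full".
#' @param n_phones inventory size.
#' @param n_tokens tokens per excerpt.
#' @param n_channels channels per planted selectivity class.
#' @param n_null permutation-null draws.
#' @param out_dir output directory for stage artifacts and manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, bands = "high-gamma",
                       preset = c("desk", "full"), n_phones = 8L,
                       n_tokens = 160L, n_channels = 4L, n_null = 100L,
                       out_dir = tempfile("phonorf_run_")) {
  preset <- match.arg(preset)
  unknown <- setdiff(bands, band_table()$band)
  if (length(unknown)) {
    stop("unknown band(s): ", paste(unknown, collapse = ", "))
  }
  if (preset == "desk") {
    n_null <- min(n_null, 200L)
  }
  structure(list(seed = as.integer(seed), bands = bands, preset = preset,
                 n_phones = as.integer(n_phones),
                 n_tokens = as.integer(n_tokens),
                 n_channels = as.integer(n_channels),
                 n_null = as.integer(n_null), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes synth -> preprocess -> features -> classify -> encode-lme
#' -> fit-mne on a planted synthetic ensemble and writes per-stage
#' outputs (TSV) plus a JSON manifest of inputs, derived seeds, and
#' output digests to the configured directory. Identical
#' configurations produce identical digests.
#'
#' @param config a `run_config`.
#' @return the manifest, invisibly (a list; also written as
#'   manifest.json).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list(),
                   package_version =
                     as.character(utils::packageVersion("phonorf")))
  stage <- "synth"
  result <- tryCatch({
    ## --- synth ---------------------------------------------------------
    inv <- make_inventory(config$n_phones, seed = derive_seed(config$seed,
                                                              "inventory"))
    stim <- synthesize_excerpt(inv, n_tokens = config$n_tokens,
                               seed = derive_seed(config$seed, "stim"))
    ens <- plant_ensemble(inv, n_surface = config$n_channels,
                          n_underlying = config$n_channels,
                          n_null = config$n_channels,
                          n_acoustic = config$n_channels,
                          stimulus = stim,
                          seed = derive_seed(config$seed, "ensemble"))
    write_intervals(stim$intervals, file.path(config$out_dir,
                                              "intervals.tsv"))
    write_wav(stim$waveform, stim$sample_rate,
              file.path(config$out_dir, "stimulus.wav"))
    manifest$stages$synth <- list(
      seed = derive_seed(config$seed, "stim"),
      n_tokens = config$n_tokens,
      n_channels = nrow(ens$recording),
      duration_s = length(stim$waveform) / stim$sample_rate)

    ## --- preprocess ----------------------------------------------------
    stage <- "preprocess"
    lfp <- ensemble_to_lfp(ens, seed = derive_seed(config$seed, "lfp"))
    prep <- preprocess_lfp(lfp)
    band <- config$bands[1]
    bp <- band_power(prep, band)
    tok <- stim$intervals[stim$intervals$phone != inv$silence_phone, ]
    sil <- stim$intervals[stim$intervals$phone == inv$silence_phone, ]
    n_ev <- min(20L, nrow(tok), nrow(sil))
    usable <- function(iv) {
      iv$start_s > 0.12 &
        iv$start_s < ncol(bp$power) / bp$sample_rate - 0.52
    }
    tok <- tok[usable(tok), ]; sil <- sil[usable(sil), ]
    n_ev <- min(n_ev, nrow(tok), nrow(sil))
    resp <- speech_responsive(bp, sil$start_s[seq_len(n_ev)],
                              tok$start_s[seq_len(n_ev)])
    manifest$stages$preprocess <- list(
      band = band, rate = prep$sample_rate,
      n_responsive = sum(resp))

    ## --- features ------------------------------------------------------
    stage <- "features"
    spec <- compute_spectrogram(stim$waveform, stim$sample_rate)
    chunks <- chunk_context(spec)
    s1 <- truncate_recent(chunks)
    vocab <- sort(unique(stim$intervals$phone))
    p_all <- label_features(stim$intervals, spec, vocabulary = vocab)
    p1 <- p_all[chunks$target_bin, , drop = FALSE]
    excerpt <- rep(stim$intervals$excerpt_id[1], nrow(s1))
    manifest$stages$features <- list(
      n_bins = ncol(spec$values), n_chunks = nrow(s1),
      bin_rate = spec$bin_rate, vocab_size = length(vocab))

    ## --- classify ------------------------------------------------------
    stage <- "classify"
    tw <- token_window_values(ens$recording, ens$sample_rate,
                              stim$intervals)
    cls <- classify_sites(tw, tap_comparison(inv))
    null <- permutation_null(tw, n_draws = config$n_null,
                             seed = derive_seed(config$seed, "null"),
                             min_tokens = max(3L, min(
                               8L, config$n_tokens %/% (2 * config$n_phones))))
    observed <- c(sum(cls$surface), sum(cls$underlying))
    utils::write.table(cls, file.path(config$out_dir, "sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(null$draws, file.path(config$out_dir,
                                             "null_draws.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$classify <- list(
      seed = derive_seed(config$seed, "null"),
      observed_surface = observed[1], observed_underlying = observed[2],
      joint_tail_p = joint_tail_probability(null, observed))

    ## --- encode-lme ----------------------------------------------------
    stage <- "encode_lme"
    designs <- build_designs(s1, p1, excerpt,
                             seed = derive_seed(config$seed, "designs"))
    n_enc <- min(4L, nrow(ens$recording))
    resp_bins <- t(vapply(seq_len(n_enc), function(ch) {
      align_response(ens$recording[ch, ], ens$sample_rate, spec)
    }, numeric(ncol(spec$values))))[, chunks$target_bin, drop = FALSE]
    rownames(resp_bins) <- rownames(ens$recording)[seq_len(n_enc)]
    half <- ncol(resp_bins) %/% 2
    speaker <- rep(c("spk1", "spk2"), c(half, ncol(resp_bins) - half))
    fits <- lapply(designs, fit_lme, response = resp_bins,
                   speaker = speaker)
    ranking <- rank_models(fits)
    utils::write.table(ranking, file.path(config$out_dir,
                                          "lme_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$encode_lme <- list(
      seed = derive_seed(config$seed, "designs"),
      best_model = ranking$model[1],
      aic = stats::setNames(as.list(ranking$aic), ranking$model))

    ## --- fit-mne -------------------------------------------------------
    stage <- "fit_mne"
    # desk preset: D = 64, shrunk if the excerpt is short (the fit
    # needs N >= 4 (D + 1) bins)
    D_mne <- min(64L, nrow(s1) %/% 5L - 1L)
    Xm <- s1[, seq_len(D_mne), drop = FALSE]
    ym <- normalize_response(resp_bins[1, ])
    jk <- fit_mne(Xm, ym, order = 2L, max_epochs = 40L)
    pred2 <- predict(jk$model, Xm)
    pred1 <- predict(jk$model, Xm, order = 1L)
    ev2 <- evaluate_prediction(pred2, ym)
    ev1 <- evaluate_prediction(pred1, ym)
    manifest$stages$fit_mne <- list(
      D = ncol(Xm), stop_epochs = jk$stop_epoch,
      z_order2 = ev2$z, z_order1 = ev1$z)

    manifest$digests <- digest_dir(config$out_dir)
    manifest
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(result, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

# md5-style content digests for the manifest (base tools only)
digest_dir <- function(dir) {
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  out <- lapply(files, function(f) {
    unname(tools::md5sum(file.path(dir, f)))
  })
  stats::setNames(out, files)
}
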