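# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; nothing is read from disk.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

fx_inventory <- function() {
  fixture("inventory", function() make_inventory(8, seed = 11))
}

fx_stimulus <- function() {
  fixture("stimulus", function() {
    synthesize_excerpt(fx_inventory(), n_tokens = 80, seed = 12)
  })
}

fx_spectrogram <- function() {
  fixture("spectrogram", function() {
    stim <- fx_stimulus()
    compute_spectrogram(stim$waveform, stim$sample_rate)
  })
}

fx_chunks <- function() {
  fixture("chunks", function() chunk_context(fx_spectrogram()))
}

# small planted ensemble shared by classification tests
fx_ensemble <- function() {
  fixture("ensemble", function() {
    plant_ensemble(fx_inventory(), n_surface = 4, n_underlying = 4,
                   n_null = 4, seed = 13)
  })
}

fx_token_windows <- function() {
  fixture("token_windows", function() {
    ens <- fx_ensemble()
    token_window_values(ens$recording, ens$sample_rate,
                        ens$stimulus$intervals)
  })
}

# independent single-channel ANOVA + Tukey oracle via aov()/TukeyHSD()
oracle_anova_tukey <- function(vals, groups) {
  df <- data.frame(y = vals, g = factor(groups))
  fit <- stats::aov(y ~ g, data = df)
  tk <- stats::TukeyHSD(fit)$g
  list(p = summary(fit)[[1]][["Pr(>F)"]][1],
       tukey = stats::setNames(tk[, "p adj"], rownames(tk)))
}
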