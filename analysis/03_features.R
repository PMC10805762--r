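#!/usr/bin/env Rscript
# Stage 3 — stimulus feature engineering.
#
# Computes the 16-bin log spectrogram (64 ms bins at 15.625 Hz), the
# overlapping 1024 ms context chunks, the 128-feature recent-context
# matrix for encoding models, per-bin phone-label proportion features,
# and the label-embedded 256-feature chunks for receptive-field
# models, plus the two shuffle controls.

suppressMessages(library(phonorf))
SEED <- 42
out <- "results/03_features"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

inv <- make_inventory(8, seed = derive_seed(SEED, "inventory"))
stim <- synthesize_excerpt(inv, n_tokens = 260,
                           seed = derive_seed(SEED, "native"),
                           excerpt_id = "native01")

spec <- compute_spectrogram(stim$waveform, stim$sample_rate)
print(spec)
chunks <- chunk_context(spec)
s1 <- truncate_recent(chunks)
cat(sprintf("context chunks: %d x 16 x 16 (1024 ms); s1 block: %d x %d\n",
            dim(chunks$chunks)[1], nrow(s1), ncol(s1)))

p1_full <- label_features(stim$intervals, spec)
p1 <- p1_full[chunks$target_bin, , drop = FALSE]
cat(sprintf("label track: %d bins x %d labels, all rows sum to 1: %s\n",
            nrow(p1_full), ncol(p1_full),
            all(abs(rowSums(p1_full) - 1) < 1e-9)))

cb <- phone_code_book(colnames(p1_full))
emb <- label_embed_chunks(chunks, stim$intervals, cb)
print(emb)

sh_exc <- shuffle_features(s1, "within_excerpt",
                           rep("native01", nrow(s1)),
                           seed = derive_seed(SEED, "s2"))
sh_ses <- shuffle_features(s1, "session", seed = derive_seed(SEED, "s3"))
cat(sprintf("shuffles preserve column marginals: %s\n",
            all(sort(sh_ses[, 1]) == sort(s1[, 1]))))

keep_bins <- seq_len(min(250L, ncol(spec$values)))
write.table(round(spec$values[, keep_bins], 2),
            file.path(out, "spectrogram.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE,
            col.names = FALSE)
write.table(round(p1, 4), file.path(out, "label_features.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(label = rownames(cb), code = apply(cb, 1, paste,
                                                          collapse = "")),
            file.path(out, "code_book.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote", out, "\n")
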