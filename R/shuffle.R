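#' Shuffle feature rows within excerpts or across a session
#'
#' Permutes the time-bin order of a feature matrix, either
#' independently within each excerpt or across the entire recording
#' session. The multiset of rows (and hence each column's marginal
#' distribution) is preserved exactly; only temporal alignment with the
#' response is destroyed.
#'
#' @param features N x D feature matrix.
#' @param unit "within_excerpt" or "session".
#' @param excerpt_id length-N excerpt identifier, required for
#'   within-excerpt shuffling.
#' @param seed integer seed; the permutation is deterministic given it.
#' @return permuted feature matrix; the permutation applied is stored
#'   in the `permutation` attribute.
#' @export
shuffle_features <- function(features, unit = c("within_excerpt", "session"),
                             excerpt_id = NULL, seed = 1L) {
  unit <- match.arg(unit)
  features <- as.matrix(features)
  n <- nrow(features)
  set.seed(derive_seed(seed, paste0("shuffle_", unit)))
  if (unit == "session") {
    perm <- sample.int(n)
  } else {
    if (is.null(excerpt_id)) {
      stop("excerpt_id is required for within-excerpt shuffling")
    }
    if (length(excerpt_id) != n) stop("excerpt_id length mismatch")
    perm <- seq_len(n)
    for (g in split(seq_len(n), excerpt_id)) perm[g] <- g[sample.int(length(g))]
  }
  out <- features[perm, , drop = FALSE]
  attr(out, "permutation") <- perm
  out
}
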