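#' Construct a synthetic phone inventory with a neutralized pair
#'
#' Builds a phone inventory that embeds the coronal-tap configuration:
#' two phones (`dxT`, `dxD`) that share one surface acoustic class
#' ("tap") but belong to different underlying phonemic categories (/t/
#' and /d/), plus a phone (`T`) that shares its underlying category with
#' `dxT` while having a distinct surface form. Remaining phones each get
#' their own surface and underlying class. A dedicated silence phone
#' (`sil`) is always appended so inter-token gaps carry an explicit
#' label.
#'
#' Each surface class is assigned a spectral prototype: 16 nonnegative
#' weights over the frequency bins of the analysis spectrogram (a smooth
#' bump at a class-specific center frequency over a small baseline), so
#' prototypes of distinct classes are pairwise distinct.
#'
#' @param n_phones number of (non-silence) phones, at least 4.
#' @param seed integer seed; the inventory is deterministic given it.
#' @param duration_range default per-phone token duration range in ms.
#' @return an object of class `phone_inventory` with fields `phones`,
#'   `surface_class`, `underlying_class`, `prototype` (16 x n classes
#'   matrix), `duration_range` (n x 2 matrix, ms) and `silence_phone`.
#' @export
make_inventory <- function(n_phones, seed = 1L, duration_range = c(50, 250)) {
  if (n_phones < 4) {
    stop("n_phones must be >= 4 to host the neutralization structure")
  }
  set.seed(derive_seed(seed, "inventory"))

  phones <- c("dxT", "dxD", "T", "D")
  surface <- c(dxT = "tap", dxD = "tap", T = "stopT", D = "stopD")
  underlying <- c(dxT = "t", dxD = "d", T = "t", D = "d")
  if (n_phones > 4) {
    extra <- sprintf("PH%02d", seq_len(n_phones - 4))
    phones <- c(phones, extra)
    surface <- c(surface, stats::setNames(paste0("sc_", extra), extra))
    underlying <- c(underlying, stats::setNames(paste0("uc_", extra), extra))
  }

  classes <- unique(surface)
  # one smooth spectral bump per surface class; centers drawn without
  # replacement so prototypes are pairwise distinct 16-vectors
  centers <- sample(seq(2, 15), length(classes),
                    replace = length(classes) > 14)
  widths <- stats::runif(length(classes), 1.2, 2.5)
  proto <- vapply(seq_along(classes), function(k) {
    env <- 0.05 + exp(-((1:16 - centers[k])^2) / (2 * widths[k]^2))
    env + stats::runif(16, 0, 0.01)  # jitter guarantees distinctness
  }, numeric(16))
  colnames(proto) <- classes

  # silence: flat, very low-energy prototype
  phones <- c(phones, "sil")
  surface <- c(surface, sil = "sil")
  underlying <- c(underlying, sil = "sil")
  proto <- cbind(proto, sil = rep(1e-4, 16))

  dur <- matrix(rep(duration_range, each = length(phones)),
                ncol = 2, dimnames = list(phones, c("min_ms", "max_ms")))
  dur["sil", ] <- c(20, 80)

  structure(list(phones = phones,
                 surface_class = surface,
                 underlying_class = underlying,
                 prototype = proto,
                 duration_range = dur,
                 silence_phone = "sil"),
            class = "phone_inventory")
}

#' @export
print.phone_inventory <- function(x, ...) {
  cat("Phone inventory:", length(x$phones) - 1L, "phones (+ silence)\n")
  cat("  surface classes:", paste(unique(x$surface_class), collapse = ", "),
      "\n")
  tap <- names(x$surface_class)[x$surface_class == "tap"]
  cat("  neutralized pair:", paste(tap, collapse = " / "),
      "(underlying", paste(x$underlying_class[tap], collapse = " vs "), ")\n")
  invisible(x)
}

# non-silence phones of an inventory
speech_phones <- function(inventory) {
  setdiff(inventory$phones, inventory$silence_phone)
}
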