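#' Standard 19-channel 10/20 montage
#'
#' Electrode labels of the international 10/20 system in the fixed order used
#' throughout the package, together with their ordinal channel aliases
#' (`C1`...`C19`). Feature names are built as `<metric>_<ordinal>`, e.g.
#' `LZC_C15` is the Lempel-Ziv complexity at electrode Pz.
#'
#' @return `montage_1020()` returns the 19 electrode labels in order.
#' @export
#' @examples
#' montage_1020()
#' channel_ordinals()["Pz"]
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' @rdname montage_1020
#' @return `channel_ordinals()` returns a named character vector mapping
#'   electrode label to ordinal alias (`Fp1` -> `C1`, ..., `O2` -> `C19`).
#' @export
channel_ordinals <- function() {
  labs <- montage_1020()
  stats::setNames(paste0("C", seq_along(labs)), labs)
}

# Normalize user-supplied channel labels: trim whitespace, strip a trailing
# reference suffix such as "-Av", match case-insensitively against the montage.
normalize_channel_labels <- function(labels) {
  x <- sub("-[A-Za-z0-9]+$", "", trimws(labels))
  ref <- montage_1020()
  idx <- match(toupper(x), toupper(ref))
  out <- ifelse(is.na(idx), x, ref[idx])
  out
}

# Feature-name grid in the canonical order: RE over all channels, then TE,
# then LZC; ordinal channel aliases C1..C19.
feature_names <- function(labels = montage_1020()) {
  ord <- paste0("C", seq_along(labels))
  c(paste0("RE_", ord), paste0("TE_", ord), paste0("LZC_", ord))
}
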