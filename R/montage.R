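#' Reduced 10-20 scalp montage
#'
#' The eight-electrode neuro-ICU montage used throughout the package:
#' frontopolar (Fp1/Fp2), central (C3/C4), temporal (T3/T4) and occipital
#' (O1/O2) electrodes, split into a left (Fp1-C3-T3-O1) and a right
#' (Fp2-C4-T4-O2) hemisphere chain.
#'
#' @param labels Character vector of exactly 8 unique channel labels.
#' @return An object of class `montage`: a list with `labels`,
#'   `hemisphere` (named character, `"left"`/`"right"`) and `position`
#'   (named character, `"frontopolar"`, `"central"`, `"temporal"`,
#'   `"occipital"`).
#' @export
#' @examples
#' m <- montage()
#' m$labels
montage <- function(labels = c("Fp1", "Fp2", "C3", "C4", "T3", "T4", "O1", "O2")) {
  if (length(labels) != 8L || anyDuplicated(labels))
    stop("a montage needs exactly 8 unique channel labels", call. = FALSE)
  hemi <- ifelse(labels %in% c("Fp1", "C3", "T3", "O1"), "left", "right")
  pos <- c(Fp = "frontopolar", C = "central", T = "temporal", O = "occipital")
  position <- pos[sub("[0-9]+$", "", labels)]
  structure(
    list(labels = labels,
         hemisphere = stats::setNames(hemi, labels),
         position = stats::setNames(unname(position), labels)),
    class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Normalize clinical EDF channel labels
#'
#' Clinical EDF exports decorate electrode names ("EEG Fp1-Ref", "FP1-REF",
#' ...). This strips a leading "EEG" word and a "-Ref"/"-REF" style suffix
#' and matches case-insensitively against the montage labels.
#'
#' @param x Character vector of raw channel labels.
#' @param labels Canonical labels to match against.
#' @return Character vector: the canonical label where one matches,
#'   otherwise `NA`.
#' @export
normalize_channel_label <- function(x, labels = montage()$labels) {
  y <- trimws(x)
  y <- sub("^EEG[ _]+", "", y, ignore.case = TRUE)
  y <- sub("-[A-Za-z0-9]+$", "", y)
  y <- trimws(y)
  idx <- match(tolower(y), tolower(labels))
  labels[idx]
}

#' All unordered channel pairs of a montage
#'
#' @param m A `montage`.
#' @return Data frame with character columns `a` and `b`, one row per
#'   unordered pair (28 for the 8-channel montage).
#' @export
montage_pairs <- function(m = montage()) {
  idx <- utils::combn(seq_along(m$labels), 2L)
  data.frame(a = m$labels[idx[1L, ]], b = m$labels[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Default region-to-electrode-pair map
#'
#' Five scalp regions, each summarized by five electrode pairs anchored on
#' the region's own electrodes: three anteroposterior divisions (anterior,
#' centrotemporal, posterior) and the two hemispheres (left, right; within-
#' hemisphere pairs only). The exact published pairing is configuration,
#' not inference: pass your own map to override.
#'
#' @return Named list of 5 regions, each a 5 x 2 character matrix of
#'   electrode pairs.
#' @export
default_region_map <- function() {
  pair <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)
  list(
    anterior       = pair("Fp1", "Fp2", "Fp1", "C3", "Fp2", "C4", "Fp1", "T3", "Fp2", "T4"),
    centrotemporal = pair("C3", "C4", "T3", "T4", "C3", "T3", "C4", "T4", "C3", "T4"),
    posterior      = pair("O1", "O2", "O1", "C3", "O2", "C4", "O1", "T3", "O2", "T4"),
    left           = pair("Fp1", "C3", "Fp1", "T3", "C3", "T3", "C3", "O1", "T3", "O1"),
    right          = pair("Fp2", "C4", "Fp2", "T4", "C4", "T4", "C4", "O2", "T4", "O2"))
}

validate_region_map <- function(region_map, m = montage()) {
  for (rn in names(region_map)) {
    p <- region_map[[rn]]
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) != 5L)
      stop("region '", rn, "' must map to a 5 x 2 matrix of electrode pairs",
           call. = FALSE)
    bad <- setdiff(as.vector(p), m$labels)
    if (length(bad))
      stop("region '", rn, "' uses electrodes outside the montage: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(p[, 1L] == p[, 2L]))
      stop("region '", rn, "' contains a self-pair", call. = FALSE)
  }
  invisible(region_map)
}
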