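#' Ictal phase labels
#'
#' The four 10-s analysis phases anchored on the seizure markers, plus the
#' inter-ictal baseline label.
#' @export
ictal_phases <- function() c("pre_ictal", "onset", "termination", "post_ictal")

#' Analysis windows around seizure and inter-ictal markers
#'
#' Four windows of `window_s` seconds per seizure — `pre_ictal =
#' [onset-w, onset)`, `onset = [onset, onset+w)`, `termination =
#' [term-w, term)`, `post_ictal = [term, term+w)` — and two windows
#' (before/after) per inter-ictal marker. Windows are half-open in samples;
#' a marker time belongs to the window that follows it. Windows extending
#' beyond the recording are dropped with a warning.
#'
#' @param markers A `marker_set`.
#' @param window_s Window length (s, default 10).
#' @param duration_s Recording duration for bounds checking (optional).
#' @return Data frame with `seizure_index` (`NA` for inter-ictal rows),
#'   `phase`, `start_s`, `end_s`.
#' @export
phase_windows <- function(markers, window_s = 10, duration_s = NULL) {
  stopifnot(inherits(markers, "marker_set"))
  sz <- markers$seizures
  w <- window_s
  rows <- list()
  if (nrow(sz)) {
    for (k in seq_len(nrow(sz))) {
      on <- sz$onset_s[k]; te <- sz$termination_s[k]
      rows[[length(rows) + 1L]] <- data.frame(
        seizure_index = k,
        phase = ictal_phases(),
        start_s = c(on - w, on, te - w, te),
        end_s = c(on, on + w, te, te + w))
    }
  }
  for (t in markers$interictal) {
    rows[[length(rows) + 1L]] <- data.frame(
      seizure_index = NA_integer_, phase = "inter_ictal",
      start_s = c(t - w, t), end_s = c(t, t + w))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(seizure_index = integer(), phase = character(),
                      start_s = numeric(), end_s = numeric()))
  oob <- out$start_s < 0
  if (!is.null(duration_s)) oob <- oob | out$end_s > duration_s
  if (any(oob)) {
    warning(sum(oob), " window(s) extend beyond the recording and were dropped",
            call. = FALSE)
    out <- out[!oob, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# Sample rows of a [start_s, end_s) window: markers between samples resolve
# to the nearest earlier sample.
window_rows <- function(window, fs) {
  i0 <- as.integer(floor(window[1L] * fs)) + 1L
  i1 <- as.integer(floor(window[2L] * fs))
  if (i1 < i0) stop("empty window", call. = FALSE)
  i0:i1
}

#' Connectivity matrix of one analysis window
#'
#' The symmetric 8 x 8 matrix of low-frequency imaginary coherence between
#' all 28 unordered channel pairs over one window; the diagonal is 0 by
#' convention.
#'
#' @param recording An `eeg_recording`.
#' @param window Numeric `c(start_s, end_s)` (half-open, inside the
#'   recording).
#' @param params A [spectral_params()].
#' @param scheme A [band_scheme()].
#' @param phase,seizure_index Optional annotations stored as attributes.
#' @return 8 x 8 numeric matrix with attributes `kind = "raw"`, `phase`,
#'   `seizure_index`.
#' @export
connectivity_matrix <- function(recording, window, params = spectral_params(),
                                scheme = band_scheme(), phase = NULL,
                                seizure_index = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (window[1L] < 0 || window[2L] > recording$duration_s + 1e-9)
    stop("window [", window[1L], ", ", window[2L], ") outside the recording",
         call. = FALSE)
  rows <- window_rows(window, recording$fs)
  mat <- tryCatch(
    lf_icoh_all_pairs(recording$signal[rows, , drop = FALSE], recording$fs,
                      params, scheme),
    error = function(e) stop("window [", window[1L], ", ", window[2L], "): ",
                             conditionMessage(e), call. = FALSE))
  attr(mat, "kind") <- "raw"
  attr(mat, "phase") <- phase
  attr(mat, "seizure_index") <- seizure_index
  mat
}

#' Inter-ictal baseline connectivity
#'
#' Elementwise mean of the raw inter-ictal connectivity matrices: the
#' per-recording baseline every ictal matrix is adjusted against.
#'
#' @param matrices Non-empty list of raw connectivity matrices.
#' @return 8 x 8 baseline matrix.
#' @export
interictal_baseline <- function(matrices) {
  if (!length(matrices))
    stop("no inter-ictal matrices: the baseline adjustment cannot proceed",
         call. = FALSE)
  out <- Reduce(`+`, matrices) / length(matrices)
  attr(out, "kind") <- "baseline"
  attr(out, "phase") <- "inter_ictal"
  out
}

#' Baseline-adjust a connectivity matrix
#'
#' Entry-wise `(Zn - Zic) / Zic`, where `Zn` is the raw matrix of one
#' analysis window and `Zic` the inter-ictal baseline: 0 means "at
#' baseline", positive values hypersynchronization relative to the
#' inter-ictal level.
#'
#' @param zn Raw connectivity matrix.
#' @param zic Baseline matrix; every off-diagonal entry must exceed
#'   `epsilon`.
#' @param epsilon Degenerate-baseline guard (default 1e-6).
#' @return Adjusted matrix (attribute `kind = "adjusted"`).
#' @export
adjust_matrix <- function(zn, zic, epsilon = 1e-6) {
  off <- row(zic) != col(zic)
  if (any(zic[off] <= epsilon)) {
    bad <- which(zic <= epsilon & off, arr.ind = TRUE)[1L, ]
    stop("degenerate baseline entry (", rownames(zic)[bad[1L]], ", ",
         colnames(zic)[bad[2L]], ") <= ", epsilon, call. = FALSE)
  }
  out <- zn
  out[off] <- (zn[off] - zic[off]) / zic[off]
  diag(out) <- 0
  attr(out, "kind") <- "adjusted"
  attr(out, "phase") <- attr(zn, "phase")
  attr(out, "seizure_index") <- attr(zn, "seizure_index")
  out
}

#' Regional synchrony averages
#'
#' Each region's synchrony is the arithmetic mean of the connectivity
#' entries of its five designated electrode pairs.
#'
#' @param mat Connectivity matrix (raw or adjusted).
#' @param region_map Named list of 5 x 2 electrode-pair matrices (see
#'   [default_region_map()]).
#' @return Named numeric vector, one value per region.
#' @export
regional_average <- function(mat, region_map = default_region_map()) {
  validate_region_map(region_map, montage(rownames(mat)))
  vapply(region_map, function(p)
    mean(mat[cbind(p[, 1L], p[, 2L])]), numeric(1))
}

#' Per-electrode total synchrony
#'
#' Row sums of the off-diagonal connectivity entries: the total (baseline-
#' normalized, when fed an adjusted matrix) synchrony of each electrode
#' with the rest of the montage.
#'
#' @param mat Connectivity matrix.
#' @return Named numeric vector, one value per electrode.
#' @export
electrode_totals <- function(mat) {
  out <- rowSums(mat)
  out - diag(mat)
}

#' Long-format synchrony table of one recording
#'
#' Runs the whole per-recording pipeline: phase windows, raw connectivity
#' matrices, the inter-ictal baseline, baseline adjustment, regional
#' averages and electrode totals, emitted as one long data frame ready for
#' the mixed-effects models. Seizures with any out-of-bounds window are
#' omitted with a warning.
#'
#' @param recording An `eeg_recording`.
#' @param markers A `marker_set` (already filtered by [select_seizures()]
#'   if selection is wanted).
#' @param region_map Named list of electrode-pair matrices.
#' @param params A [spectral_params()].
#' @param scheme A [band_scheme()].
#' @param patient_id Identifier recorded in every row.
#' @param window_s Analysis-window length (s).
#' @param adjusted If `FALSE`, emit raw instead of baseline-adjusted values
#'   (descriptive use; the modeling default is adjusted).
#' @return Data frame with columns `patient_id`, `seizure_index`, `phase`,
#'   `level` (`"region"`/`"electrode"`), `location`, `value`: per complete
#'   seizure and ictal phase, 5 region rows and 8 electrode rows.
#' @export
build_synchrony_table <- function(recording, markers,
                                  region_map = default_region_map(),
                                  params = spectral_params(),
                                  scheme = band_scheme(),
                                  patient_id = "p01", window_s = 10,
                                  adjusted = TRUE) {
  wins <- phase_windows(markers, window_s, recording$duration_s)
  ii <- wins[wins$phase == "inter_ictal", , drop = FALSE]
  if (!nrow(ii)) stop("no inter-ictal windows: cannot form the baseline",
                      call. = FALSE)
  ictal <- wins[wins$phase != "inter_ictal", , drop = FALSE]
  complete <- names(which(table(ictal$seizure_index) == 4L))
  dropped <- setdiff(unique(ictal$seizure_index), as.integer(complete))
  if (length(dropped))
    warning("omitting seizure(s) with missing windows: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  ictal <- ictal[ictal$seizure_index %in% as.integer(complete), , drop = FALSE]
  if (!nrow(ictal)) stop("no complete seizures to analyze", call. = FALSE)

  base_mats <- lapply(seq_len(nrow(ii)), function(k)
    connectivity_matrix(recording, c(ii$start_s[k], ii$end_s[k]), params, scheme,
                        phase = "inter_ictal"))
  zic <- interictal_baseline(base_mats)

  rows <- vector("list", nrow(ictal))
  for (k in seq_len(nrow(ictal))) {
    zn <- connectivity_matrix(recording, c(ictal$start_s[k], ictal$end_s[k]),
                              params, scheme, phase = ictal$phase[k],
                              seizure_index = ictal$seizure_index[k])
    mat <- if (adjusted) adjust_matrix(zn, zic) else zn
    reg <- regional_average(mat, region_map)
    ele <- electrode_totals(mat)
    rows[[k]] <- data.frame(
      patient_id = patient_id,
      seizure_index = ictal$seizure_index[k],
      phase = ictal$phase[k],
      level = c(rep("region", length(reg)), rep("electrode", length(ele))),
      location = c(names(reg), names(ele)),
      value = c(unname(reg), unname(ele)))
  }
  out <- do.call(rbind, rows)
  out$phase <- factor(out$phase, levels = ictal_phases())
  rownames(out) <- NULL
  out
}
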