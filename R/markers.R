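#' Seizure and inter-ictal markers
#'
#' A `marker_set` holds the annotation layer of a recording: seizure
#' onset/termination intervals and point markers placed in the inter-ictal
#' period (seizure-free, at least 5 min away from any seizure). Times are
#' seconds from recording start.
#'
#' @param seizures Data frame with numeric `onset_s`, `termination_s`, and
#'   optionally logical `exclude` (manual rejection flag, e.g. artifacted
#'   seizures; honored by [select_seizures()]).
#' @param interictal Numeric vector of inter-ictal marker times (s).
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(seizures = data.frame(onset_s = numeric(), termination_s = numeric()),
                       interictal = numeric()) {
  seizures <- as.data.frame(seizures)
  if (!all(c("onset_s", "termination_s") %in% names(seizures)))
    stop("seizures needs columns onset_s and termination_s", call. = FALSE)
  if (is.null(seizures$exclude)) seizures$exclude <- rep(FALSE, nrow(seizures))
  if (any(seizures$onset_s < 0) || any(interictal < 0))
    stop("marker times must be non-negative", call. = FALSE)
  if (any(seizures$termination_s <= seizures$onset_s))
    stop("every seizure needs onset_s < termination_s", call. = FALSE)
  o <- order(seizures$onset_s)
  seizures <- seizures[o, c("onset_s", "termination_s", "exclude"), drop = FALSE]
  rownames(seizures) <- NULL
  if (nrow(seizures) > 1L &&
      any(seizures$onset_s[-1L] < seizures$termination_s[-nrow(seizures)]))
    stop("seizures overlap", call. = FALSE)
  structure(list(seizures = seizures, interictal = sort(as.numeric(interictal))),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> ", nrow(x$seizures), " seizures, ",
      length(x$interictal), " inter-ictal markers\n", sep = "")
  invisible(x)
}

n_seizures <- function(markers) nrow(markers$seizures)

#' Read / write marker annotations
#'
#' Markers travel as a plain CSV with header `kind,time_s,label`, one row
#' per marker; `kind` is one of `onset`, `termination`, `interictal`.
#' Onsets and terminations must alternate (each onset paired with the next
#' termination).
#'
#' @param path CSV file path.
#' @return `read_markers()` returns a `marker_set`; `write_markers()`
#'   invisibly returns `path`.
#' @export
read_markers <- function(path) {
  if (!file.exists(path)) stop("marker file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("kind", "time_s") %in% names(d)))
    stop("marker CSV needs columns kind,time_s: ", path, call. = FALSE)
  bad <- setdiff(unique(d$kind), c("onset", "termination", "interictal"))
  if (length(bad))
    stop("unknown marker kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(d$time_s)) || any(d$time_s < 0))
    stop("marker times must be finite and non-negative", call. = FALSE)
  ev <- d[d$kind != "interictal", , drop = FALSE]
  ev <- ev[order(ev$time_s), , drop = FALSE]
  if (nrow(ev) %% 2L != 0L ||
      (nrow(ev) > 0L && !all(ev$kind == rep(c("onset", "termination"), nrow(ev) / 2L)))) {
    first_bad <- which(ev$kind != rep_len(c("onset", "termination"), nrow(ev)))[1L]
    stop("unpaired onset/termination markers (first problem at sorted marker ",
         if (is.na(first_bad)) nrow(ev) else first_bad, ")", call. = FALSE)
  }
  sz <- if (nrow(ev)) data.frame(
    onset_s = ev$time_s[ev$kind == "onset"],
    termination_s = ev$time_s[ev$kind == "termination"])
  else data.frame(onset_s = numeric(), termination_s = numeric())
  marker_set(sz, interictal = d$time_s[d$kind == "interictal"])
}

#' @rdname read_markers
#' @param markers A `marker_set`.
#' @export
write_markers <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  sz <- markers$seizures
  d <- rbind(
    if (nrow(sz)) data.frame(kind = "onset", time_s = sz$onset_s, label = "") else NULL,
    if (nrow(sz)) data.frame(kind = "termination", time_s = sz$termination_s, label = "") else NULL,
    if (length(markers$interictal))
      data.frame(kind = "interictal", time_s = markers$interictal, label = "") else NULL)
  if (is.null(d)) d <- data.frame(kind = character(), time_s = numeric(), label = character())
  d <- d[order(d$time_s), , drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the seizure-selection filters
#'
#' Retains seizures longer than `min_duration_s` (strict) that are not
#' manually flagged `exclude`, warns (without failing) when fewer than
#' `min_count` seizures survive, and drops inter-ictal markers closer than
#' `interictal_gap_s` to any retained seizure boundary.
#'
#' @param markers A `marker_set`.
#' @param min_duration_s Minimum seizure duration in seconds (default 20;
#'   a retained seizure must be strictly longer).
#' @param min_count Soft minimum on the retained-seizure count (default
#'   50): fewer triggers a warning and a report flag, never an error.
#' @param interictal_gap_s Minimum distance (s) of an inter-ictal marker
#'   from every retained seizure onset/termination (default 300 s).
#' @return List with `markers` (filtered `marker_set`) and `report`
#'   (class `selection_report`: counts plus a data frame of rejections).
#' @export
select_seizures <- function(markers, min_duration_s = 20, min_count = 50,
                            interictal_gap_s = 300) {
  stopifnot(inherits(markers, "marker_set"))
  sz <- markers$seizures
  dur <- sz$termination_s - sz$onset_s
  reasons <- character(nrow(sz))
  reasons[dur <= min_duration_s] <- sprintf("duration <= %g s", min_duration_s)
  reasons[sz$exclude] <- "manually excluded"
  keep <- reasons == ""
  rejected <- data.frame(seizure = which(!keep), reason = reasons[!keep])
  kept <- sz[keep, , drop = FALSE]

  ii <- markers$interictal
  ii_keep <- rep(TRUE, length(ii))
  if (nrow(kept) && length(ii)) {
    bounds <- c(kept$onset_s, kept$termination_s)
    dist <- vapply(ii, function(t) min(abs(t - bounds)), numeric(1))
    inside <- vapply(ii, function(t) any(t >= kept$onset_s & t <= kept$termination_s),
                     logical(1))
    ii_keep <- dist >= interictal_gap_s & !inside
  }
  out <- marker_set(kept, interictal = ii[ii_keep])
  rep_ <- structure(
    list(n_input = nrow(sz), n_retained = nrow(kept), rejected = rejected,
         n_interictal_dropped = sum(!ii_keep),
         count_below_minimum = nrow(kept) < min_count),
    class = "selection_report")
  if (rep_$count_below_minimum)
    warning("only ", nrow(kept), " seizures retained (< ", min_count, ")",
            call. = FALSE)
  list(markers = out, report = rep_)
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report> retained ", x$n_retained, "/", x$n_input,
      " seizures; dropped ", x$n_interictal_dropped, " inter-ictal markers\n",
      sep = "")
  if (nrow(x$rejected)) print(x$rejected)
  invisible(x)
}
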