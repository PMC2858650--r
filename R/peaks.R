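#' Default component search windows
#'
#' Peak search windows in ms post trigger, wide enough to accommodate the
#' ~50-60 ms stimulus-internal silence that delays all AEP latencies:
#' P1 80-160 ms, N1 120-220 ms, P2 190-320 ms.
#'
#' @return Named list of `c(lo, hi)` windows.
#' @export
default_peak_windows <- function() {
  list(P1 = c(80, 160), N1 = c(120, 220), P2 = c(190, 320))
}

component_polarity <- function(component) {
  switch(component, P1 = 1, P2 = 1, N1 = -1,
         stop("unknown component: ", component))
}

#' Detect a component peak at one electrode
#'
#' Finds the extremum of the component's polarity (maximum for P1/P2,
#' minimum for N1) within the search window. Ties are broken by the earliest
#' latency; an extremum at the window edge is flagged as a boundary peak
#' rather than dropped (the deterministic replacement for manual peak
#' confirmation).
#'
#' @param evoked An [erp_evoked()] (baseline already zero-mean, so the
#'   returned amplitude is relative to the pre-stimulus baseline).
#' @param electrode Electrode label.
#' @param component `"P1"`, `"N1"` or `"P2"`.
#' @param window Search window in ms (defaults per component, see
#'   [default_peak_windows()]).
#' @param polarity `+1` or `-1`; defaults to the component's polarity.
#' @return A one-row tibble: `component`, `electrode`, `amplitude` (uV),
#'   `latency` (ms), `boundary` (logical quality flag).
#' @export
detect_peak <- function(evoked, electrode, component,
                        window = NULL, polarity = NULL) {
  stopifnot(inherits(evoked, "erp_evoked"))
  component <- match.arg(component, c("P1", "N1", "P2"))
  if (is.null(window)) window <- default_peak_windows()[[component]]
  if (is.null(polarity)) polarity <- component_polarity(component)
  row <- match(electrode, evoked$labels)
  if (is.na(row)) stop("lookup error: unknown electrode label ", electrode)
  idx <- window_index(evoked$time, window)
  wave <- evoked$data[row, idx]
  k <- which.max(polarity * wave) # which.max takes the first (earliest) tie
  tibble::tibble(
    component = component,
    electrode = electrode,
    amplitude = wave[k],
    latency = evoked$time[idx[k]],
    boundary = k == 1L || k == length(idx)
  )
}

#' Mean amplitude over a time window (and optionally a region of interest)
#'
#' Arithmetic mean of the evoked amplitude over the window samples, averaged
#' without weighting over the given electrodes when more than one is named.
#'
#' @param evoked An [erp_evoked()].
#' @param electrodes One electrode label or a ROI electrode set.
#' @param window Window in ms (default `c(190, 290)`, the windowed P2
#'   measure).
#' @return Mean amplitude in microvolts (scalar).
#' @export
mean_window_amplitude <- function(evoked, electrodes, window = c(190, 290)) {
  stopifnot(inherits(evoked, "erp_evoked"))
  rows <- match(electrodes, evoked$labels)
  if (anyNA(rows)) {
    stop("lookup error: unknown electrode label ",
         paste(electrodes[is.na(rows)], collapse = ", "))
  }
  idx <- window_index(evoked$time, window)
  mean(evoked$data[rows, idx, drop = FALSE])
}

#' Build the long-format peak table for a study
#'
#' One row per (subject, session, stimulus, electrode, component) with peak
#' amplitude, latency and the boundary quality flag. The table is the sole
#' input to the repeated-measures ANOVA; the requested design must be
#' complete and balanced.
#'
#' @param evoked_tbl Evoked tibble from [preprocess_study()] (columns
#'   `subject`, `group`, `session`, `stimulus`, `evoked`).
#' @param electrodes Electrode labels to measure.
#' @param components Components to measure (default all three).
#' @param windows Named list of search windows (defaults per component).
#' @return A tibble with columns `subject`, `group`, `session`, `stimulus`,
#'   `electrode`, `component`, `amplitude`, `latency`, `boundary`. The
#'   windows used are attached as attribute `"peak_windows"`.
#' @export
build_peak_table <- function(evoked_tbl, electrodes,
                             components = c("P1", "N1", "P2"),
                             windows = default_peak_windows()) {
  stopifnot(is.data.frame(evoked_tbl), "evoked" %in% names(evoked_tbl))
  cells <- dplyr::count(evoked_tbl, .data$subject, .data$session,
                        .data$stimulus)
  if (any(cells$n != 1)) {
    stop("missing-design error: duplicated subject/session/stimulus cells")
  }
  design <- dplyr::count(evoked_tbl, .data$subject,
                         name = "n_cells")
  if (length(unique(design$n_cells)) != 1) {
    stop("missing-design error: subjects do not share the same session/stimulus cells")
  }
  out <- purrr::pmap_dfr(
    evoked_tbl[, c("subject", "group", "session", "stimulus", "evoked")],
    function(subject, group, session, stimulus, evoked) {
      purrr::map_dfr(electrodes, function(el) {
        purrr::map_dfr(components, function(cp) {
          pk <- detect_peak(evoked, el, cp, window = windows[[cp]])
          tibble::tibble(
            subject = subject, group = group, session = session,
            stimulus = stimulus, electrode = el, component = cp,
            amplitude = pk$amplitude, latency = pk$latency,
            boundary = pk$boundary
          )
        })
      })
    }
  )
  attr(out, "peak_windows") <- windows
  out
}

#' Windowed P2 amplitude table at the correlation locations
#'
#' Mean 190-290 ms amplitudes at Cz and over the temporal-occipital ROI, the
#' quantities correlated with d-prime.
#'
#' @param evoked_tbl Evoked tibble from [preprocess_study()].
#' @param window Averaging window in ms.
#' @return A tibble `subject`, `group`, `session`, `stimulus`, `location`,
#'   `p2_window_amplitude`.
#' @export
build_p2_window_table <- function(evoked_tbl, window = c(190, 290)) {
  rois <- list(CZ = "CZ", temporal_occipital = roi_sets()$temporal_occipital)
  purrr::pmap_dfr(
    evoked_tbl[, c("subject", "group", "session", "stimulus", "evoked")],
    function(subject, group, session, stimulus, evoked) {
      purrr::imap_dfr(rois, function(els, loc) {
        tibble::tibble(
          subject = subject, group = group, session = session,
          stimulus = stimulus, location = loc,
          p2_window_amplitude = mean_window_amplitude(evoked, els, window)
        )
      })
    }
  )
}
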