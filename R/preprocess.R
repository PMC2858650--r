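#' Baseline-correct epoched data
#'
#' Subtracts, per trial and electrode, the mean over the pre-stimulus window
#' so the baseline mean is exactly zero.
#'
#' @param epochs An [epoch_set()].
#' @param window Baseline window in ms (default `c(-100, 0)`).
#' @return The corrected [epoch_set()] with provenance updated.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- window_index(epochs$time, window)
  d <- dim(epochs$data)
  base <- rowSums(epochs$data[, , idx, drop = FALSE], dims = 2) / length(idx)
  epochs$data <- epochs$data - array(as.vector(base), d)
  epochs$provenance <- c(epochs$provenance, "baseline")
  epochs
}

#' Reject artifact trials exceeding an amplitude threshold
#'
#' Removes every trial containing at least one sample whose absolute value
#' exceeds the threshold on any channel (scalp and eye channels are both
#' screened; a sample exactly at the threshold is retained).
#'
#' @param epochs An [epoch_set()].
#' @param threshold Rejection threshold in microvolts (default 70).
#' @return The retained [epoch_set()]; the rejection log (a tibble with
#'   `trial` and `max_abs_uv` for removed trials) is attached as attribute
#'   `"rejection_log"`.
#' @export
reject_artifacts <- function(epochs, threshold = 70) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (threshold <= 0) stop("threshold must be > 0")
  d <- dim(epochs$data)
  flat <- abs(epochs$data)
  dim(flat) <- c(d[1], d[2] * d[3])
  max_abs <- apply(flat, 1, max)
  bad <- which(max_abs > threshold)
  log <- tibble::tibble(
    subject = epochs$subject, group = epochs$group,
    session = epochs$session, stimulus = epochs$stimulus,
    trial = as.integer(bad), max_abs_uv = max_abs[bad]
  )
  if (length(bad) > 0) {
    epochs$data <- epochs$data[-bad, , , drop = FALSE]
  }
  epochs$provenance <- c(epochs$provenance, "reject")
  attr(epochs, "rejection_log") <- log
  epochs
}

#' Average retained trials into an evoked response
#'
#' @param epochs An [epoch_set()] (must contain at least one trial).
#' @return An [erp_evoked()] carrying `n_trials_included` and provenance.
#' @export
average_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_tr <- dim(epochs$data)[1]
  if (n_tr == 0) {
    stop("empty-average error: no trials left to average")
  }
  avg <- colMeans(epochs$data)
  erp_evoked(avg, epochs$time, epochs$labels, epochs$subject, epochs$group,
             epochs$session, epochs$stimulus, n_trials_included = n_tr,
             provenance = c(epochs$provenance, "average"))
}

# cascaded Butterworth band-pass: high-pass order 4 (24 dB/octave) and
# low-pass order 2 (12 dB/octave), both causal (forward-only) by default,
# emulating the "analog simulation" filter of classic ERP acquisition software
make_bandpass <- function(hp, lp, sfreq) {
  if (hp >= lp) stop("config error: high-pass corner must be below low-pass corner")
  nyq <- sfreq / 2
  list(
    hp = signal::butter(4, hp / nyq, type = "high"),
    lp = signal::butter(2, lp / nyq, type = "low")
  )
}

#' Band-pass filter an evoked response
#'
#' Applies a causal Butterworth band-pass: 4th-order high-pass at `hp`
#' (24 dB/octave) cascaded with a 2nd-order low-pass at `lp` (12 dB/octave),
#' each -3 dB at its corner. A zero-phase (forward-backward) variant is
#' available behind `zero_phase`, off by default.
#'
#' @param evoked An [erp_evoked()].
#' @param hp High-pass corner frequency in Hz (default 1.0).
#' @param lp Low-pass corner frequency in Hz (default 20).
#' @param zero_phase Use forward-backward filtering (default `FALSE`).
#' @return The filtered [erp_evoked()].
#' @export
filter_band <- function(evoked, hp = 1.0, lp = 20, zero_phase = FALSE) {
  stopifnot(inherits(evoked, "erp_evoked"))
  if ("filter" %in% evoked$provenance) {
    stop("evoked has already been filtered")
  }
  sfreq <- 1000 / diff(evoked$time[1:2])
  flt <- make_bandpass(hp, lp, sfreq)
  apply_1d <- function(x) {
    if (zero_phase) {
      x <- signal::filtfilt(flt$hp, x)
      signal::filtfilt(flt$lp, x)
    } else {
      x <- as.numeric(signal::filter(flt$hp, x))
      as.numeric(signal::filter(flt$lp, x))
    }
  }
  evoked$data <- t(apply(evoked$data, 1, apply_1d))
  evoked$provenance <- c(evoked$provenance, "filter")
  evoked
}

#' Re-reference an evoked to the common average of the scalp electrodes
#'
#' Subtracts, at every sample, the mean over all scalp (non-eye) electrodes
#' from every channel's value; eye channels are excluded from the reference
#' but are re-expressed against it like every other channel. After the
#' operation the scalp mean is exactly zero at every sample.
#'
#' @param evoked An [erp_evoked()].
#' @param montage Montage tibble flagging eye channels.
#' @return The re-referenced [erp_evoked()].
#' @export
rereference_common_average <- function(evoked, montage) {
  stopifnot(inherits(evoked, "erp_evoked"))
  scalp <- montage$label[!montage$is_eye]
  scalp <- intersect(evoked$labels, scalp)
  if (length(scalp) == 0) stop("config error: no scalp electrodes to reference to")
  idx <- match(scalp, evoked$labels)
  ref <- colMeans(evoked$data[idx, , drop = FALSE])
  evoked$data <- sweep(evoked$data, 2, ref)
  evoked$provenance <- c(evoked$provenance, "rereference")
  evoked
}

#' Run the full preprocessing chain over a simulated study
#'
#' Applies the fixed pipeline order epoch -> baseline -> reject -> average ->
#' filter -> re-reference to every epoch cell of a study and returns the
#' evoked responses as a tibble with a list-column.
#'
#' @param study An `erp_study` from [simulate_study()].
#' @param baseline_window Baseline window in ms.
#' @param threshold Artifact rejection threshold in microvolts.
#' @param hp,lp Band-pass corners in Hz.
#' @param filter Apply the band-pass (default `TRUE`).
#' @return A tibble with columns `subject`, `group`, `session`, `stimulus`,
#'   `n_trials`, and `evoked` (list of [erp_evoked()]); the pooled rejection
#'   log is attached as attribute `"rejection_log"`.
#' @export
preprocess_study <- function(study, baseline_window = c(-100, 0),
                             threshold = 70, hp = 1.0, lp = 20,
                             filter = TRUE) {
  stopifnot(inherits(study, "erp_study"))
  logs <- list()
  rows <- purrr::map(study$epochs, function(ep) {
    ep <- baseline_correct(ep, baseline_window)
    ep <- reject_artifacts(ep, threshold)
    logs[[length(logs) + 1]] <<- attr(ep, "rejection_log")
    ev <- average_epochs(ep)
    if (filter) ev <- filter_band(ev, hp, lp)
    ev <- rereference_common_average(ev, study$montage)
    tibble::tibble(
      subject = ev$subject, group = ev$group, session = ev$session,
      stimulus = ev$stimulus, n_trials = ev$n_trials_included,
      evoked = list(ev)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "rejection_log") <- dplyr::bind_rows(logs)
  out
}
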