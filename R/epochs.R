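#' Epoched single-trial EEG container
#'
#' A lightweight array-backed record for one subject x session x stimulus
#' cell: `trials x electrodes x samples` in microvolts, with a uniform
#' millisecond time axis. The analysis functions of the package consume and
#' return tibbles; this container exists only to carry the raw trial arrays
#' between the simulator and the preprocessing chain.
#'
#' @param data Numeric array `trials x electrodes x samples` (microvolts).
#' @param time Numeric vector of sample times in ms (uniform, 1 kHz).
#' @param labels Character vector of electrode labels (length = dim 2).
#' @param subject,group,session,stimulus Cell metadata. `group` is 1 or 2,
#'   `session` 1..4, `stimulus` `"mba"` or `"ba"`.
#' @param provenance Character vector of preprocessing steps already applied.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time, labels, subject, group, session, stimulus,
                      provenance = character()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != length(labels)) {
    stop("electrode dimension (", dim(data)[2], ") does not match labels (",
         length(labels), ")")
  }
  if (dim(data)[3] != length(time)) {
    stop("sample dimension does not match time axis length")
  }
  dt <- diff(time)
  if (length(dt) > 0 && max(abs(dt - dt[1])) > 1e-9) {
    stop("time axis must be uniform")
  }
  if (!all(is.finite(data))) stop("epoch data must be finite")
  structure(
    list(
      data = data, time = time, labels = labels,
      subject = subject, group = as.integer(group),
      session = as.integer(session), stimulus = stimulus,
      sfreq = if (length(dt) > 0) 1000 / dt[1] else NA_real_,
      provenance = provenance
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> subject %s group %d session %d stimulus %s\n  %d trials x %d electrodes x %d samples (%g..%g ms)\n",
    x$subject, x$group, x$session, x$stimulus, d[1], d[2], d[3],
    min(x$time), max(x$time)
  ))
  if (length(x$provenance) > 0) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Averaged evoked potential container
#'
#' The trial-averaged AEP for one subject x session x stimulus cell:
#' an `electrodes x samples` matrix in microvolts with the preprocessing
#' provenance and the number of trials averaged.
#'
#' @param data Numeric matrix `electrodes x samples` (microvolts).
#' @param time Time axis in ms.
#' @param labels Electrode labels.
#' @param subject,group,session,stimulus Cell metadata.
#' @param n_trials_included Number of trials entering the average.
#' @param provenance Character vector of applied preprocessing steps.
#' @return An object of class `erp_evoked`.
#' @export
erp_evoked <- function(data, time, labels, subject = NA, group = NA,
                       session = NA, stimulus = NA, n_trials_included = NA,
                       provenance = character()) {
  stopifnot(is.matrix(data))
  if (nrow(data) != length(labels)) stop("rows of data must match labels")
  if (ncol(data) != length(time)) stop("columns of data must match time axis")
  structure(
    list(
      data = data, time = time, labels = labels,
      subject = subject, group = if (is.na(group)) NA_integer_ else as.integer(group),
      session = if (is.na(session)) NA_integer_ else as.integer(session),
      stimulus = stimulus,
      n_trials_included = n_trials_included,
      provenance = provenance
    ),
    class = "erp_evoked"
  )
}

#' @export
print.erp_evoked <- function(x, ...) {
  cat(sprintf(
    "<erp_evoked> subject %s group %s session %s stimulus %s\n  %d electrodes x %d samples, %s trials averaged\n",
    x$subject, x$group, x$session, x$stimulus,
    nrow(x$data), ncol(x$data), x$n_trials_included
  ))
  if (length(x$provenance) > 0) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Convert an evoked to a long tibble
#'
#' @param x An `erp_evoked`.
#' @param ... Unused.
#' @return A tibble with columns `electrode`, `time`, `amplitude` plus the
#'   cell metadata.
#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.erp_evoked <- function(x, ...) {
  tibble::tibble(
    subject = x$subject, group = x$group, session = x$session,
    stimulus = x$stimulus,
    electrode = rep(x$labels, times = length(x$time)),
    time = rep(x$time, each = length(x$labels)),
    amplitude = as.vector(x$data)
  )
}

#' Plot an evoked as overlaid channel waveforms
#'
#' @param object An `erp_evoked`.
#' @param electrodes Optional subset of electrode labels to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.erp_evoked <- function(object, electrodes = NULL, ...) {
  df <- as_tibble.erp_evoked(object)
  if (!is.null(electrodes)) {
    df <- dplyr::filter(df, .data$electrode %in% electrodes)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude,
                                   group = .data$electrode,
                                   colour = .data$electrode)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Time (ms)", y = expression("Amplitude (" * mu * "V)")) +
    ggplot2::theme_minimal()
}

# index of the samples falling inside a [lo, hi] ms window (inclusive)
window_index <- function(time, window) {
  if (length(window) != 2 || window[2] < window[1]) {
    stop("window must be c(lo, hi) with hi >= lo")
  }
  if (window[1] < min(time) - 1e-9 || window[2] > max(time) + 1e-9) {
    stop("window [", window[1], ", ", window[2], "] ms lies outside the epoch span [",
         min(time), ", ", max(time), "] ms")
  }
  idx <- which(time >= window[1] - 1e-9 & time <= window[2] + 1e-9)
  if (length(idx) == 0) stop("window contains no samples")
  idx
}
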