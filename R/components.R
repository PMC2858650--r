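#' Specify an AEP component
#'
#' An evoked component (P1, N1 or P2) is modelled as a Gaussian bump in time
#' with a fixed scalp topography. `width` is the half-width at half maximum
#' of the bump in ms; `latency` is measured from the effective sound onset
#' (the stimulus-internal silence is added separately per stimulus).
#'
#' @param name One of `"P1"`, `"N1"`, `"P2"`.
#' @param latency Peak latency in ms post effective stimulus onset.
#' @param width Kernel half-width (half maximum) in ms; must be > 0.
#' @param amplitude Signed peak amplitude in microvolts (P1/P2 >= 0,
#'   N1 <= 0).
#' @param topography Per-scalp-electrode weight vector in `[-1, 1]`, named by
#'   electrode label.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, latency, width, amplitude, topography) {
  name <- match.arg(name, c("P1", "N1", "P2"))
  if (!is.numeric(width) || width <= 0) {
    stop("invalid component spec: width must be > 0")
  }
  if (!all(is.finite(c(latency, amplitude, topography)))) {
    stop("invalid component spec: non-finite values")
  }
  if (any(abs(topography) > 1 + 1e-12)) {
    stop("invalid component spec: topography weights must lie in [-1, 1]")
  }
  if (name %in% c("P1", "P2") && amplitude < 0) {
    stop("invalid component spec: ", name, " amplitude must be >= 0")
  }
  if (name == "N1" && amplitude > 0) {
    stop("invalid component spec: N1 amplitude must be <= 0")
  }
  structure(
    list(name = name, latency = latency, width = width,
         amplitude = amplitude, topography = topography),
    class = "component_spec"
  )
}

#' Evaluate a component kernel on a time axis
#'
#' Gaussian bump peaking at `spec$latency` with value `spec$amplitude`,
#' parameterised so that `spec$width` is the half-width at half maximum; the
#' kernel decays below 1% of its peak beyond three widths.
#'
#' @param spec A [component_spec()].
#' @param time Uniform time axis in ms (1 kHz).
#' @return Numeric waveform (microvolts per sample), same length as `time`.
#' @examples
#' spec <- component_spec("P2", 230, 35, 2, c(CZ = 1))
#' w <- component_kernel(spec, 0:500)
#' which.max(w) - 1 # 230
#' @export
component_kernel <- function(spec, time) {
  if (!inherits(spec, "component_spec")) stop("spec must be a component_spec")
  dt <- diff(time)
  if (length(dt) > 0 && max(abs(dt - dt[1])) > 1e-9) {
    stop("time axis must be uniform")
  }
  sigma <- spec$width / sqrt(2 * log(2))
  spec$amplitude * exp(-0.5 * ((time - spec$latency) / sigma)^2)
}

#' Default P1-N1-P2 component set
#'
#' Canonical adult auditory P1-N1-P2 morphology: P1 (+1 uV at 60 ms), N1
#' (-2 uV at 110 ms) and P2 (+2 uV at 185 ms), all latencies relative to the
#' effective sound onset; widths are set so each component's support matches
#' its classic latency range (the P2 deflection, shifted by the ~50 ms
#' stimulus-internal silence, spans roughly 190-290 ms). Topographies are vertex-maximal Gaussian falloffs
#' over the montage grid, the classic fronto-central distribution of the
#' complex.
#'
#' @param montage A montage tibble; topographies cover its scalp channels.
#' @return Named list of three [component_spec()] objects.
#' @export
default_components <- function(montage = default_montage()) {
  scalp <- montage[!montage$is_eye, ]
  topo <- function(center_y, spread) {
    w <- exp(-((scalp$x - 0)^2 + (scalp$y - center_y)^2) / (2 * spread^2))
    stats::setNames(w, scalp$label)
  }
  list(
    P1 = component_spec("P1", latency = 60, width = 20, amplitude = 1,
                        topography = topo(2, 2.5)),
    N1 = component_spec("N1", latency = 110, width = 25, amplitude = -2,
                        topography = topo(2.5, 3)),
    P2 = component_spec("P2", latency = 185, width = 25, amplitude = 2,
                        topography = topo(2, 3))
  )
}

#' Plan of session-dependent amplitude gains
#'
#' Describes the experimental effect planted by the simulator: additive P2
#' (and optionally N1) amplitude gains in microvolts, indexed by group,
#' session and electrode. Session-4 gains are derived from session-3 gains
#' via `retention_decay` unless given explicitly.
#'
#' @param gains A tibble with columns `group`, `session`, `electrode`,
#'   `p2_gain` and optionally `n1_gain` (defaults to 0). Absent cells mean
#'   zero gain.
#' @param retention_decay Fraction of the session-3 gain retained at
#'   session 4 (per group if length 2, names `"1"`, `"2"`).
#' @return An object of class `effect_plan`.
#' @export
effect_plan <- function(gains, retention_decay = 0.6) {
  stopifnot(is.data.frame(gains))
  need <- c("group", "session", "electrode", "p2_gain")
  missing_cols <- setdiff(need, names(gains))
  if (length(missing_cols) > 0) {
    stop("gains is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"n1_gain" %in% names(gains)) gains$n1_gain <- 0
  if (!all(is.finite(gains$p2_gain)) || !all(is.finite(gains$n1_gain))) {
    stop("gains must be finite")
  }
  if (!all(is.finite(retention_decay))) stop("retention_decay must be finite")
  structure(
    list(gains = tibble::as_tibble(gains), retention_decay = retention_decay),
    class = "effect_plan"
  )
}

#' Default effect plan: temporal-occipital P2 growth, doubled with the task
#'
#' P2 gains of +0.5 uV (session 2) and +1.0 uV (session 3) at TP9, IZ and
#' TP10 for group 1 (exposure only), doubled for group 2 (exposure + task);
#' session-1 gain is zero and session-4 gains retain 60% of the session-3
#' gain. Gains are monotone non-decreasing over sessions 1-3.
#'
#' @param electrodes Electrodes receiving the gain.
#' @param retention_decay Fraction retained at session 4.
#' @return An [effect_plan()].
#' @export
default_effect_plan <- function(electrodes = c("TP9", "IZ", "TP10"),
                                retention_decay = 0.6) {
  g <- tidyr::expand_grid(
    group = 1:2, session = 2:3, electrode = electrodes
  )
  g$p2_gain <- ifelse(g$session == 2, 0.5, 1.0) * ifelse(g$group == 2, 2, 1)
  g$n1_gain <- 0
  effect_plan(g, retention_decay = retention_decay)
}

#' Zero-effect plan (null simulations)
#'
#' @return An [effect_plan()] with no gains at any electrode or session.
#' @export
null_effect_plan <- function() {
  effect_plan(tibble::tibble(group = integer(), session = integer(),
                             electrode = character(), p2_gain = numeric(),
                             n1_gain = numeric()),
              retention_decay = 0)
}

# gain lookup: named per-electrode vectors of (p2, n1) gain for a cell,
# deriving session 4 from session 3 x retention_decay when absent
plan_gains <- function(plan, group, session, labels) {
  g <- plan$gains
  p2 <- stats::setNames(numeric(length(labels)), labels)
  n1 <- p2
  rows <- g[g$group == group & g$session == session, ]
  if (nrow(rows) == 0 && session == 4) {
    rows <- g[g$group == group & g$session == 3, ]
    decay <- plan$retention_decay
    if (length(decay) == 2) decay <- decay[[as.character(group)]]
    rows$p2_gain <- rows$p2_gain * decay
    rows$n1_gain <- rows$n1_gain * decay
  }
  if (nrow(rows) > 0) {
    keep <- rows$electrode %in% labels
    p2[rows$electrode[keep]] <- rows$p2_gain[keep]
    n1[rows$electrode[keep]] <- rows$n1_gain[keep]
  }
  list(p2 = p2, n1 = n1)
}
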