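#' Score a 2AFC identification trial log
#'
#' Tallies signal-detection counts per subject and session: a hit is an
#' "mba" trial answered "mba" (the -20 ms VOT token correctly identified)
#' and a correct rejection a "ba" trial answered "ba". The four counts
#' partition the trials of each log.
#'
#' @param log Trial-log tibble with columns `stimulus` and `response` (both
#'   `"mba"`/`"ba"`), optionally `subject`, `group`, `session`.
#' @return A tibble with one row per (subject, session) holding `hits`,
#'   `misses`, `false_alarms`, `correct_rejections`, `n_signal`, `n_noise`.
#' @export
score_identification <- function(log) {
  stopifnot(is.data.frame(log))
  bad <- which(!(log$response %in% c("mba", "ba")) |
                 !(log$stimulus %in% c("mba", "ba")))
  if (length(bad) > 0) {
    stop("malformed response/stimulus at trial index ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  keys <- intersect(c("subject", "group", "session"), names(log))
  log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      hits = sum(.data$stimulus == "mba" & .data$response == "mba"),
      misses = sum(.data$stimulus == "mba" & .data$response == "ba"),
      false_alarms = sum(.data$stimulus == "ba" & .data$response == "mba"),
      correct_rejections = sum(.data$stimulus == "ba" & .data$response == "ba"),
      n_signal = sum(.data$stimulus == "mba"),
      n_noise = sum(.data$stimulus == "ba"),
      .groups = "drop"
    )
}

#' Equal-variance signal-detection d-prime
#'
#' `d' = z(H) - z(FA)` with hit and false-alarm rates clamped to
#' `[1/(2N), 1 - 1/(2N)]` so perfect scores stay finite (the standard edge
#' correction).
#'
#' @param hits,false_alarms Counts.
#' @param n_signal,n_noise Trials per class (default 25 each).
#' @return Numeric d-prime (vectorized).
#' @examples
#' dprime(20, 5) # H = 0.8, FA = 0.2 -> 1.683
#' @export
dprime <- function(hits, false_alarms, n_signal = 25, n_noise = 25) {
  if (any(n_signal == 0) || any(n_noise == 0)) stop("trial counts must be > 0")
  clamp <- function(rate, n) pmin(pmax(rate, 1 / (2 * n)), 1 - 1 / (2 * n))
  h <- clamp(hits / n_signal, n_signal)
  fa <- clamp(false_alarms / n_noise, n_noise)
  stats::qnorm(h) - stats::qnorm(fa)
}

#' Per-subject d-prime table from a trial log
#'
#' @param log Trial-log tibble (see [score_identification()]).
#' @return The score table with a `dprime` column appended.
#' @export
dprime_table <- function(log) {
  counts <- score_identification(log)
  counts$dprime <- dprime(counts$hits, counts$false_alarms,
                          counts$n_signal, counts$n_noise)
  counts
}

#' t tests on d-prime scores
#'
#' Paired (within-subject, across sessions) and independent two-sample
#' (between groups, pooled variance) t tests, with a configurable tail.
#' Zero-variance paired differences are reported as a degenerate case
#' rather than an infinite statistic.
#'
#' @param dprime_tbl A d-prime table (from [dprime_table()]).
#' @param comparison `"paired"` (between two sessions within matched
#'   subjects) or `"independent"` (between groups at one session).
#' @param sessions Length-2 sessions to compare (paired), or the single
#'   session at which the groups are compared (independent).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`; for the paired
#'   case the alternative refers to `session[2] - session[1]`.
#' @return A one-row tibble: `comparison`, `estimate`, `t`, `df`, `p`,
#'   `alternative`, `degenerate`.
#' @export
dprime_t_test <- function(dprime_tbl, comparison = c("paired", "independent"),
                          sessions, alternative = "two.sided") {
  comparison <- match.arg(comparison)
  if (comparison == "paired") {
    stopifnot(length(sessions) == 2)
    a <- dprime_tbl[dprime_tbl$session == sessions[1], c("subject", "dprime")]
    b <- dprime_tbl[dprime_tbl$session == sessions[2], c("subject", "dprime")]
    m <- dplyr::inner_join(a, b, by = "subject", suffix = c("_1", "_2"))
    if (nrow(m) < 2) stop("paired test needs at least 2 matched subjects")
    d <- m$dprime_2 - m$dprime_1
    if (stats::sd(d) < 1e-12 * max(abs(d), 1)) {
      # identical vectors: t = 0, p = 1; constant nonzero difference:
      # variance-zero degenerate case rather than an infinite statistic
      zero_diff <- max(abs(d)) < 1e-12
      return(tibble::tibble(
        comparison = paste0("paired s", sessions[1], " vs s", sessions[2]),
        estimate = mean(d),
        t = if (zero_diff) 0 else NA_real_,
        df = length(d) - 1,
        p = if (zero_diff) 1 else NA_real_,
        alternative = alternative, degenerate = !zero_diff
      ))
    }
    tt <- stats::t.test(m$dprime_2, m$dprime_1, paired = TRUE,
                        alternative = alternative)
    tibble::tibble(
      comparison = paste0("paired s", sessions[1], " vs s", sessions[2]),
      estimate = unname(tt$estimate), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value,
      alternative = alternative, degenerate = FALSE
    )
  } else {
    stopifnot(length(sessions) == 1)
    sub <- dprime_tbl[dprime_tbl$session == sessions, ]
    g1 <- sub$dprime[sub$group == 1]
    g2 <- sub$dprime[sub$group == 2]
    if (length(g1) < 2 || length(g2) < 2) stop("independent test needs n >= 2 per group")
    tt <- stats::t.test(g1, g2, var.equal = TRUE, alternative = alternative)
    tibble::tibble(
      comparison = paste0("independent groups at s", sessions),
      estimate = unname(diff(rev(tt$estimate))), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value,
      alternative = alternative, degenerate = FALSE
    )
  }
}

#' Correlate d-prime with windowed P2 amplitude
#'
#' Pearson correlations between each participant's d-prime and the mean
#' 190-290 ms P2 amplitude, within and across sessions, at Cz and over the
#' temporal-occipital ROI. Two-tailed p from the t transform with
#' `df = n - 2`.
#'
#' @param dprime_tbl d-prime table with `subject`, `session`, `dprime`.
#' @param p2_tbl Windowed-amplitude table from [build_p2_window_table()]
#'   (stimulus-averaged internally).
#' @param session_pairs Tibble or data frame with columns `dprime_session`,
#'   `p2_session`; defaults to all within-session pairings present in both
#'   tables.
#' @return A tibble: `dprime_session`, `p2_session`, `location`, `n`, `r`,
#'   `t`, `df`, `p`, `degenerate`.
#' @export
correlate_dprime_p2 <- function(dprime_tbl, p2_tbl, session_pairs = NULL) {
  p2 <- p2_tbl |>
    dplyr::group_by(.data$subject, .data$session, .data$location) |>
    dplyr::summarise(p2 = mean(.data$p2_window_amplitude), .groups = "drop")
  if (is.null(session_pairs)) {
    common <- intersect(unique(dprime_tbl$session), unique(p2$session))
    session_pairs <- tibble::tibble(dprime_session = common,
                                    p2_session = common)
  }
  purrr::pmap_dfr(session_pairs, function(dprime_session, p2_session) {
    d <- dprime_tbl[dprime_tbl$session == dprime_session,
                    c("subject", "dprime")]
    purrr::map_dfr(unique(p2$location), function(loc) {
      a <- p2[p2$session == p2_session & p2$location == loc,
              c("subject", "p2")]
      m <- dplyr::inner_join(d, a, by = "subject")
      n <- nrow(m)
      if (n < 3 || stats::sd(m$dprime) == 0 || stats::sd(m$p2) == 0) {
        return(tibble::tibble(
          dprime_session = dprime_session, p2_session = p2_session,
          location = loc, n = n, r = NA_real_, t = NA_real_,
          df = n - 2, p = NA_real_, degenerate = TRUE
        ))
      }
      ct <- stats::cor.test(m$dprime, m$p2)
      tibble::tibble(
        dprime_session = dprime_session, p2_session = p2_session,
        location = loc, n = n, r = unname(ct$estimate),
        t = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value,
        degenerate = FALSE
      )
    })
  })
}
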