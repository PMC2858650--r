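#' Planted-effect recovery experiment for the mean-centering task-PLS
#'
#' Simulates replicate studies under the default effect plan (P2 gains of
#' +0.5/+1.0 uV at TP9/IZ/TP10 for sessions 2/3, doubled in group 2; trial
#' noise 1 uV; 10 subjects per group), runs the full preprocessing chain and
#' the mean-centering task-PLS with permutation and bootstrap inference,
#' and reports per replicate the LV1 permutation p-value and the fraction
#' of the stable effect mass — the absolute LV1 saliencies summed over
#' columns whose |BSR| exceeds the threshold — that falls inside the
#' planted 190-290 ms x {TP9, IZ, TP10} set.
#'
#' @param n_replicates Number of simulated studies (default 20).
#' @param trials_per_block Trials per block in each simulated study
#'   (default 40; the evoked averages, not single trials, carry the
#'   analysis, so a reduced trial count changes little beyond runtime).
#' @param n_perm,n_boot Resampling counts (500 each, the analysis defaults).
#' @param threshold Bootstrap-ratio stability threshold (default 3).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return A tibble with one row per replicate: `replicate`, `p_lv1`,
#'   `mass_fraction`, `n_stable_columns`.
#' @export
recovery_experiment <- function(n_replicates = 20, trials_per_block = 40,
                                n_perm = 500, n_boot = 500, threshold = 3,
                                seed = 1L) {
  montage <- default_montage()
  components <- default_components(montage)
  plan <- default_effect_plan()
  planted_electrodes <- c("TP9", "IZ", "TP10")
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- sim_config(sessions = 1:3, trials_per_block = trials_per_block,
                      stimuli = "mba", seed = seed + r)
    study <- simulate_study(cfg, plan, montage, components)
    ev <- preprocess_study(study)
    dat <- assemble_data_matrix(ev, montage)
    fit <- fit_mc_pls(dat)
    perm <- permutation_test(dat, "mean_centering", n_perm = n_perm,
                             seed = seed + 1000L + r)
    boot <- bootstrap_stability(dat, "mean_centering", n_boot = n_boot,
                                seed = seed + 2000L + r,
                                threshold = threshold)
    stable <- abs(boot$bsr[, 1]) > threshold
    mass <- abs(fit$salience_raw[, 1])
    inside <- boot$col_info$electrode %in% planted_electrodes &
      boot$col_info$latency >= 190 & boot$col_info$latency <= 290
    frac <- if (any(stable)) sum(mass[stable & inside]) / sum(mass[stable])
      else NA_real_
    rm(study, ev, dat)
    gc(FALSE)
    tibble::tibble(replicate = r, p_lv1 = perm$p[1], mass_fraction = frac,
                   n_stable_columns = sum(stable))
  })
}

#' Null calibration of the task-PLS permutation test
#'
#' Simulates replicate studies with zero planted effects (a null effect
#' plan) on the small calibration montage and reports the LV1 permutation
#' p-value per replicate; under the null the rejection rate at alpha = 0.05
#' should sit near 0.05.
#'
#' @param n_replicates Number of null studies (default 200).
#' @param trials_per_block Trials per block (default 4; the condition means
#'   drive the test).
#' @param n_perm Permutations per study (default 199).
#' @param seed Base seed.
#' @return A tibble: `replicate`, `p_lv1`.
#' @export
null_calibration_pls <- function(n_replicates = 200, trials_per_block = 4,
                                 n_perm = 199, seed = 1L) {
  montage <- calibration_montage()
  components <- default_components(montage)
  plan <- null_effect_plan()
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- sim_config(sessions = 1:3, trials_per_block = trials_per_block,
                      stimuli = "mba", artifact_rate = 0, seed = seed + r)
    study <- simulate_study(cfg, plan, montage, components)
    ev <- preprocess_study(study)
    dat <- assemble_data_matrix(ev, montage)
    perm <- permutation_test(dat, "mean_centering", n_perm = n_perm,
                             seed = seed + 5000L + r)
    tibble::tibble(replicate = r, p_lv1 = perm$p[1])
  })
}

#' Null calibration of the repeated-measures Session test
#'
#' Draws balanced null tables (subject random intercepts plus independent
#' noise, no session effect) matching the Cz P2 design (2 groups x 10
#' subjects x 2 stimuli x 3 sessions) and reports the Greenhouse-Geisser
#' adjusted p-value of the Session main effect per replicate.
#'
#' @param n_replicates Number of replicates (default 200).
#' @param n_per_group Subjects per group (default 10).
#' @param seed Base seed.
#' @return A tibble: `replicate`, `p_session`.
#' @export
null_calibration_anova <- function(n_replicates = 200, n_per_group = 10,
                                   seed = 1L) {
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    set.seed(seed + r)
    d <- tidyr::expand_grid(
      subject = sprintf("s%02d", seq_len(2 * n_per_group)),
      stimulus = c("mba", "ba"), session = 1:3
    )
    d$group <- ifelse(d$subject %in% sprintf("s%02d", seq_len(n_per_group)),
                      1, 2)
    subj_eff <- stats::setNames(stats::rnorm(2 * n_per_group, 0, 0.5),
                                unique(d$subject))
    d$amplitude <- subj_eff[d$subject] + stats::rnorm(nrow(d))
    fit <- fit_rm_anova(d, "amplitude", between = "group",
                        within = c("stimulus", "session"))
    tibble::tibble(
      replicate = r,
      p_session = fit$table$p_gg[fit$table$effect == "session"]
    )
  })
}

#' Monte-Carlo recovery of d-prime from simulated 2AFC logs
#'
#' @param n_replicates Replicates (default 1000).
#' @param dprime_true True sensitivity (default 1).
#' @param n_trials Trials per log (default 50).
#' @param seed Seed.
#' @return A tibble: `replicate`, `dprime_hat`.
#' @export
dprime_recovery <- function(n_replicates = 1000, dprime_true = 1,
                            n_trials = 50, seed = 1L) {
  set.seed(seed)
  est <- vapply(seq_len(n_replicates), function(r) {
    log <- simulate_behavior(dprime_true, n_trials = n_trials)
    s <- score_identification(log)
    dprime(s$hits, s$false_alarms, s$n_signal, s$n_noise)
  }, 0)
  tibble::tibble(replicate = seq_len(n_replicates), dprime_hat = est)
}

#' Empirical band-pass frequency response
#'
#' Measures the steady-state gain of [filter_band()] at the given
#' frequencies by filtering long sinusoids and fitting the output's
#' quadrature amplitude over the settled half of the signal.
#'
#' @param freqs Frequencies in Hz.
#' @param hp,lp Filter corners.
#' @param duration_s Probe duration in seconds (default 10).
#' @return A tibble: `freq_hz`, `gain_db`.
#' @export
filter_response_db <- function(freqs, hp = 1.0, lp = 20, duration_s = 10) {
  t <- seq(0, duration_s * 1000 - 1) / 1000
  purrr::map_dfr(freqs, function(f) {
    x <- sin(2 * pi * f * t)
    ev <- erp_evoked(matrix(x, 1), seq_along(t) - 1, "CZ")
    y <- filter_band(ev, hp, lp)$data[1, ]
    idx <- seq(length(t) / 2, length(t))
    X <- cbind(sin(2 * pi * f * t[idx]), cos(2 * pi * f * t[idx]))
    b <- stats::coef(stats::lm(y[idx] ~ X - 1))
    tibble::tibble(freq_hz = f, gain_db = 20 * log10(sqrt(sum(b^2))))
  })
}
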