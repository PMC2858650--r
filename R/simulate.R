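#' Configure a synthetic AEP study
#'
#' Collects the design and noise parameters of the synthetic study
#' generator. Defaults mirror the reference study design: two groups of 10
#' subjects, four sessions, two stimuli ("mba", "ba") presented in blocks of
#' 400 trials at 1 kHz with epochs spanning -100..500 ms, a stimulus-internal
#' silence of ~50 ms ("mba") / ~60 ms ("ba") that delays all AEP latencies,
#' spatially correlated Gaussian trial noise, and occasional blink-artifact
#' trials exceeding +/-70 microvolts.
#'
#' @param n_subjects_per_group Subjects per group (default 10).
#' @param sessions Subset of `1:4` (default all four).
#' @param trials_per_block Trials per stimulus block (default 400).
#' @param noise_sd Trial noise standard deviation in microvolts (default 1).
#' @param spatial_noise_corr Inter-electrode noise correlation at unit grid
#'   distance; correlation decays as `corr^distance`. In `[0, 1)`.
#' @param artifact_rate Per-trial probability of a blink-artifact trial,
#'   in `[0, 1)`.
#' @param stimulus_silence Named ms delays of the effective sound onset per
#'   stimulus (default `c(mba = 50, ba = 60)`).
#' @param stimuli Stimuli to simulate.
#' @param subject_amp_sd Between-subject sd of component amplitudes (uV).
#' @param subject_lat_sd Between-subject sd of component latencies (ms).
#' @param session_amp_sd Session-to-session within-subject amplitude
#'   jitter sd (uV), shared across the scalp (a global gain fluctuation).
#' @param session_amp_electrode_sd Session-to-session per-electrode
#'   amplitude jitter sd (uV): spatially heterogeneous session variability,
#'   as produced by cap repositioning and impedance changes between
#'   recording days.
#' @param blink_amplitude Peak blink amplitude on eye channels (uV); must
#'   exceed the 70 uV screening threshold.
#' @param behavior_dprime Planted d-prime per session (named "1".."4").
#' @param behavior_trials Trials per behavioral test (default 50).
#' @param seed Integer seed recorded in all outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_group = 10,
                       sessions = 1:4,
                       trials_per_block = 400,
                       noise_sd = 1,
                       spatial_noise_corr = 0.6,
                       artifact_rate = 0.05,
                       stimulus_silence = c(mba = 50, ba = 60),
                       stimuli = c("mba", "ba"),
                       subject_amp_sd = 0.2,
                       subject_lat_sd = 8,
                       session_amp_sd = 0.2,
                       session_amp_electrode_sd = 0.3,
                       blink_amplitude = 120,
                       behavior_dprime = c(`1` = 0.3, `2` = 0.6,
                                           `3` = 0.45, `4` = 0.35),
                       behavior_trials = 50,
                       seed = 1L) {
  if (n_subjects_per_group < 1 || trials_per_block < 1) {
    stop("config error: counts must be > 0")
  }
  if (!all(sessions %in% 1:4)) {
    stop("config error: sessions must lie in {1, 2, 3, 4}")
  }
  if (artifact_rate < 0 || artifact_rate >= 1) {
    stop("config error: artifact_rate must lie in [0, 1)")
  }
  if (spatial_noise_corr < 0 || spatial_noise_corr >= 1) {
    stop("config error: spatial_noise_corr must lie in [0, 1)")
  }
  if (!all(stimuli %in% names(stimulus_silence))) {
    stop("config error: every stimulus needs a stimulus_silence entry")
  }
  structure(
    list(
      n_subjects_per_group = as.integer(n_subjects_per_group),
      sessions = sort(as.integer(sessions)),
      trials_per_block = as.integer(trials_per_block),
      noise_sd = noise_sd,
      spatial_noise_corr = spatial_noise_corr,
      artifact_rate = artifact_rate,
      stimulus_silence = stimulus_silence,
      stimuli = stimuli,
      subject_amp_sd = subject_amp_sd,
      subject_lat_sd = subject_lat_sd,
      session_amp_sd = session_amp_sd,
      session_amp_electrode_sd = session_amp_electrode_sd,
      blink_amplitude = blink_amplitude,
      behavior_dprime = behavior_dprime,
      behavior_trials = as.integer(behavior_trials),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Noiseless evoked response implied by a component set
#'
#' Sums the component kernels weighted by their topographies, after shifting
#' every latency by the stimulus-internal silence of the given stimulus.
#' The pre-stimulus window (t <= 0) is exactly zero. Eye channels carry no
#' evoked signal.
#'
#' @param components List of [component_spec()] objects with topographies
#'   named by scalp electrode.
#' @param stimulus Stimulus label (must have a silence entry).
#' @param montage Montage tibble.
#' @param time Epoch time axis in ms (default -100..500).
#' @param stimulus_silence Named silence delays in ms.
#' @param gains Optional list with named numeric vectors `p2` and `n1`:
#'   additive per-electrode amplitude gains applied with the P2/N1 kernel
#'   shapes of `components`.
#' @return An [erp_evoked()] (electrodes x samples, noiseless).
#' @export
simulate_evoked_truth <- function(components, stimulus, montage,
                                  time = -100:500,
                                  stimulus_silence = c(mba = 50, ba = 60),
                                  gains = NULL) {
  scalp <- montage$label[!montage$is_eye]
  n_ch <- nrow(montage)
  silence <- stimulus_silence[[stimulus]]
  if (is.null(silence)) stop("no stimulus_silence entry for ", stimulus)
  evoked <- matrix(0, n_ch, length(time),
                   dimnames = list(montage$label, NULL))
  post <- time > 0
  for (comp in components) {
    topo <- comp$topography
    if (is.null(names(topo))) {
      if (length(topo) != length(scalp)) {
        stop("dimension error: topography length (", length(topo),
             ") does not match scalp electrode count (", length(scalp), ")")
      }
      names(topo) <- scalp
    } else if (!all(scalp %in% names(topo))) {
      stop("dimension error: topography is missing electrodes")
    }
    shifted <- comp
    shifted$latency <- comp$latency + silence
    kern <- component_kernel(shifted, time)
    kern[!post] <- 0
    evoked[scalp, ] <- evoked[scalp, ] + outer(unname(topo[scalp]), kern)
  }
  if (!is.null(gains)) {
    for (nm in c("p1", "p2", "n1")) {
      g <- gains[[nm]]
      if (is.null(g) || all(g == 0)) next
      ref <- components[[toupper(nm)]]
      if (is.null(ref)) stop("gain for absent component ", toupper(nm))
      unit <- ref
      unit$amplitude <- if (nm == "n1") -1 else 1
      unit$latency <- ref$latency + silence
      kern <- component_kernel(unit, time)
      kern[!post] <- 0
      lab <- intersect(names(g), scalp)
      evoked[lab, ] <- evoked[lab, ] + outer(unname(g[lab]), kern)
    }
  }
  erp_evoked(evoked, time, montage$label, stimulus = stimulus,
             provenance = "noiseless-truth")
}

#' Simulate a complete synthetic study
#'
#' Generates epoched single-trial EEG for every subject x session x stimulus
#' cell, behavioral 2AFC identification logs, and a ground-truth record.
#' Each trial is the subject's noiseless evoked response plus spatially
#' correlated Gaussian noise; artifact trials additionally carry a blink
#' transient on the eye (and frontal) channels that exceeds the +/-70 uV
#' screening threshold. Identical configurations and seeds give bit-identical
#' datasets.
#'
#' @param cfg A [sim_config()].
#' @param plan An [effect_plan()] (default: [default_effect_plan()]).
#' @param montage Montage tibble.
#' @param components Baseline component set (see [default_components()]).
#' @return An object of class `erp_study`: list with `epochs` (named list of
#'   [epoch_set()]), `behavior` (trial-log tibble), `montage`, `truth`
#'   (realized component parameters, noiseless evokeds, artifact indices,
#'   planted d-prime), `config`, `plan`, `seed`.
#' @export
simulate_study <- function(cfg, plan = default_effect_plan(),
                           montage = default_montage(),
                           components = default_components(montage)) {
  stopifnot(inherits(cfg, "sim_config"), inherits(plan, "effect_plan"))
  validate_montage(montage, require_named = FALSE)
  set.seed(cfg$seed)
  time <- -100:500
  n_ch <- nrow(montage)
  n_samp <- length(time)
  eye_rows <- which(montage$is_eye)
  frontal_rows <- which(!montage$is_eye & montage$y >= 3)

  # spatially correlated noise: corr^distance, mixed through a Cholesky root
  if (cfg$spatial_noise_corr > 0) {
    D <- electrode_distances(montage)
    L <- t(chol(cfg$spatial_noise_corr^D))
  } else {
    L <- NULL
  }

  subjects <- tibble::tibble(
    subject = sprintf("S%02d", seq_len(2 * cfg$n_subjects_per_group)),
    group = rep(1:2, each = cfg$n_subjects_per_group)
  )

  comp_names <- names(components)
  base <- list()
  for (i in seq_len(nrow(subjects))) {
    amps <- lats <- stats::setNames(numeric(length(comp_names)), comp_names)
    for (cn in comp_names) {
      spec <- components[[cn]]
      a <- spec$amplitude + stats::rnorm(1, 0, cfg$subject_amp_sd)
      # keep realized amplitudes on the component's canonical side of zero
      a <- if (spec$amplitude >= 0) max(a, 0) else min(a, 0)
      amps[cn] <- a
      lats[cn] <- spec$latency + stats::rnorm(1, 0, cfg$subject_lat_sd)
    }
    base[[subjects$subject[i]]] <- list(amp = amps, lat = lats)
  }

  # blink transient (eye channels dominate; frontal scalp picks up a fraction)
  blink_kern <- cfg$blink_amplitude * exp(-0.5 * ((time - 150) / 25)^2)

  epochs <- list()
  truth_evoked <- list()
  truth_rows <- list()
  artifact_rows <- list()

  for (i in seq_len(nrow(subjects))) {
    subj <- subjects$subject[i]
    grp <- subjects$group[i]
    for (sess in cfg$sessions) {
      jitter <- stats::rnorm(length(comp_names), 0, cfg$session_amp_sd)
      names(jitter) <- comp_names
      # spatially heterogeneous session jitter, one draw per electrode and
      # component, shared across stimuli within the session
      n_scalp <- sum(!montage$is_eye)
      scalp_labels <- montage$label[!montage$is_eye]
      eps <- lapply(comp_names, function(cn) {
        stats::setNames(stats::rnorm(n_scalp, 0,
                                     cfg$session_amp_electrode_sd),
                        scalp_labels)
      })
      names(eps) <- comp_names
      for (stim in cfg$stimuli) {
        realized <- components
        for (cn in comp_names) {
          a <- base[[subj]]$amp[cn] + jitter[cn]
          a <- if (components[[cn]]$amplitude >= 0) max(a, 0) else min(a, 0)
          realized[[cn]]$amplitude <- unname(a)
          realized[[cn]]$latency <- unname(base[[subj]]$lat[cn])
        }
        gains <- plan_gains(plan, grp, sess, montage$label[!montage$is_eye])
        gains$p1 <- eps[["P1"]]
        if (!is.null(eps[["P2"]])) gains$p2 <- gains$p2 + eps[["P2"]]
        # n1 gains deepen N1 (unit kernel is negative), so the symmetric
        # jitter can be added on the same scale
        if (!is.null(eps[["N1"]])) gains$n1 <- gains$n1 + eps[["N1"]]
        truth <- simulate_evoked_truth(realized, stim, montage, time,
                                       cfg$stimulus_silence, gains)
        key <- paste(subj, sess, stim, sep = "_")
        truth_evoked[[key]] <- truth

        n_tr <- cfg$trials_per_block
        is_artifact <- stats::runif(n_tr) < cfg$artifact_rate
        Z <- matrix(stats::rnorm(n_ch * n_samp * n_tr), n_ch)
        noise <- if (is.null(L)) cfg$noise_sd * Z else cfg$noise_sd * (L %*% Z)
        arr <- aperm(array(noise, c(n_ch, n_samp, n_tr)), c(3, 1, 2))
        arr <- arr + rep(as.vector(truth$data), each = n_tr)
        n_art <- sum(is_artifact)
        if (n_art > 0) {
          blink_mat <- matrix(0, n_ch, n_samp)
          blink_mat[eye_rows, ] <- matrix(blink_kern, length(eye_rows),
                                          n_samp, byrow = TRUE)
          blink_mat[frontal_rows, ] <- 0.25 * matrix(blink_kern,
                                                     length(frontal_rows),
                                                     n_samp, byrow = TRUE)
          idx_art <- which(is_artifact)
          arr[idx_art, , ] <- arr[idx_art, , ] +
            rep(as.vector(blink_mat), each = n_art)
        }
        epochs[[key]] <- epoch_set(arr, time, montage$label, subj, grp, sess,
                                   stim)
        # ground-truth artifact marking applies the +/-70 uV rule to the data
        exceeded <- which(apply(abs(arr) > 70, 1, any))
        if (length(exceeded) > 0) {
          artifact_rows[[key]] <- tibble::tibble(
            subject = subj, group = grp, session = sess, stimulus = stim,
            trial = exceeded
          )
        }
        truth_rows[[key]] <- tibble::tibble(
          subject = subj, group = grp, session = sess, stimulus = stim,
          component = comp_names,
          amplitude = vapply(comp_names, function(cn) realized[[cn]]$amplitude, 0),
          latency = vapply(comp_names, function(cn)
            realized[[cn]]$latency + cfg$stimulus_silence[[stim]], 0)
        )
      }
    }
  }

  behavior <- simulate_study_behavior(cfg, subjects)

  dprime_truth <- tibble::tibble(
    session = cfg$sessions,
    dprime_true = unname(cfg$behavior_dprime[as.character(cfg$sessions)])
  )

  structure(
    list(
      epochs = epochs,
      behavior = behavior,
      montage = montage,
      truth = list(
        components = dplyr::bind_rows(truth_rows),
        evoked = truth_evoked,
        artifacts = dplyr::bind_rows(artifact_rows),
        dprime = dprime_truth,
        plan = plan
      ),
      config = cfg,
      plan = plan,
      seed = cfg$seed
    ),
    class = "erp_study"
  )
}

# behavioral 2AFC logs: group 2 tested every session, group 1 only at the
# retention session (session 4), mirroring the study procedure
simulate_study_behavior <- function(cfg, subjects) {
  logs <- list()
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects$subject[i]
    grp <- subjects$group[i]
    sess_tested <- if (grp == 2) cfg$sessions else intersect(cfg$sessions, 4L)
    for (sess in sess_tested) {
      d_true <- cfg$behavior_dprime[[as.character(sess)]]
      log <- simulate_behavior(d_true, n_trials = cfg$behavior_trials)
      log$subject <- subj
      log$group <- grp
      log$session <- sess
      logs[[paste(subj, sess, sep = "_")]] <- log
    }
  }
  if (length(logs) == 0) {
    return(tibble::tibble(subject = character(), group = integer(),
                          session = integer(), trial = integer(),
                          stimulus = character(), response = character()))
  }
  dplyr::bind_rows(logs)[, c("subject", "group", "session", "trial",
                             "stimulus", "response")]
}

#' @export
print.erp_study <- function(x, ...) {
  cat(sprintf(
    "<erp_study> %d epoch cells, %d subjects/group, sessions %s, stimuli %s, seed %d\n",
    length(x$epochs), x$config$n_subjects_per_group,
    paste(x$config$sessions, collapse = ","),
    paste(x$config$stimuli, collapse = ","), x$seed
  ))
  invisible(x)
}

#' Simulate a 2AFC identification trial log
#'
#' Equal-variance Gaussian observer: on "mba" trials the decision variable is
#' N(d', 1), on "ba" trials N(0, 1); the observer responds "mba" above the
#' criterion (default d'/2, i.e. unbiased). Half the trials are "mba", half
#' "ba", in randomized order.
#'
#' @param dprime_true True sensitivity. `Inf` gives a deterministic observer.
#' @param criterion Decision criterion (default `dprime_true / 2`).
#' @param n_trials Total trials; must be even (default 50, i.e. 25 + 25).
#' @param seed Optional seed.
#' @return A tibble with columns `trial`, `stimulus`, `response`.
#' @export
simulate_behavior <- function(dprime_true, criterion = dprime_true / 2,
                              n_trials = 50, seed = NULL) {
  if (n_trials %% 2 != 0 || n_trials < 2) {
    stop("config error: n_trials must be even and >= 2")
  }
  if (!is.null(seed)) set.seed(seed)
  stimulus <- sample(rep(c("mba", "ba"), each = n_trials / 2))
  if (is.infinite(dprime_true)) {
    response <- stimulus
  } else {
    evidence <- ifelse(stimulus == "mba", dprime_true, 0) +
      stats::rnorm(n_trials)
    response <- ifelse(evidence > criterion, "mba", "ba")
  }
  tibble::tibble(trial = seq_len(n_trials), stimulus = stimulus,
                 response = response)
}
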