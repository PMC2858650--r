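#' Derive module seeds from a master seed
#'
#' One master seed deterministically derives the per-module seeds recorded
#' in every output, keeping all derived seeds below 2^31.
#'
#' @param master Integer master seed.
#' @return Named integer vector of seeds (`simulate`, `permutation`,
#'   `bootstrap`, `behavior`).
#' @export
derive_seeds <- function(master) {
  master <- as.integer(master)
  offsets <- c(simulate = 1L, permutation = 2L, bootstrap = 3L, behavior = 4L)
  seeds <- (as.numeric(master) * 7919 + 104729 * as.numeric(offsets)) %%
    2147483647
  stats::setNames(as.integer(seeds), names(offsets))
}

#' Assemble a full run configuration
#'
#' Bundles the simulation, preprocessing and analysis parameters of one
#' end-to-end run. Every run writes a frozen copy of its resolved
#' configuration alongside its outputs.
#'
#' @param sim A [sim_config()] (its seed is overwritten from `seed`).
#' @param plan An [effect_plan()].
#' @param baseline_window,threshold,hp,lp Preprocessing parameters.
#' @param pls_window PLS analysis window in ms.
#' @param n_perm,n_boot Resampling counts.
#' @param bsr_threshold Bootstrap-ratio stability threshold.
#' @param nr_contrast Non-rotated session contrast.
#' @param peak_windows Named component search windows.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), plan = default_effect_plan(),
                       baseline_window = c(-100, 0), threshold = 70,
                       hp = 1.0, lp = 20, pls_window = c(0, 300),
                       n_perm = 500, n_boot = 500, bsr_threshold = 3,
                       nr_contrast = c(-1, 0, 1),
                       peak_windows = default_peak_windows(),
                       seed = 1L) {
  if (n_perm < 1 || n_boot < 1) stop("config error: resample counts must be >= 1")
  seeds <- derive_seeds(seed)
  sim$seed <- seeds[["simulate"]]
  structure(
    list(sim = sim, plan = plan, baseline_window = baseline_window,
         threshold = threshold, hp = hp, lp = lp, pls_window = pls_window,
         n_perm = n_perm, n_boot = n_boot, bsr_threshold = bsr_threshold,
         nr_contrast = nr_contrast, peak_windows = peak_windows,
         seed = as.integer(seed), seeds = seeds),
    class = "run_config"
  )
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes simulate -> preprocess -> peaks -> PLS -> ANOVAs -> behavior:
#' mean-centering PLS per stimulus, non-rotated PLS per group x stimulus
#' (sessions 1-3), repeated-measures ANOVAs of P2 amplitude and latency at
#' Cz and over the two regions of interest, retention contrasts (session 1
#' vs 4 and 3 vs 4 at the temporal-occipital ROI) when session 4 is
#' simulated, and d-prime scoring with t tests and brain-behavior
#' correlations. With fewer than two sessions the PLS and session ANOVAs
#' are skipped with a notice while peak tables are still produced.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, all tables and
#'   results are written there (see [write_results_bundle()]).
#' @param study Optional pre-simulated `erp_study` (skips simulation).
#' @return A result bundle (list) with elements `config`, `study`,
#'   `evoked`, `rejection_log`, `peaks`, `p2_windows`, `mc_pls`, `nr_pls`,
#'   `anova`, `retention`, `behavior`, `notices`.
#' @export
run_pipeline <- function(config, out_dir = NULL, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  notices <- character()
  if (is.null(study)) study <- simulate_study(config$sim, config$plan)
  evoked <- preprocess_study(study, config$baseline_window, config$threshold,
                             config$hp, config$lp)
  rejection_log <- attr(evoked, "rejection_log")
  peaks <- build_peak_table(
    evoked,
    electrodes = unique(unlist(roi_sets())),
    windows = config$peak_windows
  )
  p2_windows <- build_p2_window_table(evoked)

  sessions <- sort(unique(evoked$session))
  main_sessions <- intersect(sessions, 1:3)
  mc_pls <- list()
  nr_pls <- list()
  anova <- list()
  retention <- list()

  if (length(main_sessions) < 2) {
    notices <- c(notices,
                 "fewer than two sessions: PLS and session ANOVAs skipped")
  } else {
    ev_main <- dplyr::filter(evoked, .data$session %in% main_sessions)
    for (stim in unique(ev_main$stimulus)) {
      key <- paste0("mc_", stim)
      dat <- assemble_data_matrix(ev_main, study$montage, config$pls_window,
                                  stimulus = stim)
      mc_pls[[key]] <- pls_inference(
        dat, "mean_centering", n_perm = config$n_perm, n_boot = config$n_boot,
        seed = config$seeds[["permutation"]], threshold = config$bsr_threshold
      )
      for (grp in sort(unique(ev_main$group))) {
        ev_g <- dplyr::filter(ev_main, .data$group == grp)
        dat_g <- assemble_data_matrix(ev_g, study$montage, config$pls_window,
                                      stimulus = stim)
        contrast <- config$nr_contrast
        if (length(contrast) != nrow(dat_g$conditions)) {
          notices <- c(notices, sprintf(
            "nr contrast length %d != %d sessions for group %d: skipped",
            length(contrast), nrow(dat_g$conditions), grp))
          next
        }
        nr_pls[[paste0("nr_g", grp, "_", stim)]] <- pls_inference(
          dat_g, "non_rotated", contrast = contrast,
          n_perm = config$n_perm, n_boot = config$n_boot,
          seed = config$seeds[["permutation"]] + grp,
          threshold = config$bsr_threshold
        )
      }
    }

    # ROI / Cz ANOVAs over sessions 1-3, separately for amplitude and latency
    pk_main <- dplyr::filter(peaks, .data$component == "P2",
                             .data$session %in% main_sessions)
    rois <- roi_sets()
    # a single-stimulus run drops the one-level Stimulus factor
    stim_within <- if (length(unique(pk_main$stimulus)) > 1) "stimulus"
    for (measure in c("amplitude", "latency")) {
      anova[[paste0("cz_", measure)]] <- fit_rm_anova(
        dplyr::filter(pk_main, .data$electrode == "CZ"),
        dv = measure, between = "group",
        within = c(stim_within, "session")
      )
      for (roi in c("anterior_central", "temporal_occipital")) {
        anova[[paste0(roi, "_", measure)]] <- fit_rm_anova(
          dplyr::filter(pk_main, .data$electrode %in% rois[[roi]]),
          dv = measure, between = "group",
          within = c(stim_within, "session", "electrode")
        )
      }
    }
  }

  if (4 %in% sessions && length(main_sessions) > 0) {
    pk_to <- dplyr::filter(peaks, .data$component == "P2",
                           .data$electrode %in% roi_sets()$temporal_occipital)
    stim_within <- if (length(unique(pk_to$stimulus)) > 1) "stimulus"
    for (ref in intersect(c(1, 3), sessions)) {
      retention[[paste0("s", ref, "_vs_s4")]] <- fit_rm_anova(
        dplyr::filter(pk_to, .data$session %in% c(ref, 4)),
        dv = "amplitude", between = "group",
        within = c(stim_within, "session", "electrode")
      )
    }
  }

  behavior <- NULL
  if (nrow(study$behavior) > 0) {
    dp <- dprime_table(study$behavior)
    tests <- list()
    g2 <- dp[dp$group == 2, ]
    if (all(c(1, 2) %in% g2$session)) {
      tests$s1_vs_s2_one_tailed <-
        dprime_t_test(g2, "paired", c(1, 2), alternative = "greater")
    }
    if (all(c(1, 4) %in% g2$session)) {
      tests$s1_vs_s4 <- dprime_t_test(g2, "paired", c(1, 4))
    }
    if (all(c(3, 4) %in% g2$session)) {
      tests$s3_vs_s4 <- dprime_t_test(g2, "paired", c(3, 4))
    }
    if (4 %in% dp$session && length(unique(dp$group[dp$session == 4])) == 2) {
      tests$groups_at_s4 <- dprime_t_test(dp, "independent", 4)
    }
    correlations <- correlate_dprime_p2(
      dp[dp$group == 2, ],
      dplyr::semi_join(p2_windows, dp[dp$group == 2, ],
                       by = c("subject", "session"))
    )
    behavior <- list(dprime = dp, t_tests = dplyr::bind_rows(tests),
                     correlations = correlations)
  }

  bundle <- list(
    config = config, study = study, evoked = evoked,
    rejection_log = rejection_log, peaks = peaks, p2_windows = p2_windows,
    mc_pls = mc_pls, nr_pls = nr_pls, anova = anova, retention = retention,
    behavior = behavior, notices = notices
  )
  if (!is.null(out_dir)) write_results_bundle(bundle, out_dir)
  bundle
}

# --- containers ------------------------------------------------------------

#' Write / read the epochs container
#'
#' The epochs container is a versioned RDS payload holding the trial array,
#' time axis, labels and metadata of one [epoch_set()]; write-then-read
#' round-trips bit-exactly.
#'
#' @param epochs An [epoch_set()].
#' @param path File path (conventionally `.epochs.rds`).
#' @return `path` invisibly / the restored [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  payload <- list(format = "erpls-epochs", version = 1L,
                  body = unclass(epochs))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "erpls-epochs")) {
    stop("I/O error: not an erpls epochs container: ", path)
  }
  if (!identical(payload$version, 1L)) {
    stop("I/O error: unsupported epochs container version ", payload$version)
  }
  b <- payload$body
  epoch_set(b$data, b$time, b$labels, b$subject, b$group, b$session,
            b$stimulus, b$provenance)
}

#' Write / read a montage table as TSV
#'
#' @param montage Montage tibble.
#' @param path File path.
#' @return `path` invisibly / the validated montage tibble.
#' @export
write_montage <- function(montage, path) {
  readr::write_tsv(montage, path)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  validate_montage(m)
  m
}

#' Serialize PLS results to JSON (scalars) + TSV (salience/BSR table)
#'
#' @param fit An `erpls_pls` (ideally with inference attached).
#' @param stem Output path stem; writes `<stem>.json` and
#'   `<stem>_saliences.tsv`.
#' @return The two paths, invisibly.
#' @export
write_pls_result <- function(fit, stem) {
  stopifnot(inherits(fit, "erpls_pls"))
  meta <- list(
    kind = fit$kind,
    singular_values = fit$s,
    cov_fractions = fit$cov_fraction,
    design_saliences = fit$design_saliences,
    conditions = fit$conditions,
    contrast = fit$contrast,
    permutation_p = if (!is.null(fit$permutation)) fit$permutation$p else NULL,
    bsr_threshold = if (!is.null(fit$bootstrap)) fit$bootstrap$threshold else NULL
  )
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(meta, json_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  tsv_path <- paste0(stem, "_saliences.tsv")
  readr::write_tsv(tidy.erpls_pls(fit, "saliences"), tsv_path)
  invisible(c(json_path, tsv_path))
}

#' Write every table of a pipeline result bundle
#'
#' Emits the frozen run configuration (JSON), rejection log, peak and
#' windowed-amplitude tables, ANOVA tables, PLS results and behavioral
#' tables into `out_dir`. Every file is stamped with the master seed
#' through the configuration record.
#'
#' @param bundle Result of [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_results_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  cfg_json <- list(
    seed = cfg$seed, seeds = as.list(cfg$seeds),
    baseline_window = cfg$baseline_window, threshold = cfg$threshold,
    hp = cfg$hp, lp = cfg$lp, pls_window = cfg$pls_window,
    n_perm = cfg$n_perm, n_boot = cfg$n_boot,
    bsr_threshold = cfg$bsr_threshold, nr_contrast = cfg$nr_contrast,
    peak_windows = cfg$peak_windows,
    sim = unclass(cfg$sim),
    plan = list(gains = cfg$plan$gains,
                retention_decay = cfg$plan$retention_decay)
  )
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  readr::write_tsv(bundle$rejection_log, file.path(out_dir, "rejection_log.tsv"))
  readr::write_tsv(bundle$peaks, file.path(out_dir, "peaks.tsv"))
  readr::write_tsv(bundle$p2_windows, file.path(out_dir, "p2_windows.tsv"))
  write_montage(bundle$study$montage, file.path(out_dir, "montage.tsv"))
  if (nrow(bundle$study$behavior) > 0) {
    readr::write_tsv(bundle$study$behavior, file.path(out_dir, "behavior_trials.tsv"))
  }
  for (nm in names(bundle$mc_pls)) {
    write_pls_result(bundle$mc_pls[[nm]], file.path(out_dir, nm))
  }
  for (nm in names(bundle$nr_pls)) {
    write_pls_result(bundle$nr_pls[[nm]], file.path(out_dir, nm))
  }
  for (nm in names(bundle$anova)) {
    readr::write_tsv(bundle$anova[[nm]]$table,
                     file.path(out_dir, paste0("anova_", nm, ".tsv")))
  }
  for (nm in names(bundle$retention)) {
    readr::write_tsv(bundle$retention[[nm]]$table,
                     file.path(out_dir, paste0("retention_", nm, ".tsv")))
  }
  if (!is.null(bundle$behavior)) {
    readr::write_tsv(bundle$behavior$dprime, file.path(out_dir, "dprime.tsv"))
    readr::write_tsv(bundle$behavior$t_tests, file.path(out_dir, "dprime_t_tests.tsv"))
    readr::write_tsv(bundle$behavior$correlations,
                     file.path(out_dir, "dprime_p2_correlations.tsv"))
  }
  if (length(bundle$notices) > 0) {
    writeLines(bundle$notices, file.path(out_dir, "notices.txt"))
  }
  invisible(out_dir)
}
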