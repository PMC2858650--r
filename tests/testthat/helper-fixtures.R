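# shared small fixtures, built in code at test time

# tiny study on the reduced montage; cached per session so several test
# files can reuse it without re-simulating
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_subjects_per_group = 3, sessions = 1:3, trials_per_block = 6,
        noise_sd = 1, artifact_rate = 0.2, stimuli = "mba", seed = 42
      )
      m <- reduced_montage()
      cache <<- simulate_study(cfg, montage = m,
                               components = default_components(m))
    }
    cache
  }
})

tiny_evoked_tbl <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- preprocess_study(tiny_study())
    cache
  }
})

# an evoked holding an arbitrary matrix, for unit-level contracts
make_evoked <- function(data, labels = paste0("E", seq_len(nrow(data))),
                        time = seq(-100, by = 1, length.out = ncol(data))) {
  erp_evoked(data, time, labels)
}

# balanced long table for ANOVA tests: 2 groups x n_per x within factors
balanced_table <- function(n_per = 4, k_stim = 2, k_sess = 3, seed = 1,
                           effect = 0) {
  set.seed(seed)
  d <- tidyr::expand_grid(
    subject = sprintf("s%02d", seq_len(2 * n_per)),
    stimulus = letters[seq_len(k_stim)],
    session = seq_len(k_sess)
  )
  d$group <- ifelse(d$subject %in% sprintf("s%02d", seq_len(n_per)), 1, 2)
  d$y <- stats::rnorm(nrow(d)) +
    effect * d$session * (d$group == 2)
  d
}
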