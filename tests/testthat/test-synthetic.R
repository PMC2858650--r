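test_that("component kernel peaks at the specified latency and amplitude", {
  topo <- c(CZ = 1)
  spec <- component_spec("P2", latency = 230, width = 35, amplitude = 2,
                         topography = topo)
  w <- component_kernel(spec, 0:500)
  expect_equal(which.max(w) - 1, 230)
  expect_equal(max(w), 2)
  # decays below 1% of peak beyond 3 widths
  expect_lt(max(abs(w[abs(0:500 - 230) > 3 * 35])), 0.01 * 2)
  # zero amplitude -> all-zero waveform
  spec0 <- component_spec("P2", 230, 35, 0, topo)
  expect_equal(component_kernel(spec0, 0:500), rep(0, 501))
})

test_that("kernels with disjoint supports sum without interference", {
  topo <- c(CZ = 1)
  a <- component_spec("P1", latency = 100, width = 10, amplitude = 1.5, topography = topo)
  b <- component_spec("P2", latency = 300, width = 10, amplitude = 2.5, topography = topo)
  t <- 0:500
  w <- component_kernel(a, t) + component_kernel(b, t)
  # peaks recoverable independently (closed-form evaluation as oracle)
  expect_equal(w[t == 100], 1.5, tolerance = 1e-6)
  expect_equal(w[t == 300], 2.5, tolerance = 1e-6)
  expect_equal(t[which.max(w * (t < 200))], 100)
})

test_that("invalid component specs are rejected", {
  expect_error(component_spec("P2", 230, -1, 2, c(CZ = 1)), "width")
  expect_error(component_spec("N1", 110, 25, 2, c(CZ = 1)), "N1")
  expect_error(component_spec("P1", 60, 20, -1, c(CZ = 1)), "P1")
  expect_error(component_spec("P2", 230, 35, 2, c(CZ = 1.5)), "topography")
})

test_that("noiseless evoked is the topography-weighted kernel sum, zero pre-stimulus", {
  m <- reduced_montage()
  comps <- default_components(m)
  # all amplitudes zero -> identically zero evoked
  z <- lapply(comps, function(cs) { cs$amplitude <- 0; cs })
  ev0 <- simulate_evoked_truth(z, "mba", m)
  expect_equal(max(abs(ev0$data)), 0)
  # P2-only subject: evoked at electrode e equals kernel x topography[e]
  p2only <- list(P2 = comps$P2)
  ev <- simulate_evoked_truth(p2only, "mba", m)
  kern <- component_kernel(
    component_spec("P2", comps$P2$latency + 50, comps$P2$width,
                   comps$P2$amplitude, comps$P2$topography),
    -100:500
  )
  kern[-100:500 <= 0] <- 0
  for (el in c("CZ", "TP9")) {
    expect_equal(ev$data[ev$labels == el, ],
                 kern * comps$P2$topography[[el]], tolerance = 1e-12)
  }
  # pre-stimulus window exactly zero
  expect_equal(max(abs(ev$data[, -100:500 <= 0])), 0)
})

test_that("mba and ba noiseless evokeds differ by a pure 10 ms shift", {
  m <- reduced_montage()
  comps <- default_components(m)
  t <- -100:500
  a <- simulate_evoked_truth(comps, "mba", m, t) # 50 ms silence
  b <- simulate_evoked_truth(comps, "ba", m, t)  # 60 ms silence
  keep <- which(t > 10 & t <= 400)
  expect_equal(b$data[, keep + 10], a$data[, keep], tolerance = 1e-12)
})

test_that("simulate_study is bit-deterministic under the same config", {
  cfg <- sim_config(n_subjects_per_group = 2, sessions = 1:2,
                    trials_per_block = 4, stimuli = "mba", seed = 9)
  m <- reduced_montage()
  s1 <- simulate_study(cfg, montage = m, components = default_components(m))
  s2 <- simulate_study(cfg, montage = m, components = default_components(m))
  expect_identical(s1$epochs[[1]]$data, s2$epochs[[1]]$data)
  expect_identical(s1$behavior, s2$behavior)
  expect_identical(s1$truth$components, s2$truth$components)
})

test_that("zero-noise zero-gain study repeats the same trial across sessions", {
  cfg <- sim_config(n_subjects_per_group = 1, sessions = 1:3,
                    trials_per_block = 3, noise_sd = 0, artifact_rate = 0,
                    subject_amp_sd = 0, subject_lat_sd = 0,
                    session_amp_sd = 0, session_amp_electrode_sd = 0,
                    stimuli = "mba", seed = 3)
  m <- reduced_montage()
  st <- simulate_study(cfg, null_effect_plan(), m, default_components(m))
  e1 <- st$epochs[["S01_1_mba"]]$data
  e3 <- st$epochs[["S01_3_mba"]]$data
  expect_equal(e1, e3)
  expect_equal(e1[1, , ], e1[3, , ]) # trials identical too
})

test_that("artifact trial count is binomial and truth marking matches the 70 uV rule", {
  cfg <- sim_config(n_subjects_per_group = 1, sessions = 1,
                    trials_per_block = 400, artifact_rate = 0.1,
                    stimuli = "mba", seed = 11)
  m <- reduced_montage()
  st <- simulate_study(cfg, null_effect_plan(), m, default_components(m))
  art1 <- st$truth$artifacts[st$truth$artifacts$subject == "S01", ]
  expect_gte(nrow(art1), qbinom(0.005, 400, 0.1))
  expect_lte(nrow(art1), qbinom(0.995, 400, 0.1))
  arr <- st$epochs[["S01_1_mba"]]$data
  exceeds <- which(apply(abs(arr) > 70, 1, any))
  expect_identical(sort(art1$trial), sort(exceeds))
})

test_that("planted P2 gain is recovered exactly from noiseless evoked differences", {
  m <- reduced_montage()
  plan <- effect_plan(tibble::tibble(group = 1, session = 3,
                                     electrode = "TP9", p2_gain = 1))
  cfg <- sim_config(n_subjects_per_group = 1, sessions = c(1, 3),
                    trials_per_block = 2, noise_sd = 0, artifact_rate = 0,
                    subject_amp_sd = 0, subject_lat_sd = 0,
                    session_amp_sd = 0, session_amp_electrode_sd = 0,
                    stimuli = "mba", seed = 5)
  st <- simulate_study(cfg, plan, m, default_components(m))
  d <- st$truth$evoked[["S01_3_mba"]]$data - st$truth$evoked[["S01_1_mba"]]$data
  tp9 <- st$truth$evoked[[1]]$labels == "TP9"
  t <- st$truth$evoked[[1]]$time
  expect_equal(max(d[tp9, ]), 1, tolerance = 1e-9)
  expect_equal(t[which.max(d[tp9, ])], 235) # 185 ms + 50 ms silence
  expect_equal(max(abs(d[!tp9, ])), 0)      # gain planted nowhere else
})

test_that("config errors are raised for invalid simulation settings", {
  expect_error(sim_config(sessions = c(1, 5)), "sessions")
  expect_error(sim_config(artifact_rate = 1), "artifact_rate")
  expect_error(sim_config(n_subjects_per_group = 0), "counts")
  expect_error(simulate_behavior(1, n_trials = 51), "even")
})

test_that("simulated 2AFC logs have 25/25 composition and a deterministic limit", {
  log <- simulate_behavior(1.0, n_trials = 50, seed = 1)
  expect_equal(sum(log$stimulus == "mba"), 25)
  expect_equal(sum(log$stimulus == "ba"), 25)
  det <- simulate_behavior(Inf, n_trials = 50, seed = 1)
  s <- score_identification(det)
  expect_equal(s$hits, 25)
  expect_equal(s$false_alarms, 0)
})
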