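# hand-built pls_data for algebraic tests
manual_pls_data <- function(X, group, session, subject) {
  ri <- tibble::tibble(subject = subject, group = group, session = session)
  ci <- tibble::tibble(electrode = paste0("E", seq_len(ncol(X))),
                       latency = seq_len(ncol(X)))
  structure(list(X = X, row_info = ri, col_info = ci,
                 conditions = dplyr::distinct(ri[, c("group", "session")])),
            class = "pls_data")
}

zero_evoked_tbl <- function(n_per_group = 10, sessions = 1:3,
                            montage = default_montage()) {
  t <- -100:500
  cells <- tidyr::expand_grid(
    subject = sprintf("S%02d", seq_len(2 * n_per_group)),
    session = sessions
  )
  cells$group <- ifelse(cells$subject %in%
                          sprintf("S%02d", seq_len(n_per_group)), 1, 2)
  cells$stimulus <- "mba"
  cells$n_trials <- 1
  cells$evoked <- purrr::map2(cells$subject, cells$session, function(su, se) {
    erp_evoked(matrix(0, nrow(montage), length(t)), t, montage$label,
               subject = su, session = se, stimulus = "mba")
  })
  cells
}

test_that("data matrix has the documented shape and round-trips values", {
  m <- default_montage()
  tbl <- zero_evoked_tbl(10, 1:3, m)
  # plant one recognizable value
  ev <- tbl$evoked[[7]]
  ev$data[which(m$label == "TP9"), which(ev$time == 250)] <- 7.5
  tbl$evoked[[7]] <- ev
  dat <- assemble_data_matrix(tbl, m)
  expect_equal(dim(dat$X), c(60, 59 * 301)) # 60 x 17759
  expect_equal(nrow(dat$col_info), 17759)
  # column index maps back to the evoked sample exactly
  col <- which(dat$col_info$electrode == "TP9" & dat$col_info$latency == 250)
  row <- which(dat$row_info$subject == tbl$subject[7] &
                 dat$row_info$session == tbl$session[7])
  expect_equal(dat$X[row, col], 7.5)
  expect_equal(sum(dat$X != 0), 1)
  # rows grouped contiguously by condition
  key <- paste(dat$row_info$group, dat$row_info$session)
  expect_equal(rle(key)$lengths, rep(10, 6))
})

test_that("tiny matrices and stimulus mixing behave per contract", {
  m <- reduced_montage()[1:2, ]
  m$is_eye <- FALSE
  t <- -100:500
  tbl <- tibble::tibble(
    subject = "S01", group = 1, session = 1, stimulus = "mba", n_trials = 1,
    evoked = list(erp_evoked(matrix(1, 2, length(t)), t, m$label))
  )
  dat <- assemble_data_matrix(tbl, m, window = c(0, 2))
  expect_equal(dim(dat$X), c(1, 6))
  tbl2 <- dplyr::bind_rows(tbl, dplyr::mutate(tbl, stimulus = "ba"))
  expect_error(assemble_data_matrix(tbl2, m), "design error")
  expect_silent(assemble_data_matrix(tbl2, m, stimulus = "mba"))
})

test_that("mean-centering subtracts the grand mean of condition means", {
  X <- rbind(c(1, 2), c(3, 4))
  dat <- manual_pls_data(X, group = c(1, 1), session = c(1, 2),
                         subject = c("a", "a"))
  M <- mean_center_conditions(dat)
  expect_equal(unname(M), rbind(c(-1, -1), c(1, 1)))
  expect_lt(max(abs(colSums(M))), 1e-9)
  # translation invariance
  dat2 <- manual_pls_data(X + 100, c(1, 1), c(1, 2), c("a", "a"))
  expect_equal(mean_center_conditions(dat2), M)
  # all condition means equal -> zero matrix
  dat3 <- manual_pls_data(rbind(c(1, 2), c(1, 2)), c(1, 1), c(1, 2),
                          c("a", "a"))
  expect_equal(max(abs(mean_center_conditions(dat3))), 0)
})

test_that("mean-centering PLS returns one LV per condition with exact algebra", {
  # centered matrix [[-1,-1],[1,1]]: s1 = 2, 100% covariance, s2 = 0
  dat <- manual_pls_data(rbind(c(1, 2), c(3, 4)), c(1, 1), c(1, 2),
                         c("a", "a"))
  fit <- fit_mc_pls(dat)
  expect_equal(length(fit$s), 2)
  expect_equal(fit$s[1], 2)
  expect_equal(fit$s[2], 0)
  expect_equal(fit$cov_fraction, c(1, 0))
  # 2 groups x 3 sessions -> exactly 6 LVs
  st <- tiny_study()
  ev <- tiny_evoked_tbl()
  dat6 <- assemble_data_matrix(ev, st$montage)
  fit6 <- fit_mc_pls(dat6)
  expect_equal(length(fit6$s), 6)
  expect_equal(sum(fit6$cov_fraction), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit6$design_saliences), diag(6), tolerance = 1e-9)
  # zero matrix -> degenerate flag
  datz <- manual_pls_data(matrix(0, 4, 3), rep(1, 4), rep(1:2, 2),
                          c("a", "b", "a", "b"))
  fitz <- fit_mc_pls(datz)
  expect_true(fitz$degenerate)
  expect_equal(max(fitz$s), 0)
})

test_that("singular values and saliencies match brute-force SVD on random matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    n_cond <- 6
    p <- 20
    X <- matrix(rnorm(2 * n_cond * p), 2 * n_cond, p)
    dat <- manual_pls_data(
      X,
      group = rep(1:2, each = n_cond),
      session = rep(rep(1:3, each = 2), 2),
      subject = rep(sprintf("s%d", 1:4), each = 3)
    )
    fit <- fit_mc_pls(dat)
    M <- mean_center_conditions(dat)
    sv <- svd(M)
    expect_lt(max(abs(fit$s[1:5] - sv$d[1:5])), 1e-8)
    # reconstruction to 1e-8
    recon <- fit$design_saliences %*% diag(fit$s) %*% t(fit$saliences)
    expect_lt(max(abs(M - recon)), 1e-8)
    # subject scores are data projected on electrode saliencies
    expect_equal(fit$scores, X %*% fit$saliences)
  }
})

test_that("scaling the data scales singular values but not saliencies or BSRs", {
  set.seed(3)
  X <- matrix(rnorm(12 * 8), 12, 8)
  args <- list(group = rep(1:2, each = 6), session = rep(1:3, 4),
               subject = rep(sprintf("s%d", 1:4), each = 3))
  d1 <- manual_pls_data(X, args$group, args$session, args$subject)
  d2 <- manual_pls_data(5 * X, args$group, args$session, args$subject)
  f1 <- fit_mc_pls(d1)
  f2 <- fit_mc_pls(d2)
  expect_equal(f2$s, 5 * f1$s, tolerance = 1e-8)
  expect_lt(max(abs(abs(f2$saliences) - abs(f1$saliences))), 1e-7)
  b1 <- bootstrap_stability(d1, "mean_centering", n_boot = 50, seed = 7)
  b2 <- bootstrap_stability(d2, "mean_centering", n_boot = 50, seed = 7)
  # LV sign is an eigenvector convention and may flip with scale
  expect_equal(abs(b1$bsr), abs(b2$bsr), tolerance = 1e-6)
})

test_that("non-rotated PLS projects onto the normalized contrast", {
  # condition means (0,0), (1,0), (2,0); contrast (-1, 0, 1)
  X <- rbind(c(0, 0), c(1, 0), c(2, 0))
  dat <- manual_pls_data(X, rep(1, 3), 1:3, rep("a", 3))
  fit <- fit_nr_pls(dat, c(-1, 0, 1))
  expect_equal(length(fit$s), 1)
  expect_equal(fit$s, sqrt(sum(c(2, 0)^2)) / sqrt(2))
  expect_equal(abs(fit$saliences[, 1]), c(1, 0))
  # contrast orthogonal to all condition differences -> singular value 0
  fit0 <- fit_nr_pls(manual_pls_data(rbind(c(0, 1), c(1, 1), c(2, 1)),
                                     rep(1, 3), 1:3, rep("a", 3)),
                     c(1, -2, 1))
  expect_equal(fit0$s, 0)
  expect_error(fit_nr_pls(dat, c(1, 1, -1)), "sum to 0")
  expect_error(fit_nr_pls(dat, c(-1, 1)), "length")
})

test_that("permutation p follows the (b+1)/(n+1) counting convention", {
  # constant matrix: all permuted values tie the observed zeros -> p = 1
  datz <- manual_pls_data(matrix(1, 6, 4), rep(1:2, each = 3),
                          rep(1:3, 2), rep(c("a", "b"), each = 3))
  pz <- permutation_test(datz, "mean_centering", n_perm = 19, seed = 1)
  expect_equal(pz$p, rep(1, 6))
  # overwhelming planted effect: observed exceeds every permuted value
  set.seed(9)
  n <- 8
  X <- matrix(rnorm(3 * n * 2, sd = 0.01), 3 * n, 2)
  sess <- rep(1:3, n)
  X[, 1] <- X[, 1] + 10 * sess
  dat <- manual_pls_data(X, rep(1, 3 * n), sess,
                         rep(sprintf("s%d", seq_len(n)), each = 3))
  p <- permutation_test(dat, "non_rotated", contrast = c(-1, 0, 1),
                        n_perm = 500, seed = 2)
  expect_equal(p$p[1], 1 / 501)
  expect_true(all(p$p >= 1 / 501 & p$p <= 1))
  expect_error(permutation_test(dat, "non_rotated", n_perm = 0), "config")
})

test_that("zero resampling variance sends planted-column BSRs to infinity", {
  # two identical subjects per condition cell: bootstrap refits never vary
  means <- rbind(c(0, 0), c(1, 0), c(2, 0))
  X <- means[rep(1:3, each = 2), ]
  dat <- manual_pls_data(X, rep(1, 6), rep(1:3, each = 2),
                         rep(c("a", "b"), 3))
  boot <- bootstrap_stability(dat, "non_rotated", contrast = c(-1, 0, 1),
                              n_boot = 30, seed = 1)
  expect_true(is.infinite(boot$bsr[1, 1]))
  expect_equal(boot$bsr[2, 1], 0) # zero salience, zero variance
  expect_true(boot$stable[1, 1])
  expect_equal(boot$n_redraws, 0L)
})

test_that("tidiers expose LVs, saliences and scores as tibbles", {
  st <- tiny_study()
  dat <- assemble_data_matrix(tiny_evoked_tbl(), st$montage)
  fit <- pls_inference(dat, "mean_centering", n_perm = 19, n_boot = 19,
                       seed = 4)
  lv <- tidy(fit)
  expect_equal(nrow(lv), 6)
  expect_true(all(c("singular_value", "cov_fraction", "p") %in% names(lv)))
  sal <- tidy(fit, "saliences")
  expect_equal(nrow(sal), 6 * nrow(dat$col_info))
  expect_true(all(c("electrode", "latency", "salience", "bsr") %in% names(sal)))
  sc <- tidy(fit, "scores")
  expect_equal(nrow(sc), nrow(dat$X))
  g <- glance(fit)
  expect_equal(g$n_lv, 6)
  p <- autoplot(fit, lv = 1, montage = st$montage)
  expect_s3_class(p, "ggplot")
})
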