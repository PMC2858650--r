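#' Assemble the spatiotemporal PLS data matrix
#'
#' Stacks each subject's evoked response into one row per subject x
#' condition, with columns holding every (electrode, latency) amplitude in
#' the analysis window (default 0-300 ms, i.e. 301 samples at 1 kHz, over
#' the scalp electrodes only). Rows are grouped contiguously by condition
#' (group, then session), subjects in label order within a condition;
#' columns are time-major (all electrodes at the first latency, then all at
#' the next). Exactly one stimulus may enter a matrix, because the two
#' stimuli differ by an obligatory 10 ms latency offset that is not an
#' experimental effect.
#'
#' @param evoked_tbl Evoked tibble from [preprocess_study()], already
#'   filtered to the sessions of interest.
#' @param montage Montage tibble (defines the scalp electrodes and order).
#' @param window Analysis window in ms (default `c(0, 300)`).
#' @param stimulus Stimulus to select; may be omitted when the table holds a
#'   single stimulus.
#' @return An object of class `pls_data`: list with the numeric matrix `X`,
#'   `row_info` (subject, group, session), `col_info` (electrode, latency),
#'   and `conditions` (ordered group x session cells).
#' @export
assemble_data_matrix <- function(evoked_tbl, montage, window = c(0, 300),
                                 stimulus = NULL) {
  stopifnot(is.data.frame(evoked_tbl), "evoked" %in% names(evoked_tbl))
  stims <- unique(evoked_tbl$stimulus)
  if (!is.null(stimulus)) {
    evoked_tbl <- dplyr::filter(evoked_tbl, .data$stimulus == !!stimulus)
    if (nrow(evoked_tbl) == 0) stop("design error: no rows for stimulus ", stimulus)
  } else if (length(stims) > 1) {
    stop("design error: matrix would mix stimuli (",
         paste(stims, collapse = ", "), "); pass `stimulus`")
  }
  evoked_tbl <- dplyr::arrange(evoked_tbl, .data$group, .data$session,
                               .data$subject)
  scalp <- montage$label[!montage$is_eye]
  first <- evoked_tbl$evoked[[1]]
  idx_t <- window_index(first$time, window)
  lat <- first$time[idx_t]
  rows <- purrr::map(evoked_tbl$evoked, function(ev) {
    if (!identical(ev$time, first$time)) stop("design error: evokeds disagree on time axis")
    ridx <- match(scalp, ev$labels)
    if (anyNA(ridx)) stop("design error: evoked is missing scalp electrodes")
    # time-major: column block per latency, electrodes within a block
    as.vector(ev$data[ridx, idx_t])
  })
  X <- do.call(rbind, rows)
  row_info <- evoked_tbl[, c("subject", "group", "session")]
  col_info <- tibble::tibble(
    electrode = rep(scalp, times = length(lat)),
    latency = rep(lat, each = length(scalp))
  )
  conditions <- dplyr::distinct(row_info[, c("group", "session")])
  structure(
    list(X = X, row_info = row_info, col_info = col_info,
         conditions = conditions),
    class = "pls_data"
  )
}

#' @export
print.pls_data <- function(x, ...) {
  cat(sprintf("<pls_data> %d rows x %d columns, %d conditions\n",
              nrow(x$X), ncol(x$X), nrow(x$conditions)))
  invisible(x)
}

# rows x conditions averaging matrix for a given assignment of rows to
# condition cells (1/n_cell entries); `cond_id` is an integer in 1..n_cond
condition_indicator <- function(cond_id, n_cond) {
  n <- length(cond_id)
  A <- matrix(0, n, n_cond)
  A[cbind(seq_len(n), cond_id)] <- 1
  sweep(A, 2, pmax(colSums(A), 1), "/")
}

row_condition_id <- function(data) {
  key <- paste(data$row_info$group, data$row_info$session)
  ckey <- paste(data$conditions$group, data$conditions$session)
  match(key, ckey)
}

#' Mean-centered condition-means matrix
#'
#' Computes each condition's column means and subtracts the (unweighted)
#' grand mean of the condition means; the returned rows sum to the zero
#' vector.
#'
#' @param data A `pls_data` object.
#' @return Numeric matrix conditions x columns.
#' @export
mean_center_conditions <- function(data) {
  stopifnot(inherits(data, "pls_data"))
  n_cond <- nrow(data$conditions)
  if (n_cond < 2) stop("design error: need at least 2 conditions")
  cond_id <- row_condition_id(data)
  if (!all(seq_len(n_cond) %in% cond_id)) {
    stop("design error: empty condition cell")
  }
  A <- condition_indicator(cond_id, n_cond)
  CM <- crossprod(A, data$X)
  sweep(CM, 2, colMeans(CM))
}

# SVD of the centered condition-means matrix via its (small) cross-product;
# returns the full set of n_cond singular triplets, zero-padded when rank
# deficient
centered_svd <- function(M, tol = 1e-12) {
  G <- tcrossprod(M)
  e <- eigen(G, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  s <- sqrt(lam)
  U <- e$vectors
  V <- matrix(0, ncol(M), length(s))
  # relative rank cut: numerically-zero eigenvalues scale with the matrix,
  # so the threshold must too (keeps the decomposition scale-equivariant)
  ok <- lam > tol * max(lam, .Machine$double.xmin)
  if (any(ok)) {
    V[, ok] <- crossprod(M, U[, ok, drop = FALSE]) %*%
      diag(1 / s[ok], sum(ok))
  }
  list(s = s, u = U, v = V)
}

#' Fit a mean-centering task-PLS
#'
#' Singular value decomposition of the mean-centered condition-means matrix,
#' computed through the conditions x conditions cross-product. A 2-group x
#' 3-session design yields exactly 6 latent variables (LVs), each consisting
#' of a singular value, orthonormal design saliencies over conditions, and
#' electrode saliencies over (electrode, latency) columns. Covariance
#' fractions are squared singular values over their sum; subject scores are
#' the projections of the row data onto the electrode saliencies.
#'
#' @param data A `pls_data` object.
#' @return An object of class `erpls_pls` with elements `kind`, `s`
#'   (singular values, descending), `design_saliences` (conditions x LV),
#'   `saliences` (columns x LV, unit norm), `salience_raw` (columns x LV,
#'   scaled by the singular value), `cov_fraction`, `scores` (rows x LV),
#'   `conditions`, `row_info`, `col_info`, `degenerate`.
#' @export
fit_mc_pls <- function(data) {
  stopifnot(inherits(data, "pls_data"))
  n_cond <- nrow(data$conditions)
  if (nrow(data$X) < n_cond) stop("design error: fewer rows than conditions")
  M <- mean_center_conditions(data)
  dec <- centered_svd(M)
  build_pls_result(data, kind = "mean_centering", s = dec$s, u = dec$u,
                   v = dec$v, contrast = NULL)
}

#' Fit a non-rotated (contrast-driven) task-PLS
#'
#' Projects the mean-centered condition means onto one a-priori contrast
#' over conditions (unit-normalized internally; must sum to zero), yielding
#' exactly one latent variable: the electrode salience is the centered
#' matrix transposed times the normalized contrast and the singular value is
#' its norm. The default contrast `(-1, 0, 1)` over sessions 1, 2, 3 tests a
#' linear amplitude increase over sessions.
#'
#' @param data A `pls_data` object (typically one group's sessions).
#' @param contrast Numeric contrast, one weight per condition cell in the
#'   condition ordering of `data`.
#' @return An `erpls_pls` object with a single LV.
#' @export
fit_nr_pls <- function(data, contrast = c(-1, 0, 1)) {
  stopifnot(inherits(data, "pls_data"))
  n_cond <- nrow(data$conditions)
  if (length(contrast) != n_cond) {
    stop("design error: contrast length (", length(contrast),
         ") must equal the number of conditions (", n_cond, ")")
  }
  if (abs(sum(contrast)) > 1e-9) {
    stop("design error: contrast must sum to 0")
  }
  cn <- contrast / sqrt(sum(contrast^2))
  M <- mean_center_conditions(data)
  sal <- as.vector(crossprod(M, cn))
  s <- sqrt(sum(sal^2))
  v <- if (s > 0) matrix(sal / s, ncol = 1) else matrix(0, length(sal), 1)
  build_pls_result(data, kind = "non_rotated", s = s,
                   u = matrix(cn, ncol = 1), v = v, contrast = contrast)
}

build_pls_result <- function(data, kind, s, u, v, contrast) {
  total <- sum(s^2)
  res <- structure(
    list(
      kind = kind,
      s = s,
      design_saliences = u,
      saliences = v,
      salience_raw = sweep(v, 2, s, "*"),
      cov_fraction = if (total > 0) s^2 / total else rep(0, length(s)),
      scores = data$X %*% v,
      conditions = data$conditions,
      row_info = data$row_info,
      col_info = data$col_info,
      contrast = contrast,
      degenerate = total <= 1e-24
    ),
    class = "erpls_pls"
  )
  res
}

#' @export
print.erpls_pls <- function(x, ...) {
  cat(sprintf("<erpls_pls> %s, %d LV(s) over %d conditions x %d columns\n",
              x$kind, length(x$s), nrow(x$conditions), nrow(x$col_info)))
  frac <- sprintf("%.1f%%", 100 * x$cov_fraction)
  cat("  singular values:", paste(signif(x$s, 4), collapse = ", "), "\n")
  cat("  covariance fractions:", paste(frac, collapse = ", "), "\n")
  if (!is.null(x$permutation)) {
    cat("  permutation p:", paste(signif(x$permutation$p, 3), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# --- resampling ------------------------------------------------------------

# singular values for an arbitrary rows->condition assignment, computed from
# the small cross-product; for the non-rotated case only the contrast
# projection is needed
assignment_singular_values <- function(X, cond_id, n_cond, contrast_norm = NULL,
                                       weights = NULL) {
  if (is.null(weights)) {
    A <- condition_indicator(cond_id, n_cond)
  } else {
    n <- length(cond_id)
    A <- matrix(0, n, n_cond)
    A[cbind(seq_len(n), cond_id)] <- weights
    cs <- colSums(A)
    if (any(cs == 0)) return(NULL) # empty cell under resampling
    A <- sweep(A, 2, cs, "/")
  }
  CM <- crossprod(A, X)
  M <- sweep(CM, 2, colMeans(CM))
  if (is.null(contrast_norm)) {
    G <- tcrossprod(M)
    sqrt(pmax(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0))
  } else {
    G <- tcrossprod(M)
    sqrt(max(0, drop(crossprod(contrast_norm, G %*% contrast_norm))))
  }
}

# restricted permutation honoring the repeated-measures design: session
# labels are permuted within each subject and whole subjects are permuted
# across groups
permute_assignment <- function(row_info, conditions, restricted = TRUE) {
  n <- nrow(row_info)
  if (!restricted) {
    perm <- sample.int(n)
    key <- paste(row_info$group[perm], row_info$session[perm])
    return(match(key, paste(conditions$group, conditions$session)))
  }
  subjects <- unique(row_info$subject)
  # permute group assignment across subjects (sizes preserved)
  subj_group <- row_info$group[match(subjects, row_info$subject)]
  new_group <- stats::setNames(sample(subj_group), subjects)
  new_session <- row_info$session
  for (s in subjects) {
    idx <- which(row_info$subject == s)
    new_session[idx] <- sample(row_info$session[idx])
  }
  key <- paste(new_group[row_info$subject], new_session)
  match(key, paste(conditions$group, conditions$session))
}

#' Permutation test of latent-variable strength
#'
#' Recomputes the singular values under permutations of the condition
#' labels and reports, per LV, `p = (#permuted >= observed + 1) /
#' (n_perm + 1)`. The default scheme respects the repeated-measures design:
#' session labels are permuted within subject and whole subjects are
#' permuted across groups; `restricted = FALSE` reorders rows freely.
#'
#' @param data A `pls_data` object.
#' @param kind `"mean_centering"` or `"non_rotated"`.
#' @param contrast Contrast weights (non-rotated only).
#' @param n_perm Number of permutations (default 500).
#' @param seed RNG seed.
#' @param restricted Use the design-respecting scheme (default `TRUE`).
#' @return A tibble with columns `lv`, `singular_value`, `p`.
#' @export
permutation_test <- function(data, kind = c("mean_centering", "non_rotated"),
                             contrast = NULL, n_perm = 500, seed = 1L,
                             restricted = TRUE) {
  stopifnot(inherits(data, "pls_data"))
  kind <- match.arg(kind)
  if (n_perm < 1) stop("config error: n_perm must be >= 1")
  fit <- if (kind == "mean_centering") fit_mc_pls(data) else
    fit_nr_pls(data, contrast %||% c(-1, 0, 1))
  cn <- if (kind == "non_rotated") {
    ct <- contrast %||% c(-1, 0, 1)
    ct / sqrt(sum(ct^2))
  } else NULL
  n_cond <- nrow(data$conditions)
  obs <- fit$s
  set.seed(seed)
  count <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    cid <- permute_assignment(data$row_info, data$conditions, restricted)
    s_perm <- assignment_singular_values(data$X, cid, n_cond, cn)
    count <- count + (s_perm >= obs - 1e-12)
  }
  tibble::tibble(
    lv = seq_along(obs),
    singular_value = obs,
    p = (count + 1) / (n_perm + 1)
  )
}

#' Bootstrap-ratio stability of electrode saliencies
#'
#' Resamples subjects with replacement within each group (keeping every
#' subject's session rows together), refits the decomposition, sign-aligns
#' each bootstrap LV to the original by the sign of the salience dot
#' product, and reports the bootstrap ratio: original salience divided by
#' the standard deviation of the salience over bootstrap refits. Saliencies
#' are used on the singular-value scale (the cross-block structure
#' `M' u`). Columns with `|BSR|` above the threshold (default 3) form the
#' stable-feature mask.
#'
#' @param data A `pls_data` object.
#' @param kind `"mean_centering"` or `"non_rotated"`.
#' @param contrast Contrast weights (non-rotated only).
#' @param n_boot Number of bootstrap samples (default 500).
#' @param seed RNG seed.
#' @param threshold Stability threshold on `|BSR|` (default 3).
#' @return An object of class `erpls_bsr`: list with `bsr` (columns x LV),
#'   `stable` (logical mask), `se` (bootstrap sd), `col_info`, `threshold`,
#'   `n_boot`, `n_redraws`.
#' @export
bootstrap_stability <- function(data, kind = c("mean_centering", "non_rotated"),
                                contrast = NULL, n_boot = 500, seed = 1L,
                                threshold = 3) {
  stopifnot(inherits(data, "pls_data"))
  kind <- match.arg(kind)
  if (n_boot < 1) stop("config error: n_boot must be >= 1")
  fit <- if (kind == "mean_centering") fit_mc_pls(data) else
    fit_nr_pls(data, contrast %||% c(-1, 0, 1))
  cn <- if (kind == "non_rotated") {
    ct <- contrast %||% c(-1, 0, 1)
    matrix(ct / sqrt(sum(ct^2)), ncol = 1)
  } else NULL
  orig <- fit$salience_raw
  n_cond <- nrow(data$conditions)
  cond_id <- row_condition_id(data)
  subjects <- unique(data$row_info$subject)
  subj_group <- data$row_info$group[match(subjects, data$row_info$subject)]
  groups <- unique(subj_group)
  set.seed(seed)
  sum_sal <- matrix(0, nrow(orig), ncol(orig))
  sum_sq <- sum_sal
  n_redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      drawn <- unlist(lapply(groups, function(g) {
        pool <- subjects[subj_group == g]
        sample(pool, length(pool), replace = TRUE)
      }))
      w_subj <- table(factor(drawn, levels = subjects))
      w_row <- as.numeric(w_subj[data$row_info$subject])
      # cell emptiness guard (cannot occur with whole-subject resampling,
      # but kept per contract)
      ok <- all(vapply(seq_len(n_cond), function(k)
        sum(w_row[cond_id == k]) > 0, TRUE))
      if (ok) break
      n_redraws <- n_redraws + 1L
    }
    n <- length(cond_id)
    A <- matrix(0, n, n_cond)
    A[cbind(seq_len(n), cond_id)] <- w_row
    A <- sweep(A, 2, colSums(A), "/")
    CM <- crossprod(A, data$X)
    M <- sweep(CM, 2, colMeans(CM))
    if (kind == "mean_centering") {
      dec <- centered_svd(M)
      sal_b <- crossprod(M, dec$u) # columns x LV, singular-value scaled
      flip <- sign(colSums(sal_b * orig))
      flip[flip == 0] <- 1
      sal_b <- sweep(sal_b, 2, flip, "*")
    } else {
      sal_b <- crossprod(M, cn)
    }
    sum_sal <- sum_sal + sal_b
    sum_sq <- sum_sq + sal_b^2
  }
  se <- sqrt(pmax(sum_sq - sum_sal^2 / n_boot, 0) / (n_boot - 1))
  # catastrophic-cancellation floor: refits that never vary leave an O(eps)
  # residual, which must read as exactly zero resampling variance
  se[se < 1e-7 * abs(sum_sal / n_boot)] <- 0
  bsr <- orig / se
  bsr[se == 0 & orig == 0] <- 0
  bsr[se == 0 & orig != 0] <- sign(orig[se == 0 & orig != 0]) * Inf
  structure(
    list(bsr = bsr, stable = abs(bsr) > threshold, se = se,
         col_info = data$col_info, threshold = threshold, n_boot = n_boot,
         n_redraws = n_redraws),
    class = "erpls_bsr"
  )
}

#' @export
print.erpls_bsr <- function(x, ...) {
  cat(sprintf(
    "<erpls_bsr> %d columns x %d LV(s); %d stable columns at |BSR| > %g (%d bootstraps)\n",
    nrow(x$bsr), ncol(x$bsr), sum(x$stable[, 1]), x$threshold, x$n_boot
  ))
  invisible(x)
}

#' Full task-PLS inference: fit + permutation + bootstrap
#'
#' @inheritParams permutation_test
#' @inheritParams bootstrap_stability
#' @param n_perm,n_boot Resampling counts (500 each by default).
#' @return The fitted `erpls_pls` with `permutation` (tibble) and
#'   `bootstrap` (`erpls_bsr`) attached.
#' @export
pls_inference <- function(data, kind = c("mean_centering", "non_rotated"),
                          contrast = NULL, n_perm = 500, n_boot = 500,
                          seed = 1L, threshold = 3, restricted = TRUE) {
  kind <- match.arg(kind)
  fit <- if (kind == "mean_centering") fit_mc_pls(data) else
    fit_nr_pls(data, contrast %||% c(-1, 0, 1))
  fit$permutation <- permutation_test(data, kind, contrast, n_perm,
                                      seed = seed, restricted = restricted)
  fit$bootstrap <- bootstrap_stability(data, kind, contrast, n_boot,
                                       seed = seed + 1L, threshold = threshold)
  fit
}

# --- tidiers and plots -----------------------------------------------------

#' Tidy a task-PLS fit
#'
#' @param x An `erpls_pls`.
#' @param what `"lv"` (one row per latent variable), `"saliences"` (long
#'   electrode x latency saliencies) or `"scores"` (subject scores).
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.erpls_pls <- function(x, what = c("lv", "saliences", "scores"), ...) {
  what <- match.arg(what)
  if (what == "lv") {
    out <- tibble::tibble(
      lv = seq_along(x$s),
      singular_value = x$s,
      cov_fraction = x$cov_fraction
    )
    if (!is.null(x$permutation)) out$p <- x$permutation$p
    return(out)
  }
  if (what == "saliences") {
    sal <- x$salience_raw
    grid <- tidyr::expand_grid(lv = seq_len(ncol(sal)), i = seq_len(nrow(sal)))
    out <- dplyr::bind_cols(
      grid["lv"],
      x$col_info[grid$i, ],
      tibble::tibble(salience = sal[cbind(grid$i, grid$lv)])
    )
    if (!is.null(x$bootstrap)) {
      out$bsr <- x$bootstrap$bsr[cbind(grid$i, grid$lv)]
      out$stable <- abs(out$bsr) > x$bootstrap$threshold
    }
    return(out)
  }
  dplyr::bind_cols(
    x$row_info,
    tibble::as_tibble(x$scores, .name_repair = ~ paste0("lv", seq_along(.x)))
  )
}

#' One-line summary of a task-PLS fit
#'
#' @param x An `erpls_pls`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @exportS3Method generics::glance
glance.erpls_pls <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_lv = length(x$s),
    n_conditions = nrow(x$conditions),
    n_columns = nrow(x$col_info),
    lv1_singular_value = x$s[1],
    lv1_cov_fraction = x$cov_fraction[1],
    lv1_p = if (!is.null(x$permutation)) x$permutation$p[1] else NA_real_,
    degenerate = x$degenerate
  )
}

#' Salience image of a task-PLS latent variable
#'
#' Electrode x time heat map of the (singular-value scaled) saliencies for
#' one LV, electrodes ordered by sagittal layer; columns whose bootstrap
#' ratio exceeds the threshold are overlaid as points when bootstrap results
#' are attached.
#'
#' @param object An `erpls_pls` (ideally from [pls_inference()]).
#' @param lv Latent variable to draw (default 1).
#' @param montage Montage used for layer ordering (default
#'   [default_montage()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.erpls_pls <- function(object, lv = 1, montage = default_montage(),
                               ...) {
  df <- tidy.erpls_pls(object, "saliences")
  df <- dplyr::filter(df, .data$lv == !!lv)
  ord <- montage[!montage$is_eye, ]
  ord <- ord[order(ord$layer, -ord$y), ]
  df$electrode <- factor(df$electrode, levels = ord$label)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$latency, y = .data$electrode,
                                        fill = .data$salience)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "Time (ms)", y = NULL,
                  fill = "Salience",
                  title = sprintf("LV %d (%.1f%% covariance)", lv,
                                  100 * object$cov_fraction[lv])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 4))
  if ("stable" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(df, .data$stable),
      shape = 4, size = 0.3, colour = "black"
    )
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
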