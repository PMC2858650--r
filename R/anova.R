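#' Greenhouse-Geisser epsilon from a contrast-score covariance
#'
#' For a within-subject effect with orthonormalized contrast scores whose
#' d x d covariance matrix is `sigma`, the sphericity correction is
#' `epsilon = tr(sigma)^2 / (d * sum(sigma^2))` (equivalently
#' `(sum lambda)^2 / (d * sum lambda^2)` over the eigenvalues), clamped to
#' `[1/d, 1]`. A two-level factor (d = 1) always gives 1; a rank-1
#' covariance at d = 2 gives the lower bound 0.5.
#'
#' @param sigma Covariance matrix of the orthonormalized contrast scores.
#' @return Epsilon in `[1/d, 1]`; attribute `"clamped"` flags a degenerate
#'   (near-singular / zero-variance) covariance forced to the lower bound.
#' @export
gg_epsilon <- function(sigma) {
  sigma <- as.matrix(sigma)
  d <- nrow(sigma)
  if (d < 1) stop("sigma must have at least one contrast")
  tr <- sum(diag(sigma))
  ss <- sum(sigma^2)
  if (ss <= 0 || tr <= 0) {
    eps <- 1 / d
    attr(eps, "clamped") <- TRUE
    return(eps)
  }
  eps <- tr^2 / (d * ss)
  clamped <- eps < 1 / d || eps > 1
  eps <- min(max(eps, 1 / d), 1)
  attr(eps, "clamped") <- clamped
  eps
}

# orthonormal contrast matrix for a k-level factor (columns orthonormal and
# orthogonal to the constant)
orthonormal_contrasts <- function(k) {
  if (k < 2) stop("factor needs >= 2 levels")
  H <- stats::contr.helmert(k)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Balanced repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits a fully crossed, balanced design with one optional between-subject
#' factor and one or more within-subject factors. Sums of squares are
#' computed via orthonormal within-subject contrasts, each effect tested
#' against the error of its own stratum; within-subject effects with more
#' than one numerator degree of freedom receive the Greenhouse-Geisser
#' epsilon from the pooled covariance of their contrast scores. Reported
#' are uncorrected degrees of freedom with GG-adjusted p-values, plus
#' partial eta squared per effect. Unbalanced or incomplete designs are an
#' error: no imputation is attempted.
#'
#' @param data Long-format tibble, one row per subject x within-cell.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param between Optional name of the between-subject factor column.
#' @param within Character vector of within-subject factor columns.
#' @return An object of class `rm_anova` whose `table` element is a tibble
#'   with columns `effect`, `ss`, `df1`, `ss_error`, `df2`, `statistic`
#'   (F), `epsilon`, `p_uncorrected`, `p_gg`, `partial_eta_sq`,
#'   `epsilon_clamped`.
#' @export
fit_rm_anova <- function(data, dv, subject = "subject", between = NULL,
                         within) {
  stopifnot(is.data.frame(data), length(within) >= 1)
  cols <- c(dv, subject, between, within)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("data is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- data[, cols]
  df[[subject]] <- factor(df[[subject]])
  for (f in c(between, within)) df[[f]] <- factor(df[[f]])
  if (anyNA(df[[dv]]) || !all(is.finite(df[[dv]]))) {
    stop("dependent variable must be finite")
  }

  levs <- lapply(within, function(f) levels(df[[f]]))
  names(levs) <- within
  k <- vapply(levs, length, 0L)
  n_cells <- prod(k)

  # subject x cell matrix, cells ordered with the first within factor slowest
  cell_key <- function(d) {
    keys <- lapply(within, function(f) d[[f]])
    idx <- 0
    for (f in within) idx <- idx * length(levs[[f]]) + (as.integer(d[[f]]) - 1)
    idx + 1
  }
  df$.cell <- cell_key(df)
  counts <- table(df[[subject]], df$.cell)
  if (any(counts != 1) || ncol(counts) != n_cells) {
    stop("unbalanced design: every subject must appear in every within-cell exactly once")
  }
  subjects <- levels(df[[subject]])
  n_subj <- length(subjects)
  df <- df[order(df[[subject]], df$.cell), ]
  Y <- matrix(df[[dv]], nrow = n_subj, ncol = n_cells, byrow = TRUE)

  if (!is.null(between)) {
    grp_of <- df[[between]][match(subjects, df[[subject]])]
    if (length(unique(table(grp_of))) != 1) {
      stop("unbalanced design: groups must have equal sizes")
    }
  } else {
    grp_of <- factor(rep("all", n_subj))
  }
  groups <- levels(droplevels(grp_of))
  n_grp <- length(groups)
  if (n_subj <= n_grp) stop("need more subjects than groups")

  Q <- lapply(within, function(f) orthonormal_contrasts(k[[f]]))
  names(Q) <- within
  u <- lapply(within, function(f) matrix(1 / sqrt(k[[f]]), k[[f]], 1))
  names(u) <- within

  rows <- list()

  project <- function(parts) Reduce(kronecker, parts)

  group_stats <- function(T) {
    tbar_g <- rowsum(T, grp_of) / as.vector(table(grp_of))
    tbar <- colMeans(tbar_g) # unweighted (groups are equal-sized anyway)
    resid <- T - tbar_g[as.integer(droplevels(grp_of)), , drop = FALSE]
    list(tbar = tbar, tbar_g = tbar_g, resid = resid)
  }

  f_row <- function(effect, ss, df1, ss_err, df2, eps, clamped, stratum) {
    ms_err <- ss_err / df2
    stat <- if (ss < 1e-12 * max(1, ss + ss_err)) 0 else ss / df1 / ms_err
    p_un <- if (ms_err <= 0) {
      if (ss <= 1e-12) 1 else 0
    } else stats::pf(stat, df1, df2, lower.tail = FALSE)
    p_gg <- if (df1 > 1 && eps < 1) {
      if (ms_err <= 0) p_un else
        stats::pf(stat, eps * df1, eps * df2, lower.tail = FALSE)
    } else p_un
    tibble::tibble(
      effect = effect, ss = ss, df1 = df1, ss_error = ss_err, df2 = df2,
      statistic = stat, epsilon = eps, p_uncorrected = p_un, p_gg = p_gg,
      partial_eta_sq = if (ss + ss_err > 0) ss / (ss + ss_err) else 0,
      epsilon_clamped = clamped, stratum = stratum
    )
  }

  # between-subject stratum
  C0 <- project(u)
  t0 <- as.vector(Y %*% C0)
  g0 <- group_stats(matrix(t0, ncol = 1))
  ss_err0 <- sum(g0$resid^2)
  df_err0 <- n_subj - n_grp
  if (!is.null(between)) {
    ss_b <- sum(table(grp_of) * (g0$tbar_g[, 1] - mean(g0$tbar_g[, 1]))^2)
    rows[[length(rows) + 1]] <-
      f_row(between, ss_b, n_grp - 1, ss_err0, df_err0, 1, FALSE, "between")
  }

  # within strata: one per nonempty subset of within factors
  subsets <- unlist(lapply(seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    parts <- lapply(within, function(f) if (f %in% S) Q[[f]] else u[[f]])
    C_S <- project(parts)
    d <- ncol(C_S)
    T <- Y %*% C_S
    g <- group_stats(T)
    sigma <- crossprod(g$resid) / (n_subj - n_grp)
    eps <- gg_epsilon(sigma)
    clamped <- isTRUE(attr(eps, "clamped"))
    eps <- as.numeric(eps)
    ss_err <- sum(g$resid^2)
    df_err <- (n_subj - n_grp) * d
    effect_name <- paste(S, collapse = ":")
    ss_S <- n_subj * sum(g$tbar^2)
    rows[[length(rows) + 1]] <-
      f_row(effect_name, ss_S, d, ss_err, df_err, eps, clamped, effect_name)
    if (!is.null(between)) {
      ss_int <- sum(as.vector(table(grp_of)) *
                      rowSums((g$tbar_g - matrix(g$tbar, n_grp, d,
                                                 byrow = TRUE))^2))
      rows[[length(rows) + 1]] <-
        f_row(paste(between, effect_name, sep = ":"), ss_int,
              (n_grp - 1) * d, ss_err, df_err, eps, clamped, effect_name)
    }
  }

  structure(
    list(
      table = dplyr::bind_rows(rows),
      data = tibble::as_tibble(data[, cols]),
      dv = dv, subject = subject, between = between, within = within
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova> dv =", x$dv,
      if (!is.null(x$between)) paste0("; between = ", x$between),
      "; within =", paste(x$within, collapse = ", "), "\n")
  tbl <- x$table
  tbl$ss <- signif(tbl$ss, 4)
  tbl$statistic <- signif(tbl$statistic, 4)
  tbl$p_gg <- signif(tbl$p_gg, 3)
  print(as.data.frame(
    tbl[, c("effect", "df1", "df2", "statistic", "epsilon", "p_gg",
            "partial_eta_sq")]
  ), row.names = FALSE)
  invisible(x)
}

#' Tidy a repeated-measures ANOVA table
#'
#' @param x An `rm_anova` fit.
#' @param ... Unused.
#' @return The effect table as a tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.rm_anova <- function(x, ...) x$table

#' One-row design summary of an rm_anova fit
#'
#' @param x An `rm_anova` fit.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
#' @exportS3Method generics::glance
glance.rm_anova <- function(x, ...) {
  tibble::tibble(
    dv = x$dv,
    n_subjects = length(unique(x$data[[x$subject]])),
    between = x$between %||% NA_character_,
    within = paste(x$within, collapse = ":"),
    n_effects = nrow(x$table)
  )
}

#' Post-hoc analyses: simple effects and Bonferroni pairwise comparisons
#'
#' With `by` given, performs simple-effect tests: the ANOVA is refitted
#' within each level of the moderating factor (error terms computed within
#' the sliced data) and the requested effect's F test is reported per
#' level, together with Bonferroni-adjusted pairwise comparisons of the
#' effect's levels inside each slice. Without `by`, pairwise comparisons of
#' the effect's marginal means are reported (paired t for within factors,
#' pooled-variance two-sample t for the between factor). Adjusted p-values
#' are the raw p multiplied by the number of comparisons in the family,
#' capped at 1; a single comparison is returned unadjusted.
#'
#' @param fit An `rm_anova` object.
#' @param effect Name of the factor whose effect is probed.
#' @param by Optional moderating factor (for simple effects within an
#'   interaction).
#' @return A list of class `rm_posthoc` with tibbles `simple_effects`
#'   (possibly empty) and `pairwise`.
#' @export
posthoc <- function(fit, effect, by = NULL) {
  stopifnot(inherits(fit, "rm_anova"))
  all_factors <- c(fit$between, fit$within)
  if (!effect %in% all_factors) stop("unknown effect: ", effect)
  if (!is.null(by) && !by %in% all_factors) stop("unknown moderator: ", by)

  simple <- tibble::tibble()
  pairwise <- list()
  if (is.null(by)) {
    pairwise[[1]] <- pairwise_comparisons(fit$data, fit, effect, slice = NULL)
  } else {
    for (lv in levels(factor(fit$data[[by]]))) {
      sliced <- fit$data[fit$data[[by]] == lv, , drop = FALSE]
      between2 <- if (identical(by, fit$between)) NULL else fit$between
      within2 <- setdiff(fit$within, by)
      if (effect %in% within2 || identical(effect, between2)) {
        refit <- fit_rm_anova(sliced, fit$dv, fit$subject, between2, within2)
        row <- refit$table[refit$table$effect == effect, ]
        row <- dplyr::mutate(row, moderator = by, level = lv,
                             .before = 1)
        simple <- dplyr::bind_rows(simple, row)
        sub_fit <- refit
      } else {
        sub_fit <- fit
      }
      pairwise[[length(pairwise) + 1]] <-
        dplyr::mutate(
          pairwise_comparisons(sliced, fit, effect, slice = lv),
          moderator = by, level = lv, .before = 1
        )
    }
  }
  structure(
    list(simple_effects = simple, pairwise = dplyr::bind_rows(pairwise),
         effect = effect, by = by),
    class = "rm_posthoc"
  )
}

# Bonferroni pairwise comparisons of a factor's marginal means
pairwise_comparisons <- function(data, fit, effect, slice = NULL) {
  dv <- fit$dv
  subj <- fit$subject
  lev <- levels(factor(data[[effect]]))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  m <- length(pairs)
  rows <- purrr::map_dfr(pairs, function(pr) {
    if (identical(effect, fit$between)) {
      a <- marginal_means(data, dv, subj, effect, pr[1])
      b <- marginal_means(data, dv, subj, effect, pr[2])
      tt <- stats::t.test(a$m, b$m, var.equal = TRUE)
      est <- unname(diff(rev(tt$estimate)))
    } else {
      a <- marginal_means(data, dv, subj, effect, pr[1])
      b <- marginal_means(data, dv, subj, effect, pr[2])
      mm <- dplyr::inner_join(a, b, by = "subject", suffix = c("_1", "_2"))
      d <- mm$m_1 - mm$m_2
      if (stats::sd(d) == 0) {
        return(tibble::tibble(
          contrast = paste(pr[1], "-", pr[2]), estimate = mean(d),
          t = NA_real_, df = length(d) - 1, p_raw = if (mean(d) == 0) 1 else 0,
          degenerate = TRUE
        ))
      }
      tt <- stats::t.test(mm$m_1, mm$m_2, paired = TRUE)
      est <- unname(tt$estimate)
    }
    tibble::tibble(
      contrast = paste(pr[1], "-", pr[2]), estimate = est,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, degenerate = FALSE
    )
  })
  rows$n_comparisons <- m
  rows$p_adjusted <- if (m == 1) rows$p_raw else pmin(rows$p_raw * m, 1)
  rows
}

marginal_means <- function(data, dv, subj, effect, level) {
  d <- data[data[[effect]] == level, ]
  out <- d |>
    dplyr::group_by(subject = .data[[subj]]) |>
    dplyr::summarise(m = mean(.data[[dv]]), .groups = "drop")
  out
}

#' @export
print.rm_posthoc <- function(x, ...) {
  if (nrow(x$simple_effects) > 0) {
    cat("Simple effects of", x$effect, "by", x$by, ":\n")
    print(as.data.frame(x$simple_effects[, c("moderator", "level", "effect",
                                             "df1", "df2", "statistic",
                                             "p_gg")]), row.names = FALSE)
  }
  cat("Pairwise comparisons (Bonferroni):\n")
  cols <- intersect(c("moderator", "level", "contrast", "estimate", "t",
                      "p_raw", "p_adjusted"), names(x$pairwise))
  print(as.data.frame(x$pairwise[, cols]), row.names = FALSE)
  invisible(x)
}
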