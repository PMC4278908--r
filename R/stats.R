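#' Two-by-two mixed-design ANOVA with partial eta squared
#'
#' Classical Group (between, 2 levels) x CS-type (within, 2 levels) mixed
#' ANOVA on proportional startle scores, as used for each conditioning
#' phase. Returns the Group main effect, the CS-type main effect and the
#' CS-type x Group interaction with F, degrees of freedom, two-tailed p
#' and partial eta squared (SS_effect / (SS_effect + SS_error)).
#'
#' For a two-level within factor the decomposition reduces to exact
#' closed forms: the between-subject part is a one-way ANOVA on subject
#' means, and the within part is carried by the per-subject difference
#' d = CS+ - CS-. Unbalanced groups are handled with unweighted marginal
#' means (Type III, matching common statistical-package defaults).
#' Participants missing either cell are dropped listwise; the number
#' dropped is recorded in the `n_dropped` attribute.
#'
#' @param table Tibble with one row per participant: a group column (two
#'   levels) and the two cell score columns.
#' @param phase `"acquisition"` or `"extinction"`; selects the default
#'   cell columns `<acq|ext>_prop_csp` / `_csm`.
#' @param group_col,csp_col,csm_col Column names, overriding the
#'   phase-based defaults.
#' @return A tibble of class `startle_anova` with columns `effect`, `ss`,
#'   `ss_error`, `df_num`, `df_den`, `f`, `p`, `eta_p_sq`; attributes `n`
#'   (participants analysed) and `n_dropped`.
#' @export
#' @examples
#' dsn <- cohort_design(seed = 7)
#' scores <- simulate_cohort_scores(dsn)
#' mixed_anova_2x2(scores, phase = "extinction")
mixed_anova_2x2 <- function(table, phase = c("acquisition", "extinction"),
                            group_col = "group", csp_col = NULL, csm_col = NULL) {
  phase <- match.arg(phase)
  pre <- if (phase == "acquisition") "acq" else "ext"
  csp_col <- csp_col %||% paste0(pre, "_prop_csp")
  csm_col <- csm_col %||% paste0(pre, "_prop_csm")
  d <- tibble(
    group = as.character(table[[group_col]]),
    csp = table[[csp_col]],
    csm = table[[csm_col]]
  )
  n0 <- nrow(d)
  d <- d[stats::complete.cases(d), ]
  n_dropped <- n0 - nrow(d)
  groups <- sort(unique(d$group))
  if (length(groups) == 1) {
    # degenerate single-group design: only the within factor is estimable,
    # as a one-way repeated-measures ANOVA (F equals the squared paired t)
    N <- nrow(d)
    diff_i <- d$csp - d$csm
    ss_cs <- N * mean(diff_i)^2 / 2
    ss_err <- sum((diff_i - mean(diff_i))^2) / 2
    f_cs <- ss_cs / (ss_err / (N - 1L))
    eff <- tibble(
      effect = "cs_type", ss = ss_cs, ss_error = ss_err,
      df_num = 1L, df_den = N - 1L, f = f_cs,
      p = stats::pf(f_cs, 1, N - 1L, lower.tail = FALSE),
      eta_p_sq = ss_cs / (ss_cs + ss_err)
    )
    return(tibble::new_tibble(eff, class = "startle_anova",
                              n = N, n_dropped = n_dropped, phase = phase))
  }
  if (length(groups) != 2) {
    abort("exactly two group levels are required", class = "startlekit_stats_error")
  }
  n_g <- unname(vapply(groups, \(g) sum(d$group == g), integer(1)))
  if (any(n_g < 2)) {
    abort("each group needs at least two complete participants",
          class = "startlekit_stats_error")
  }
  N <- nrow(d)

  # between-subject part: one-way ANOVA on subject means (x2 for the two
  # within measurements per subject)
  m_i <- (d$csp + d$csm) / 2
  m_g <- unname(vapply(groups, \(g) mean(m_i[d$group == g]), numeric(1)))
  ss_subj_within <- 2 * sum((m_i - m_g[match(d$group, groups)])^2)
  df_subj <- N - 2L
  # Type III group SS: unweighted contrast of group means
  cg <- m_g[1] - m_g[2]
  ss_group <- 2 * cg^2 / (1 / n_g[1] + 1 / n_g[2])
  f_group <- if (ss_group == 0) 0 else ss_group / (ss_subj_within / df_subj)

  # within-subject part via per-subject differences
  diff_i <- d$csp - d$csm
  d_g <- unname(vapply(groups, \(g) mean(diff_i[d$group == g]), numeric(1)))
  ss_err_within <- sum((diff_i - d_g[match(d$group, groups)])^2) / 2
  ms_err_within <- ss_err_within / df_subj
  # zero-SS effects have F = 0 by convention, even against a zero MS error
  safe_f <- function(ss, ms) if (ss == 0) 0 else ss / ms
  # CS-type main effect: unweighted mean of group difference means
  c_cs <- (d_g[1] + d_g[2]) / 2
  ss_cs <- c_cs^2 / (2 * (1 / (4 * n_g[1]) + 1 / (4 * n_g[2])))
  f_cs <- safe_f(ss_cs, ms_err_within)
  # interaction: difference of the group difference means
  c_int <- d_g[1] - d_g[2]
  ss_int <- c_int^2 / (2 * (1 / n_g[1] + 1 / n_g[2]))
  f_int <- safe_f(ss_int, ms_err_within)

  eff <- tibble(
    effect = c("group", "cs_type", "cs_type:group"),
    ss = c(ss_group, ss_cs, ss_int),
    ss_error = c(ss_subj_within, ss_err_within, ss_err_within),
    df_num = 1L,
    df_den = df_subj,
    f = c(f_group, f_cs, f_int)
  )
  eff$p <- stats::pf(eff$f, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$eta_p_sq <- ifelse(eff$ss == 0, 0, eff$ss / (eff$ss + eff$ss_error))
  out <- tibble::new_tibble(eff, class = "startle_anova",
                            n = N, n_dropped = n_dropped, phase = phase)
  out
}

#' @export
print.startle_anova <- function(x, ...) {
  cat(sprintf("2x2 mixed ANOVA (%s phase): N = %d, dropped = %d\n",
              attr(x, "phase"), attr(x, "n"), attr(x, "n_dropped")))
  df <- as.data.frame(x)
  df$label <- sprintf("F(%d, %d) = %.2f, p = %.3g, eta_p^2 = %.3f",
                      df$df_num, df$df_den, df$f, df$p, df$eta_p_sq)
  print(df[, c("effect", "label")], row.names = FALSE)
  invisible(x)
}

#' @method tidy startle_anova
#' @export
tidy.startle_anova <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance startle_anova
#' @export
glance.startle_anova <- function(x, ...) {
  tibble(
    n = attr(x, "n"), n_dropped = attr(x, "n_dropped"),
    phase = attr(x, "phase"),
    f_interaction = x$f[x$effect == "cs_type:group"],
    p_interaction = x$p[x$effect == "cs_type:group"]
  )
}

t_result <- function(t, df, kind, estimate, n) {
  tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df), kind = kind,
         estimate = estimate, n = n)
}

#' Paired and independent-samples t-tests
#'
#' Thin tibble-returning wrappers of the Student t statistics used
#' throughout the analysis: `paired_t()` on two within-participant
#' measurement vectors, `independent_t()` on two group vectors with the
#' pooled-variance (Student) form by default or Welch via
#' `var_equal = FALSE`. All p-values are two-tailed.
#'
#' @param x,y Numeric vectors (same length and pairing for `paired_t()`).
#' @param var_equal Pooled-variance form if `TRUE` (default), Welch
#'   otherwise.
#' @return A one-row tibble: `t`, `df`, `p`, `kind`, `estimate` (mean
#'   difference), `n`.
#' @export
paired_t <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) {
    abort("need at least two complete pairs", class = "startlekit_stats_error")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    abort("zero variance of paired differences", class = "startlekit_stats_error")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  t_result(unname(ht$statistic), unname(ht$parameter), "paired",
           unname(ht$estimate), length(x))
}

#' @rdname paired_t
#' @export
independent_t <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("need at least two observations per sample",
          class = "startlekit_stats_error")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    abort("zero variance in both samples", class = "startlekit_stats_error")
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  t_result(unname(ht$statistic), unname(ht$parameter),
           if (var_equal) "independent_pooled" else "independent_welch",
           unname(ht$estimate[1] - ht$estimate[2]), length(x) + length(y))
}

#' Independent t-test from printed summary statistics
#'
#' Recomputes a two-sample t from group means, SDs and sizes, so printed
#' demographic tables can be checked without raw data. Pooled-variance
#' (Student) by default; Welch with `var_equal = FALSE`.
#'
#' @param m1,s1,n1 Mean, SD and size of the first group.
#' @param m2,s2,n2 Mean, SD and size of the second group.
#' @param var_equal Pooled if `TRUE`, Welch otherwise.
#' @return A one-row tibble as in [paired_t()].
#' @export
#' @examples
#' independent_t_summary(15.1, 4.8, 37, 17.3, 4.1, 40) # t close to -2.16
independent_t_summary <- function(m1, s1, n1, m2, s2, n2, var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) {
    abort("need n >= 2 per group", class = "startlekit_stats_error")
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) abort("zero pooled variance", class = "startlekit_stats_error")
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    kind <- "independent_pooled"
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    kind <- "independent_welch"
  }
  t_result(t, df, kind, m1 - m2, n1 + n2)
}

#' Pearson correlation
#'
#' Pearson product-moment correlation with df = n - 2 and a two-tailed p.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return A one-row tibble: `r`, `df`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("need at least three complete pairs", class = "startlekit_stats_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("constant input has no defined correlation",
          class = "startlekit_stats_error")
  }
  ht <- stats::cor.test(x, y)
  tibble(r = unname(ht$estimate), df = unname(ht$parameter),
         p = ht$p.value, n = length(x))
}

#' Pearson chi-square on a 2x2 contingency table
#'
#' Pearson chi-square without continuity correction, df = 1.
#'
#' @param counts 2x2 matrix (or coercible) of counts.
#' @return A one-row tibble: `chisq`, `df`, `p`, `n`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(20, 21, 17, 19), 2)) # sex distribution check
chi_square_2x2 <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(2, 2))) {
    abort("counts must be 2x2", class = "startlekit_stats_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero margin in contingency table", class = "startlekit_stats_error")
  }
  # the asymptotic statistic is the defined output even at small expected
  # counts, so the small-count advisory warning is silenced
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(chisq = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, n = sum(m))
}

#' Contingency-awareness classification
#'
#' Maps the post-acquisition CS-identification answers to the standard
#' three-level classification: fully aware (both CS+ and CS- identified
#' correctly), partially aware (at least one correct), unaware (none
#' correct).
#'
#' @param cs_plus_correct,cs_minus_correct Logical vectors (recycled to
#'   common length).
#' @return Character vector in `{"fully_aware", "partially_aware",
#'   "unaware"}`.
#' @export
classify_awareness <- function(cs_plus_correct, cs_minus_correct) {
  n <- max(length(cs_plus_correct), length(cs_minus_correct))
  a <- rep_len(as.logical(cs_plus_correct), n)
  b <- rep_len(as.logical(cs_minus_correct), n)
  dplyr::case_when(
    a & b ~ "fully_aware",
    a | b ~ "partially_aware",
    .default = "unaware"
  )
}
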