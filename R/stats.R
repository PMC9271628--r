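#' Univariate ANCOVA with an age covariate
#'
#' Fits `y ~ age + group` by least squares and tests the group effect with a
#' marginal (type-III) F-test: the full model against the model with group
#' dropped. Partial eta squared is `SS_group / (SS_group + SS_error)`.
#'
#' @param data Data frame with one row per subject.
#' @param y,group,age Column names (strings) of the outcome, the two-level
#'   grouping factor, and the covariate.
#' @return An object of class `ms_ancova`; see [tidy.ms_ancova()] and
#'   [glance.ms_ancova()].
#' @export
ancova_univariate <- function(data, y = "value", group = "group", age = "age") {
  stopifnot(is.data.frame(data), all(c(y, group, age) %in% names(data)))
  df <- data.frame(
    y = as.numeric(data[[y]]),
    group = factor(data[[group]]),
    age = as.numeric(data[[age]])
  )
  if (any(!is.finite(df$y)) || any(!is.finite(df$age))) {
    stop("outcome and covariate must be finite", call. = FALSE)
  }
  if (nlevels(df$group) < 2) stop("need two groups", call. = FALSE)
  if (min(table(df$group)) < 2) stop("need >= 2 subjects per group", call. = FALSE)
  if (stats::var(df$age) == 0 && nlevels(df$group) < 2) {
    stop("singular design", call. = FALSE)
  }
  full <- stats::lm(y ~ age + group, data = df)
  red <- stats::lm(y ~ age, data = df)
  ss_err <- sum(stats::residuals(full)^2)
  ss_grp <- sum(stats::residuals(red)^2) - ss_err
  df_num <- full$rank - red$rank
  df_den <- stats::df.residual(full)
  if (df_num < 1 || df_den < 1) stop("singular design", call. = FALSE)
  f <- (ss_grp / df_num) / (ss_err / df_den)
  f <- max(f, 0)
  p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
  structure(
    list(
      effect = "group", F = f, df_num = df_num, df_den = df_den, p = p,
      partial_eta_sq = if (ss_grp + ss_err > 0) ss_grp / (ss_grp + ss_err) else 0,
      fit = full
    ),
    class = "ms_ancova"
  )
}

#' @export
print.ms_ancova <- function(x, ...) {
  cat(sprintf(
    "ANCOVA %s effect: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
    x$effect, x$df_num, x$df_den, x$F, x$p, x$partial_eta_sq
  ))
  invisible(x)
}

#' Tidy / glance methods for ANCOVA results
#'
#' @param x An `ms_ancova` or `ms_rm_ancova` object.
#' @param ... Unused.
#' @return `tidy()`: one row per tested effect with `effect`, `F`, `df_num`,
#'   `df_den`, `p`, `partial_eta_sq`. `glance()`: a one-row model summary.
#' @export
tidy.ms_ancova <- function(x, ...) {
  tibble::tibble(
    effect = x$effect, F = x$F, df_num = x$df_num, df_den = x$df_den,
    p = x$p, partial_eta_sq = x$partial_eta_sq
  )
}

#' @rdname tidy.ms_ancova
#' @export
glance.ms_ancova <- function(x, ...) {
  tibble::tibble(
    n = length(stats::residuals(x$fit)),
    r_squared = summary(x$fit)$r.squared,
    sigma = summary(x$fit)$sigma
  )
}

#' Mixed-design repeated-measures ANCOVA
#'
#' Univariate mixed-design analysis with one within-subject factor (the four
#' microstate classes), one between-subject factor (group) and a
#' between-subject covariate (age, centered before entry). The between
#' stratum tests group against the subject-to-subject error after adjusting
#' for age (an ANCOVA on subject means); the within stratum tests the class
#' main effect and the class x group interaction against the class x subject
#' error. The Greenhouse-Geisser epsilon of the within-subject covariance is
#' reported, and optionally applied to the within-stratum tests.
#'
#' @param data Long data frame: one row per subject x class.
#' @param y,class,subject,group,age Column names.
#' @param gg_correction Apply the Greenhouse-Geisser correction to the
#'   within-stratum p-values (default `FALSE`; epsilon is reported either
#'   way).
#' @return An object of class `ms_rm_ancova` with a `tidy()` method; effects
#'   are `"group"`, `"class"`, `"class:group"`.
#' @export
rm_ancova <- function(data, y = "value", class = "class", subject = "subject_id",
                      group = "group", age = "age", gg_correction = FALSE) {
  stopifnot(is.data.frame(data), all(c(y, class, subject, group, age) %in% names(data)))
  df <- data.frame(
    y = as.numeric(data[[y]]),
    class = factor(data[[class]]),
    subject = factor(data[[subject]]),
    group = factor(data[[group]]),
    age = as.numeric(data[[age]])
  )
  if (any(!is.finite(df$y))) stop("incomplete outcome values", call. = FALSE)
  k <- nlevels(df$class)
  tab <- table(df$subject, df$class)
  if (any(tab != 1)) {
    stop("each subject needs exactly one value per within-subject level",
      call. = FALSE
    )
  }
  df$age <- df$age - mean(df$age)
  # wide subject x class matrix for means, deviations and epsilon
  wide <- stats::reshape(
    df[, c("subject", "class", "y")],
    idvar = "subject", timevar = "class", direction = "wide"
  )
  ymat <- as.matrix(wide[, -1, drop = FALSE])
  subj_info <- unique(df[, c("subject", "group", "age")])
  subj_info <- subj_info[match(wide$subject, subj_info$subject), ]
  if (k > 1 && all(abs(ymat - rowMeans(ymat)) < 1e-12)) {
    stop("within-subject levels are identical; class effect degenerate",
      call. = FALSE
    )
  }
  n <- nrow(ymat)
  g <- nlevels(df$group)

  # between stratum: ANCOVA on subject means
  means_df <- data.frame(
    value = rowMeans(ymat),
    group = subj_info$group, age = subj_info$age
  )
  between <- ancova_univariate(means_df, "value", "group", "age")
  if (k == 1) {
    # single within-level: the design collapses to the univariate ANCOVA
    res <- tidy.ms_ancova(between)
    return(structure(
      list(table = res, gg_epsilon = 1, gg_correction = gg_correction,
           n_subjects = n, n_levels = 1L),
      class = "ms_rm_ancova"
    ))
  }

  # within stratum: deviations from subject means
  dev <- ymat - rowMeans(ymat)
  grp <- subj_info$group
  grand <- colMeans(dev)
  ss_class <- n * sum(grand^2)
  cellm <- apply(dev, 2, function(col) tapply(col, grp, mean))
  ng <- as.numeric(table(grp))
  ss_int <- sum(ng * rowSums(sweep(cellm, 2, grand)^2))
  ss_tot_w <- sum(dev^2)
  ss_err_w <- ss_tot_w - ss_class - ss_int
  df_class <- k - 1
  df_int <- (k - 1) * (g - 1)
  df_err_w <- (n - g) * (k - 1)
  if (df_err_w < 1) stop("not enough subjects for the within-stratum error", call. = FALSE)
  f_class <- (ss_class / df_class) / (ss_err_w / df_err_w)
  f_int <- (ss_int / df_int) / (ss_err_w / df_err_w)
  eps <- gg_epsilon(ymat)
  adj <- function(fv, d1, d2) {
    e <- if (gg_correction) eps else 1
    stats::pf(fv, d1 * e, d2 * e, lower.tail = FALSE)
  }
  eta <- function(ss_eff, ss_err) if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0
  res <- tibble::tibble(
    effect = c("group", "class", "class:group"),
    F = c(between$F, f_class, f_int),
    df_num = c(between$df_num, df_class, df_int),
    df_den = c(between$df_den, df_err_w, df_err_w),
    p = c(between$p, adj(f_class, df_class, df_err_w), adj(f_int, df_int, df_err_w)),
    partial_eta_sq = c(
      between$partial_eta_sq,
      eta(ss_class, ss_err_w), eta(ss_int, ss_err_w)
    )
  )
  structure(
    list(table = res, gg_epsilon = eps, gg_correction = gg_correction,
         n_subjects = n, n_levels = k),
    class = "ms_rm_ancova"
  )
}

# Greenhouse-Geisser epsilon from the subject x level data matrix
gg_epsilon <- function(ymat) {
  k <- ncol(ymat)
  if (k < 2) return(1)
  s <- stats::cov(ymat)
  cm <- diag(k) - 1 / k
  sc <- cm %*% s %*% cm
  tr <- sum(diag(sc))
  denom <- (k - 1) * sum(sc^2)
  if (denom <= 0) return(1)
  min(1, max(1 / (k - 1), tr^2 / denom))
}

#' @export
print.ms_rm_ancova <- function(x, ...) {
  cat(sprintf(
    "Mixed-design repeated-measures ANCOVA (%d subjects x %d levels), GG epsilon = %.3f%s\n",
    x$n_subjects, x$n_levels, x$gg_epsilon,
    if (x$gg_correction) " (applied)" else ""
  ))
  print(x$table)
  invisible(x)
}

#' @rdname tidy.ms_ancova
#' @export
tidy.ms_rm_ancova <- function(x, ...) {
  x$table
}

#' @rdname tidy.ms_ancova
#' @export
glance.ms_rm_ancova <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_levels = x$n_levels,
    gg_epsilon = x$gg_epsilon, gg_correction = x$gg_correction
  )
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` for an explicit family size `m` (defaults to the
#' number of p-values).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; must be at least `length(p)` when given.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(p)) stop("family size m must be >= length(p)", call. = FALSE)
  pmin(1, m * p)
}

#' Two-sample pooled-variance t-test
#'
#' Classical independent-samples Student t-test (equal variances pooled), as
#' used for demographic comparisons.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return One-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(
        t = 0, df = length(x) + length(y) - 2, p = 1,
        mean_x = mean(x), mean_y = mean(y)
      ))
    }
    stop("zero variance in both samples with unequal means", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
    mean_x = mean(x), mean_y = mean(y)
  )
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Without continuity correction by default, matching how demographic
#' contingency tables are reported in this literature.
#'
#' @param table 2 x 2 matrix of non-negative counts.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `chi_sq`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble::tibble(
    chi_sq = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value
  )
}

#' Group inference over a cohort outcome table
#'
#' Runs the full statistical design over the long outcome table produced by
#' [cohort_outcomes()] and [cohort_omega()]: a mixed-design repeated-measures
#' ANCOVA per microstate parameter (classes as the within factor), post-hoc
#' univariate ANCOVAs per class, univariate ANCOVAs per transition pair and
#' per omega region, all with age as covariate, with Bonferroni adjustment
#' within each declared family (4 classes per parameter; the 12 ordered
#' transition pairs; 3 omega regions).
#'
#' @param outcomes Long tibble with columns `subject_id`, `group`, `age`,
#'   `measure`, `class`, `value`.
#' @param gg_correction Passed to [rm_ancova()].
#' @return A list: `rm` (tibble of repeated-measures effects per measure) and
#'   `univariate` (tibble of per-level ANCOVAs with raw and adjusted p).
#' @export
run_group_stats <- function(outcomes, gg_correction = FALSE) {
  stopifnot(all(c("subject_id", "group", "age", "measure", "class", "value") %in%
    names(outcomes)))
  ms_measures <- intersect(
    c("duration_ms", "occurrence_per_s", "coverage_pct"),
    unique(outcomes$measure)
  )
  rm_rows <- lapply(ms_measures, function(ms) {
    sub <- outcomes[outcomes$measure == ms, ]
    res <- tidy.ms_rm_ancova(rm_ancova(sub, gg_correction = gg_correction))
    res$measure <- ms
    res
  })
  uni_one <- function(sub) {
    tidy.ms_ancova(ancova_univariate(sub))
  }
  uni_family <- function(ms) {
    sub <- outcomes[outcomes$measure == ms, ]
    lvls <- sort(unique(sub$class))
    rows <- lapply(lvls, function(cl) {
      r <- uni_one(sub[sub$class == cl, ])
      r$measure <- ms
      r$class <- cl
      r
    })
    out <- dplyr::bind_rows(rows)
    out$p_adj <- bonferroni_adjust(out$p, m = length(lvls))
    out
  }
  uni_measures <- intersect(
    c(ms_measures, "transition", "omega"),
    unique(outcomes$measure)
  )
  uni <- dplyr::bind_rows(lapply(uni_measures, uni_family))
  list(
    rm = if (length(rm_rows)) dplyr::bind_rows(rm_rows) else tibble::tibble(),
    univariate = uni
  )
}
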