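test_that("identical groups give a null ANCOVA result", {
  d <- data.frame(
    value = rep(c(1, 2, 3, 4), 2),
    group = rep(c("NC", "LLS"), each = 4),
    age = rep(c(61, 65, 70, 75), 2)
  )
  a <- ancova_univariate(d)
  expect_equal(a$F, 0, tolerance = 1e-12)
  expect_equal(a$partial_eta_sq, 0, tolerance = 1e-12)
})

test_that("ANCOVA matches an independent normal-equations solution", {
  # fixed 2x4 fixture
  d <- data.frame(
    value = c(10.2, 11.5, 9.8, 12.1, 13.0, 14.2, 12.8, 15.1),
    group = rep(c("a", "b"), each = 4),
    age = c(62, 68, 71, 75, 63, 67, 70, 76)
  )
  a <- ancova_univariate(d)
  # oracle: explicit least squares on the design matrices
  X_full <- cbind(1, d$age, as.numeric(d$group == "b"))
  X_red <- cbind(1, d$age)
  rss <- function(X, y) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  ss_err <- rss(X_full, d$value)
  ss_grp <- rss(X_red, d$value) - ss_err
  f_oracle <- (ss_grp / 1) / (ss_err / (8 - 3))
  expect_equal(a$F, f_oracle, tolerance = 1e-8)
  expect_equal(a$df_num, 1)
  expect_equal(a$df_den, 5)
  expect_equal(a$partial_eta_sq, ss_grp / (ss_grp + ss_err), tolerance = 1e-10)
  expect_equal(a$p, pf(f_oracle, 1, 5, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("ANCOVA group F agrees with car's type-III table", {
  set.seed(21)
  d <- data.frame(
    value = rnorm(24) + rep(c(0, 0.6), each = 12),
    group = rep(c("a", "b"), each = 12),
    age = runif(24, 60, 90)
  )
  a <- ancova_univariate(d)
  fit <- lm(value ~ age + group, data = d,
    contrasts = list(group = stats::contr.sum)
  )
  ca <- car::Anova(fit, type = 3)
  expect_equal(a$F, ca["group", "F value"], tolerance = 1e-10)
  expect_equal(a$p, ca["group", "Pr(>F)"], tolerance = 1e-10)
})

test_that("with a null covariate the group F approaches the one-way ANOVA F", {
  set.seed(11)
  d <- data.frame(
    value = rnorm(60) + rep(c(0, 0.8), each = 30),
    group = rep(c("a", "b"), each = 30),
    age = runif(60, 60, 90) # independent of y
  )
  a <- ancova_univariate(d)
  f_anova <- summary(aov(value ~ group, data = d))[[1]]["group", "F value"]
  expect_equal(a$F, f_anova, tolerance = 0.15)
})

test_that("the mixed-design ANCOVA reproduces the aov error strata", {
  long <- make_rm_data(n = 16, seed = 2, class_effect = 0.5, interaction = 0.3)
  r <- rm_ancova(long)
  td <- tidy(r)
  long$agec <- long$age - mean(long$age)
  av <- summary(stats::aov(value ~ agec + group * class + Error(subject_id),
    data = long
  ))
  btw <- av[["Error: subject_id"]][[1]]
  wth <- av[["Error: Within"]][[1]]
  expect_equal(td$F[td$effect == "group"], btw["group", "F value"],
    tolerance = 1e-8
  )
  expect_equal(td$F[td$effect == "class"], wth["class", "F value"],
    tolerance = 1e-8
  )
  expect_equal(td$F[td$effect == "class:group"], wth["group:class", "F value"],
    tolerance = 1e-8
  )
  expect_equal(td$df_den[td$effect == "class"], wth["Residuals", "Df"])
  expect_true(r$gg_epsilon >= 1 / 3 && r$gg_epsilon <= 1)
})

test_that("a flat design yields near-zero mixed-design F values", {
  long <- make_rm_data(n = 12, seed = 3, class_effect = 0, interaction = 0)
  long$value <- 5 + 0.001 * rnorm(nrow(long))
  td <- tidy(rm_ancova(long))
  expect_true(all(td$p > 0.01))
})

test_that("identical within-subject columns are rejected as degenerate", {
  long <- make_rm_data(n = 10, seed = 4, class_effect = 0)
  base <- long$value[long$class == "A"]
  for (cl in c("B", "C", "D")) long$value[long$class == cl] <- base
  expect_error(rm_ancova(long), "identical")
})

test_that("a single within-level collapses to the univariate ANCOVA", {
  long <- make_rm_data(n = 12, seed = 5)
  one <- long[long$class == "A", ]
  r <- rm_ancova(one)
  td <- tidy(r)
  expect_equal(nrow(td), 1)
  a <- ancova_univariate(one)
  expect_equal(td$F, a$F, tolerance = 1e-12)
  expect_equal(td$p, a$p, tolerance = 1e-12)
})

test_that("Bonferroni adjustment is m*p capped at one", {
  expect_equal(bonferroni_adjust(0.004, m = 12), 0.048)
  expect_equal(bonferroni_adjust(0.2, m = 12), 1)
  expect_equal(bonferroni_adjust(c(0.01, 0.4)), c(0.02, 0.8))
  expect_equal(bonferroni_adjust(0.03, m = 1), 0.03)
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), "family size")
})

test_that("pooled t-test and chi-square match their references", {
  set.seed(6)
  x <- rnorm(20)
  y <- rnorm(20, 1)
  tt <- two_sample_t(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
  same <- two_sample_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # the demographic gender table: chi-square about 0.035
  tab <- matrix(c(29, 10, 29, 11), 2, byrow = TRUE)
  cs <- chi_square_2x2(tab)
  expect_lt(abs(cs$chi_sq - 0.035), 5e-4)
  expect_equal(cs$chi_sq,
    unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic),
    tolerance = 1e-12
  )
  eq <- chi_square_2x2(matrix(c(10, 20, 10, 20), 2, byrow = TRUE))
  expect_equal(eq$chi_sq, 0, tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "marginal")
})

test_that("partial eta squared grows with the injected effect in simulation means", {
  mean_eta <- vapply(c(0, 0.5, 1, 2), function(delta) {
    mean(vapply(1:50, function(s) {
      set.seed(1000 + s)
      d <- data.frame(
        value = rnorm(40) + rep(c(0, delta), each = 20),
        group = rep(c("a", "b"), each = 20),
        age = runif(40, 60, 90)
      )
      ancova_univariate(d)$partial_eta_sq
    }, 0))
  }, 0)
  expect_true(all(diff(mean_eta) > 0))
  expect_true(all(mean_eta >= 0 & mean_eta <= 1))
})

test_that("group stats run over a full outcome table with adjusted p-values", {
  coh <- generate_group_cohort(seed = 30, synthesize = FALSE)
  out <- truth_outcomes(coh)
  res <- run_group_stats(out)
  expect_true(all(c("duration_ms", "occurrence_per_s", "coverage_pct") %in%
    res$rm$measure))
  expect_true(all(res$univariate$p_adj >= res$univariate$p, na.rm = TRUE))
  trans <- res$univariate[res$univariate$measure == "transition", ]
  expect_equal(nrow(trans), 12)
  expect_equal(trans$p_adj, pmin(1, trans$p * 12), tolerance = 1e-12)
})
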