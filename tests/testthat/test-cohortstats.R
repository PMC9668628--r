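test_that("Levene's test matches an independent implementation", {
  expect_equal(levene_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$statistic, 0)
  cc <- levene_test(rep(2, 5), rep(2, 5))
  expect_equal(cc$statistic, 0); expect_equal(cc$p_value, 1)

  set.seed(9)
  x <- rnorm(40, 0, 1); y <- rnorm(25, 3, 2.5)
  mine <- levene_test(x, y)
  ref <- car::leveneTest(c(x, y), factor(rep(1:2, c(40, 25))),
                         center = mean)
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("unequal spreads at the published sizes are often detected", {
  # true power of the mean-centred Levene test for sd 0.03 vs 0.04 at
  # n = 115/32 is 0.471 (established by a 1000-replicate simulation):
  # far above the 0.05 false-positive rate, but short of a majority
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    levene_test(rnorm(115, 0.54, 0.03), rnorm(32, 0.49, 0.04))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.35)
  expect_lt(mean(hits), 0.60)
})

test_that("the variance gate dispatches to the right t-test", {
  x <- c(1.1, 2.3, 1.9, 2.8); y <- c(3.2, 4.1, 3.7, 4.9)

  # Welch branch against the hand-written formula
  w <- two_sample_test(x, y, alpha_levene = 1)
  expect_match(w$method, "Welch")
  vx <- var(x) / 4; vy <- var(y) / 4
  t_man <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_man <- (vx + vy)^2 / (vx^2 / 3 + vy^2 / 3)
  expect_equal(w$statistic, t_man, tolerance = 1e-6)
  expect_equal(w$df, df_man, tolerance = 1e-6)
  expect_equal(w$p_value, 2 * pt(-abs(t_man), df_man), tolerance = 1e-6)

  # Student branch against the pooled formula
  s <- two_sample_test(x, y, alpha_levene = 0)
  expect_match(s$method, "Student")
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_p <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(s$statistic, t_p, tolerance = 1e-6)
  expect_equal(s$df, 6)

  # identical samples: statistic 0, p 1
  id <- two_sample_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)

  # Welch df never exceeds the pooled df (equal here: equal variances)
  expect_lte(w$df, 6 + 1e-9)
})

test_that("group comparison at the published moments is highly significant", {
  set.seed(1)
  tt <- two_sample_test(rnorm(115, 0.54, 0.03), rnorm(32, 0.49, 0.04))
  expect_lt(tt$p_value, 0.001)
})

test_that("Bonferroni correction clips, preserves order and is monotone", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 4), 1)
  p <- c(0.04, 0.001, 0.2)
  expect_equal(order(bonferroni(p, 3)), order(p))
  expect_error(bonferroni(p, 2), "family size")
  # idempotent on already clipped values (single-test family per value)
  pc <- bonferroni(p, 3)
  expect_equal(vapply(pc, bonferroni, numeric(1), m = 1), pc)
  # monotone in m
  expect_true(all(bonferroni(p, 5) >= bonferroni(p, 3)))
})

test_that("the 2x2 chi-square equals the brute-force statistic", {
  # published sex contingency: 13 f / 19 m patients vs 60 f / 55 m controls
  sexes <- matrix(c(13, 19, 60, 55), 2, 2)
  expect_equal(round(chi2_2x2(sexes)$statistic, 3), 1.336)
  expect_equal(chi2_2x2(sexes)$df, 1)
  expect_gt(chi2_2x2(sexes)$p_value, 0.05)

  expect_equal(chi2_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi2_2x2(matrix(c(20, 10, 10, 20), 2, 2))$statistic,
               20 / 3, tolerance = 1e-10)

  brute <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    m <- matrix(c(a, b, cc, d), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(suppressWarnings(chi2_2x2(m)$statistic), brute(m),
                 tolerance = 1e-10)
  }

  expect_error(chi2_2x2(matrix(c(0, 0, 1, 2), 2, 2)), "margin")
})

test_that("the Mann-Whitney test behaves at its extremes", {
  sep <- mann_whitney(1:10, 21:30)
  expect_equal(unname(sep$statistic), 0)
  expect_lt(sep$p_value, 0.001)
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney type-I error is near nominal", {
  rej <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    mann_whitney(rnorm(30), rnorm(30))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.10)
})

test_that("adjusted effects reduce to the classic d without covariates", {
  mom <- published_group_moments()
  tab <- bilateral_means(simulate_cohort(mom, seed = 21))
  tab$age <- 40; tab$sex <- "m"          # constant covariates
  out <- adjusted_group_effect(cohort_table(tab), "PT_FA")
  x <- tab$PT_FA[tab$group == "HSP"]; y <- tab$PT_FA[tab$group == "HC"]
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
             (length(x) + length(y) - 2))
  expect_equal(out$effect$cohens_d, (mean(x) - mean(y)) / sp,
               tolerance = 1e-6)
  expect_equal(out$effect$basis, "raw")
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(out$test$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("adjusted effects recover an injected one-SD group shift", {
  set.seed(31)
  n1 <- 115; n2 <- 32
  age <- c(round(runif(n1, 20, 65)), round(runif(n2, 20, 65)))
  sexes <- sample(c("f", "m"), n1 + n2, replace = TRUE)
  grp <- rep(c("HC", "HSP"), c(n1, n2))
  y <- 0.5 + 0.001 * age + rnorm(n1 + n2, 0, 0.03) +
    ifelse(grp == "HSP", 0.03, 0)        # +1 residual SD
  tab <- cohort_table(data.frame(id = sprintf("s%03d", 1:(n1 + n2)),
                                 group = grp, age = age, sex = sexes,
                                 PT_FA = y))
  out <- adjusted_group_effect(tab, "PT_FA")
  expect_equal(out$effect$cohens_d, 1, tolerance = 0.2)
  expect_equal(out$effect$band, "large")
  expect_lt(out$test$p_value, 0.001)
})

test_that("null cohorts give small adjusted effects", {
  ds <- vapply(1:20, function(s) {
    set.seed(400 + s)
    n <- 100
    age <- round(runif(n, 20, 65))
    y <- 0.4 + 0.002 * age + rnorm(n, 0, 0.04)
    tab <- cohort_table(data.frame(id = sprintf("s%03d", 1:n),
                                   group = sample(rep(c("HC", "HSP"), n / 2)),
                                   age = age,
                                   sex = sample(c("f", "m"), n, TRUE),
                                   PT_FA = y))
    adjusted_group_effect(tab, "PT_FA")$effect$cohens_d
  }, numeric(1))
  expect_lt(median(abs(ds)), 0.2)
})

test_that("correlation and quadratic regression behave", {
  x <- 1:20
  lin <- correlate(x, 2 * x, "linear")
  expect_equal(lin$r, 1)
  expect_true(all(c("x", "fit", "lwr", "upr") %in% names(lin$band)))

  # independent data: |r| small for most seeds
  rs <- vapply(1:20, function(s) {
    set.seed(500 + s)
    abs(correlate(rnorm(115), rnorm(115), "linear")$r)
  }, numeric(1))
  expect_gt(mean(rs < 0.2), 0.8)

  # pure quadratic on symmetric support: linear r near 0, curvature real
  xs <- seq(-3, 3, length.out = 31)
  ys <- xs^2
  expect_lt(abs(correlate(xs, ys, "linear")$r), 1e-10)
  q <- correlate(xs, ys, "quadratic")
  expect_equal(unname(q$coefficients["I(x^2)"]), 1, tolerance = 1e-8)
  expect_lt(q$p, 1e-6)

  expect_error(correlate(rep(1, 10), rnorm(10)), "zero variance")
})
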