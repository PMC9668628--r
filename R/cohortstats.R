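# Cohort statistics layer: variance-gated two-sample comparisons
# (Levene, then Student or Welch), Bonferroni correction, chi-square and
# Mann-Whitney tests for demographics, covariate-adjusted group effects
# with Cohen's d from estimated marginal means, and correlation /
# quadratic regression against clinical scores.

test_result <- function(method, statistic, df, p_value, adjusted_p = NA_real_,
                        extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(method = method, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value),
                   adjusted_p = adjusted_p), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s: statistic %.4g, df %s, p %.4g%s>\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value,
              if (!is.na(x$adjusted_p)) sprintf(", adj p %.4g", x$adjusted_p)
              else ""))
  invisible(x)
}

#' Levene's test of equal variance (mean-centred)
#'
#' Classic Levene: one-way ANOVA on the absolute deviations from the
#' group means. (The median-centred Brown-Forsythe variant is available
#' via `center = stats::median`.)
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param center centring function, default [mean()].
#' @return A `test_result` (F statistic, df (1, n - 2), p).
#' @export
levene_test <- function(x, y, center = mean) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  z <- c(abs(x - center(x)), abs(y - center(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  if (stats::sd(z) == 0)
    return(test_result("Levene", 0, c(1, length(z) - 2), 1))
  a <- stats::anova(stats::lm(z ~ g))
  test_result("Levene", a$`F value`[1], c(a$Df[1], a$Df[2]), a$`Pr(>F)`[1])
}

#' Variance-gated two-sample comparison
#'
#' Runs the mean-centred Levene test first; if it rejects equal variance
#' at `alpha_levene` the group means are compared with Welch's t-test
#' (Satterthwaite df), otherwise with Student's pooled t-test. Two-sided.
#'
#' @param x,y numeric samples.
#' @param alpha_levene significance level of the variance gate
#'   (default 0.05).
#' @return A `test_result` with extra fields `levene` (the gate result)
#'   and `mean_diff` (`mean(x) - mean(y)`).
#' @export
two_sample_test <- function(x, y, alpha_levene = 0.05) {
  lev <- levene_test(x, y)
  welch <- lev$p_value < alpha_levene
  tt <- stats::t.test(x, y, var.equal = !welch)
  test_result(if (welch) "Welch t" else "Student t",
              tt$statistic, tt$parameter, tt$p.value,
              extra = list(levene = lev,
                           mean_diff = mean(x) - mean(y)))
}

#' Bonferroni correction
#'
#' @param p_values numeric p-values.
#' @param m family size, `>= length(p_values)` (default the length).
#' @return `pmin(1, p_values * m)`, order preserved.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop("family size m must be >= length(p_values)")
  pmin(1, p_values * m)
}

#' Pearson chi-square test on a 2 x 2 table
#'
#' Without continuity correction (df = 1), as used for the sex
#' comparison between groups.
#'
#' @param table 2 x 2 matrix of non-negative counts with positive
#'   margins.
#' @return A `test_result`.
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("table must be 2 x 2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in the table")
  ct <- stats::chisq.test(table, correct = FALSE)
  test_result("chi-square", ct$statistic, ct$parameter, ct$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided, normal approximation with tie correction (the large-sample
#' form used for the age comparison).
#'
#' @param x,y numeric samples, each non-empty.
#' @return A `test_result`; `statistic` is the U statistic.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("empty group")
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  test_result("Mann-Whitney U", wt$statistic, NA_real_, wt$p.value)
}

band_effect <- function(d) {
  ad <- abs(d)
  if (ad >= 0.80) "large" else if (ad >= 0.50) "medium"
  else if (ad >= 0.20) "small" else "negligible"
}

#' Covariate-adjusted group effect and Cohen's d
#'
#' Fits the univariate general linear model
#' `metric ~ age + sex + group`, reports the t-test of the group
#' coefficient, and computes Cohen's d from estimated marginal means
#' (model predictions at the mean age with the sexes balanced) divided
#' by the residual standard deviation. Bands: small |d| 0.20-0.49,
#' medium 0.50-0.79, large >= 0.80. Covariates with no variation are
#' dropped, in which case the result reduces exactly to the unadjusted
#' pooled t-test and classic pooled-SD Cohen's d.
#'
#' @param table a [cohort_table()].
#' @param metric response column name (e.g. `"PT_FA"` after
#'   [bilateral_means()], or any ROI column).
#' @param covariates covariate column names (default age and sex).
#' @return List with `test` (a `test_result`) and `effect` (list
#'   `cohens_d`, `basis`, `band`, `emm` named estimated marginal means).
#' @export
adjusted_group_effect <- function(table, metric, covariates = c("age", "sex")) {
  df <- as.data.frame(table)
  if (!metric %in% names(df)) stop("metric column not found: ", metric)
  keep <- stats::complete.cases(df[c(metric, "group", covariates)])
  df <- df[keep, ]
  df$group <- factor(df$group, levels = c("HC", "HSP"))
  if ("sex" %in% covariates) df$sex <- factor(df$sex, levels = c("f", "m"))
  use <- covariates[vapply(covariates, function(cv)
    length(unique(df[[cv]])) > 1, logical(1))]
  fml <- stats::reformulate(c(use, "group"), response = metric)
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit))))
    stop("collinear design: model is singular")
  sm <- summary(fit)$coefficients
  row <- grep("^groupHSP$", rownames(sm))
  emm <- summary(emmeans::emmeans(fit, "group"))
  mu <- stats::setNames(emm$emmean, as.character(emm$group))
  d <- unname((mu["HSP"] - mu["HC"]) / stats::sigma(fit))
  basis <- if (length(use)) "adjusted-marginal-means" else "raw"
  list(test = test_result("GLM group effect (t)", sm[row, "t value"],
                          fit$df.residual, sm[row, "Pr(>|t|)"]),
       effect = list(cohens_d = d, basis = basis, band = band_effect(d),
                     emm = mu))
}

#' Linear correlation or quadratic regression
#'
#' `kind = "linear"`: Pearson r with a two-sided t-test and a 95 %
#' confidence band of the fitted line. `kind = "quadratic"`: least
#' squares fit of `y ~ x + x^2` with the quadratic-term t-test and the
#' same style of band.
#'
#' @param x,y numeric vectors (n >= 3 linear, >= 4 quadratic).
#' @param kind `"linear"` or `"quadratic"`.
#' @param band_n number of x positions for the confidence band.
#' @return List with `kind`, `r` (linear only), `p`, `coefficients`, and
#'   `band` (data.frame x, fit, lwr, upr).
#' @export
correlate <- function(x, y, kind = c("linear", "quadratic"), band_n = 50L) {
  kind <- match.arg(kind)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  if (kind == "linear") {
    if (length(x) < 3) stop("need n >= 3 for linear correlation")
    ct <- stats::cor.test(x, y)
    fit <- stats::lm(y ~ x)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    if (length(x) < 4) stop("need n >= 4 for quadratic regression")
    fit <- stats::lm(y ~ x + I(x^2))
    sm <- summary(fit)$coefficients
    r <- NA_real_; p <- sm["I(x^2)", "Pr(>|t|)"]
  }
  gx <- seq(min(x), max(x), length.out = band_n)
  pr <- stats::predict(fit, newdata = data.frame(x = gx),
                       interval = "confidence", level = 0.95)
  list(kind = kind, r = r, p = p,
       coefficients = stats::coef(fit),
       band = data.frame(x = gx, fit = pr[, "fit"], lwr = pr[, "lwr"],
                         upr = pr[, "upr"]))
}
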