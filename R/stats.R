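#' Normality and homogeneity-of-variance screen
#'
#' Shapiro-Wilk normality per group and Levene's test (on absolute
#' deviations from the group means) across groups, the standard screen
#' before choosing parametric group comparisons.
#'
#' @param table data.frame.
#' @param variable response column name.
#' @param grouping factor column name.
#' @return list: `shapiro` (data.frame group, W, p), `levene` (statistic,
#'   df1, df2, p).
#' @export
normality_and_variance <- function(table, variable, grouping) {
  x <- table[[variable]]
  g <- factor(table[[grouping]])
  ok <- complete.cases(x, g)
  x <- x[ok]; g <- droplevels(g[ok])
  n <- tapply(x, g, length)
  if (any(n < 3)) stop("each group needs at least 3 observations")
  v <- tapply(x, g, var)
  if (any(v == 0)) stop("degenerate (zero-variance) group: ",
                        paste(names(v)[v == 0], collapse = ", "))
  sh <- do.call(rbind, lapply(levels(g), function(lv) {
    s <- shapiro.test(x[g == lv])
    data.frame(group = lv, W = unname(s$statistic), p = s$p.value)
  }))
  dev <- abs(x - ave(x, g))
  fit <- anova(lm(dev ~ g))
  lev <- list(statistic = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
              p = fit$`Pr(>F)`[1])
  list(shapiro = sh, levene = lev)
}

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Classical one-way ANOVA across factor levels; when requested, all
#' pairwise two-sample pooled-variance t tests with p values multiplied by
#' the number of pairs (clamped at 1).
#'
#' @param table data.frame.
#' @param variable response column name.
#' @param factor_col factor column name (e.g. tooth class).
#' @return list: `F`, `df1`, `df2`, `p`, `pairwise` (data.frame a, b,
#'   raw_p, p_adj).
#' @export
anova_bonferroni <- function(table, variable, factor_col) {
  x <- table[[variable]]
  g <- factor(table[[factor_col]])
  ok <- complete.cases(x, g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("at least 2 factor levels are required")
  if (any(tapply(x, g, length) < 2)) stop("at least 2 observations per level")
  fit <- anova(lm(x ~ g))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tt <- t.test(x[g == a], x[g == b], var.equal = TRUE)
    data.frame(a = a, b = b, raw_p = tt$p.value,
               p_adj = min(1, tt$p.value * m))
  }))
  list(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1], pairwise = pw)
}

#' Unpaired two-sample t test between treatment groups
#'
#' Pooled-variance (Student) unpaired t test by default, matching the
#' homogeneous-variance design; Welch available by flag.
#'
#' @param table data.frame.
#' @param variable response column name.
#' @param grouping two-level factor column name (e.g. TB vs BB).
#' @param welch use the Welch correction instead of pooling.
#' @return list: `t`, `df`, `p`, `mean_diff`, `ci` (95%), `means`.
#' @export
two_sample_t <- function(table, variable, grouping, welch = FALSE) {
  x <- table[[variable]]
  g <- factor(table[[grouping]])
  ok <- complete.cases(x, g)
  x <- x[ok]; g <- droplevels(g[ok])
  if (nlevels(g) != 2) stop("grouping must have exactly 2 levels")
  if (any(tapply(x, g, length) < 2)) stop("at least 2 observations per group")
  tt <- t.test(x[g == levels(g)[1]], x[g == levels(g)[2]],
               var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(diff(rev(tt$estimate))),
       ci = unname(tt$conf.int), means = setNames(tt$estimate, levels(g)))
}

#' Pearson chi-square test on a 2 x 2 count table
#'
#' Used for the gender-homogeneity check between groups. No continuity
#' correction by default.
#'
#' @param counts 2 x 2 matrix of non-negative integer counts.
#' @param correct apply the Yates continuity correction.
#' @return list: `chisq`, `df`, `p`.
#' @export
chi_square_gender <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the count table")
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Multiple linear regression of root resorption on expander type and
#' expansion
#'
#' Ordinary least squares of a per-tooth resorption outcome on the
#' expander type indicator and the skeletal (PWE) and dento-alveolar
#' (DAE) expansion changes, fitted with an intercept; reports
#' unstandardized B with SE, standardized beta, t, p, 95% CI and model
#' R-squared. Fitted separately per tooth class by the reporting layer.
#'
#' @param table data.frame.
#' @param outcome outcome column name (e.g. `delta_v`).
#' @param predictors predictor column names; a two-level factor/character
#'   column is converted to a 0/1 indicator.
#' @return object of class `rm_regression`: `coefficients` data.frame
#'   (term, B, se, beta, t, p, ci_lo, ci_hi), `r_squared`, `n`.
#' @export
err_regression <- function(table, outcome,
                           predictors = c("expander", "pwe", "dae")) {
  df <- table[, c(outcome, predictors)]
  for (p in predictors) {
    if (is.character(df[[p]]) || is.factor(df[[p]]))
      df[[p]] <- as.numeric(factor(df[[p]])) - 1
  }
  df <- df[complete.cases(df), ]
  if (nrow(df) <= length(predictors) + 1)
    stop("too few observations for the regression")
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("collinear design; aliased predictor(s): ",
         paste(aliased, collapse = ", "))
  }
  s <- summary(fit)
  co <- s$coefficients
  ci <- confint(fit)
  sy <- sd(df[[outcome]])
  beta <- vapply(rownames(co), function(tm) {
    if (tm == "(Intercept)") NA_real_ else co[tm, 1] * sd(df[[tm]]) / sy
  }, numeric(1))
  res <- data.frame(term = rownames(co), B = co[, 1], se = co[, 2],
                    beta = beta, t = co[, 3], p = co[, 4],
                    ci_lo = ci[, 1], ci_hi = ci[, 2], row.names = NULL)
  structure(list(coefficients = res, r_squared = s$r.squared, n = nrow(df)),
            class = "rm_regression")
}

#' @export
print.rm_regression <- function(x, ...) {
  cat(sprintf("rm_regression (n = %d, R-squared = %.3f)\n", x$n, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Intraclass correlation coefficient, two-way random effects, absolute
#' agreement, single measurement (ICC(2,1))
#'
#' Reliability of repeated measurements (subjects x raters/sessions) from
#' the two-way ANOVA variance decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param measurements numeric matrix or data.frame, subjects in rows,
#'   raters/sessions in columns, complete.
#' @return list of class `rm_icc`: `icc`, `model`, `n_subjects`,
#'   `n_raters`, `ms` (mean squares).
#' @export
icc_agreement <- function(measurements) {
  M <- as.matrix(measurements)
  if (any(!is.finite(M))) stop("missing cells in the reliability table")
  n <- nrow(M); k <- ncol(M)
  if (n < 5 || k < 2) stop("need at least 5 subjects and 2 raters")
  grand <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((M - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc,
                 model = "two-way random effects, absolute agreement, single rater (ICC(2,1))",
                 n_subjects = n, n_raters = k,
                 ms = c(MSR = msr, MSC = msc, MSE = mse)),
            class = "rm_icc")
}

#' @export
print.rm_icc <- function(x, ...) {
  cat(sprintf("ICC = %.4f  [%s; %d subjects x %d raters]\n",
              x$icc, x$model, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Sample size for a two-sided two-sample t test
#'
#' Smallest integer n per group reaching the target power for detecting
#' `mean_diff` with the given group SDs (pooled), via noncentral-t power
#' iteration.
#'
#' @param mean_diff detectable mean difference (same units as the SDs).
#' @param sd1,sd2 group standard deviations.
#' @param alpha two-sided type-I error level.
#' @param power target power.
#' @param n_max search cap.
#' @return n per group (integer, >= 2).
#' @export
sample_size_two_means <- function(mean_diff, sd1, sd2 = sd1, alpha = 0.05,
                                  power = 0.80, n_max = 1e6) {
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (mean_diff == 0) stop("mean difference must be non-zero")
  sp <- sqrt((sd1^2 + sd2^2) / 2)
  d <- abs(mean_diff) / sp
  for (n in 2:n_max) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tcrit <- qt(1 - alpha / 2, df)
    pw <- 1 - pt(tcrit, df, ncp = ncp) + pt(-tcrit, df, ncp = ncp)
    if (pw >= power) return(n)
  }
  stop("no n below the search cap reaches the target power")
}

#' Side-pooling equivalence pre-test
#'
#' The preliminary right-versus-left comparison run before pooling sides:
#' an unpaired t test of the measurement between sides, per tooth class.
#' Pooling is considered admissible when no side comparison is
#' significant.
#'
#' @param table per-tooth table with a `side` column (`L`/`R`).
#' @param variable measurement column.
#' @param by optional stratification column (default `tooth_class`).
#' @param alpha significance level.
#' @return data.frame (stratum, t, p, poolable).
#' @export
side_pooling_pretest <- function(table, variable, by = "tooth_class",
                                 alpha = 0.05) {
  strata <- unique(table[[by]])
  out <- do.call(rbind, lapply(strata, function(s) {
    sub <- table[table[[by]] == s, ]
    tt <- two_sample_t(sub, variable, "side")
    data.frame(stratum = s, t = tt$t, p = tt$p, poolable = tt$p > alpha)
  }))
  out
}
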