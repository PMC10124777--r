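# Psychometric evaluation battery: construct validity against area-based
# chance levels, six-week stability (two-way ICCs), HC3-robust group
# discrimination, and Spearman clinical correlations with optional
# rank-based partialing. No multiple-comparison adjustment anywhere, by
# design. All tests are two-sided except where an inequality null is
# stated explicitly (pupil constriction > 0).

#' One-sample construct-validity test
#'
#' `t = (M - mu0) / (SD / sqrt(n))` with `df = n - 1` and the one-sample
#' effect size `d = (M - mu0) / SD`. Accepts either raw values or printed
#' summary statistics (n, M, SD), so published tables can be reproduced
#' exactly from their rounded inputs.
#'
#' @param values numeric vector (ignored when summary inputs are given)
#' @param mu0 chance level under the null
#' @param n,m,s optional summary inputs (sample size, mean, SD)
#' @param alternative "two.sided", "greater" or "less"
#' @return list(t, df, p, d, m, sd, n)
#' @export
one_sample_construct_test <- function(values = NULL, mu0,
                                      n = NULL, m = NULL, s = NULL,
                                      alternative = "two.sided") {
  if (is.null(n)) {
    values <- values[is.finite(values)]
    n <- length(values)
    if (n < 2) stop_config("need at least 2 finite values")
    m <- mean(values); s <- stats::sd(values)
  }
  d <- (m - mu0) / s
  t <- d * sqrt(n)
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  if (!is.finite(t)) warning("zero SD: t statistic is not finite")
  list(t = t, df = df, p = p, d = d, m = m, sd = s, n = n)
}

#' Pooled-SD Cohen's d
#'
#' `d = (M1 - M2) / s_p` with the usual pooled variance. Accepts raw
#' vectors or printed summary statistics.
#'
#' @param x,y group value vectors (ignored when summaries given)
#' @param n1,m1,s1,n2,m2,s2 optional summary inputs
#' @return numeric d
#' @export
pooled_cohens_d <- function(x = NULL, y = NULL,
                            n1 = NULL, m1 = NULL, s1 = NULL,
                            n2 = NULL, m2 = NULL, s2 = NULL) {
  if (is.null(n1)) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop_config("need n >= 2 in both groups")
    m1 <- mean(x); m2 <- mean(y)
    s1 <- stats::sd(x); s2 <- stats::sd(y)
  }
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) warning("zero pooled SD")
  (m1 - m2) / sp
}

#' Two-way intraclass correlations for two-occasion stability
#'
#' From the subjects x occasions ANOVA decomposition with k = 2 occasions:
#' the consistency variant (two-way mixed, ICC(3,1))
#' `(MSR - MSE) / (MSR + MSE)` and the absolute-agreement variant
#' (ICC(A,1)) `(MSR - MSE) / (MSR + MSE + (2/n)(MSC - MSE))`. Both are
#' always returned, with classification against the moderate (>= 0.5) and
#' high (>= 0.75) stability bands.
#'
#' @param t1,t2 paired measurements (rows with any NA are dropped)
#' @param variant which estimate to place in `icc`: "agreement" (default)
#'   or "consistency"
#' @return list(icc, icc_consistency, icc_agreement, n, df, band)
#' @export
icc_stability <- function(t1, t2, variant = c("agreement", "consistency")) {
  variant <- match.arg(variant)
  keep <- is.finite(t1) & is.finite(t2)
  t1 <- t1[keep]; t2 <- t2[keep]
  n <- length(t1)
  if (n < 3) stop_config("need at least 3 complete pairs (got %d)", n)
  k <- 2
  gm <- mean(c(t1, t2))
  rm_ <- (t1 + t2) / 2
  cm <- c(mean(t1), mean(t2))
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((t1 - gm)^2) + sum((t2 - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc_c <- (msr - mse) / (msr + mse)
  icc_a <- (msr - mse) / (msr + mse + (k / n) * (msc - mse))
  icc <- if (variant == "agreement") icc_a else icc_c
  band <- if (is.na(icc)) NA_character_
          else if (icc >= 0.75) "high"
          else if (icc >= 0.5) "moderate" else "low"
  list(icc = icc, icc_consistency = icc_c, icc_agreement = icc_a,
       n = n, df = n - 1, band = band)
}

#' HC3 covariance matrix for a linear model
#'
#' `(X'X)^-1 X' diag(e_i^2 / (1 - h_ii)^2) X (X'X)^-1` with leverages
#' `h_ii` from the hat matrix.
#'
#' @param fit an `lm` fit
#' @return p x p covariance matrix
#' @export
hc3_vcov <- function(fit) {
  X <- stats::model.matrix(fit)
  e <- stats::residuals(fit)
  h <- stats::hatvalues(fit)
  XtXinv <- chol2inv(chol(crossprod(X)))
  meat <- crossprod(X * (e / (1 - h)), X * (e / (1 - h)))
  XtXinv %*% meat %*% XtXinv
}

#' Group discrimination with HC3-robust inference
#'
#' Fits `y ~ group (+ covariates)` by least squares and tests the group
#' term with a Wald F using the HC3 covariance (df1 = 1, df2 = n - p),
#' accommodating unequal group variances. Reported alongside: the
#' classical partial eta squared from the (non-robust) sequential ANOVA
#' decomposition with group entered last, and the unadjusted pooled
#' Cohen's d on raw means.
#'
#' @param y outcome vector
#' @param group two-level factor or character (first level is the
#'   reference; alphabetical when character)
#' @param covariates optional data.frame of covariates (factors become
#'   indicator contrasts)
#' @return list(F, df1, df2, p, d, eta_p2, n, means, sds, ns)
#' @export
group_discrimination <- function(y, group, covariates = NULL) {
  dat <- data.frame(y = y, group = factor(group))
  if (nlevels(dat$group) < 2) stop_config("need at least 2 groups")
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  form <- if (is.null(covariates)) y ~ group
          else stats::reformulate(c("group", colnames(covariates)), "y")
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit))))
    stop_config("rank-deficient design; aliased: %s",
                paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                      collapse = ", "))
  p <- length(stats::coef(fit))
  V <- hc3_vcov(fit)
  gi <- which(startsWith(names(stats::coef(fit)), "group"))[1]
  Fstat <- stats::coef(fit)[gi]^2 / V[gi, gi]
  df2 <- n - p
  pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  # classical partial eta^2: group entered last
  fit0 <- stats::update(fit, . ~ . - group)
  ss_group <- sum(stats::residuals(fit0)^2) - sum(stats::residuals(fit)^2)
  ss_resid <- sum(stats::residuals(fit)^2)
  levs <- levels(dat$group)
  g1 <- dat$y[dat$group == levs[1]]; g2 <- dat$y[dat$group == levs[2]]
  list(F = unname(Fstat), df1 = 1, df2 = df2, p = unname(pval),
       d = pooled_cohens_d(g1, g2),
       eta_p2 = ss_group / (ss_group + ss_resid),
       n = n,
       means = stats::setNames(c(mean(g1), mean(g2)), levs[1:2]),
       sds = stats::setNames(c(stats::sd(g1), stats::sd(g2)), levs[1:2]),
       ns = stats::setNames(c(length(g1), length(g2)), levs[1:2]))
}

# Spearman rho with t-approximation p-value; optional partialing on
# rank-transformed covariates (rank-then-partial-Pearson).
spearman_one <- function(x, y, covariates = NULL) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  x <- x[keep]; y <- y[keep]
  n <- sum(keep)
  if (n < 4 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  k <- 0L
  if (!is.null(covariates)) {
    Z <- vapply(as.data.frame(covariates)[keep, , drop = FALSE],
                function(v) rank(as.numeric(v)), numeric(n))
    k <- ncol(Z)
    rx <- stats::residuals(stats::lm.fit(cbind(1, Z), rx))
    ry <- stats::residuals(stats::lm.fit(cbind(1, Z), ry))
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2 - k
  t <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t), df), n = n)
}

#' Spearman correlation matrix between biomarker and clinical columns
#'
#' Pairwise complete cases; plain Spearman, or partial Spearman computed as
#' partial Pearson on mid-rank-transformed variables (covariates also rank
#' transformed) when `partial_covariates` is given.
#'
#' @param data data.frame holding all columns
#' @param biomarker_cols,clinical_cols column names
#' @param partial_covariates optional column names to partial out
#' @return list of matrices `rho`, `p`, `n`
#' @export
spearman_matrix <- function(data, biomarker_cols, clinical_cols,
                            partial_covariates = NULL) {
  data <- as.data.frame(data)
  rho <- p <- nmat <- matrix(NA_real_, length(biomarker_cols),
                             length(clinical_cols),
                             dimnames = list(biomarker_cols, clinical_cols))
  for (b in biomarker_cols) for (cl in clinical_cols) {
    cov_df <- if (is.null(partial_covariates)) NULL
              else data[, partial_covariates, drop = FALSE]
    r <- spearman_one(as.numeric(data[[b]]), as.numeric(data[[cl]]), cov_df)
    rho[b, cl] <- r$rho; p[b, cl] <- r$p; nmat[b, cl] <- r$n
  }
  list(rho = rho, p = p, n = nmat)
}

#' Stability and discrimination within age and IQ subgroups
#'
#' Splits a biomarker table at age 8.5 years (< vs >=) and IQ 75 (< vs >=)
#' and reruns [icc_stability()] per cell for each requested variable.
#' Cells with fewer than 3 complete pairs are omitted with a warning.
#'
#' @param wide table with one row per participant containing `<var>_t1`,
#'   `<var>_t2`, `age_years`, `iq`
#' @param vars variable stems to analyse
#' @param age_cut,iq_cut split points
#' @return data.table: subgroup, variable, icc (agreement), icc_consistency,
#'   n, df
#' @export
subgroup_analyses <- function(wide, vars, age_cut = 8.5, iq_cut = 75) {
  cells <- list(
    age_lt = wide$age_years < age_cut,
    age_ge = wide$age_years >= age_cut,
    iq_lt = wide$iq < iq_cut,
    iq_ge = wide$iq >= iq_cut
  )
  rows <- list()
  for (cn in names(cells)) for (v in vars) {
    t1 <- wide[[paste0(v, "_t1")]][cells[[cn]]]
    t2 <- wide[[paste0(v, "_t2")]][cells[[cn]]]
    if (sum(is.finite(t1) & is.finite(t2)) < 3) {
      warning(sprintf("subgroup %s has < 3 complete pairs for %s; omitted",
                      cn, v))
      next
    }
    ic <- icc_stability(t1, t2)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      subgroup = cn, variable = v, icc = ic$icc_agreement,
      icc_consistency = ic$icc_consistency, n = ic$n, df = ic$df)
  }
  if (!length(rows)) return(data.table::data.table())
  data.table::rbindlist(rows)
}
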