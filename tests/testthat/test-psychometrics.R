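# Evaluation battery: construct validity, Cohen's d, ICC vs brute-force
# oracle, HC3 inference, Spearman with partialing, subgroups.

test_that("construct test reproduces published statistics from summary
           inputs", {
  r <- one_sample_construct_test(mu0 = 3.2, n = 119, m = 27.6, s = 8.5)
  expect_equal(r$df, 118)
  expect_equal(round(r$t, 1), 31.3)
  expect_equal(round(r$d, 2), 2.87)
  expect_lt(r$p, 0.001)
  r2 <- one_sample_construct_test(mu0 = 50, n = 119, m = 54.8, s = 6.1)
  expect_equal(round(r2$d, 2), 0.79)
  # degenerate cases
  r3 <- one_sample_construct_test(values = c(5, 5, 5, 5) + c(1, -1, 1, -1),
                                  mu0 = 5)
  expect_equal(r3$t, 0)
  expect_equal(r3$d, 0)
  expect_warning(one_sample_construct_test(values = rep(3, 5), mu0 = 1),
                 "zero SD")
  expect_error(one_sample_construct_test(values = 1, mu0 = 0), "at least 2")
  # one-sided option
  r4 <- one_sample_construct_test(mu0 = 0, n = 117, m = 0.505, s = 0.074,
                                  alternative = "greater")
  expect_lt(r4$p, 0.001)
})

test_that("pooled Cohen's d matches the published composite value", {
  d <- pooled_cohens_d(n1 = 272, m1 = 24.4, s1 = 8.5,
                       n2 = 119, m2 = 30.9, s2 = 7.6)
  expect_equal(round(abs(d), 3), 0.788, tolerance = 2e-3)
  set.seed(51)
  x <- stats::rnorm(50); y <- x
  expect_equal(pooled_cohens_d(x, y), 0)
  # location-scale property: shifting group 1 by +s_p changes d by +1
  sp <- sqrt(((49) * stats::var(x) + 49 * stats::var(y)) / 98)
  expect_equal(pooled_cohens_d(x + sp, y) - pooled_cohens_d(x, y), 1)
})

test_that("ICC estimators agree with the brute-force ANOVA oracle", {
  # hand matrix
  m <- matrix(c(1, 2, 3, 3, 5, 4, 7, 8, 9, 9), ncol = 2, byrow = TRUE)
  ic <- icc_stability(m[, 1], m[, 2])
  or <- oracle_icc(m[, 1], m[, 2])
  expect_equal(ic$icc_consistency, or$consistency, tolerance = 1e-12)
  expect_equal(ic$icc_agreement, or$agreement, tolerance = 1e-12)
  # perfect agreement
  expect_equal(icc_stability(m[, 1], m[, 1])$icc_agreement, 1)
  expect_equal(icc_stability(m[, 1], m[, 1])$icc_consistency, 1)
  # property: 200 random 6x2 integer matrices
  set.seed(52)
  for (i in 1:200) {
    t1 <- sample.int(20, 6, replace = TRUE)
    t2 <- sample.int(20, 6, replace = TRUE)
    if (stats::var((t1 + t2) / 2) == 0) next
    ic <- icc_stability(t1, t2)
    or <- oracle_icc(t1, t2)
    expect_equal(ic$icc_consistency, or$consistency, tolerance = 1e-10)
    expect_equal(ic$icc_agreement, or$agreement, tolerance = 1e-10)
  }
  # zero between-subject variance: non-positive ICC reported as-is
  ic0 <- icc_stability(c(1, 1, 1, 1), c(2, 0, 2, 0))
  expect_lte(ic0$icc_consistency, 0)
  expect_error(icc_stability(1:2, 2:3), "at least 3")
})

test_that("HC3 covariance equals the explicit matrix formula on a fixture", {
  set.seed(53)
  X <- cbind(1, stats::rnorm(10), stats::runif(10))
  beta <- c(1, 2, -1)
  y <- drop(X %*% beta) + stats::rnorm(10, sd = c(rep(0.5, 5), rep(2, 5)))
  fit <- stats::lm(y ~ X[, 2] + X[, 3])
  # textbook arithmetic, spelled out independently
  XtXi <- solve(t(X) %*% X)
  H <- X %*% XtXi %*% t(X)
  e <- y - X %*% XtXi %*% t(X) %*% y
  Omega <- diag(as.numeric(e)^2 / (1 - diag(H))^2)
  V_ref <- XtXi %*% t(X) %*% Omega %*% X %*% XtXi
  V <- hc3_vcov(fit)
  expect_equal(max(abs(V - V_ref) / (abs(V_ref) + 1e-12)), 0,
               tolerance = 1e-10)
})

test_that("HC3 F approaches the classical F under homoskedasticity", {
  set.seed(54)
  n <- 4000
  g <- rep(c("a", "b"), each = n / 2)
  y <- stats::rnorm(n) + (g == "b") * 0.2
  r <- group_discrimination(y, g)
  fit <- stats::lm(y ~ factor(g))
  F_classic <- summary(fit)$fstatistic[["value"]]
  expect_lt(abs(r$F - F_classic) / F_classic, 0.02)
  # eta_p2 consistent with classical decomposition
  a <- stats::anova(fit)
  expect_equal(r$eta_p2,
               a[1, "Sum Sq"] / (a[1, "Sum Sq"] + a[2, "Sum Sq"]),
               tolerance = 1e-12)
})

test_that("group discrimination handles covariates and rank deficiency", {
  set.seed(55)
  n <- 120
  g <- rep(c("ASD", "TD"), each = n / 2)
  cov_df <- data.frame(age = stats::runif(n, 6, 11.5),
                       site = factor(sample(c("A", "B", "C"), n, TRUE)))
  y <- stats::rnorm(n) - (g == "TD") * 0.8 + 0.1 * cov_df$age
  r <- group_discrimination(y, g, cov_df)
  expect_equal(r$df2, n - 5)
  expect_lt(r$p, 0.01)
  expect_gt(r$d, 0)         # ASD minus TD, ASD higher here? no: negative
  # aliased covariate triggers a named error
  cov_bad <- data.frame(grp_copy = as.numeric(g == "TD"))
  expect_error(group_discrimination(y, g, cov_bad), "aliased")
})

test_that("spearman matches hand computation and is monotone-invariant", {
  x <- 1:6; y <- c(2, 1, 4, 3, 6, 5)
  r <- gazeomi:::spearman_one(x, y)
  expect_equal(r$rho, 1 - 6 * 6 / (6 * 35), tolerance = 1e-12)  # 0.8286
  # strictly monotone transform changes nothing
  r2 <- gazeomi:::spearman_one(exp(x), y^3)
  expect_equal(r2$rho, r$rho, tolerance = 1e-12)
  # perfect monotone association
  expect_equal(gazeomi:::spearman_one(x, log(x + 2))$rho, 1)
  # constant column undefined
  expect_true(is.na(gazeomi:::spearman_one(rep(1, 6), y)$rho))
})

test_that("partial spearman removes a shared rank-linear driver", {
  set.seed(56)
  n <- 300
  z <- stats::rnorm(n)
  x <- z + stats::rnorm(n, sd = 0.6)
  y <- z + stats::rnorm(n, sd = 0.6)
  plain <- gazeomi:::spearman_one(x, y)
  part <- gazeomi:::spearman_one(x, y, data.frame(z = z))
  expect_gt(plain$rho, 0.5)
  expect_lt(abs(part$rho), 0.15)
  # matrix wrapper shapes
  dat <- data.frame(a = x, b = y, s1 = z, cov = z)
  m <- spearman_matrix(dat, c("a", "b"), "s1", partial_covariates = "cov")
  expect_equal(dim(m$rho), c(2L, 1L))
})

test_that("subgroup splits are inclusive at the cut points", {
  wide <- data.frame(
    participant_id = sprintf("P%d", 1:8),
    age_years = c(8.4, 8.5, rep(7, 3), rep(10, 3)),
    iq = c(74, 75, rep(60, 3), rep(110, 3)),
    omi_t1 = c(1, 2, 3, 4, 5, 6, 7, 8),
    omi_t2 = c(1.1, 2, 3.2, 4, 5.1, 6, 7.2, 8))
  res <- subgroup_analyses(wide, "omi")
  young <- res[res$subgroup == "age_lt"]
  old <- res[res$subgroup == "age_ge"]
  expect_equal(young$n, 4L)   # 8.4 is young, 8.5 is old
  expect_equal(old$n, 4L)
  # all-old table: young cell omitted with warning
  wide2 <- wide; wide2$age_years <- 10
  expect_warning(subgroup_analyses(wide2, "omi"), "omitted")
})
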