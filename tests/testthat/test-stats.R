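test_that("Lilliefors normality test behaves on normal and bimodal data", {
  ok <- 0
  for (s in 1:50) {
    set.seed(s)
    res <- ks_normality(rnorm(200))
    expect_true(res$statistic >= 0 && res$statistic <= 1)
    if (res$p > 0.05) ok <- ok + 1
  }
  expect_gte(ok / 50, 0.9)
  set.seed(1)
  bimodal <- c(rnorm(100, -3), rnorm(100, 3))
  expect_lt(ks_normality(bimodal)$p, 0.05)
  expect_error(ks_normality(rep(1, 20)), "constant")
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
})

test_that("Pearson chi-square matches the hand-computed statistic", {
  res <- chi_square_independence(rbind(c(10, 20), c(20, 10)))
  expect_equal(res$chisq, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # identical gender ratios -> 0
  expect_equal(chi_square_independence(rbind(c(10, 20, 30), c(20, 40, 60)))$chisq,
               0, tolerance = 1e-12)
  expect_equal(chi_square_independence(matrix(5, 2, 4))$df, 3)
  expect_error(chi_square_independence(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("two-group ANCOVA without covariates is the pooled t-test", {
  set.seed(42)
  a <- rnorm(20); b <- rnorm(15, 0.5)
  res <- ancova_oneway(c(a, b), rep(c("A", "B"), c(20, 15)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  # and matches one-way ANOVA in general
  g <- rep(c("A", "B", "C"), c(10, 12, 14))
  y <- rnorm(36) + as.numeric(factor(g)) * 0.3
  expect_equal(ancova_oneway(y, g)$F, anova(lm(y ~ factor(g)))$F[1],
               tolerance = 1e-8)
})

test_that("ANCOVA absorbs a confounder and degrees of freedom are right", {
  set.seed(7)
  n <- c(134, 11, 10, 44)
  g <- factor(rep(c("PD", "PSP", "MSA", "Control"), n))
  age <- rnorm(sum(n), mean = c(67, 72, 63, 66)[as.integer(factor(g, levels = c("PD", "PSP", "MSA", "Control")))], sd = 8)
  gender <- rbinom(sum(n), 1, 0.5)
  # group effect entirely carried by age
  y <- 0.02 * age + rnorm(sum(n), 0, 0.05)
  f_anova <- ancova_oneway(y, g)$F
  res <- ancova_oneway(y, g, data.frame(age = age, gender = gender))
  expect_lt(res$F / f_anova, 0.5)
  expect_equal(res$df_between, 3)
  expect_equal(res$df_within, sum(n) - 4 - 2)   # the F_{3,193} layout
  # adjusted means and LSD pairwise table are complete
  expect_equal(sort(names(res$adjusted_means)), sort(levels(g)))
  expect_equal(nrow(res$pairwise), 6)
  expect_true(all(res$pairwise$p >= 0 & res$pairwise$p <= 1))
  expect_error(ancova_oneway(y, g, data.frame(a = age, b = 2 * age)),
               "collinear")
})

test_that("LSD pairwise p-values agree with emmeans", {
  set.seed(12)
  g <- factor(rep(c("A", "B", "C"), each = 25))
  age <- rnorm(75, 60, 8)
  y <- 0.1 * (g == "B") + 0.01 * age + rnorm(75, 0, 0.2)
  res <- ancova_oneway(y, g, data.frame(age = age))
  fit <- lm(y ~ g + age)
  em <- summary(emmeans::emmeans(fit, pairwise ~ g, adjust = "none")$contrasts)
  expect_equal(res$pairwise$p, em$p.value, tolerance = 1e-8)
  expect_equal(abs(res$pairwise$diff), abs(em$estimate), tolerance = 1e-8)
})

test_that("Mann-Whitney U matches enumeration and is symmetric", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)      # 2/6 orderings
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 4)
  expect_equal(unname(mann_whitney_u(a, b)$U), length(a) * length(b) / 2)
  set.seed(5)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(y, x)$p)
})

test_that("AUC equals the exhaustive pair-count oracle", {
  brute_auc <- function(p, n) {
    s <- 0
    for (i in seq_along(p)) for (j in seq_along(n))
      s <- s + (p[i] > n[j]) + 0.5 * (p[i] == n[j])
    s / (length(p) * length(n))
  }
  expect_equal(roc_auc(c(3, 5), c(1, 4))$auc, brute_auc(c(3, 5), c(1, 4)))
  expect_equal(roc_auc(c(3, 5), c(1, 4))$auc, 0.75)
  expect_equal(roc_auc(11:20, 1:10)$auc, 1.0)        # perfect separation
  for (s in 1:10) {
    set.seed(s)
    p <- round(rnorm(sample(5:30, 1), 0.5), 1)
    n <- round(rnorm(sample(5:30, 1)), 1)
    raw <- brute_auc(p, n)
    r <- roc_auc(p, n)
    expect_equal(r$auc, if (raw < 0.5) 1 - raw else raw, tolerance = 1e-12)
    # antisymmetry of the raw statistic
    expect_equal(brute_auc(n, p), 1 - raw, tolerance = 1e-12)
    # reported operating point reproduces its own sens/spec
    if (r$direction == ">") {
      expect_equal(r$sensitivity, mean(p >= r$threshold))
      expect_equal(r$specificity, mean(n < r$threshold))
    }
  }
})

test_that("DeLong variance is sane and the interval tightens with n", {
  set.seed(21)
  d1 <- delong_ci(rnorm(20, 1), rnorm(20))
  d2 <- delong_ci(rnorm(200, 1), rnorm(200))
  expect_gte(d1$variance, 0)
  expect_gte(d2$variance, 0)
  expect_lt(d2$ci_hi - d2$ci_lo, d1$ci_hi - d1$ci_lo)
  # matches the reference implementation
  sp <- rnorm(40, 1); sn <- rnorm(50)
  d <- delong_ci(sp, sn)
  ci <- pROC::ci.auc(pROC::roc(controls = sn, cases = sp, quiet = TRUE,
                               direction = "<"), method = "delong")
  expect_equal(c(d$ci_lo, d$ci_hi), c(ci[1], ci[3]), tolerance = 1e-10)
  # degenerate separation collapses the interval with a flag
  dd <- delong_ci(c(10, 11, 12), c(1, 2, 3))
  expect_true(dd$degenerate)
  expect_equal(dd$variance, 0)
})

test_that("equal-prior LDA matches the closed-form boundary and MASS", {
  set.seed(42)
  x <- c(rnorm(50, 0), rnorm(50, 4))
  y <- rep(c("lo", "hi"), each = 50)
  fit <- lda_fit(matrix(x, ncol = 1), y)
  mid <- (mean(x[1:50]) + mean(x[51:100])) / 2
  # the decision boundary of 1-D equal-variance equal-prior LDA is the
  # midpoint of the class means: predictions flip within +-1e-6 of it
  expect_equal(as.character(predict(fit, matrix(mid - 1e-6))$class), "lo")
  expect_equal(as.character(predict(fit, matrix(mid + 1e-6))$class), "hi")
  # equal priors: duplicating one class's points leaves the boundary put
  fit2 <- lda_fit(matrix(c(x, x[1:50]), ncol = 1), c(y, rep("lo", 50)))
  expect_equal(as.character(predict(fit2, matrix(mid + 1e-6))$class), "hi")
  expect_equal(as.character(predict(fit2, matrix(mid - 1e-6))$class), "lo")
  # multiclass 5-D agreement with the reference implementation
  set.seed(9)
  X <- matrix(rnorm(300), 75, 4)
  X[1:25, 1] <- X[1:25, 1] + 2; X[26:50, 2] <- X[26:50, 2] + 2
  yy <- rep(c("a", "b", "c"), each = 25)
  p1 <- predict(lda_fit(X, yy), X)$class
  p2 <- predict(MASS::lda(X, grouping = yy, prior = rep(1 / 3, 3)), X)$class
  expect_equal(as.character(p1), as.character(p2))
  # clearly separated classes classify perfectly
  Xs <- rbind(matrix(rnorm(125, 0, 0.1), 25, 5), matrix(rnorm(125, 5, 0.1), 25, 5))
  ys <- rep(c("n", "p"), each = 25)
  expect_equal(mean(predict(lda_fit(Xs, ys), Xs)$class == ys), 1)
})

test_that("LOOCV is order-invariant and never beats resubstitution here", {
  set.seed(33)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 1.2), 30, 2))
  y <- rep(c("neg", "pos"), each = 30)
  loo <- loocv_classify(X, y, positive = "pos")
  fit <- lda_fit(X, y)
  resub <- swiqsm:::confusion_to_result(predict(fit, X)$class, y, positive = "pos")
  expect_lte(loo$accuracy, resub$accuracy)           # optimism property
  # permutation invariance
  perm <- sample(length(y))
  loo2 <- loocv_classify(X[perm, ], y[perm], positive = "pos")
  expect_equal(loo2$accuracy, loo$accuracy)
  expect_equal(loo2$TP, loo$TP)
  # perfect separation -> perfect LOOCV
  Xs <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2), matrix(rnorm(40, 3, 0.05), 20, 2))
  expect_equal(loocv_classify(Xs, rep(c("a", "b"), each = 20))$accuracy, 1)
})

test_that("confusion reconstruction round-trips printed rates", {
  r <- confusion_from_rates(1, 1, 10, 20)
  expect_equal(r$ppv, 1); expect_equal(r$npv, 1); expect_equal(r$accuracy, 1)
  # round-trip: recomputed sens/spec reproduce the inputs to 3 decimals
  for (case in list(c(1, .970, 11, 134), c(.909, .900, 11, 10),
                    c(.700, .948, 10, 134), c(1, .910, 11, 134),
                    c(.909, .970, 11, 134), c(.619, .568, 134, 44))) {
    rr <- confusion_from_rates(case[1], case[2], case[3], case[4])
    expect_equal(round(rr$sensitivity, 3), round(case[1], 3))
    expect_equal(round(rr$specificity, 3), round(case[2], 3))
    expect_equal(rr$TP + rr$FN, case[3]); expect_equal(rr$TN + rr$FP, case[4])
  }
  # degenerate predicted class flags NA predictive value
  r0 <- confusion_from_rates(0, 1, 5, 5)
  expect_true(is.na(r0$ppv) && r0$flagged)
})

test_that("partial correlation matches its closed-form and residual oracles", {
  set.seed(2)
  n <- 150
  z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- 0.3 * z + rnorm(n)
  pc <- pearson_partial_correlation(x, y, data.frame(z = z))
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_lt(abs(pc$r - oracle), 1e-10)
  expect_equal(pc$df, n - 3)
  # no covariates: plain Pearson
  pc0 <- pearson_partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc0$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pc0$p, ct$p.value, tolerance = 1e-10)
  # y = x -> r = 1 given a covariate
  expect_equal(pearson_partial_correlation(x, x + 0, data.frame(z = z))$r, 1)
  # many covariates: residualization oracle
  z2 <- rnorm(n); z3 <- rnorm(n)
  pc2 <- pearson_partial_correlation(x, y, data.frame(z, z2, z3))
  rx <- resid(lm(x ~ z + z2 + z3)); ry <- resid(lm(y ~ z + z2 + z3))
  expect_lt(abs(pc2$r - cor(rx, ry)), 1e-10)
})

test_that("Bonferroni correction is alpha over m", {
  expect_equal(round(bonferroni_alpha(0.05, 30), 4), 0.0017)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.10, 4), 0.025)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("the full analysis report is complete and deterministic", {
  co <- scenario_cohort(seed = 7)
  r1 <- run_full_analysis(co)
  r2 <- run_full_analysis(co)
  expect_identical(r1$roc, r2$roc)
  expect_identical(r1$pairwise, r2$pairwise)
  expect_equal(nrow(r1$roc), 30)                     # 6 pairs x 5 regions
  expect_equal(nrow(r1$pairwise), 30)
  expect_setequal(names(r1$lda_pairs),
                  c("PSP_vs_PD", "PSP_vs_MSA", "MSA_vs_PD", "PSP_vs_Control",
                    "MSA_vs_Control", "PD_vs_Control"))
  # the dentate MSA-PD comparison is routed to Mann-Whitney
  mw <- r1$pairwise[r1$pairwise$test == "mann_whitney", ]
  expect_equal(nrow(mw), 1)
  expect_equal(mw$region, "dn")
  expect_true(all(sort(c(mw$group_a, mw$group_b)) == c("MSA", "PD")))
  # missing columns produce a named error
  expect_error(run_full_analysis(co[, setdiff(names(co), c("sn", "rn"))]),
               "sn")
})
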