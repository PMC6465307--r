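# Statistical layer: normality and contingency checks, ANCOVA with LSD
# pairwise comparisons, Mann-Whitney U, ROC with DeLong confidence
# intervals, equal-prior LDA with LOOCV, confusion-matrix reconstruction,
# partial correlations and Bonferroni correction.

#' Kolmogorov-Smirnov normality test (Lilliefors)
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample, with the Lilliefors correction of the
#' p-value (the naive KS p would be anti-conservative when parameters are
#' estimated).
#'
#' @param sample numeric vector, n >= 5.
#' @return List with `statistic` (in `[0, 1]`) and `p`.
#' @export
ks_normality <- function(sample) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 5) stop("need at least 5 observations")
  if (stats::sd(sample) == 0) stop("sample is constant; normality test undefined")
  res <- nortest::lillie.test(sample)
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Pearson chi-square test of independence
#'
#' @param table nonnegative integer contingency table (e.g. gender x group)
#'   with all margins positive.
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' One-way ANCOVA with LSD pairwise comparisons
#'
#' Fits `values ~ group + covariates` and reports the F test for the group
#' factor (for an additive model this equals the SPSS Type III F),
#' covariate-adjusted group means (covariates at their grand means), and
#' unadjusted pairwise t-tests on the adjusted means — the least
#' significant difference (LSD) procedure. With zero covariates this
#' reduces exactly to one-way ANOVA.
#'
#' @param values numeric response.
#' @param group factor (or coercible) of group membership, >= 2 levels.
#' @param covariates data frame of numeric covariates (may be empty or
#'   `NULL`). Categorical covariates should be coded numerically (e.g.
#'   gender 0/1).
#' @param pairwise compute LSD pairwise comparisons (default TRUE).
#' @return Object of class `ancova_result`: F, df_between, df_within, p,
#'   adjusted_means, pairwise (data frame group_a/group_b/diff/p).
#' @export
ancova_oneway <- function(values, group, covariates = NULL, pairwise = TRUE) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  dat <- data.frame(.y = values, .g = group)
  cov_names <- character()
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    for (cn in names(covariates)) dat[[cn]] <- as.numeric(covariates[[cn]])
    cov_names <- names(covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  k <- nlevels(dat$.g)
  if (n <= k + length(cov_names) + 1) stop("too few observations")
  rhs_cov <- if (length(cov_names)) paste(cov_names, collapse = " + ") else NULL
  f_full <- stats::as.formula(paste(".y ~ .g",
                                    if (!is.null(rhs_cov)) paste("+", rhs_cov) else ""))
  fit <- stats::lm(f_full, data = dat)
  if (any(is.na(stats::coef(fit)))) stop("collinear covariates")
  f_red <- stats::as.formula(paste(".y ~", if (!is.null(rhs_cov)) rhs_cov else "1"))
  fit0 <- stats::lm(f_red, data = dat)
  an <- stats::anova(fit0, fit)
  Fstat <- an$F[2]; pval <- an$`Pr(>F)`[2]
  df_b <- k - 1
  df_w <- fit$df.residual
  # adjusted means: predict each group at the covariate grand means
  newd <- data.frame(.g = factor(levels(dat$.g), levels = levels(dat$.g)))
  for (cn in cov_names) newd[[cn]] <- mean(dat[[cn]])
  adj <- stats::predict(fit, newdata = newd)
  names(adj) <- levels(dat$.g)
  pw <- NULL
  if (pairwise) {
    V <- stats::vcov(fit)
    cf <- stats::coef(fit)
    gl <- levels(dat$.g)
    cn_of <- function(g) if (g == gl[1]) NULL else paste0(".g", g)
    combs <- utils::combn(gl, 2)
    pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
      a <- combs[1, j]; b <- combs[2, j]
      cvec <- stats::setNames(numeric(length(cf)), names(cf))
      if (!is.null(cn_of(a))) cvec[cn_of(a)] <- 1
      if (!is.null(cn_of(b))) cvec[cn_of(b)] <- cvec[cn_of(b)] - 1
      diff <- sum(cvec * cf)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      tt <- diff / se
      data.frame(group_a = a, group_b = b, diff = diff, se = se, t = tt,
                 p = 2 * stats::pt(-abs(tt), df_w), stringsAsFactors = FALSE)
    }))
  }
  structure(list(F = unname(Fstat), df_between = df_b, df_within = df_w,
                 p = unname(pval), adjusted_means = adj, pairwise = pw,
                 n = n, covariates = cov_names),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("One-way ANCOVA: F(%d, %d) = %.3f, p = %.4g (n = %d%s)\n",
              x$df_between, x$df_within, x$F, x$p, x$n,
              if (length(x$covariates))
                paste0("; covariates: ", paste(x$covariates, collapse = ", "))
              else ""))
  if (!is.null(x$pairwise)) {
    cat("LSD pairwise comparisons:\n")
    print(format(x$pairwise, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with mid-rank ties: exact p-value when
#' `min(n) <= 8` and there are no ties, otherwise the normal approximation
#' with tie correction (no continuity correction).
#'
#' @param sample_a,sample_b numeric vectors.
#' @return List with `U` (for `sample_a`) and `p`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("samples must be nonempty")
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  exact <- min(length(sample_a), length(sample_b)) <= 8 && !ties
  res <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                             exact = exact, correct = FALSE))
  list(U = unname(res$statistic), p = res$p.value)
}

# rank-based AUC of "positive scores tend higher": Mann-Whitney probability
# with half credit for ties
auc_rank <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve summary with Youden-optimal operating point
#'
#' AUC as the Mann-Whitney probability (half credit for ties) under the
#' convention "higher value implies the positive class"; if the raw AUC is
#' below 0.5 the direction is flipped and flagged. The operating point is
#' the threshold maximizing Youden's J = sensitivity + specificity - 1,
#' ties broken toward higher specificity. The confidence interval is
#' computed by [delong_ci()].
#'
#' @param scores_pos,scores_neg scores of the positive / negative class.
#' @param level confidence level (default 0.95).
#' @return Object of class `roc_result`: auc, ci_lo, ci_hi, threshold,
#'   sensitivity, specificity, direction (`">"` if positives score higher).
#' @export
roc_auc <- function(scores_pos, scores_neg, level = 0.95) {
  if (!length(scores_pos) || !length(scores_neg)) stop("both groups must be nonempty")
  direction <- ">"
  if (auc_rank(scores_pos, scores_neg) < 0.5) {
    direction <- "<"
    scores_pos <- -scores_pos
    scores_neg <- -scores_neg
  }
  auc <- auc_rank(scores_pos, scores_neg)
  thr <- sort(unique(c(scores_pos, scores_neg)))
  best <- NULL
  for (t in thr) {
    sens <- mean(scores_pos >= t)
    spec <- mean(scores_neg < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(j = j, thr = t, sens = sens, spec = spec)
    }
  }
  ci <- if (length(scores_pos) >= 2 && length(scores_neg) >= 2)
    delong_ci(scores_pos, scores_neg, level) else
      list(ci_lo = NA_real_, ci_hi = NA_real_, variance = NA_real_)
  thr_out <- if (direction == "<") -best$thr else best$thr
  structure(list(auc = auc, ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
                 variance = ci$variance, threshold = thr_out,
                 sensitivity = best$sens, specificity = best$spec,
                 direction = direction,
                 n_pos = length(scores_pos), n_neg = length(scores_neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%d%% CI %.3f-%.3f), sens %.1f%% / spec %.1f%% at threshold %.4g%s\n",
              x$auc, 95, x$ci_lo, x$ci_hi, 100 * x$sensitivity,
              100 * x$specificity, x$threshold,
              if (x$direction == "<") " (direction reversed)" else ""))
  invisible(x)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric variance of the AUC from DeLong's structural components:
#' `var = S10 / n_pos + S01 / n_neg`, with a Wald interval clipped to
#' `[0, 1]`. A degenerate AUC of exactly 0 or 1 yields zero variance and a
#' collapsed interval, flagged in the result.
#'
#' @param scores_pos,scores_neg scores (n >= 2 each).
#' @param level confidence level.
#' @return List with `ci_lo`, `ci_hi`, `variance`, `se`, `degenerate`.
#' @export
delong_ci <- function(scores_pos, scores_neg, level = 0.95) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np < 2 || nn < 2) stop("need at least 2 observations per group")
  psi <- outer(scores_pos, scores_neg,
               function(x, y) (x > y) + 0.5 * (x == y))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # structural components over positives
  v01 <- colMeans(psi)   # ... and negatives
  s10 <- stats::var(v10); s01 <- stats::var(v01)
  variance <- s10 / np + s01 / nn
  degenerate <- auc %in% c(0, 1) || variance == 0
  se <- sqrt(max(variance, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(ci_lo = max(0, auc - z * se), ci_hi = min(1, auc + z * se),
       variance = variance, se = se, degenerate = degenerate)
}

#' Linear discriminant analysis with equal priors
#'
#' Gaussian LDA with pooled within-class covariance. Priors default to
#' equal across classes — correcting for unbalanced group sizes, so the
#' decision boundary is invariant to resampling ratios of the classes. A
#' near-singular pooled covariance is regularized by a small ridge on the
#' diagonal.
#'
#' @param features numeric matrix (subjects x variables).
#' @param labels class labels (factor or coercible).
#' @param priors named numeric vector of prior probabilities, or `"equal"`
#'   (default).
#' @param ridge relative ridge added when the pooled covariance is
#'   ill-conditioned (default 1e-8); set to 0 to error instead.
#' @return Object of class `susc_lda` with class means, pooled covariance
#'   (inverse), priors and levels. Use [predict.susc_lda()].
#' @export
lda_fit <- function(features, labels, priors = "equal", ridge = 1e-8) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (any(table(y) < 2)) stop("each class needs n >= 2")
  lev <- levels(y)
  p <- ncol(X)
  mu <- matrix(0, length(lev), p, dimnames = list(lev, colnames(X)))
  for (l in lev) mu[l, ] <- colMeans(X[y == l, , drop = FALSE])
  Sw <- matrix(0, p, p)
  for (l in lev) {
    Xl <- X[y == l, , drop = FALSE]
    Sw <- Sw + crossprod(sweep(Xl, 2, colMeans(Xl)))
  }
  Sw <- Sw / (nrow(X) - nlevels(y))
  if (rcond(Sw) < 1e-10) {
    if (ridge <= 0) stop("pooled within-class covariance is singular")
    Sw <- Sw + diag(ridge * mean(diag(Sw)), p)
    if (rcond(Sw) < 1e-12) stop("pooled covariance singular even with ridge")
  }
  Sinv <- solve(Sw)
  pr <- if (identical(priors, "equal"))
    stats::setNames(rep(1 / length(lev), length(lev)), lev)
  else {
    if (is.null(names(priors)) || !all(lev %in% names(priors)))
      stop("priors must be named by class")
    priors[lev] / sum(priors[lev])
  }
  structure(list(means = mu, cov_inv = Sinv, priors = pr, levels = lev,
                 p = p),
            class = "susc_lda")
}

#' Predict classes from an equal-prior LDA model
#'
#' @param object a fitted [lda_fit()] model.
#' @param newdata numeric matrix of features.
#' @param ... unused.
#' @return List with `class` (factor) and `posterior` (matrix).
#' @export
predict.susc_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) stop("feature dimension mismatch")
  scores <- vapply(object$levels, function(l) {
    m <- object$means[l, ]
    drop(X %*% (object$cov_inv %*% m)) -
      0.5 * drop(t(m) %*% object$cov_inv %*% m) + log(object$priors[[l]])
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X),
                   dimnames = list(NULL, object$levels))
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  cls <- factor(object$levels[max.col(scores, ties.method = "first")],
                levels = object$levels)
  list(class = cls, posterior = post)
}

#' Confusion-matrix diagnostics from counts
#'
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @return Object of class `diagnostic_result` with sensitivity,
#'   specificity, ppv, npv, accuracy and the counts. Undefined predictive
#'   values (empty predicted class) are `NA` and flagged.
#' @export
diagnostic_result <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0) NA_real_ else tn / (tn + fn)
  structure(list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 ppv = ppv, npv = npv,
                 accuracy = (tp + tn) / (tp + fp + tn + fn),
                 TP = tp, FP = fp, TN = tn, FN = fn,
                 flagged = is.na(ppv) || is.na(npv)),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf("sens %.1f%%  spec %.1f%%  accuracy %.1f%%  PPV %s  NPV %s  (TP %d FP %d TN %d FN %d)\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              ifelse(is.na(x$ppv), "NA", sprintf("%.1f%%", 100 * x$ppv)),
              ifelse(is.na(x$npv), "NA", sprintf("%.1f%%", 100 * x$npv)),
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Leave-one-out cross-validated classification
#'
#' Refits the equal-prior LDA with each subject excluded in turn and
#' predicts the held-out subject. For two classes, returns a
#' `diagnostic_result` with the first argument of `positive` as the
#' positive class; for more classes, returns the LOOCV confusion matrix and
#' accuracy. Deterministic, and invariant to the row order of the input.
#'
#' @param features numeric matrix (subjects x variables).
#' @param labels class labels.
#' @param priors passed to [lda_fit()].
#' @param positive positive class for two-class problems (default: first
#'   factor level).
#' @return A `diagnostic_result` (two classes) or list with `confusion`
#'   and `accuracy`.
#' @export
loocv_classify <- function(features, labels, priors = "equal",
                           positive = NULL) {
  X <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  n <- nrow(X)
  if (any(table(y) < 2)) stop("each class needs n >= 2")
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    fit <- lda_fit(X[-i, , drop = FALSE], y[-i], priors = priors)
    pred[i] <- predict(fit, X[i, , drop = FALSE])$class
  }
  confusion_to_result(pred, y, positive)
}

# shared aggregation for LOOCV / resubstitution predictions
confusion_to_result <- function(pred, truth, positive = NULL) {
  truth <- droplevels(as.factor(truth))
  if (nlevels(truth) == 2) {
    pos <- if (is.null(positive)) levels(truth)[1] else positive
    neg <- setdiff(levels(truth), pos)
    diagnostic_result(tp = sum(pred == pos & truth == pos),
                      fp = sum(pred == pos & truth == neg),
                      tn = sum(pred == neg & truth == neg),
                      fn = sum(pred == neg & truth == pos))
  } else {
    cm <- table(truth = truth, predicted = factor(pred, levels = levels(truth)))
    list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
  }
}

#' Reconstruct confusion-matrix metrics from printed rates
#'
#' Given a sensitivity, a specificity and the two group sizes, rebuilds the
#' integer confusion matrix (rounding half away from zero) and recomputes
#' PPV, NPV and accuracy — the reconstruction used to recover predictive
#' values from published sensitivity/specificity pairs. Round trip: the
#' recomputed sensitivity/specificity match the inputs to 3 decimals.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param n_pos,n_neg group sizes (>= 1).
#' @return A `diagnostic_result`.
#' @export
confusion_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos >= 1, n_neg >= 1)
  rnd <- function(x) sign(x) * floor(abs(x) + 0.5)  # half away from zero
  tp <- rnd(sensitivity * n_pos)
  tn <- rnd(specificity * n_neg)
  diagnostic_result(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Pearson partial correlation
#'
#' Correlation between the residuals of `x` and `y` after least-squares
#' regression on the covariates (plus intercept). The p-value is two-sided
#' from `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - n_covariates`.
#' With no covariates this is the plain Pearson correlation test.
#'
#' @param x,y numeric vectors.
#' @param covariates data frame / matrix of numeric covariates, or `NULL`.
#' @return List with `r`, `p`, `df`, `n`.
#' @export
pearson_partial_correlation <- function(x, y, covariates = NULL) {
  dat <- data.frame(x = x, y = y)
  k <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    for (cn in names(covariates)) dat[[cn]] <- as.numeric(covariates[[cn]])
    k <- length(names(covariates))
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= k + 2) stop("too few complete observations")
  resid_on <- function(v) {
    if (k == 0) return(v - mean(v))
    Z <- cbind(1, as.matrix(dat[, -(1:2), drop = FALSE]))
    stats::lsfit(Z, v, intercept = FALSE)$residuals
  }
  rx <- resid_on(dat$x); ry <- resid_on(dat$y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero residual variance; partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df), df = df, n = n)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise error rate.
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}
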