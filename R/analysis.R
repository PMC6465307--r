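# Full statistical report on a cohort table: mirrors the analysis layout
# used for the four-group parkinsonism comparison — per-region ANCOVA with
# LSD pairwise tests (Mann-Whitney where configured), per pair-by-region
# ROC with DeLong intervals, pairwise equal-prior LDA with LOOCV on all
# five regions, and partial correlations with clinical scores in PD.

GROUP_PAIRS <- list(c("PSP", "PD"), c("PSP", "MSA"), c("MSA", "PD"),
                    c("PSP", "Control"), c("MSA", "Control"),
                    c("PD", "Control"))

#' Run the complete cohort analysis
#'
#' @param cohort cohort data frame with columns group, age, gender,
#'   duration, updrs_iii, hoehn_yahr and the five region columns
#'   gp/put/sn/rn/dn (referenced ppm).
#' @param alpha base significance level (default 0.05).
#' @param bonferroni_m number of pairwise comparisons for the Bonferroni
#'   correction (default 30: 6 group pairs x 5 regions).
#' @param mann_whitney_pairs list of `list(region =, groups = c(a, b))`
#'   entries for which the pairwise test is replaced by Mann-Whitney U
#'   (default: dentate nucleus, MSA vs PD, where normality fails).
#' @return Object of class `susc_analysis`: per-region ANCOVA results,
#'   pairwise table with Bonferroni flags, ROC table, LDA/LOOCV
#'   diagnostics per group pair, overall 4-class LOOCV, and partial
#'   correlations in PD.
#' @export
run_full_analysis <- function(cohort, alpha = 0.05, bonferroni_m = 30,
                              mann_whitney_pairs = list(
                                list(region = "dn", groups = c("MSA", "PD")))) {
  cohort <- as.data.frame(cohort)
  needed <- c("group", "age", "gender", REGION_CODES)
  missing <- setdiff(needed, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  cohort$group <- factor(cohort$group, levels = QSM_GROUPS)
  gender01 <- as.numeric(factor(cohort$gender, levels = c("M", "F"))) - 1
  covs <- data.frame(age = cohort$age, gender = gender01)
  alpha_corr <- bonferroni_alpha(alpha, bonferroni_m)

  # --- per-region ANCOVA + pairwise --------------------------------------
  ancova <- lapply(stats::setNames(REGION_CODES, REGION_CODES), function(r)
    ancova_oneway(cohort[[r]], cohort$group, covs))
  pairwise <- do.call(rbind, lapply(REGION_CODES, function(r) {
    pw <- ancova[[r]]$pairwise
    pw$region <- r
    pw$test <- "ancova_lsd"
    for (mw in mann_whitney_pairs) {
      if (mw$region != r) next
      i <- which((pw$group_a == mw$groups[1] & pw$group_b == mw$groups[2]) |
                   (pw$group_a == mw$groups[2] & pw$group_b == mw$groups[1]))
      if (length(i)) {
        res <- mann_whitney_u(cohort[[r]][cohort$group == pw$group_a[i]],
                              cohort[[r]][cohort$group == pw$group_b[i]])
        pw$p[i] <- res$p
        pw$test[i] <- "mann_whitney"
      }
    }
    pw
  }))
  pairwise$significant <- pairwise$p < alpha_corr

  # --- ROC per group pair x region ---------------------------------------
  roc <- do.call(rbind, lapply(GROUP_PAIRS, function(pr) {
    do.call(rbind, lapply(REGION_CODES, function(r) {
      rr <- roc_auc(cohort[[r]][cohort$group == pr[1]],
                    cohort[[r]][cohort$group == pr[2]])
      data.frame(positive = pr[1], negative = pr[2], region = r,
                 auc = rr$auc, ci_lo = rr$ci_lo, ci_hi = rr$ci_hi,
                 sensitivity = rr$sensitivity, specificity = rr$specificity,
                 threshold = rr$threshold, direction = rr$direction,
                 stringsAsFactors = FALSE)
    }))
  }))

  # --- pairwise LDA with LOOCV (all five regions) ------------------------
  X <- as.matrix(cohort[, REGION_CODES])
  lda_pairs <- lapply(GROUP_PAIRS, function(pr) {
    sel <- cohort$group %in% pr
    y <- droplevels(cohort$group[sel])
    Xs <- X[sel, , drop = FALSE]
    fit <- lda_fit(Xs, y)
    resub <- confusion_to_result(predict(fit, Xs)$class, y, positive = pr[1])
    loocv <- loocv_classify(Xs, y, positive = pr[1])
    list(pair = pr, resubstitution = resub, loocv = loocv)
  })
  names(lda_pairs) <- vapply(GROUP_PAIRS, paste, "", collapse = "_vs_")
  lda_all <- loocv_classify(X, cohort$group)

  # --- partial correlations in PD ----------------------------------------
  pd <- cohort[cohort$group == "PD", , drop = FALSE]
  correlations <- NULL
  if (nrow(pd) > 6 && all(c("duration", "updrs_iii", "hoehn_yahr") %in% names(pd))) {
    pd_cov3 <- data.frame(age = pd$age,
                          gender = as.numeric(factor(pd$gender, c("M", "F"))) - 1,
                          duration = pd$duration)
    correlations <- do.call(rbind, lapply(REGION_CODES, function(r) {
      rbind(
        data.frame(region = r, score = "updrs_iii",
                   as.data.frame(pearson_partial_correlation(
                     pd[[r]], pd$updrs_iii, pd_cov3)[c("r", "p")])),
        data.frame(region = r, score = "hoehn_yahr",
                   as.data.frame(pearson_partial_correlation(
                     pd[[r]], pd$hoehn_yahr, pd_cov3)[c("r", "p")])),
        data.frame(region = r, score = "duration",
                   as.data.frame(pearson_partial_correlation(
                     pd[[r]], pd$duration, pd_cov3[, c("age", "gender")])[c("r", "p")]))
      )
    }))
    correlations$significant <- correlations$p < alpha
  }

  structure(list(ancova = ancova, pairwise = pairwise, roc = roc,
                 lda_pairs = lda_pairs, lda_all_groups = lda_all,
                 correlations = correlations,
                 alpha = alpha, alpha_corrected = alpha_corr,
                 group_sizes = table(cohort$group)),
            class = "susc_analysis")
}

#' @export
print.susc_analysis <- function(x, ...) {
  cat("Cohort susceptibility analysis\n")
  cat("  groups:", paste(sprintf("%s n=%d", names(x$group_sizes),
                                 x$group_sizes), collapse = ", "), "\n")
  cat(sprintf("  significance: alpha = %.3g, Bonferroni-corrected = %.4f\n",
              x$alpha, x$alpha_corrected))
  cat("  region ANCOVA F (p):\n")
  for (r in names(x$ancova))
    cat(sprintf("    %-4s F(%d,%d) = %7.3f  p = %.3g\n", r,
                x$ancova[[r]]$df_between, x$ancova[[r]]$df_within,
                x$ancova[[r]]$F, x$ancova[[r]]$p))
  cat("  pairwise LDA (LOOCV accuracy):\n")
  for (nm in names(x$lda_pairs)) {
    d <- x$lda_pairs[[nm]]$loocv
    cat(sprintf("    %-14s %.1f%% (sens %.1f%%, spec %.1f%%)\n",
                gsub("_vs_", " vs ", nm), 100 * d$accuracy,
                100 * d$sensitivity, 100 * d$specificity))
  }
  cat(sprintf("  four-group LOOCV accuracy: %.1f%%\n",
              100 * x$lda_all_groups$accuracy))
  invisible(x)
}

#' @export
summary.susc_analysis <- function(object, ...) {
  sig <- object$pairwise[object$pairwise$significant, , drop = FALSE]
  cat(sprintf("%d of %d pairwise region comparisons significant at %.4f\n",
              nrow(sig), nrow(object$pairwise), object$alpha_corrected))
  if (nrow(sig))
    print(format(sig[, c("region", "group_a", "group_b", "p", "test")],
                 digits = 3), row.names = FALSE)
  if (!is.null(object$correlations)) {
    cs <- object$correlations[object$correlations$significant, , drop = FALSE]
    cat(sprintf("\n%d significant partial correlations in PD (alpha %.2f):\n",
                nrow(cs), object$alpha))
    if (nrow(cs)) print(format(cs, digits = 3), row.names = FALSE)
  }
  invisible(object)
}
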