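## ROI-wise group statistics: hypoperfusion / atrophy t-tests with
## Bonferroni control, per-ROI severity regression, demographic comparisons.

#' ROI-wise two-sample t-tests with Bonferroni correction
#'
#' Runs a two-tailed two-sample t-test per parcel (pooled variance by
#' default, Welch optional) comparing group 1 against group 2, and controls
#' the family-wise error over `n_tests` comparisons by Bonferroni. The same
#' engine serves mean-CBF (hypoperfusion) and ROI-volume (atrophy)
#' comparisons. Parcels missing (NA) in more than half of either group are
#' skipped and logged.
#'
#' @param values_a,values_b numeric matrices, participants x parcels
#'   (group 1 and group 2).
#' @param n_tests number of tests Bonferroni corrects over (default the
#'   parcel count).
#' @param var_equal pooled-variance t-test when TRUE (df = n1 + n2 - 2).
#' @param alpha family-wise significance level.
#' @return list of class `roi_test_table`: `table` (data.frame parcel,
#'   t_statistic, df, p_raw, p_bonferroni, significant_fwe, direction),
#'   `log`, `n_tests`, `alpha`.
#' @export
roi_group_ttest <- function(values_a, values_b, n_tests = ncol(values_a),
                            var_equal = TRUE, alpha = 0.05) {
  stopifnot(ncol(values_a) == ncol(values_b))
  p <- ncol(values_a)
  log <- character(0)
  rows <- vector("list", p)
  for (j in seq_len(p)) {
    a <- values_a[, j]; b <- values_b[, j]
    if (mean(is.na(a)) > 0.5 || mean(is.na(b)) > 0.5) {
      log <- c(log, sprintf("parcel %d skipped: missing in > 50%% of a group", j))
      rows[[j]] <- data.frame(parcel = j, t_statistic = NA_real_, df = NA_real_,
                              p_raw = NA_real_, p_bonferroni = NA_real_,
                              significant_fwe = FALSE, direction = NA_character_)
      next
    }
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      log <- c(log, sprintf("parcel %d skipped: fewer than 2 observations in a group", j))
      rows[[j]] <- data.frame(parcel = j, t_statistic = NA_real_, df = NA_real_,
                              p_raw = NA_real_, p_bonferroni = NA_real_,
                              significant_fwe = FALSE, direction = NA_character_)
      next
    }
    if (stats::var(a) + stats::var(b) == 0) {
      # degenerate: no within-group variability (tiny parcels); no evidence
      # of a difference unless the constants differ
      df0 <- length(a) + length(b) - 2
      tt <- if (mean(a) == mean(b))
        list(statistic = 0, parameter = df0, p.value = 1)
      else
        list(statistic = sign(mean(a) - mean(b)) * Inf, parameter = df0,
             p.value = 0)
    } else {
      tt <- stats::t.test(a, b, var.equal = var_equal)
    }
    p_b <- min(1, tt$p.value * n_tests)
    rows[[j]] <- data.frame(parcel = j,
                            t_statistic = unname(tt$statistic),
                            df = unname(tt$parameter),
                            p_raw = tt$p.value,
                            p_bonferroni = p_b,
                            significant_fwe = p_b < alpha,
                            direction = if (mean(a) < mean(b)) "lower_in_group1"
                                        else "higher_in_group1",
                            stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), log = log,
                 n_tests = n_tests, alpha = alpha),
            class = "roi_test_table")
}

#' @export
print.roi_test_table <- function(x, ...) {
  sig <- sum(x$table$significant_fwe, na.rm = TRUE)
  cat(sprintf("roi_test_table: %d parcels, %d significant at Bonferroni pFWE < %.2f\n",
              nrow(x$table), sig, x$alpha))
  invisible(x)
}

#' Per-ROI linear regression of CBF on a severity score
#'
#' Ordinary least squares per parcel with CBF as the response. Participants
#' without a severity score (NA) are excluded. Significance is reported
#' uncorrected at `alpha`; an inverse association is a negative slope.
#'
#' @param roi_cbf participants x parcels matrix of ROI mean CBF.
#' @param severity per-participant severity scores (NA allowed).
#' @param alpha uncorrected significance level.
#' @return data.frame: parcel, slope, intercept, p_raw,
#'   significant_uncorrected, n.
#' @export
severity_regression <- function(roi_cbf, severity, alpha = 0.05) {
  stopifnot(nrow(roi_cbf) == length(severity))
  keep <- !is.na(severity)
  if (sum(keep) < 3) stop("need at least 3 participants with severity scores")
  s <- severity[keep]
  if (stats::var(s) == 0) stop("severity score has zero variance")
  y <- roi_cbf[keep, , drop = FALSE]
  do.call(rbind, lapply(seq_len(ncol(y)), function(j) {
    ok <- !is.na(y[, j])
    fit <- stats::lm(y[ok, j] ~ s[ok])
    # noise-free inputs give an exact fit; the perfect-fit caution is moot
    cf <- suppressWarnings(summary(fit))$coefficients
    pv <- if (nrow(cf) >= 2) cf[2, 4] else NA_real_
    data.frame(parcel = j, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]), p_raw = pv,
               significant_uncorrected = !is.na(pv) && pv < alpha,
               n = sum(ok))
  }))
}

#' Demographic comparisons between the two patient groups
#'
#' Pooled-variance t-tests for ordinal covariates (age, education, severity;
#' df = n1 + n2 - 2) and a chi-squared test for sex.
#'
#' @param manifest cohort manifest data.frame with columns `group`, `age`,
#'   `education`, `severity`, `sex`.
#' @param groups the two groups compared.
#' @param correct continuity correction for the chi-squared test.
#' @return data.frame: variable, test, statistic, df, p_value.
#' @export
compare_demographics <- function(manifest, groups = c("tau_like", "tdp_like"),
                                 correct = FALSE) {
  a <- manifest[manifest$group == groups[1], ]
  b <- manifest[manifest$group == groups[2], ]
  if (nrow(a) < 2 || nrow(b) < 2) stop("need at least 2 participants per group")
  rows <- list()
  for (v in intersect(c("age", "education", "severity"), names(manifest))) {
    tt <- stats::t.test(a[[v]], b[[v]], var.equal = TRUE)
    rows[[v]] <- data.frame(variable = v, test = "t",
                            statistic = unname(tt$statistic),
                            df = unname(tt$parameter), p_value = tt$p.value)
  }
  if ("sex" %in% names(manifest)) {
    tab <- table(factor(c(rep(groups[1], nrow(a)), rep(groups[2], nrow(b))),
                        levels = groups),
                 factor(c(a$sex, b$sex)))
    cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    rows$sex <- data.frame(variable = "sex", test = "chisq",
                           statistic = unname(cs$statistic),
                           df = unname(cs$parameter), p_value = cs$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
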