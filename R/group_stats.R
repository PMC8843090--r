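#' Voxel-wise spatial correlation between two maps
#'
#' Pearson correlation across voxels of two maps over the same ROI
#' support, with a t-approximation p-value. Spatial autocorrelation is
#' not corrected: the p-value is optimistic for smooth maps, which is
#' why coefficient-space correlation ([coefficient_correlation()]) is
#' provided as the complementary statistic (trend-surface coefficients
#' are orthogonal summaries).
#'
#' @param map1,map2 numeric vectors over the same ROI voxel list.
#' @return list `r`, `p`, `n`, and `note` flagging the autocorrelation
#'   caveat.
#' @export
spatial_correlation <- function(map1, map2) {
  if (length(map1) != length(map2))
    stop("support mismatch: maps have different voxel counts")
  if (sd(map1) == 0 || sd(map2) == 0) stop("zero-variance map")
  n <- length(map1)
  r <- cor(map1, map2)
  list(r = r, p = cor_p(r, n), n = n,
       note = "spatial autocorrelation not corrected")
}

cor_p <- function(r, n) {
  if (abs(r) >= 1) return(.Machine$double.xmin)
  tv <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tv), df = n - 2)
}

#' Correlation across trend-surface coefficient vectors
#'
#' Pearson correlation between two concatenated coefficient vectors
#' (e.g. the 36 coefficients of four striatal subregions). Both vectors
#' must use the identical concatenation order.
#'
#' @param beta_a,beta_b coefficient vectors of equal length.
#' @return list `r`, `p`, `n`.
#' @export
coefficient_correlation <- function(beta_a, beta_b) {
  if (length(beta_a) != length(beta_b))
    stop("coefficient vectors have different lengths")
  n <- length(beta_a)
  r <- cor(beta_a, beta_b)
  list(r = r, p = cor_p(r, n), n = n)
}

#' Quality-filter subject modes by correlation with a reference
#'
#' Keeps subjects whose mode correlates with the group reference at
#' strictly more than `r_min` (a subject at exactly `r_min` is dropped).
#'
#' @param modes list of per-subject mode vectors (or
#'   `connectivity_mode`s) on a common support.
#' @param reference group-level mode vector (or `connectivity_mode`).
#' @param r_min correlation threshold (default 0.5).
#' @return list `kept` (indices), `r` (per subject), `n_kept`,
#'   `n_dropped`.
#' @export
filter_by_reference <- function(modes, reference, r_min = 0.5) {
  ref <- if (inherits(reference, "connectivity_mode")) reference$values
         else as.numeric(reference)
  r <- vapply(modes, function(m) {
    v <- if (inherits(m, "connectivity_mode")) m$values else as.numeric(m)
    if (length(v) != length(ref)) stop("support mismatch")
    cor(v, ref)
  }, numeric(1))
  kept <- which(r > r_min)
  list(kept = kept, r = r, n_kept = length(kept),
       n_dropped = length(modes) - length(kept))
}

#' ICC(2,k): two-way random effects, absolute agreement, average measures
#'
#' Computed from the two-way ANOVA decomposition of a subjects x
#' sessions matrix:
#' `ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)` with `MS_R`
#' the between-subject, `MS_C` the between-session and `MS_E` the
#' residual mean square. The confidence interval is a nonparametric
#' percentile bootstrap over subjects.
#'
#' @param measure_matrix n x k numeric matrix (subjects x sessions,
#'   complete, k >= 2, n >= 3).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap.
#' @param ci_level confidence level (default 0.95).
#' @return list `icc`, `ci_low`, `ci_high`, `n_boot`, `ms` (the three
#'   mean squares).
#' @export
icc_2k <- function(measure_matrix, n_boot = 1000, seed = NULL,
                   ci_level = 0.95) {
  M <- as.matrix(measure_matrix)
  if (any(!is.finite(M))) stop("measurement matrix must be complete")
  n <- nrow(M); k <- ncol(M)
  if (k < 2) stop("need at least 2 sessions")
  if (n < 3) stop("need at least 3 subjects")
  icc_point <- function(M) {
    n <- nrow(M); k <- ncol(M)
    gm <- mean(M)
    ss_r <- k * sum((rowMeans(M) - gm)^2)
    ss_c <- n * sum((colMeans(M) - gm)^2)
    ss_e <- sum((M - outer(rowMeans(M), colMeans(M), "+") + gm)^2)
    ms_r <- ss_r / (n - 1)
    ms_c <- ss_c / (k - 1)
    ms_e <- ss_e / ((n - 1) * (k - 1))
    list(icc = (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n),
         ms = c(MS_R = ms_r, MS_C = ms_c, MS_E = ms_e))
  }
  pt_est <- icc_point(M)
  if (!is.finite(pt_est$icc))
    stop("degenerate variance decomposition (MS_R = MS_E = 0)")
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  boots <- vapply(seq_len(n_boot), function(b) {
    icc_point(M[sample.int(n, n, replace = TRUE), , drop = FALSE])$icc
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  qs <- quantile(boots, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                 names = FALSE)
  list(icc = pt_est$icc, ci_low = qs[1], ci_high = qs[2],
       n_boot = n_boot, ms = pt_est$ms)
}

#' Within- versus between-subject permutation test of mode reproducibility
#'
#' `within_r` is the mean over subjects of the correlation between their
#' session-1 and session-2 modes; `between_r` the mean over ordered
#' pairs of different subjects. The null permutes the session-2 subject
#' labels and recomputes `within_r - between_r`; the p-value uses the
#' add-one estimator `(1 + #{perm >= observed}) / (1 + n_perm)`, which
#' is strictly positive (hence "p < 1/(n_perm)"-style reporting at the
#' attained minimum).
#'
#' @param modes_s1,modes_s2 V x n matrices (columns = subjects, matched
#'   order) or lists of per-subject vectors.
#' @param n_perm number of permutations (default 10000).
#' @param seed seed.
#' @return list `within_r`, `between_r`, `statistic`
#'   (`within - between`), `perm_p`, `n_perm`, `n`.
#' @export
within_between_permutation <- function(modes_s1, modes_s2,
                                       n_perm = 10000, seed = NULL) {
  as_mat <- function(m) {
    if (is.list(m))
      m <- sapply(m, function(x)
        if (inherits(x, "connectivity_mode")) x$values else as.numeric(x))
    as.matrix(m)
  }
  M1 <- as_mat(modes_s1); M2 <- as_mat(modes_s2)
  if (!all(dim(M1) == dim(M2))) stop("subject lists are not matched")
  n <- ncol(M1)
  if (n < 3) stop("need at least 3 subjects")
  R <- cor(M1, M2)                      # R[i, j] = r(s1_i, s2_j)
  tot <- sum(R)
  within <- mean(diag(R))
  between <- (tot - sum(diag(R))) / (n * (n - 1))
  obs <- within - between
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    w <- mean(R[cbind(seq_len(n), perm)])
    stat <- w - (tot - w * n) / (n * (n - 1))
    if (stat >= obs) count <- count + 1L
  }
  list(within_r = within, between_r = between, statistic = obs,
       perm_p = (1 + count) / (1 + n_perm), n_perm = n_perm, n = n)
}

# coefficient columns of a table (versioned contract: b1, b2, ...)
coef_columns <- function(coeffs) {
  grep("^b[0-9]+$", names(coeffs), value = TRUE)
}

#' Omnibus likelihood-ratio test of coefficients against a binary label
#'
#' Logistic regression of the group label on all trend-surface
#' coefficients (plus optional covariates) versus the null model without
#' the coefficients. `X^2 = 2 (l_full - l_null)` on `df = number of
#' coefficients`. Perfect separation (possible at small n with 12
#' coefficients) is detected via diverging coefficients and flagged
#' rather than silently reported.
#'
#' The default p-value uses a finite-sample F-calibrated reference: the
#' LR statistic is mapped through the monotone transform
#' `F = (exp(X^2/n) - 1) (n - df - q - 1) / df` (q = number of
#' covariates) and referred to `F(df, n - df - q - 1)`. For nested
#' linear models this transform recovers the exact null distribution of
#' the LR statistic; for the balanced logistic omnibus it removes the
#' O(1/n) anti-conservatism of the chi-square reference (verified by
#' null calibration simulations in the test suite). The asymptotic
#' chi-square p-value is reported alongside as `p_chisq`.
#'
#' @param coeffs coefficient table with columns `b1..b_p` and the group
#'   column; one row per subject (filter to one session first).
#' @param group_col name of the two-level group column.
#' @param covariates optional character vector of covariate columns.
#' @return An `omnibus_result`: `statistic`, `df`, `p`, `n`,
#'   `model_full`, `model_null`, `separation` flag.
#' @export
omnibus_lr_binary <- function(coeffs, group_col = "group",
                              covariates = NULL) {
  bc <- coef_columns(coeffs)
  if (!length(bc)) stop("no coefficient columns (b1, b2, ...) found")
  if (anyNA(coeffs[bc])) stop("missing coefficient entries")
  g <- factor(coeffs[[group_col]])
  if (nlevels(g) != 2) stop("`", group_col, "` must have exactly 2 levels")
  df_all <- data.frame(.g = as.integer(g) - 1L,
                       coeffs[c(bc, covariates)])
  n <- nrow(df_all)
  if (min(table(g)) < length(bc) + 5)
    warning("fewer than df + 5 subjects per group; test may be unstable")
  rhs_null <- if (length(covariates))
    paste(covariates, collapse = " + ") else "1"
  full <- suppressWarnings(
    glm(stats::reformulate(c(bc, covariates), ".g"), family = binomial(),
        data = df_all))
  null <- suppressWarnings(
    glm(stats::reformulate(rhs_null, ".g"), family = binomial(),
        data = df_all))
  x2 <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  df <- length(bc)
  sep <- any(abs(coef(full)[bc]) > 15) ||
    all(abs(full$fitted.values - df_all$.g) < 1e-8)
  if (sep)
    warning("possible perfect separation in the logistic model; ",
            "statistic flagged as unreliable")
  structure(list(statistic = x2, df = df,
                 p = lr_p_calibrated(x2, df, n, length(covariates)),
                 p_chisq = pchisq(x2, df, lower.tail = FALSE), n = n,
                 model_full = "group ~ coefficients",
                 model_null = paste0("group ~ ", rhs_null),
                 separation = sep),
            class = "omnibus_result")
}

# finite-sample F-calibrated p-value for an LR chi-square from a model
# with df tested terms and q covariates: invert the nested-linear-model
# identity X^2 = n log(1 + df F / df2) and refer to F(df, df2). Falls
# back to the asymptotic chi-square when the residual df is exhausted.
lr_p_calibrated <- function(x2, df, n, q = 0) {
  df2 <- n - df - q - 1
  if (df2 < 1) {
    warning("residual df exhausted; using the asymptotic chi-square p")
    return(pchisq(x2, df, lower.tail = FALSE))
  }
  f_stat <- (exp(x2 / n) - 1) * df2 / df
  stats::pf(f_stat, df, df2, lower.tail = FALSE)
}

#' Omnibus likelihood-ratio test of coefficients against a continuous outcome
#'
#' Linear model of the outcome on all coefficients (plus optional
#' covariates) versus the null model; the likelihood-ratio statistic is
#' `X^2 = n log(RSS_null / RSS_full)` on `df = number of coefficients`.
#' Because the LR statistic is a monotone transform of the exact F
#' statistic, the default p-value is computed from the exact F null
#' distribution (so it is exactly calibrated at any n); the asymptotic
#' chi-square p is reported alongside as `p_chisq`. `form = "F"`
#' reports the F statistic itself instead of the LR chi-square.
#'
#' @param coeffs coefficient table (one row per subject).
#' @param outcome_col name of the continuous outcome column.
#' @param covariates optional covariate column names.
#' @param form `"LR"` (default, chi-square) or `"F"`.
#' @return An `omnibus_result`.
#' @export
omnibus_lr_continuous <- function(coeffs, outcome_col = "outcome",
                                  covariates = NULL, form = c("LR", "F")) {
  form <- match.arg(form)
  bc <- coef_columns(coeffs)
  if (!length(bc)) stop("no coefficient columns (b1, b2, ...) found")
  if (anyNA(coeffs[c(bc, outcome_col, covariates)]))
    stop("incomplete cases in coefficients/outcome")
  y <- coeffs[[outcome_col]]
  if (sd(y) == 0) stop("zero-variance outcome")
  df_all <- data.frame(.y = y, coeffs[c(bc, covariates)])
  n <- nrow(df_all)
  rhs_null <- if (length(covariates))
    paste(covariates, collapse = " + ") else "1"
  full <- lm(stats::reformulate(c(bc, covariates), ".y"), data = df_all)
  null <- lm(stats::reformulate(rhs_null, ".y"), data = df_all)
  rss_f <- sum(full$residuals^2)
  rss_n <- sum(null$residuals^2)
  df <- length(bc)
  df2 <- full$df.residual
  f_stat <- ((rss_n - rss_f) / df) / (rss_f / df2)
  p_exact <- stats::pf(f_stat, df, df2, lower.tail = FALSE)
  if (form == "LR") {
    x2 <- n * log(rss_n / rss_f)
    p <- p_exact
    p_chisq <- pchisq(x2, df, lower.tail = FALSE)
  } else {
    x2 <- f_stat
    p <- p_exact
    p_chisq <- p_exact
  }
  structure(list(statistic = x2, df = df, p = p, p_chisq = p_chisq,
                 n = n,
                 model_full = paste0(outcome_col, " ~ coefficients"),
                 model_null = paste0(outcome_col, " ~ ", rhs_null),
                 separation = FALSE, form = form),
            class = "omnibus_result")
}

#' @export
print.omnibus_result <- function(x, ...) {
  cat(sprintf("<omnibus_result> X2 = %.3f, df = %d, p = %.4g (n = %d)%s\n",
              x$statistic, x$df, x$p, x$n,
              if (isTRUE(x$separation)) " [separation flagged]" else ""))
  invisible(x)
}

#' Change-score omnibus analysis between two sessions
#'
#' Forms per-subject coefficient and outcome differences (`delta = B -
#' A`) between two paired sessions and runs the continuous omnibus test
#' of `delta outcome` on `delta coefficients`.
#'
#' @param coeffs_sessA,coeffs_sessB coefficient tables for the two
#'   sessions with a shared `subject` column and coefficient columns.
#' @param outcomeA,outcomeB per-row outcome vectors (default: the
#'   tables' `outcome` columns).
#' @return An `omnibus_result` on the change scores.
#' @export
change_score_analysis <- function(coeffs_sessA, coeffs_sessB,
                                  outcomeA = coeffs_sessA$outcome,
                                  outcomeB = coeffs_sessB$outcome) {
  bc <- coef_columns(coeffs_sessA)
  if (!setequal(bc, coef_columns(coeffs_sessB)))
    stop("sessions have different coefficient columns")
  a <- coeffs_sessA[order(coeffs_sessA$subject), , drop = FALSE]
  b <- coeffs_sessB[order(coeffs_sessB$subject), , drop = FALSE]
  oa <- outcomeA[order(coeffs_sessA$subject)]
  ob <- outcomeB[order(coeffs_sessB$subject)]
  if (!identical(a$subject, b$subject))
    stop("unpaired subjects between sessions")
  delta <- as.data.frame(as.matrix(b[bc]) - as.matrix(a[bc]))
  delta$outcome <- ob - oa
  delta$subject <- a$subject
  omnibus_lr_continuous(delta, outcome_col = "outcome")
}

#' Post-hoc per-coefficient Pearson correlations with an outcome
#'
#' One (r, p) per coefficient, deliberately uncorrected for multiple
#' comparisons: these are descriptive follow-ups to a significant
#' omnibus test, identifying which coefficients drive it.
#'
#' @param coeffs coefficient table.
#' @param outcome outcome vector (default the table's `outcome` column).
#' @return data.frame with `coefficient`, `r`, `p`.
#' @export
posthoc_pearson <- function(coeffs, outcome = coeffs$outcome) {
  bc <- coef_columns(coeffs)
  n <- nrow(coeffs)
  if (sd(outcome) == 0) stop("zero-variance outcome")
  out <- lapply(bc, function(cn) {
    x <- coeffs[[cn]]
    if (sd(x) == 0) stop("zero-variance coefficient column: ", cn)
    r <- cor(x, outcome)
    data.frame(coefficient = cn, r = r, p = cor_p(r, n))
  })
  do.call(rbind, out)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise alpha.
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`, e.g. 0.05 / 4 = 0.0125.
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("`m` must be >= 1")
  alpha / m
}
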