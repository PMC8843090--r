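test_that("spatial_correlation matches the direct formula with its caveat", {
  x <- c(1, 4, 2, 8, 5, 7)
  y <- c(2, 5, 1, 9, 4, 8)
  res <- spatial_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  expect_equal(res$p, stats::cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_match(res$note, "autocorrelation")
  expect_equal(spatial_correlation(x, x)$r, 1)
  expect_equal(spatial_correlation(x, -x)$r, -1)
  expect_error(spatial_correlation(x, y[1:5]), "support mismatch")
  expect_error(spatial_correlation(x, rep(1, 6)), "zero-variance")
})

test_that("coefficient_correlation behaves across scaling and orthogonality", {
  set.seed(61)
  a <- rnorm(36)
  expect_equal(coefficient_correlation(a, 2 * a)$r, 1, tolerance = 1e-12)
  # orthogonalized long random vectors decorrelate
  x <- rnorm(1000)
  z <- rnorm(1000)
  z <- z - sum(z * (x - mean(x))) / sum((x - mean(x))^2) * (x - mean(x))
  expect_lte(abs(coefficient_correlation(x, z)$r), 0.05)
  expect_error(coefficient_correlation(a, a[1:10]), "lengths")
})

test_that("filter_by_reference applies a strict threshold", {
  set.seed(62)
  ref <- rnorm(40)
  exact <- rnorm(40)
  # engineer a subject at exactly r = 0.5 via projection mixing
  refc <- (ref - mean(ref)) / sd(ref)
  e <- exact - mean(exact)
  e <- e - sum(e * refc) / sum(refc^2) * refc
  e <- e / sd(e)
  at_half <- 0.5 * refc + sqrt(1 - 0.25) * e
  stopifnot(abs(cor(at_half, ref) - 0.5) < 1e-12)
  anti <- -ref + rnorm(40, sd = 0.3)     # strongly negative, r > -1
  modes <- list(ref, at_half, anti, ref + rnorm(40, sd = 0.1))
  res <- filter_by_reference(modes, ref, r_min = 0.5)
  expect_false(2 %in% res$kept)          # r = 0.5 exactly -> dropped
  expect_true(all(c(1, 4) %in% res$kept))
  expect_false(3 %in% res$kept)
  expect_equal(res$n_kept + res$n_dropped, 4)
  expect_equal(filter_by_reference(modes, ref, r_min = -1)$n_kept, 4)
})

test_that("icc_2k equals the ANOVA oracle and honours its contract", {
  set.seed(63)
  for (rep in 1:5) {
    n <- sample(6:30, 1)
    M <- matrix(rnorm(n * 2), n, 2) + rnorm(n) * 1.5
    res <- icc_2k(M, n_boot = 50, seed = rep)
    expect_equal(res$icc, oracle_icc_aov(M), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_lte(res$icc, 1)
    expect_lte(res$ci_low, res$icc + 1e-12)
    expect_gte(res$ci_high, res$icc - 1e-12)
  }
  # duplicated sessions -> exactly 1
  M <- matrix(rnorm(10), 10, 1)[, c(1, 1)]
  expect_equal(icc_2k(M, n_boot = 10, seed = 1)$icc, 1)
  # independent sessions at large n -> near 0
  iccs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    icc_2k(matrix(rnorm(400), 200, 2), n_boot = 2, seed = s)$icc
  }, numeric(1))
  expect_lte(mean(abs(iccs)), 0.15)
  expect_error(icc_2k(matrix(rnorm(4), 2, 2)), "3 subjects")
  expect_error(icc_2k(matrix(rnorm(6), 6, 1)), "2 sessions")
  expect_error(icc_2k(matrix(1, 5, 2)), "degenerate")
})

test_that("within/between permutation test attains its bounds and validity", {
  set.seed(64)
  # perfectly reproducible, subject-distinct modes: minimal p attained
  M <- matrix(rnorm(50 * 8), 50, 8)
  res <- within_between_permutation(M, M, n_perm = 999, seed = 2)
  expect_equal(res$within_r, 1)
  expect_lt(res$between_r, 0.7)
  expect_equal(res$perm_p, 1 / 1000)
  expect_gte(res$within_r, res$between_r)

  # exchangeable null: all subjects share one mode plus noise
  ps <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    base <- rnorm(30)
    M1 <- base + matrix(rnorm(30 * 6), 30, 6)
    M2 <- base + matrix(rnorm(30 * 6), 30, 6)
    within_between_permutation(M1, M2, n_perm = 99, seed = s)$perm_p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(within_between_permutation(M, M[, 1:3]), "not matched")
})

test_that("binary omnibus LR test is exact in structure and flags separation", {
  set.seed(65)
  n <- 60
  B <- matrix(rnorm(n * 6), n, 6)
  tab <- data.frame(B); names(tab) <- paste0("b", 1:6)
  tab$group <- rep(c("A", "B"), each = 30)
  res <- omnibus_lr_binary(tab)
  expect_equal(res$df, 6)
  expect_gte(res$statistic, 0)
  expect_true(res$p > 0 && res$p <= 1)
  # df follows the coefficient count (12-coefficient variant)
  B12 <- matrix(rnorm(30 * 12), 30, 12)
  t12 <- data.frame(B12); names(t12) <- paste0("b", 1:12)
  t12$group <- rep(c("A", "B"), each = 15)
  expect_warning(r12 <- omnibus_lr_binary(t12), "df \\+ 5")
  expect_equal(r12$df, 12)
  # gross separation is flagged
  sep <- tab
  sep$b1 <- ifelse(sep$group == "A", -5, 5) + rnorm(n, sd = 0.01)
  expect_warning(rs <- omnibus_lr_binary(sep), "separation")
  expect_true(rs$separation)
  # matches glm's own anova chi-square
  fit_full <- glm(I(group == "B") ~ ., data = tab, family = binomial())
  dev_drop <- fit_full$null.deviance - fit_full$deviance
  expect_equal(res$statistic, dev_drop, tolerance = 1e-8)
})

test_that("continuous omnibus LR and F forms agree with direct computation", {
  set.seed(66)
  n <- 50
  tab <- data.frame(matrix(rnorm(n * 6), n, 6))
  names(tab) <- paste0("b", 1:6)
  tab$outcome <- tab$b1 * 0.5 + rnorm(n)
  res <- omnibus_lr_continuous(tab)
  full <- lm(outcome ~ ., data = tab)
  null <- lm(outcome ~ 1, data = tab)
  x2_direct <- n * log(sum(null$residuals^2) / sum(full$residuals^2))
  expect_equal(res$statistic, x2_direct, tolerance = 1e-10)
  expect_equal(res$df, 6)
  resF <- omnibus_lr_continuous(tab, form = "F")
  expect_equal(resF$statistic,
               unname(anova(null, full)$F[2]), tolerance = 1e-10)
  expect_error(omnibus_lr_continuous(transform(tab, outcome = 1)),
               "zero-variance")
  # a covariate uncorrelated with both sides barely moves the statistic
  tab$cov <- rnorm(n)
  res_cov <- omnibus_lr_continuous(tab, covariates = "cov")
  expect_lt(abs(res_cov$statistic - res$statistic), 5)
})

test_that("change-score analysis pairs subjects and uses B minus A", {
  set.seed(67)
  n <- 30
  mk <- function(betas, outcome) {
    d <- data.frame(subject = 1:n, betas)
    names(d)[-1] <- paste0("b", 1:6)
    d$outcome <- outcome
    d
  }
  BA <- matrix(rnorm(n * 6), n, 6)
  BB <- BA + 0.4                  # uniform coefficient change
  dB <- rnorm(n)
  a <- mk(BA, rep(0, n))
  b <- mk(BB, dB)
  # delta coefficients are constant here, so they cannot predict delta
  # outcome; the omnibus runs but the statistic is essentially zero
  expect_error(change_score_analysis(a, a), "zero-variance")
  # planted coupling between delta-beta and delta-outcome is detected
  BB2 <- BA + matrix(rnorm(n * 6, sd = 0.5), n, 6)
  d_out <- (BB2[, 1] - BA[, 1]) * 2 + rnorm(n, sd = 0.2)
  b2 <- mk(BB2, d_out)
  res <- change_score_analysis(a, b2)
  expect_lt(res$p, 0.001)
  # sign convention: delta = B - A, checked on a hand pair
  one_a <- mk(matrix(0, n, 6), rep(0, n))
  one_b <- mk(matrix(1, n, 6), rnorm(n))
  expect_error(change_score_analysis(one_a, one_b[1:10, ]),
               "unpaired|not matched|differ")
})

test_that("posthoc_pearson gives one uncorrected (r, p) per coefficient", {
  set.seed(68)
  n <- 40
  tab <- data.frame(matrix(rnorm(n * 6), n, 6))
  names(tab) <- paste0("b", 1:6)
  tab$outcome <- tab$b3
  res <- posthoc_pearson(tab)
  expect_equal(nrow(res), 6)     # table length = omnibus df
  expect_equal(res$r[res$coefficient == "b3"], 1)
  # matches cor.test on a hand 5-point case
  t5 <- data.frame(b1 = c(1, 3, 2, 5, 4), outcome = c(2, 3, 1, 6, 5))
  r5 <- posthoc_pearson(t5)
  ct <- stats::cor.test(t5$b1, t5$outcome)
  expect_equal(r5$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r5$p, ct$p.value, tolerance = 1e-10)
})

test_that("bonferroni matches the published correction scheme", {
  expect_equal(bonferroni(0.05, 4), 0.0125)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(0.05, 0), "m")
  # the omnibus p = 0.007 survives 0.05/4; p = 0.035 does not
  expect_lt(0.007, bonferroni(0.05, 4))
  expect_gt(0.035, bonferroni(0.05, 4))
})
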