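#' Polynomial spatial basis over ROI world coordinates
#'
#' Builds the trend-surface design matrix: per-axis powers
#' `x^1..x^d, y^1..y^d, z^1..z^d` of world (mm) coordinates, giving
#' exactly `3 * degree` columns — no cross-terms and no intercept (the
#' mode's mean is absorbed by centring the response). A degree-2 model
#' therefore has 6 coefficients and a degree-4 model 12.
#'
#' Coordinates are affinely normalized per axis to \[-1, 1\] before
#' powering: raw mm coordinates raised to the 4th power are severely
#' ill-conditioned. For cross-subject comparability the normalization
#' must be computed once per ROI mask and reused for every subject;
#' pass the first basis's `normalization` back in to enforce this.
#'
#' @param world_coords V x 3 matrix of world coordinates (mm).
#' @param degree polynomial degree, 2..5.
#' @param normalization optional 2 x 3 matrix (rows: centre, half-range)
#'   from a previous basis over the same ROI mask.
#' @return A `spatial_basis`: list with `design` (V x 3*degree),
#'   `degree`, `normalization`, `col_means` (used to centre the design
#'   during fitting) and `condition_number`.
#' @export
build_basis <- function(world_coords, degree, normalization = NULL) {
  world_coords <- as.matrix(world_coords)
  if (!(degree %in% 2:5)) stop("`degree` must be in 2..5")
  V <- nrow(world_coords)
  if (V <= 3 * degree)
    stop(sprintf("need more than %d voxels for degree %d", 3 * degree, degree))
  if (is.null(normalization)) {
    lo <- apply(world_coords, 2, min)
    hi <- apply(world_coords, 2, max)
    if (any(hi - lo < .Machine$double.eps))
      stop("degenerate axis: all coordinates equal along axis ",
           paste(which(hi - lo < .Machine$double.eps), collapse = ", "))
    normalization <- rbind(centre = (lo + hi) / 2, half_range = (hi - lo) / 2)
  }
  u <- sweep(sweep(world_coords, 2, normalization[1, ]), 2,
             normalization[2, ], "/")
  design <- matrix(0, V, 3 * degree)
  nm <- character(3 * degree)
  ax <- c("x", "y", "z")
  for (a in 1:3) for (p in seq_len(degree)) {
    j <- (a - 1) * degree + p
    design[, j] <- u[, a]^p
    nm[j] <- paste0(ax[a], p)
  }
  colnames(design) <- nm
  sv <- svd(design, nu = 0, nv = 0)$d
  structure(list(design = design, degree = degree,
                 normalization = normalization,
                 col_means = colMeans(design),
                 condition_number = sv[1] / sv[length(sv)]),
            class = "spatial_basis")
}

# the basis carries no intercept column, so the fit centres both the
# response and the design columns; the mode's mean is restored on
# reconstruction
centred_design <- function(basis) {
  sweep(basis$design, 2, basis$col_means)
}

# evidence machinery: economy SVD of the (centred) design, reused across
# (alpha, lambda) evaluations. alpha = weight precision, lambda = noise
# precision.
blr_svd <- function(design, y) {
  sv <- svd(design)
  list(d = sv$d, u = sv$u, v = sv$v,
       c = drop(crossprod(sv$u, y)),    # projections of y on left basis
       yy = sum(y^2), n = length(y), p = ncol(design))
}

blr_evidence <- function(sv, alpha, lambda) {
  d2 <- sv$d^2
  denom <- alpha + lambda * d2
  m_rot <- lambda * sv$d * sv$c / denom      # coefficients in rotated basis
  resid2 <- sum((sv$c * alpha / denom)^2) + (sv$yy - sum(sv$c^2))
  m2 <- sum(m_rot^2)
  e_mn <- lambda / 2 * resid2 + alpha / 2 * m2
  log_det_a <- sum(log(denom)) + (sv$p - length(d2)) * log(alpha)
  0.5 * sv$p * log(alpha) + 0.5 * sv$n * log(lambda) - e_mn -
    0.5 * log_det_a - 0.5 * sv$n * log(2 * pi)
}

blr_beta <- function(sv, alpha, lambda) {
  denom <- alpha + lambda * sv$d^2
  drop(sv$v %*% (lambda * sv$d * sv$c / denom))
}

# gradient of the log evidence in (log alpha, log lambda); standard
# envelope-theorem expressions evaluated at the posterior mean
blr_evidence_grad <- function(sv, alpha, lambda) {
  d2 <- sv$d^2
  denom <- alpha + lambda * d2
  m_rot <- lambda * sv$d * sv$c / denom
  resid2 <- sum((sv$c * alpha / denom)^2) + (sv$yy - sum(sv$c^2))
  m2 <- sum(m_rot^2)
  g_a <- sv$p / (2 * alpha) - m2 / 2 - 0.5 * sum(1 / denom)
  g_l <- sv$n / (2 * lambda) - resid2 / 2 - 0.5 * sum(d2 / denom)
  c(alpha * g_a, lambda * g_l)
}

#' Fit a trend surface model by empirical-Bayes linear regression
#'
#' Bayesian linear regression of a (centred) connectivity mode on the
#' polynomial spatial basis, with an isotropic Gaussian prior on the
#' weights (precision `alpha`) and Gaussian noise (precision `lambda`).
#' The two hyperparameters — controlling the data (weight) variance and
#' the noise variance — are set by empirical Bayes: maximizing the
#' closed-form log marginal likelihood (model evidence) over
#' `(log alpha, log lambda)` with a gradient-based optimizer run from
#' several starts. The reported coefficients are the maximum a
#' posteriori (= posterior mean) weights at the optimum; at fixed
#' hyperparameters they coincide with the ridge solution with penalty
#' `alpha / lambda`.
#'
#' @param basis a [build_basis()] result.
#' @param y mode values (length V); centred internally, the mean is
#'   stored on the fit.
#' @param max_iter optimizer iteration cap per start.
#' @param starts matrix of starting values, rows = `(log alpha,
#'   log lambda)`.
#' @return A `tsm_fit`: `degree`, `beta` (3*degree MAP coefficients),
#'   `y_mean`, `hyper` (`noise_variance = 1/lambda`,
#'   `weight_variance = 1/alpha`), `log_evidence`,
#'   `variance_explained`, `converged`.
#' @export
fit_blr <- function(basis, y, max_iter = 200,
                    starts = rbind(c(0, 0), c(-4, 2), c(4, -2))) {
  stopifnot(inherits(basis, "spatial_basis"))
  y <- as.numeric(y)
  if (length(y) != nrow(basis$design))
    stop("length of y does not match the basis")
  y_mean <- mean(y)
  yc <- y - y_mean
  if (sum(yc^2) < .Machine$double.eps)
    stop("zero-variance response")
  sv <- blr_svd(centred_design(basis), yc)
  neg_ev <- function(th) -blr_evidence(sv, exp(th[1]), exp(th[2]))
  neg_gr <- function(th) -blr_evidence_grad(sv, exp(th[1]), exp(th[2]))
  # hyperparameters are confined to [1e-14, 1e14]: a noiseless response
  # pushes the noise precision to the boundary, where the fit is
  # (correctly) ordinary least squares
  bound <- 14 * log(10)
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    opt <- optim(starts[i, ], neg_ev, gr = neg_gr, method = "L-BFGS-B",
                 lower = c(-bound, -bound), upper = c(bound, bound),
                 control = list(maxit = max_iter, factr = 10))
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!any_conv)
    stop(sprintf(
      "evidence optimization did not converge in %d iterations (last log evidence %.6g)",
      max_iter, -best$value))
  alpha <- exp(best$par[1]); lambda <- exp(best$par[2])
  beta <- blr_beta(sv, alpha, lambda)
  names(beta) <- colnames(basis$design)
  fitted <- drop(centred_design(basis) %*% beta)
  ve <- 1 - sum((yc - fitted)^2) / sum(yc^2)
  structure(list(degree = basis$degree, beta = beta, y_mean = y_mean,
                 hyper = c(noise_variance = 1 / lambda,
                           weight_variance = 1 / alpha),
                 log_evidence = -best$value,
                 variance_explained = ve,
                 converged = any_conv),
            class = "tsm_fit")
}

#' @export
print.tsm_fit <- function(x, ...) {
  cat(sprintf(
    "<tsm_fit> degree %d (%d coefficients), variance explained %.1f%%\n",
    x$degree, length(x$beta), 100 * x$variance_explained))
  invisible(x)
}

#' Log marginal likelihood of a trend surface model at fixed hyperparameters
#'
#' Evaluates the closed-form model evidence for given weight and noise
#' precisions; used to verify that the fitted hyperparameters are a
#' maximum.
#'
#' @param basis a `spatial_basis`.
#' @param y response vector (centred internally).
#' @param alpha weight (prior) precision, > 0.
#' @param lambda noise precision, > 0.
#' @return scalar log evidence.
#' @export
tsm_log_evidence <- function(basis, y, alpha, lambda) {
  yc <- y - mean(y)
  blr_evidence(blr_svd(centred_design(basis), yc), alpha, lambda)
}

#' Ridge (fixed-hyperparameter) trend surface coefficients
#'
#' The posterior-mean weights at fixed `(alpha, lambda)`; equal to the
#' ridge solution `(X'X + (alpha/lambda) I)^-1 X' y_c`.
#'
#' @inheritParams tsm_log_evidence
#' @return coefficient vector of length `3 * degree`.
#' @export
tsm_ridge <- function(basis, y, alpha, lambda) {
  yc <- y - mean(y)
  beta <- blr_beta(blr_svd(centred_design(basis), yc), alpha, lambda)
  names(beta) <- colnames(basis$design)
  beta
}

#' Fraction of mode variance explained by a trend surface fit
#'
#' `1 - SS_resid / SS_total` of the reconstruction over the ROI. Can be
#' negative for a badly mis-specified forced degree; set
#' `clamp = TRUE` to floor reported values at 0 (the unclamped value is
#' always attached as an attribute).
#'
#' @param fit a `tsm_fit`.
#' @param basis the `spatial_basis` it was fitted on.
#' @param y the mode values.
#' @param clamp floor negative values at 0 for reporting.
#' @return fraction of variance explained.
#' @export
variance_explained <- function(fit, basis, y, clamp = FALSE) {
  if (fit$degree != basis$degree) stop("degree mismatch")
  if (var(y) < .Machine$double.eps) stop("zero-variance response")
  yhat <- reconstruct_surface(fit, basis)
  ve <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  out <- if (clamp) max(ve, 0) else ve
  attr(out, "unclamped") <- ve
  out
}

#' Reconstruct a mode surface from its trend coefficients
#'
#' `y_hat = design %*% beta + y_mean`; used for visualization and for
#' mapping coefficient-space effects back onto voxels.
#'
#' @param fit a `tsm_fit`.
#' @param basis the matching `spatial_basis`.
#' @return numeric vector of length V.
#' @export
reconstruct_surface <- function(fit, basis) {
  if (fit$degree != basis$degree) stop("degree mismatch")
  drop(centred_design(basis) %*% fit$beta) + fit$y_mean
}

#' Scree-based selection of the trend surface degree
#'
#' Fits all candidate degrees and scores each (default: variance
#' explained, averaged over subjects when `y` is a matrix). The scree
#' elbow is operationalized as the largest degree whose score gain over
#' the previous degree exceeds a relative threshold `tau`: for variance
#' explained the gain is measured relative to the variance still
#' unexplained at the previous degree (the smallest candidate is
#' compared against a null model explaining nothing); for the
#' log-evidence criterion, relative to the largest single-step gain. If
#' no step clears the threshold the smallest candidate is chosen, with a
#' warning.
#'
#' @param world_coords V x 3 world coordinates (or a precomputed list of
#'   `spatial_basis`, one per candidate).
#' @param y mode values: vector, or V x n matrix of n subjects.
#' @param candidates candidate degrees (default 2:5).
#' @param tau relative gain threshold (default 0.05).
#' @param criterion `"variance_explained"` or `"log_evidence"`.
#' @return A `degree_selection`: `candidates`, `scores`, `chosen`,
#'   `criterion`.
#' @export
select_degree <- function(world_coords, y, candidates = 2:5, tau = 0.05,
                          criterion = c("variance_explained",
                                        "log_evidence")) {
  criterion <- match.arg(criterion)
  candidates <- sort(candidates)
  y <- as.matrix(y)
  scores <- numeric(length(candidates))
  norm0 <- NULL
  for (i in seq_along(candidates)) {
    basis <- build_basis(world_coords, candidates[i], normalization = norm0)
    if (is.null(norm0)) norm0 <- basis$normalization
    per_subj <- apply(y, 2, function(col) {
      fit <- fit_blr(basis, col)
      if (criterion == "variance_explained") fit$variance_explained
      else fit$log_evidence
    })
    scores[i] <- mean(per_subj)
  }
  if (criterion == "variance_explained") {
    prev <- c(0, scores[-length(scores)])
    relgain <- (scores - prev) / pmax(1 - prev, .Machine$double.eps)
  } else {
    gain <- diff(c(min(scores), scores))
    relgain <- gain / max(abs(gain), .Machine$double.eps)
  }
  ok <- which(relgain > tau)
  if (length(ok)) {
    chosen <- candidates[max(ok)]
  } else {
    chosen <- candidates[1]
    warning("no scree elbow found; choosing the smallest candidate degree")
  }
  structure(list(candidates = candidates, scores = scores,
                 chosen = chosen, criterion = criterion, tau = tau),
            class = "degree_selection")
}

#' @export
print.degree_selection <- function(x, ...) {
  cat(sprintf("<degree_selection> chosen degree %d (%s)\n",
              x$chosen, x$criterion))
  print(setNames(round(x$scores, 4), paste0("d", x$candidates)))
  invisible(x)
}
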