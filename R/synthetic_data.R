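#' Build a phantom scene with planted spatial gradients
#'
#' Constructs the ground-truth scaffold every downstream validation runs
#' on: one or more cuboid ROIs placed in a 3D grid, each carrying a set
#' of planted spatial gradients built from low-order polynomials of
#' world coordinates (Gram-Schmidt orthogonalized, unit norm). BOLD
#' synthesized from the scene ([synthesize_bold()]) mixes a set of
#' "network" time courses with weights that vary smoothly along the
#' planted gradients, so the mapping pipeline should recover gradient k
#' as its k-th nontrivial connectivity mode.
#'
#' Gradient k is a polynomial of the stated degree in world coordinate
#' axis `((k - 1) mod 3) + 1`. In the mixing-weight space each gradient
#' is rescaled to standard deviation `1 - 0.15 * (k - 1)`: extents are
#' comparable (so every planted gradient appears among the leading
#' modes) yet strictly decreasing (so the mode order is deterministic
#' and matches the planted order). Mixing-weight anchors are laid out on
#' a regular grid covering the gradient-value range, one network per
#' anchor; the effective network count is the smallest full grid with at
#' least `n_networks` points.
#'
#' @param grid_shape integer 3-vector, voxel grid dimensions.
#' @param n_roi_blobs number of cuboid ROIs (placed along the x axis).
#' @param gradient_degrees polynomial degrees of the planted gradients
#'   (same set in every ROI), e.g. `c(1, 2)`.
#' @param n_networks requested number of network time courses; must be
#'   at least `length(gradient_degrees) + 1`.
#' @param snr ratio of signal sd to noise sd in synthesized BOLD
#'   (`Inf` = noiseless, `0` = pure noise).
#' @param seed integer seed; the scene and everything generated from it
#'   are bit-reproducible.
#' @param roi_side side length of each cuboid ROI, in voxels.
#' @param voxel_size_mm isotropic voxel size used in the affine.
#' @param kernel_sigma width of the Gaussian mixing kernel in
#'   gradient-value space.
#' @return A `phantom_scene`: grid, affine, `roi_specs`,
#'   `planted_gradients` (per ROI, V x m matrix of orthonormal columns),
#'   anchor layout and mixing parameters.
#' @export
build_scene <- function(grid_shape = c(12, 12, 12), n_roi_blobs = 1,
                        gradient_degrees = c(1, 2), n_networks = 12,
                        snr = 5, seed = 1, roi_side = 7,
                        voxel_size_mm = 2, kernel_sigma = 1.4) {
  m <- length(gradient_degrees)
  if (n_networks < m + 1)
    stop("`n_networks` must be at least the number of planted gradients + 1")
  # place blobs along x with 1-voxel margins
  need_x <- n_roi_blobs * (roi_side + 1) + 1
  if (grid_shape[1] < need_x || any(grid_shape[2:3] < roi_side + 2))
    stop(sprintf(
      "infeasible geometry: %d blob(s) of side %d do not fit in a %s grid",
      n_roi_blobs, roi_side, paste(grid_shape, collapse = "x")))
  affine <- diag(c(rep(voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  scales <- 1 - 0.15 * (seq_len(m) - 1)
  ng <- max(2L, ceiling(n_networks^(1 / m)))
  rois <- vector("list", n_roi_blobs)
  grads <- vector("list", n_roi_blobs)
  anchors <- vector("list", n_roi_blobs)
  for (b in seq_len(n_roi_blobs)) {
    mask <- array(0, grid_shape)
    x0 <- 1 + (b - 1) * (roi_side + 1) + 1
    y0 <- floor((grid_shape[2] - roi_side) / 2) + 1
    z0 <- floor((grid_shape[3] - roi_side) / 2) + 1
    mask[x0:(x0 + roi_side - 1), y0:(y0 + roi_side - 1),
         z0:(z0 + roi_side - 1)] <- 1
    roi <- make_roi(mask, threshold = 0, name = sprintf("roi%02d", b),
                    affine = affine)
    cn <- scale(roi$world_coords)
    G <- matrix(0, n_voxels(roi), m)
    for (k in seq_len(m)) {
      g <- cn[, ((k - 1) %% 3) + 1]^gradient_degrees[k]
      g <- g - mean(g)
      if (k > 1) for (j in 1:(k - 1)) g <- g - sum(g * G[, j]) * G[, j]
      nrm <- sqrt(sum(g^2))
      if (nrm < 1e-10)
        stop("infeasible geometry: planted gradients are collinear")
      G[, k] <- g / nrm
    }
    # anchor grid in scaled gradient-value space
    Gs <- sweep(G, 2, apply(G, 2, sd), "/")
    Gs <- sweep(Gs, 2, scales, "*")
    ax <- lapply(seq_len(m), function(j)
      seq(min(Gs[, j]), max(Gs[, j]), length.out = ng))
    rois[[b]] <- roi
    grads[[b]] <- G
    anchors[[b]] <- list(scaled_gradients = Gs,
                         anchors = as.matrix(expand.grid(ax)))
  }
  structure(list(grid_shape = grid_shape, affine = affine,
                 roi_specs = rois, planted_gradients = grads,
                 mixing = anchors, gradient_degrees = gradient_degrees,
                 gradient_scales = scales,
                 n_networks = nrow(anchors[[1]]$anchors),
                 kernel_sigma = kernel_sigma,
                 snr = snr, seed = seed,
                 voxel_size_mm = voxel_size_mm),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %s grid, %d ROI(s), %d planted gradient(s), %d networks, snr = %g\n",
    paste(x$grid_shape, collapse = "x"), length(x$roi_specs),
    length(x$gradient_degrees), x$n_networks, x$snr))
  invisible(x)
}

# smoothed Gaussian noise time course, unit variance: the analysis only
# consumes second-order (correlation) structure, so no hemodynamics
smooth_timecourse <- function(t, width = 5) {
  x <- stats::filter(rnorm(t + 2 * width), rep(1, width) / width, sides = 2)
  x <- as.numeric(x[(width + 1):(width + t)])
  (x - mean(x)) / sd(x)
}

# Gaussian-kernel mixing weights of ROI voxels over network anchors,
# evaluated at (possibly perturbed) gradient values in scaled space
mixing_weights <- function(scene, roi_index, perturbation = NULL) {
  mix <- scene$mixing[[roi_index]]
  Gs <- mix$scaled_gradients
  if (!is.null(perturbation)) {
    P <- as.matrix(perturbation)
    if (nrow(P) != nrow(Gs))
      stop("perturbation length does not match ROI voxel count")
    if (ncol(P) == 1 && ncol(Gs) > 1)
      P <- cbind(P, matrix(0, nrow(P), ncol(Gs) - 1))
    G0 <- scene$planted_gradients[[roi_index]]
    sds <- apply(G0, 2, sd)
    Gs <- Gs + sweep(sweep(P, 2, sds, "/"), 2,
                     scene$gradient_scales[seq_len(ncol(Gs))], "*")
  }
  A <- mix$anchors
  d2 <- outer(rowSums(Gs^2), rowSums(A^2), "+") - 2 * tcrossprod(Gs, A)
  W <- exp(-d2 / (2 * scene$kernel_sigma^2))
  W / rowSums(W)
}

#' Synthesize a 4D BOLD phantom from a scene
#'
#' Network time courses are independent smoothed Gaussian series (unit
#' variance). Every non-ROI voxel carries one network's series; every
#' ROI voxel carries a mixture of all networks with Gaussian-kernel
#' weights in gradient-value space, so voxels close in planted-gradient
#' value have similar connectivity fingerprints — exactly the smooth
#' fingerprint change that Laplacian eigenmaps recovers. White noise is
#' added at the scene's signal-to-noise ratio (`snr = 0` yields pure
#' noise, `snr = Inf` no noise).
#'
#' @param scene a [build_scene()] result.
#' @param t number of timepoints (>= 50).
#' @param session_perturbation optional per-ROI list of V-vectors (or a
#'   single vector for a one-ROI scene) added to the first planted
#'   gradient's values before weight computation; this is how
#'   subject/session gradient variation is injected.
#' @param seed seed for this realization (defaults to the scene seed).
#' @return list with `bold` (a [bold_series()]) and `brain_mask` (3D
#'   array, all grid voxels in-brain).
#' @export
synthesize_bold <- function(scene, t = 300, session_perturbation = NULL,
                            seed = scene$seed) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (t < 50) stop("need t >= 50 timepoints")
  if (!is.null(session_perturbation) && !is.list(session_perturbation))
    session_perturbation <- list(session_perturbation)
  set.seed(as.integer(seed %% .Machine$integer.max))
  K <- scene$n_networks
  net <- sapply(seq_len(K), function(k) smooth_timecourse(t))
  noise_sd <- if (scene$snr == 0) 1 else 1 / scene$snr
  pure_noise <- scene$snr == 0
  flat_all <- seq_len(prod(scene$grid_shape))
  roi_flat_all <- integer(0)
  mat <- matrix(0, prod(scene$grid_shape), t)    # voxels x time
  d <- scene$grid_shape
  for (b in seq_along(scene$roi_specs)) {
    roi <- scene$roi_specs[[b]]
    flat <- roi$voxel_index_list[, 1] + 1L +
      d[1] * roi$voxel_index_list[, 2] +
      d[1] * d[2] * roi$voxel_index_list[, 3]
    roi_flat_all <- c(roi_flat_all, flat)
    W <- mixing_weights(scene, b,
                        if (!is.null(session_perturbation))
                          session_perturbation[[b]] else NULL)
    if (!pure_noise) {
      sig <- net %*% t(W)                        # t x V
      sig <- sweep(sig, 2, apply(sig, 2, sd), "/")
      mat[flat, ] <- t(sig)
    }
  }
  ref_flat <- setdiff(flat_all, roi_flat_all)
  if (!pure_noise)
    mat[ref_flat, ] <- t(net[, rep(seq_len(K), length.out = length(ref_flat)),
                             drop = FALSE])
  if (is.finite(scene$snr))
    mat <- mat + matrix(rnorm(length(mat), sd = noise_sd), nrow(mat))
  vol <- array(mat, c(d, t))
  list(bold = bold_series(vol, scene$affine, tr_seconds = 1),
       brain_mask = array(TRUE, d))
}

#' Derive a density map from a planted gradient
#'
#' Produces a 3D scalar map (a stand-in for a dopamine-transporter
#' SPECT-like image) whose within-ROI values are a monotone transform of
#' a planted gradient, 0 outside the ROI.
#'
#' @param scene a `phantom_scene`.
#' @param roi_index which ROI.
#' @param transform `"identity"`, `"logistic"` (scale set to one
#'   gradient sd, keeping the quasi-linear range) or `"affine"`.
#' @param gradient_index which planted gradient (default 1).
#' @param slope,intercept parameters of the affine transform.
#' @return A [density_map()].
#' @export
derive_density_map <- function(scene, roi_index = 1,
                               transform = c("identity", "logistic",
                                             "affine"),
                               gradient_index = 1, slope = 1,
                               intercept = 0) {
  transform <- match.arg(transform)
  roi <- scene$roi_specs[[roi_index]]
  g <- scene$planted_gradients[[roi_index]][, gradient_index]
  vals <- switch(transform,
    identity = g,
    logistic = 1 / (1 + exp(-g / sd(g))),
    affine = slope * g + intercept)
  out <- array(0, scene$grid_shape)
  d <- scene$grid_shape
  flat <- roi$voxel_index_list[, 1] + 1L +
    d[1] * roi$voxel_index_list[, 2] +
    d[1] * d[2] * roi$voxel_index_list[, 3]
  out[flat] <- vals
  density_map(out, scene$affine)
}

#' Describe a simulated cohort
#'
#' Parameters of a multi-subject, multi-session phantom cohort. Subject
#' and session variation, group effects and coefficient-outcome
#' couplings are all expressed in trend-surface coefficient space and
#' mapped onto voxels through the polynomial basis, so ground-truth
#' effect sizes for the omnibus tests are known exactly.
#'
#' @param n_subjects per-group subject counts; a single number means one
#'   group, a length-2 vector two groups ("A", "B").
#' @param n_sessions 1 or 2.
#' @param within_subject_sd,between_subject_sd sds of the per-session /
#'   per-subject coefficient perturbations (>= 0).
#' @param group_effect additive shift applied to group B's generating
#'   coefficients in the affected ROI (scalar or length 3*degree).
#' @param affected_roi index of the ROI receiving the group effect and
#'   driving the outcome.
#' @param outcome_coupling linear weights from subject coefficients to
#'   the continuous outcome (scalar 0 = no coupling).
#' @param outcome_noise_sd sd of the outcome noise.
#' @param degree trend-surface degree used to generate (and later
#'   recover) coefficients.
#' @param seed integer seed.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_subjects = c(30, 30), n_sessions = 2,
                          within_subject_sd = 0.05,
                          between_subject_sd = 0.15,
                          group_effect = 0, affected_roi = 1,
                          outcome_coupling = 0, outcome_noise_sd = 1,
                          degree = 2, seed = 1) {
  if (!(n_sessions %in% 1:2)) stop("`n_sessions` must be 1 or 2")
  if (within_subject_sd < 0 || between_subject_sd < 0 ||
      outcome_noise_sd < 0)
    stop("standard deviations must be >= 0")
  structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                 within_subject_sd = within_subject_sd,
                 between_subject_sd = between_subject_sd,
                 group_effect = group_effect,
                 affected_roi = affected_roi,
                 outcome_coupling = outcome_coupling,
                 outcome_noise_sd = outcome_noise_sd,
                 degree = degree, seed = seed),
            class = "cohort_design")
}

#' Simulate a multi-subject, multi-session phantom cohort
#'
#' Each subject's gradient field is the scene's first planted gradient
#' (standardized to unit sd across voxels, so the design's sds read as
#' fractions of the gradient amplitude) plus a between-subject
#' perturbation drawn in coefficient space; each session adds a
#' within-subject perturbation; group "B" is additionally
#' shifted by `group_effect` in the affected ROI's coefficients. The
#' continuous outcome is `outcome_coupling . (subject coefficients)`
#' plus noise. Per-subject random streams are separated (subject i's
#' data do not change when more subjects are added).
#'
#' @param scene a [build_scene()] result.
#' @param design a [cohort_design()].
#' @param synthesize if `TRUE`, also synthesize per-session 4D BOLD
#'   (slow); otherwise only the ground-truth gradient fields and
#'   coefficient/phenotype tables are returned.
#' @param t timepoints per synthesized session.
#' @return list with `phenotypes` (subject, session, group, outcome,
#'   usage_count), `true_coefficients` (one row per subject x session x
#'   ROI with the generating coefficients `b1..b_{3d}`), `gradients`
#'   (nested list `[[subject]][[session]][[roi]]` of V-vectors),
#'   `bases` (per-ROI `spatial_basis`), and optionally `bold`
#'   (`[[subject]][[session]]`).
#' @export
simulate_cohort <- function(scene, design, synthesize = FALSE, t = 300) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(design, "cohort_design"))
  n_groups <- length(design$n_subjects)
  groups <- rep(LETTERS[seq_len(n_groups)], design$n_subjects)
  n_tot <- sum(design$n_subjects)
  n_roi <- length(scene$roi_specs)
  p <- 3 * design$degree
  bases <- lapply(scene$roi_specs,
                  function(r) build_basis(r$world_coords, design$degree))
  # cohort generation works on the standardized gradient scale (field sd
  # = 1 across voxels) so the design's sds and effects are interpretable
  # fractions of the gradient's own amplitude
  g_sd <- vapply(seq_len(n_roi),
                 function(b) sd(scene$planted_gradients[[b]][, 1]),
                 numeric(1))
  # generating coefficients of the standardized first planted gradient
  # (OLS: the planted field is itself polynomial, so this is essentially
  # exact)
  beta0 <- lapply(seq_len(n_roi), function(b) {
    g <- scene$planted_gradients[[b]][, 1] / g_sd[b]
    qr.coef(qr(sweep(bases[[b]]$design, 2, colMeans(bases[[b]]$design))),
            g - mean(g))
  })
  g_mean <- vapply(seq_len(n_roi),
                   function(b) mean(scene$planted_gradients[[b]][, 1]) /
                     g_sd[b],
                   numeric(1))
  eff <- rep(design$group_effect, length.out = p)
  coupling <- rep(design$outcome_coupling, length.out = p)
  pheno <- NULL
  coef_rows <- NULL
  gradients <- vector("list", n_tot)
  bold <- if (synthesize) vector("list", n_tot) else NULL
  for (i in seq_len(n_tot)) {
    subj_seed <- (design$seed + 7919 * i) %% .Machine$integer.max
    set.seed(as.integer(subj_seed))
    b_i <- lapply(seq_len(n_roi), function(b)
      rnorm(p, sd = design$between_subject_sd))
    shift <- groups[i] == "B"
    subj_beta <- lapply(seq_len(n_roi), function(b) {
      sb <- beta0[[b]] + b_i[[b]]
      if (shift && b == design$affected_roi) sb <- sb + eff
      sb
    })
    outcome <- sum(coupling * subj_beta[[design$affected_roi]]) +
      rnorm(1, sd = design$outcome_noise_sd)
    usage_count <- stats::rpois(1, 10)
    gradients[[i]] <- vector("list", design$n_sessions)
    if (synthesize) bold[[i]] <- vector("list", design$n_sessions)
    for (s in seq_len(design$n_sessions)) {
      w_is <- lapply(seq_len(n_roi), function(b)
        rnorm(p, sd = design$within_subject_sd))
      sess_beta <- lapply(seq_len(n_roi),
                          function(b) subj_beta[[b]] + w_is[[b]])
      fields <- lapply(seq_len(n_roi), function(b) {
        Xc <- sweep(bases[[b]]$design, 2, colMeans(bases[[b]]$design))
        drop(Xc %*% sess_beta[[b]]) + g_mean[b]
      })
      gradients[[i]][[s]] <- fields
      # perturbation handed to the BOLD synthesizer lives on the raw
      # (unit-norm) gradient scale
      perturb <- lapply(seq_len(n_roi), function(b)
        g_sd[b] * fields[[b]] - scene$planted_gradients[[b]][, 1])
      if (synthesize) {
        sess_seed <- (subj_seed + 104729 * s) %% .Machine$integer.max
        bold[[i]][[s]] <- synthesize_bold(scene, t = t,
                                          session_perturbation = perturb,
                                          seed = sess_seed)$bold
      }
      for (b in seq_len(n_roi)) {
        row <- data.frame(subject = i, session = s,
                          roi = scene$roi_specs[[b]]$name,
                          group = groups[i], outcome = outcome,
                          usage_count = usage_count,
                          degree = design$degree)
        cb <- as.data.frame(t(sess_beta[[b]]))
        names(cb) <- paste0("b", seq_len(p))
        coef_rows <- rbind(coef_rows, cbind(row, cb))
      }
      pheno <- rbind(pheno,
                     data.frame(subject = i, session = s,
                                group = groups[i], outcome = outcome,
                                usage_count = usage_count))
    }
  }
  list(phenotypes = pheno, true_coefficients = coef_rows,
       gradients = gradients, bases = bases, bold = bold,
       design = design)
}

#' Recover trend-surface coefficients from a cohort's gradient fields
#'
#' Fits the trend surface model to every subject x session x ROI
#' gradient field of a simulated cohort and returns the versioned
#' coefficient table consumed by the group statistics: one row per
#' (subject, session, roi) with columns `b1..b_{3d}`, hyperparameters,
#' log evidence and variance explained, joined to the phenotypes.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param scene the scene it was simulated from.
#' @return data.frame coefficient table.
#' @export
cohort_coefficient_table <- function(cohort, scene) {
  bases <- cohort$bases
  out <- NULL
  for (i in seq_along(cohort$gradients)) {
    for (s in seq_along(cohort$gradients[[i]])) {
      for (b in seq_along(bases)) {
        y <- cohort$gradients[[i]][[s]][[b]]
        fit <- fit_blr(bases[[b]], y)
        ph <- cohort$phenotypes[cohort$phenotypes$subject == i &
                                  cohort$phenotypes$session == s, ]
        row <- data.frame(subject = i, session = s,
                          roi = scene$roi_specs[[b]]$name,
                          group = ph$group[1], outcome = ph$outcome[1],
                          usage_count = ph$usage_count[1],
                          degree = fit$degree)
        cb <- as.data.frame(t(fit$beta))
        names(cb) <- paste0("b", seq_along(fit$beta))
        row <- cbind(row, cb,
                     data.frame(noise_variance = fit$hyper[["noise_variance"]],
                                weight_variance = fit$hyper[["weight_variance"]],
                                log_evidence = fit$log_evidence,
                                variance_explained = fit$variance_explained))
        out <- rbind(out, row)
      }
    }
  }
  out
}
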