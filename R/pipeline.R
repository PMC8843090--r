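#' Analysis run configuration
#'
#' Collects every tunable of a subject-to-group run in one validated,
#' schema-versioned object; unknown keys are rejected so typos fail
#' loudly. The configuration is echoed into every results bundle for
#' provenance, and reruns under the same configuration are
#' bit-identical.
#'
#' @param n_modes nontrivial modes to extract per subject.
#' @param selected_order which mode order enters the trend-surface and
#'   group statistics (0 = first nontrivial; the dopamine-like striatal
#'   topography in the motivating analysis is order 2).
#' @param degree trend-surface degree, or `"scree"` to select per ROI by
#'   [select_degree()].
#' @param alpha family-wise significance level.
#' @param m_comparisons Bonferroni divisor (e.g. 4 = 2 groups x 2
#'   subregions).
#' @param n_perm permutations for the within/between test.
#' @param n_boot bootstrap replicates for the ICC interval.
#' @param seed master seed for all stochastic steps.
#' @param knn optional graph sparsification for the eigenmaps.
#' @param ... rejected; any unknown key is an error.
#' @return A `run_config` list.
#' @export
run_config <- function(n_modes = 3, selected_order = 2, degree = 2,
                       alpha = 0.05, m_comparisons = 4, n_perm = 10000,
                       n_boot = 1000, seed = 1, knn = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  if (!identical(degree, "scree") && !(degree %in% 2:5))
    stop("`degree` must be in 2..5 or \"scree\"")
  if (selected_order < 0 || selected_order >= n_modes)
    stop("`selected_order` must be in [0, n_modes)")
  structure(list(schema_version = "1", n_modes = n_modes,
                 selected_order = selected_order, degree = degree,
                 alpha = alpha, m_comparisons = m_comparisons,
                 n_perm = n_perm, n_boot = n_boot, seed = seed,
                 knn = knn),
            class = "run_config")
}

#' Subject-level mapping and trend-surface fitting for a cohort
#'
#' For every subject, session and ROI: run the mapping chain
#' ([map_subject()]), form group-level reference modes from the average
#' similarity matrix per ROI, align each subject mode to the group
#' reference, select the configured mode order, fit the trend surface
#' (with per-ROI degree fixed by config or chosen by scree on the
#' group reference mode) and append a coefficient row. Per-subject
#' failures are isolated and reported in the summary rather than
#' aborting the run.
#'
#' @param config a [run_config()].
#' @param bold_list nested list `[[subject]][[session]]` of
#'   [bold_series()] (e.g. from [simulate_cohort()] with
#'   `synthesize = TRUE`).
#' @param rois list of `roi_spec`.
#' @param brain_mask 3D in-brain mask shared by all images.
#' @param phenotypes optional data.frame with `subject`, `session`,
#'   `group`, `outcome`, `usage_count`, joined onto the coefficient
#'   table.
#' @return list with `coefficients` (versioned table), `modes`
#'   (`[[roi]][[session]]` V x n matrices of aligned selected modes),
#'   `group_modes` (`[[roi]]`, list of `connectivity_mode`), `degrees`
#'   (per ROI), `failures` (data.frame), `config`.
#' @export
run_subject_level <- function(config, bold_list, rois, brain_mask,
                              phenotypes = NULL) {
  stopifnot(inherits(config, "run_config"))
  n_subj <- length(bold_list)
  n_sess <- length(bold_list[[1]])
  n_roi <- length(rois)
  failures <- NULL
  # pass 1: similarity matrices
  sims <- lapply(seq_len(n_roi), function(b)
    vector("list", n_subj * n_sess))
  subj_maps <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    subj_maps[[i]] <- vector("list", n_sess)
    for (s in seq_len(n_sess)) {
      res <- tryCatch(
        lapply(seq_len(n_roi), function(b)
          map_subject(bold_list[[i]][[s]], rois[[b]], brain_mask,
                      n_modes = config$n_modes, knn = config$knn)),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures,
                          data.frame(subject = i, session = s,
                                     stage = "mapping",
                                     message = conditionMessage(res)))
        next
      }
      subj_maps[[i]][[s]] <- res
      for (b in seq_len(n_roi))
        sims[[b]][[(i - 1) * n_sess + s]] <- res[[b]]$similarity
    }
  }
  # group reference modes from averaged similarity
  group_modes <- vector("list", n_roi)
  for (b in seq_len(n_roi)) {
    ok <- Filter(Negate(is.null), sims[[b]])
    if (!length(ok)) stop("no successful subject maps for ROI ", b)
    group_modes[[b]] <- laplacian_eigenmaps(group_similarity(ok),
                                            n_modes = config$n_modes,
                                            knn = config$knn)
  }
  # per-ROI degree and basis (normalization fixed once per ROI mask)
  degrees <- integer(n_roi)
  bases <- vector("list", n_roi)
  for (b in seq_len(n_roi)) {
    ref <- group_modes[[b]][[config$selected_order + 1]]$values
    degrees[b] <- if (identical(config$degree, "scree"))
      select_degree(rois[[b]]$world_coords, ref)$chosen
    else config$degree
    bases[[b]] <- build_basis(rois[[b]]$world_coords, degrees[b])
  }
  # pass 2: align, fit, tabulate
  coef_rows <- NULL
  mode_store <- lapply(seq_len(n_roi), function(b)
    lapply(seq_len(n_sess), function(s)
      matrix(NA_real_, n_voxels(rois[[b]]), n_subj)))
  for (i in seq_len(n_subj)) for (s in seq_len(n_sess)) {
    maps <- subj_maps[[i]][[s]]
    if (is.null(maps)) next
    for (b in seq_len(n_roi)) {
      row <- tryCatch({
        ref <- group_modes[[b]][[config$selected_order + 1]]
        mode <- align_mode(maps[[b]]$modes[[config$selected_order + 1]],
                           ref, reference_id = rois[[b]]$name)
        fit <- fit_blr(bases[[b]], mode$values)
        mode_store[[b]][[s]][, i] <- mode$values
        cb <- as.data.frame(t(fit$beta))
        names(cb) <- paste0("b", seq_along(fit$beta))
        cbind(data.frame(subject = i, session = s, roi = rois[[b]]$name,
                         degree = degrees[b]),
              cb,
              data.frame(noise_variance = fit$hyper[["noise_variance"]],
                         weight_variance = fit$hyper[["weight_variance"]],
                         log_evidence = fit$log_evidence,
                         variance_explained = fit$variance_explained))
      }, error = function(e) e)
      if (inherits(row, "error")) {
        failures <- rbind(failures,
                          data.frame(subject = i, session = s,
                                     stage = paste0("tsm:", rois[[b]]$name),
                                     message = conditionMessage(row)))
      } else {
        coef_rows <- rbind(coef_rows, row)
      }
    }
  }
  if (!is.null(phenotypes) && !is.null(coef_rows)) {
    coef_rows <- merge(coef_rows,
                       unique(phenotypes[c("subject", "session",
                                           setdiff(names(phenotypes),
                                                   c("subject", "session")))]),
                       by = c("subject", "session"), sort = FALSE)
    coef_rows <- coef_rows[order(coef_rows$subject, coef_rows$session,
                                 coef_rows$roi), ]
  }
  list(coefficients = coef_rows, modes = mode_store,
       group_modes = group_modes, degrees = degrees, bases = bases,
       failures = failures, config = config)
}

#' Group-level statistics over a subject-level run
#'
#' Executes the statistical surface over a [run_subject_level()] result:
#' optional density-map correlations (voxel-wise and coefficient-space),
#' the reliability suite (per-coefficient ICC(2,k) and within/between
#' permutation test, when two sessions are present), a binary group
#' omnibus test per ROI at the Bonferroni-corrected level, the
#' continuous-outcome omnibus with post-hoc per-coefficient
#' correlations, and (with two sessions) the change-score analysis.
#'
#' @param config the [run_config()] used for the subject-level run.
#' @param subject_results a [run_subject_level()] result.
#' @param rois the ROI list used for the run.
#' @param density optional [density_map()] on the same grid; correlated
#'   against the selected group mode per ROI.
#' @return list of results: `density`, `reliability`, `group_tests`,
#'   `outcome_tests`, `change_score`, `alpha_corrected`, `config`.
#' @export
run_group_level <- function(config, subject_results, rois,
                            density = NULL) {
  coeffs <- subject_results$coefficients
  if (is.null(coeffs)) stop("no subject-level coefficients available")
  bc <- coef_columns(coeffs)
  alpha_c <- bonferroni(config$alpha, config$m_comparisons)
  n_roi <- length(rois)
  roi_names <- vapply(rois, function(r) r$name, character(1))
  n_sess <- length(subject_results$modes[[1]])
  out <- list(alpha_corrected = alpha_c, config = config)
  # density-map correlations
  if (!is.null(density)) {
    dens <- lapply(seq_len(n_roi), function(b)
      roi_values(density, rois[[b]]))
    mode_cat <- unlist(lapply(seq_len(n_roi), function(b)
      subject_results$group_modes[[b]][[config$selected_order + 1]]$values))
    vox <- spatial_correlation(mode_cat, unlist(dens))
    beta_mode <- unlist(lapply(seq_len(n_roi), function(b) {
      fit_blr(subject_results$bases[[b]],
              subject_results$group_modes[[b]][[config$selected_order +
                                                  1]]$values)$beta
    }))
    beta_dens <- unlist(lapply(seq_len(n_roi), function(b)
      fit_blr(subject_results$bases[[b]], dens[[b]])$beta))
    out$density <- list(voxelwise = vox,
                        coefficient = coefficient_correlation(beta_mode,
                                                              beta_dens))
  }
  # reliability
  if (n_sess >= 2) {
    rel <- list()
    for (b in seq_len(n_roi)) {
      cb1 <- coeffs[coeffs$session == 1 & coeffs$roi == roi_names[b], ]
      cb2 <- coeffs[coeffs$session == 2 & coeffs$roi == roi_names[b], ]
      common <- intersect(cb1$subject, cb2$subject)
      cb1 <- cb1[match(common, cb1$subject), ]
      cb2 <- cb2[match(common, cb2$subject), ]
      iccs <- vapply(bc, function(cn)
        icc_2k(cbind(cb1[[cn]], cb2[[cn]]), n_boot = config$n_boot,
               seed = config$seed)$icc, numeric(1))
      M1 <- subject_results$modes[[b]][[1]]
      M2 <- subject_results$modes[[b]][[2]]
      keep <- colSums(is.na(M1)) == 0 & colSums(is.na(M2)) == 0
      wb <- within_between_permutation(M1[, keep, drop = FALSE],
                                       M2[, keep, drop = FALSE],
                                       n_perm = config$n_perm,
                                       seed = config$seed)
      rel[[roi_names[b]]] <- list(icc_per_coefficient = iccs,
                                  icc_mean = mean(iccs),
                                  within_between = wb)
    }
    out$reliability <- rel
  }
  # binary omnibus per ROI (session 1)
  if ("group" %in% names(coeffs) &&
      length(unique(coeffs$group)) == 2) {
    gt <- list()
    for (b in seq_len(n_roi)) {
      cb <- coeffs[coeffs$session == 1 & coeffs$roi == roi_names[b], ]
      res <- omnibus_lr_binary(cb)
      res$significant <- res$p < alpha_c
      gt[[roi_names[b]]] <- res
    }
    out$group_tests <- gt
  }
  # continuous-outcome omnibus + post-hoc (session 1)
  if ("outcome" %in% names(coeffs)) {
    ot <- list()
    for (b in seq_len(n_roi)) {
      cb <- coeffs[coeffs$session == 1 & coeffs$roi == roi_names[b], ]
      if (sd(cb$outcome) == 0) next
      res <- omnibus_lr_continuous(cb)
      res$significant <- res$p < alpha_c
      ot[[roi_names[b]]] <- list(omnibus = res,
                                 posthoc = posthoc_pearson(cb))
    }
    out$outcome_tests <- ot
  }
  out
}
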