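#' Lossless SVD reduction of the reference time series
#'
#' Reduces the non-ROI reference matrix `B` (t x W, columns demeaned) to
#' an orthonormal temporal basis by economy singular value decomposition.
#' The retained dimension is the numerical rank (singular values above
#' `max(t, W) * eps * sigma_1`), so projecting `B` onto the components
#' preserves all of its column-space information: fingerprints computed
#' against the components carry the same correlation structure as
#' fingerprints against all W columns.
#'
#' @param B t x W numeric matrix, columns demeaned over time.
#' @return A `reduced_reference`: list with `components` (t x r,
#'   orthonormal), `singular_values` (length r) and `rank`.
#' @export
reduce_reference <- function(B) {
  B <- as.matrix(B)
  if (all(B == 0)) stop("reference matrix is all zeros")
  sv <- svd(B, nu = min(dim(B)), nv = 0)
  tol <- max(dim(B)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  structure(list(components = sv$u[, seq_len(r), drop = FALSE],
                 singular_values = sv$d[seq_len(r)],
                 rank = r),
            class = "reduced_reference")
}

#' @export
print.reduced_reference <- function(x, ...) {
  cat(sprintf("<reduced_reference> rank %d, t = %d\n",
              x$rank, nrow(x$components)))
  invisible(x)
}

#' Connectivity fingerprints of ROI voxels
#'
#' Correlates every ROI voxel's time series with every temporal component
#' of the reduced reference, yielding one fingerprint (row) per voxel.
#'
#' @param A t x V matrix of ROI voxel time series (columns in ROI voxel
#'   order).
#' @param ref a [reduce_reference()] result with matching t.
#' @return V x r matrix `C` of Pearson correlations, entries in
#'   \[-1, 1\].
#' @export
compute_fingerprints <- function(A, ref) {
  stopifnot(inherits(ref, "reduced_reference"))
  if (nrow(A) != nrow(ref$components))
    stop("timepoint mismatch between A and reference components")
  C <- cor(A, ref$components)
  # clip roundoff excursions beyond [-1, 1]
  C[C > 1] <- 1
  C[C < -1] <- -1
  C
}

#' Eta-squared similarity between connectivity fingerprints
#'
#' For fingerprints x and y (rows of `C`), with m_j = (x_j + y_j)/2 and
#' M the grand mean of all entries of x and y jointly,
#' \deqn{\eta^2 = 1 - \frac{\sum_j (x_j - m_j)^2 + (y_j - m_j)^2}
#'                         {\sum_j (x_j - M)^2 + (y_j - M)^2}}
#' i.e. one minus the ratio of within-pair to total sum of squares: 1 for
#' identical profiles, 0 when all structure is within-pair. The V x V
#' matrix over all voxel pairs is computed with vectorised algebra; a
#' brute-force per-pair evaluation is used as an independent oracle in
#' the test suite.
#'
#' A pair of identical constant fingerprints has a zero denominator; its
#' similarity is defined as 1 (with a warning), consistent with the
#' x == y limit.
#'
#' @param C V x r fingerprint matrix (V >= 2, r >= 2).
#' @return V x V symmetric `similarity_matrix` with unit diagonal,
#'   entries in \[0, 1\].
#' @export
eta2_similarity <- function(C) {
  C <- as.matrix(C)
  V <- nrow(C); r <- ncol(C)
  if (V < 2 || r < 2) stop("need V >= 2 voxels and r >= 2 components")
  Q <- rowSums(C^2)
  s <- rowSums(C)
  # within-pair SS: sum_j (x_j - m_j)^2 + (y_j - m_j)^2 = ||x - y||^2 / 2
  G <- tcrossprod(C)
  d2 <- outer(Q, Q, "+") - 2 * G
  d2[d2 < 0] <- 0
  num <- d2 / 2
  M <- outer(s, s, "+") / (2 * r)
  den <- outer(Q, Q, "+") - 2 * r * M^2
  S <- 1 - num / den
  degen <- den <= .Machine$double.eps * r
  if (any(degen & num <= .Machine$double.eps * r)) {
    S[degen] <- 1
    if (any(degen & upper.tri(degen)))
      warning("identical constant fingerprint pair(s); similarity set to 1")
  }
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S[S < 0] <- 0
  S[S > 1] <- 1
  structure(S, class = c("similarity_matrix", "matrix", "array"))
}

#' Element-wise mean of similarity matrices (group-level similarity)
#'
#' Group-level connectopic maps are obtained from the average of the
#' individual similarity matrices; averaging preserves symmetry, the
#' unit diagonal and the \[0, 1\] range.
#'
#' @param s_list list of V x V similarity matrices over the same ROI.
#' @return The element-wise mean `similarity_matrix`.
#' @export
group_similarity <- function(s_list) {
  if (!length(s_list)) stop("empty list")
  V <- nrow(s_list[[1]])
  for (S in s_list)
    if (!all(dim(S) == c(V, V))) stop("similarity matrix size mismatch")
  out <- Reduce(`+`, lapply(s_list, unclass)) / length(s_list)
  structure(out, class = c("similarity_matrix", "matrix", "array"))
}

#' Laplacian-eigenmap decomposition of a similarity matrix
#'
#' Builds a graph over ROI voxels (weights `W = S` with zeroed diagonal
#' by default; optionally sparsified to a symmetrized k-nearest-neighbour
#' graph), forms the Laplacian `L = D - W` with degree matrix `D`, and
#' solves the generalized eigenproblem `L v = lambda D v` via the
#' symmetric normalized form. The trivial constant eigenvector
#' (lambda ~ 0) is discarded; the next `n_modes` eigenvectors, in
#' ascending eigenvalue order, are the connectivity modes. Each mode has
#' its D-weighted mean removed, unit Euclidean norm, and a deterministic
#' sign convention (first entry exceeding 1e-8 of the max magnitude is
#' positive) applied before any alignment.
#'
#' Dense solves are used throughout: the ROIs this is designed for are
#' small (hundreds to ~2000 voxels), where a dense symmetric
#' eigendecomposition is cheap and fully deterministic.
#'
#' @param S V x V similarity matrix ([eta2_similarity()]).
#' @param n_modes number of nontrivial modes to return (< V - 1).
#' @param knn optional neighbourhood size; when given, weights are kept
#'   only for each voxel's `knn` strongest neighbours (symmetrized by
#'   max). Default is the dense graph.
#' @return list of `connectivity_mode` objects, each with fields
#'   `order` (0 = first nontrivial), `values` (length V), `eigenvalue`
#'   and `aligned_to` (NULL until [align_mode()]).
#' @export
laplacian_eigenmaps <- function(S, n_modes = 3, knn = NULL) {
  S <- unclass(as.matrix(S))
  V <- nrow(S)
  if (n_modes >= V - 1) stop("`n_modes` must be smaller than V - 1")
  W <- S
  diag(W) <- 0
  if (!is.null(knn)) {
    if (knn < 1 || knn >= V) stop("`knn` must be in [1, V)")
    keep <- matrix(FALSE, V, V)
    for (i in seq_len(V)) {
      nb <- order(W[i, ], decreasing = TRUE)[seq_len(knn)]
      keep[i, nb] <- TRUE
    }
    keep <- keep | t(keep)          # symmetrize by max
    W[!keep] <- 0
  }
  comp <- graph_components(W > 0)
  if (max(comp) > 1L)
    stop(sprintf("similarity graph is disconnected: %d components of sizes %s",
                 max(comp),
                 paste(tabulate(comp), collapse = ", ")))
  d <- rowSums(W)
  dh <- 1 / sqrt(d)
  # normalized Laplacian: D^-1/2 (D - W) D^-1/2
  M <- -(W * dh) * rep(dh, each = V)
  diag(M) <- diag(M) + 1
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ord <- rev(seq_len(V))            # ascending eigenvalues
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  modes <- vector("list", n_modes)
  for (k in seq_len(n_modes)) {
    v <- dh * vecs[, k + 1]         # skip trivial constant vector
    v <- v - sum(d * v) / sum(d)    # D-weighted mean removal
    v <- v / sqrt(sum(v^2))
    v <- fix_sign(v)
    modes[[k]] <- structure(
      list(order = k - 1L, values = v,
           eigenvalue = max(vals[k + 1], 0), aligned_to = NULL),
      class = "connectivity_mode")
  }
  modes
}

# connected components of an undirected adjacency matrix, by BFS
graph_components <- function(adj) {
  V <- nrow(adj)
  comp <- integer(V)
  cur <- 0L
  for (s in seq_len(V)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(adj[i, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# deterministic sign: first entry with magnitude > 1e-8 * max is positive
fix_sign <- function(v) {
  mx <- max(abs(v))
  if (mx == 0) return(v)
  first <- which(abs(v) > 1e-8 * mx)[1]
  if (v[first] < 0) -v else v
}

#' @export
print.connectivity_mode <- function(x, ...) {
  cat(sprintf("<connectivity_mode> order %d, lambda = %.4g, V = %d%s\n",
              x$order, x$eigenvalue, length(x$values),
              if (is.null(x$aligned_to)) "" else
                paste0(", aligned to ", x$aligned_to)))
  invisible(x)
}

#' Align a connectivity mode to a reference mode
#'
#' Eigenvectors are sign-ambiguous; subject-level modes are aligned to a
#' group-level reference by inversion if negatively correlated, so that
#' visual and statistical comparisons across subjects share a sign.
#'
#' @param mode a `connectivity_mode`.
#' @param reference a `connectivity_mode` (or numeric vector) of equal
#'   length; `reference_id` labels the result.
#' @param reference_id identifier recorded in `aligned_to`.
#' @return The aligned `connectivity_mode`.
#' @export
align_mode <- function(mode, reference, reference_id = "reference") {
  ref_vals <- if (inherits(reference, "connectivity_mode"))
    reference$values else as.numeric(reference)
  if (length(mode$values) != length(ref_vals))
    stop("mode and reference lengths differ")
  if (sd(mode$values) == 0 || sd(ref_vals) == 0)
    stop("zero-variance input to alignment")
  r <- cor(mode$values, ref_vals)
  if (r < 0) mode$values <- -mode$values
  mode$aligned_to <- reference_id
  mode
}

#' Map one subject: BOLD + ROI to connectivity modes
#'
#' The full mapping chain: [extract_timeseries()] ->
#' [reduce_reference()] -> [compute_fingerprints()] ->
#' [eta2_similarity()] -> [laplacian_eigenmaps()]. Deterministic given
#' its inputs.
#'
#' @param bold a [bold_series()].
#' @param roi an `roi_spec`.
#' @param brain_mask 3D in-brain mask containing the ROI.
#' @param n_modes number of nontrivial modes.
#' @param knn optional graph sparsification (see
#'   [laplacian_eigenmaps()]).
#' @return list with `modes` (list of `connectivity_mode`), `similarity`
#'   (V x V), and `log` (reference rank, dropped-voxel count).
#' @export
map_subject <- function(bold, roi, brain_mask, n_modes = 3, knn = NULL) {
  pair <- extract_timeseries(bold, roi, brain_mask)
  ref <- reduce_reference(pair$B)
  C <- compute_fingerprints(pair$A, ref)
  S <- eta2_similarity(C)
  modes <- laplacian_eigenmaps(S, n_modes = n_modes, knn = knn)
  list(modes = modes, similarity = S,
       log = list(reference_rank = ref$rank,
                  n_dropped_reference = pair$n_dropped,
                  n_voxels = n_voxels(roi)))
}
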