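test_that("reduce_reference is a lossless factorization at numerical rank", {
  set.seed(31)
  # rank forced by construction
  U <- qr.Q(qr(matrix(rnorm(40 * 5), 40, 5)))
  B5 <- U %*% matrix(rnorm(5 * 30), 5, 30)
  B5 <- sweep(B5, 2, colMeans(B5))
  expect_equal(reduce_reference(B5)$rank, 5)

  B <- matrix(rnorm(100 * 900), 100, 900)
  B <- sweep(B, 2, colMeans(B))
  ref <- reduce_reference(B)
  expect_equal(crossprod(ref$components),
               diag(ref$rank), tolerance = 1e-8)
  # reconstruction from retained factors is exact at full rank
  Bhat <- ref$components %*% crossprod(ref$components, B)
  expect_lt(norm(B - Bhat, "F") / norm(B, "F"), 1e-8)
  expect_error(reduce_reference(matrix(0, 10, 4)), "all zeros")
})

test_that("fingerprints against the reduced reference preserve eta2 similarity", {
  # oracle: compress the full reference with a second, independent SVD
  # routine (eigen of the Gram matrix) and compare similarity matrices
  set.seed(32)
  t_n <- 100; W <- 900; V <- 15
  B <- matrix(rnorm(t_n * W), t_n, W); B <- sweep(B, 2, colMeans(B))
  A <- matrix(rnorm(t_n * V), t_n, V); A <- sweep(A, 2, colMeans(A))
  # singular vectors are sign-ambiguous and eta2 is sign-sensitive, so
  # both routes canonicalize each component's largest entry to positive
  canon <- function(U) {
    s <- apply(U, 2, function(u) sign(u[which.max(abs(u))]))
    sweep(U, 2, s, "*")
  }
  ref <- reduce_reference(B)
  ref$components <- canon(ref$components)
  S_pkg <- eta2_similarity(compute_fingerprints(A, ref))

  eg <- eigen(tcrossprod(B), symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  U2 <- canon(eg$vectors[, keep])
  expect_equal(ncol(U2), ref$rank)
  C2 <- cor(A, U2)
  S_oracle <- oracle_eta2(C2)
  expect_lt(max(abs(S_pkg - S_oracle)), 1e-8)
})

test_that("compute_fingerprints matches the direct correlation formula", {
  set.seed(33)
  t_n <- 20
  comp <- qr.Q(qr(matrix(rnorm(t_n * 5), t_n, 5)))
  ref <- structure(list(components = comp, singular_values = rep(1, 5),
                        rank = 5), class = "reduced_reference")
  A <- matrix(rnorm(t_n * 5), t_n, 5)
  A[, 2] <- comp[, 3]                # voxel equal to component 3
  C <- compute_fingerprints(A, ref)
  expect_equal(C[2, 3], 1, tolerance = 1e-12)
  direct <- matrix(0, 5, 5)
  for (v in 1:5) for (j in 1:5) direct[v, j] <- cor(A[, v], comp[, j])
  expect_equal(unname(C), direct, tolerance = 1e-12)
})

test_that("eta2_similarity matches the brute-force oracle and its invariants", {
  set.seed(34)
  for (rep in 1:5) {
    C <- matrix(rnorm(20 * 5), 20, 5)
    S <- eta2_similarity(C)
    expect_lt(max(abs(S - oracle_eta2(C))), 1e-12)
    expect_lt(max(abs(S - t(S))), 1e-10)
    expect_true(all(S >= 0 & S <= 1))
    expect_equal(unname(diag(S)), rep(1, 20))
  }
  # x = y gives 1; mirrored profiles around the joint mean give 0
  C2 <- rbind(c(1, -1, 2, -2), c(1, -1, 2, -2), c(-1, 1, -2, 2))
  S2 <- eta2_similarity(C2)
  expect_equal(S2[1, 2], 1)
  expect_equal(S2[1, 3], 0)
  # the formula is invariant to jointly shifting BOTH fingerprints by a
  # constant (pair means and the grand mean shift identically) but not
  # to shifting only one of them
  C3 <- matrix(rnorm(8), 2, 4)
  expect_equal(eta2_similarity(C3)[1, 2], eta2_similarity(C3 + 5)[1, 2],
               tolerance = 1e-9)
  C4 <- C3
  C4[1, ] <- C4[1, ] + 2
  expect_gt(abs(eta2_similarity(C3)[1, 2] - eta2_similarity(C4)[1, 2]),
            1e-3)
})

test_that("laplacian_eigenmaps matches the dense generalized-eigen oracle", {
  set.seed(35)
  for (rep in 1:5) {
    V <- sample(10:50, 1)
    S <- random_similarity(V)
    modes <- laplacian_eigenmaps(S, n_modes = 3)
    oracle <- oracle_geneig(S, 3)
    for (k in 1:3) {
      expect_lt(max(abs(modes[[k]]$values - oracle[[k]]$values)), 1e-8)
      expect_equal(modes[[k]]$eigenvalue, oracle[[k]]$eigenvalue,
                   tolerance = 1e-8)
    }
    lam <- vapply(modes, function(m) m$eigenvalue, numeric(1))
    expect_true(all(diff(lam) >= -1e-12))      # nondecreasing
    expect_true(all(lam >= 0))
  }
})

test_that("eigenmap structure: block separation and chain monotonicity", {
  # two equal blocks joined by epsilon ties: mode 0 separates them by sign
  V <- 20
  S <- matrix(1e-4, V, V)
  S[1:10, 1:10] <- 0.9
  S[11:20, 11:20] <- 0.9
  diag(S) <- 1
  m0 <- laplacian_eigenmaps(S, n_modes = 1)[[1]]$values
  expect_true(all(sign(m0[1:10]) == sign(m0[1])))
  expect_true(all(sign(m0[11:20]) == -sign(m0[1])))

  # chain-structured similarity: mode 0 is monotone along the chain
  Sc <- matrix(1e-6, V, V)
  for (i in 1:(V - 1)) Sc[i, i + 1] <- Sc[i + 1, i] <- 0.8
  diag(Sc) <- 1
  mc <- laplacian_eigenmaps(Sc, n_modes = 1)[[1]]$values
  expect_true(all(diff(mc) > 0) || all(diff(mc) < 0))

  # trivial eigenvalue is ~0 and excluded: a constant vector is not returned
  expect_gt(sd(mc), 0)
})

test_that("disconnected graphs and oversized mode requests are errors", {
  S <- diag(10) * 0 + diag(10)
  S[1:5, 1:5] <- 0.9; S[6:10, 6:10] <- 0.9
  S[1:5, 6:10] <- 0; S[6:10, 1:5] <- 0
  diag(S) <- 1
  expect_error(laplacian_eigenmaps(S, 1), "disconnected.*2 components")
  expect_error(laplacian_eigenmaps(random_similarity(8), n_modes = 7),
               "n_modes")
})

test_that("permutation equivariance of similarity and modes", {
  set.seed(36)
  C <- matrix(rnorm(25 * 6), 25, 6)
  S <- eta2_similarity(C)
  perm <- sample(25)
  Sp <- eta2_similarity(C[perm, ])
  expect_equal(unclass(Sp), unclass(S)[perm, perm], tolerance = 1e-12)
  m <- laplacian_eigenmaps(S, 2)
  mp <- laplacian_eigenmaps(Sp, 2)
  for (k in 1:2)
    expect_equal(abs(cor(mp[[k]]$values, m[[k]]$values[perm])), 1,
                 tolerance = 1e-8)
})

test_that("align_mode flips exactly when negatively correlated", {
  set.seed(37)
  ref <- laplacian_eigenmaps(random_similarity(15), 1)[[1]]
  m <- ref
  m$values <- -ref$values
  aligned <- align_mode(m, ref)
  expect_equal(aligned$values, ref$values)   # mode = -ref returns ref
  expect_equal(aligned$aligned_to, "reference")

  noisy <- ref
  noisy$values <- ref$values * 0.3 + rnorm(15, sd = sd(ref$values))
  r0 <- cor(noisy$values, ref$values)
  out <- align_mode(noisy, ref)
  expect_equal(cor(out$values, ref$values), abs(r0), tolerance = 1e-12)
  expect_error(align_mode(structure(list(values = rep(0, 15)),
                                    class = "connectivity_mode"), ref),
               "zero-variance")
})

test_that("group_similarity is the element-wise mean", {
  set.seed(38)
  S1 <- random_similarity(12); S2 <- random_similarity(12)
  G <- group_similarity(list(S1, S2))
  expect_equal(unclass(G), (S1 + S2) / 2, tolerance = 1e-15)
  expect_lt(max(abs(G - t(G))), 1e-12)
  expect_equal(unclass(group_similarity(list(S1, S1))), S1)
  expect_error(group_similarity(list(S1, random_similarity(5))),
               "size mismatch")
})

test_that("map_subject equals the manually chained operations and is deterministic", {
  scene <- build_scene(grid_shape = c(10, 10, 10), roi_side = 4,
                       gradient_degrees = 1, n_networks = 6, snr = 5,
                       seed = 40)
  syn <- synthesize_bold(scene, t = 80, seed = 40)
  roi <- scene$roi_specs[[1]]
  res <- map_subject(syn$bold, roi, syn$brain_mask, n_modes = 2)
  pair <- extract_timeseries(syn$bold, roi, syn$brain_mask)
  manual <- laplacian_eigenmaps(
    eta2_similarity(compute_fingerprints(pair$A,
                                         reduce_reference(pair$B))), 2)
  for (k in 1:2)
    expect_equal(res$modes[[k]]$values, manual[[k]]$values)
  # determinism: an identical session gives bit-identical modes
  res2 <- map_subject(syn$bold, roi, syn$brain_mask, n_modes = 2)
  expect_identical(res$modes[[1]]$values, res2$modes[[1]]$values)
  expect_equal(res$log$n_voxels, n_voxels(roi))
})
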