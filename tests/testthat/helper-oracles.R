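# Independent oracle implementations used to cross-check the package.
# These deliberately use naive loops / alternative routines, never the
# package's own code paths.

# eta-squared similarity, per-pair loop over the textbook formula
oracle_eta2 <- function(C) {
  V <- nrow(C)
  S <- matrix(0, V, V)
  for (a in seq_len(V)) for (b in seq_len(V)) {
    x <- C[a, ]; y <- C[b, ]
    m <- (x + y) / 2
    M <- mean(c(x, y))
    S[a, b] <- 1 - (sum((x - m)^2) + sum((y - m)^2)) /
      (sum((x - M)^2) + sum((y - M)^2))
  }
  diag(S) <- 1
  S
}

# normalization convention shared with the package's modes, re-stated
# independently: remove D-weighted mean, unit norm, first significant
# entry positive
oracle_normalize <- function(v, d) {
  v <- v - sum(d * v) / sum(d)
  v <- v / sqrt(sum(v^2))
  first <- which(abs(v) > 1e-8 * max(abs(v)))[1]
  if (v[first] < 0) -v else v
}

# generalized eigenproblem L v = lambda D v solved as a plain
# nonsymmetric eigendecomposition of D^-1 L (dense oracle)
oracle_geneig <- function(S, n_modes) {
  W <- S; diag(W) <- 0
  d <- rowSums(W)
  L <- diag(d) - W
  e <- eigen(diag(1 / d) %*% L)
  ord <- order(Re(e$values))
  lapply(seq_len(n_modes), function(k) {
    v <- Re(e$vectors[, ord[k + 1]])    # skip trivial constant vector
    list(values = oracle_normalize(v, d),
         eigenvalue = Re(e$values[ord[k + 1]]))
  })
}

# ridge closed form (X'X + k I)^-1 X' y on the centred response and
# column-centred design (the fit's intercept-free convention)
oracle_ridge <- function(X, y, k) {
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  drop(solve(crossprod(Xc) + diag(k, ncol(Xc)), crossprod(Xc, yc)))
}

# ICC(2,k) via stats::aov on the long-format two-way layout
oracle_icc_aov <- function(M) {
  n <- nrow(M); k <- ncol(M)
  long <- data.frame(y = as.vector(M),
                     subject = factor(rep(seq_len(n), k)),
                     session = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + session, data = long))[[1]][,
    "Mean Sq"]
  (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n)
}

# random symmetric similarity-like matrix: entries in (0, 1), unit
# diagonal, dense hence connected
random_similarity <- function(V) {
  R <- matrix(runif(V * V, 0.05, 0.95), V, V)
  S <- (R + t(R)) / 2
  diag(S) <- 1
  S
}

# small standard phantom shared across tests
small_scene <- function(seed = 1, ...) {
  build_scene(grid_shape = c(12, 12, 12), gradient_degrees = c(1, 2),
              snr = 5, seed = seed, ...)
}
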