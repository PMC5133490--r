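# Independent oracles: naive per-pair metric formulas, a dense brute-force
# mixed-model likelihood, and Monte-Carlo gene dropping for kinship. These
# deliberately avoid the package's vectorized code paths.

oracle_pair <- function(x, y, method, Cinv = NULL) {
  div0 <- function(num, den) if (den == 0) 0 else num / den
  switch(method,
    eucl = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    chebyshev = max(abs(x - y)),
    bhja = sqrt(sum((sqrt(x) - sqrt(y))^2)),
    dive = sum(mapply(function(a, b) div0((a - b)^2, (a + b)^2), x, y)),
    canberra = sum(mapply(function(a, b) div0(abs(a - b), abs(a) + abs(b)),
                          x, y)),
    bray = div0(sum(abs(x - y)), sum(x + y)),
    soergel = div0(sum(abs(x - y)), sum(pmax(x, y))),
    chord = sqrt(sum((x / sqrt(sum(x^2)) - y / sqrt(sum(y^2)))^2)),
    geodesic = acos(min(1, max(-1,
      sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))))),
    hellinger = sqrt(sum((sqrt(x / sum(x)) - sqrt(y / sum(y)))^2)),
    whittaker = sum(abs(x / sum(x) - y / sum(y))) / 2,
    mahalanobis = sqrt(drop(t(x - y) %*% Cinv %*% (x - y))),
    corr = {
      xc <- x - mean(x); yc <- y - mean(y)
      sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
    },
    cosine = sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2))),
    ejac = sum(x * y) / (sum(x^2) + sum(y^2) - sum(x * y)),
    stop("oracle: unknown method ", method))
}

# plain numeric matrix: drop class and provenance attributes
bare <- function(S) {
  m <- unclass(S)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

# double-loop similarity/distance matrix from the per-pair formula
oracle_matrix <- function(X, method) {
  n <- nrow(X)
  Cinv <- if (method == "mahalanobis") solve(stats::cov(X)) else NULL
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    M[i, j] <- oracle_pair(X[i, ], X[j, ], method, Cinv)
  if (!method %in% c("corr", "cosine", "ejac")) diag(M) <- 0 else diag(M) <- 1
  M
}

# explicit-inverse Gaussian log-likelihood with GLS-profiled fixed effects
oracle_loglik <- function(theta, y, X, kernels) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (j in seq_along(kernels)) V <- V + theta[j] * kernels[[j]]
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  -0.5 * (ld + drop(t(r) %*% Vi %*% r) + n * log(2 * pi))
}

# Monte-Carlo gene dropping: 2*phi estimated as expected allele sharing.
# Founders get unique allele labels; every descendant inherits one random
# parental allele from each parent; phi(i,j) is the match probability of one
# random allele from each.
oracle_gene_drop_kinship <- function(ped, n_drops = 10000, seed = 99) {
  set.seed(seed)
  ids <- ped$individual_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  # parents-before-children order, resolved iteratively
  ord <- integer(0)
  done <- rep(FALSE, n)
  while (length(ord) < n) {
    ready <- which(!done &
                     (is.na(fa) | done[pmax(fa, 1, na.rm = TRUE)]) &
                     (is.na(mo) | done[pmax(mo, 1, na.rm = TRUE)]))
    stopifnot(length(ready) > 0)
    ord <- c(ord, ready)
    done[ready] <- TRUE
  }
  phi_sum <- matrix(0, n, n)
  for (d in seq_len(n_drops)) {
    a1 <- integer(n); a2 <- integer(n)
    next_allele <- 0L
    u1 <- stats::runif(n) < 0.5
    u2 <- stats::runif(n) < 0.5
    for (i in ord) {
      if (is.na(fa[i])) {
        a1[i] <- next_allele + 1L; a2[i] <- next_allele + 2L
        next_allele <- next_allele + 2L
      } else {
        a1[i] <- if (u1[i]) a1[fa[i]] else a2[fa[i]]
        a2[i] <- if (u2[i]) a1[mo[i]] else a2[mo[i]]
      }
    }
    A1 <- outer(a1, a1, "==") + outer(a1, a2, "==") +
          outer(a2, a1, "==") + outer(a2, a2, "==")
    phi_sum <- phi_sum + A1 / 4
  }
  k <- 2 * phi_sum / n_drops
  dimnames(k) <- list(ids, ids)
  k
}
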