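test_that("profile_loglik matches closed-form and brute-force Gaussian likelihoods", {
  # n = 2, y = 0, X = intercept, V = I: density is -log(2*pi)
  spec0 <- mixed_model_spec(c(0, 0))
  expect_equal(as.numeric(profile_loglik(1, spec0)), -log(2 * pi))

  # identity kernel: likelihood constant along the sigma2_A + sigma2_e ridge
  set.seed(31)
  y <- rnorm(12)
  specI <- mixed_model_spec(y, kernels = list(I = diag(12)))
  l1 <- as.numeric(profile_loglik(c(0.3, 0.7), specI))
  l2 <- as.numeric(profile_loglik(c(0.9, 0.1), specI))
  l3 <- as.numeric(profile_loglik(c(0.0, 1.0), specI))
  expect_equal(l1, l2)
  expect_equal(l1, l3)

  # dense explicit-inverse oracle on random 20-individual problems
  set.seed(32)
  for (rep in 1:4) {
    n <- 20
    K1 <- crossprod(matrix(rnorm(n * n), n)) / n
    K2 <- crossprod(matrix(rnorm(n * n), n)) / n
    X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    y <- rnorm(n)
    spec <- mixed_model_spec(y, X, list(a = K1, b = K2), standardize = FALSE)
    th <- runif(3, 0.2, 2)
    expect_equal(as.numeric(profile_loglik(th, spec)),
                 oracle_loglik(th, y, X, list(K1, K2)), tolerance = 1e-8)
  }
})

test_that("analytic gradient agrees with numerical differentiation", {
  set.seed(33)
  n <- 15
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  spec <- mixed_model_spec(rnorm(n), cbind(1, rnorm(n)), list(K = K),
                          standardize = FALSE)
  th <- c(0.8, 0.6)
  g <- attr(profile_loglik(th, spec, gradient = TRUE), "gradient")
  eps <- 1e-6
  for (j in 1:2) {
    tp <- tm <- th
    tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
    num <- (as.numeric(profile_loglik(tp, spec)) -
              as.numeric(profile_loglik(tm, spec))) / (2 * eps)
    expect_equal(g[j], num, tolerance = 1e-4)
  }
})

test_that("ML fitting is scale-equivariant and handles pure noise", {
  st <- small_study(seed = 41, n_replicates = 1)
  K <- unclass(st$kinship)
  set.seed(42)
  y <- rnorm(nrow(K))
  spec <- mixed_model_spec(y, kernels = list(kin = K))
  fit <- fit_ml(spec)
  expect_true(fit$converged)
  expect_true(all(fit$sigma2 >= 0))
  expect_equal(sum(fit$proportions), 1)

  fit10 <- fit_ml(mixed_model_spec(10 * y, kernels = list(kin = K)))
  expect_equal(fit10$sigma2, 100 * fit$sigma2, tolerance = 1e-3)
  expect_equal(fit10$h2, fit$h2, tolerance = 1e-4)
  # likelihood difference to a nested alternative is unchanged under scaling
  S <- unclass(make_psd(standardize_vc_matrix(
    similarity_matrix(t(st$expression$values), "corr"))))
  alt <- fit_ml(mixed_model_spec(y, kernels = list(kin = K, path = S)),
                start = c(fit$sigma2[1], 0, fit$sigma2[2]))
  alt10 <- fit_ml(mixed_model_spec(10 * y, kernels = list(kin = K, path = S)),
                  start = c(fit10$sigma2[1], 0, fit10$sigma2[2]))
  expect_equal(lrt(fit, alt)$statistic, lrt(fit10, alt10)$statistic,
               tolerance = 1e-3)
})

test_that("warm-started alternative never falls below the null likelihood", {
  st <- small_study(seed = 43, n_replicates = 4)
  K <- unclass(st$kinship)
  S <- unclass(make_psd(standardize_vc_matrix(
    similarity_matrix(t(st$expression$values), "ejac"))))
  for (r in 1:4) {
    y <- st$phenotypes[r, ]
    nf <- fit_ml(mixed_model_spec(y, kernels = list(kin = K)))
    af <- fit_ml(mixed_model_spec(y, kernels = list(kin = K, path = S)),
                 start = c(nf$sigma2[1], 0, nf$sigma2[2]))
    expect_gte(af$loglik, nf$loglik - 1e-6)
  }
})

test_that("likelihood is invariant to a simultaneous permutation of individuals", {
  set.seed(44)
  n <- 18
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  th <- c(0.5, 0.8)
  perm <- sample(n)
  l1 <- as.numeric(profile_loglik(th, mixed_model_spec(y, X, list(K = K),
                                                       standardize = FALSE)))
  l2 <- as.numeric(profile_loglik(th, mixed_model_spec(
    y[perm], X[perm, , drop = FALSE], list(K = K[perm, perm]),
    standardize = FALSE)))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("boundary LRT p values follow the half-half mixture", {
  fake_fit <- function(ll, nk, y, X) {
    structure(list(loglik = ll,
                   spec = list(y = y, X = X,
                               kernels = rep(list(diag(2)), nk))),
              class = "varcomp_fit")
  }
  y <- c(0, 1); X <- matrix(1, 2, 1)
  n0 <- fake_fit(-5, 1, y, X)
  # equal likelihoods: statistic 0, p = 0.5 by the boundary convention
  res0 <- lrt(n0, fake_fit(-5, 2, y, X))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 0.5)
  # statistic 2.706 is the chi2_1 upper 10% point: mixture p = 0.05
  res1 <- lrt(n0, fake_fit(-5 + 2.706 / 2, 2, y, X))
  expect_equal(res1$p_value, 0.05, tolerance = 1e-3)
  # naive chi2_1 mode doubles the boundary p
  res2 <- lrt(n0, fake_fit(-5 + 2.706 / 2, 2, y, X), null_dist = "chi2_1")
  expect_equal(res2$p_value, 2 * res1$p_value, tolerance = 1e-12)
  # a worse alternative is clipped at zero
  resn <- lrt(n0, fake_fit(-5.4, 2, y, X))
  expect_equal(resn$statistic, 0)
  # mismatched phenotypes are rejected
  expect_error(lrt(n0, fake_fit(-4, 2, c(5, 5), X)), "share y and X")
})

test_that("variance proportions are sigma2 shares summing to one", {
  fit <- structure(list(sigma2 = c(kin = 1, path = 1, e = 2)),
                   class = "varcomp_fit")
  expect_equal(unname(variance_explained(fit)), c(0.25, 0.25, 0.5))
  fit0 <- structure(list(sigma2 = c(kin = 0.4, path = 0, e = 0.6)),
                    class = "varcomp_fit")
  expect_equal(unname(variance_explained(fit0))[2], 0)
  expect_equal(sum(variance_explained(fit0)), 1)
})

test_that("REML removes the ML denominator bias in the no-kernel case", {
  # intercept-only, V = sigma2*I: ML maximum is SSE/n, REML's is SSE/(n-1)
  set.seed(46)
  y <- rnorm(25, mean = 3, sd = 2)
  sse <- sum((y - mean(y))^2)
  spec <- mixed_model_spec(y)
  fml <- fit_ml(spec)
  frm <- fit_ml(spec, reml = TRUE)
  expect_equal(unname(fml$sigma2["e"]), sse / 25, tolerance = 1e-5)
  expect_equal(unname(frm$sigma2["e"]), sse / 24, tolerance = 1e-5)
  # REML gradient matches numerical differentiation with a kernel present
  n <- 12
  K <- crossprod(matrix(rnorm(n * n), n)) / n
  spec2 <- mixed_model_spec(rnorm(n), cbind(1, rnorm(n)), list(K = K),
                            standardize = FALSE)
  th <- c(0.7, 0.9)
  g <- attr(profile_loglik(th, spec2, gradient = TRUE, reml = TRUE),
            "gradient")
  eps <- 1e-6
  for (j in 1:2) {
    tp <- tm <- th
    tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
    num <- (as.numeric(profile_loglik(tp, spec2, reml = TRUE)) -
              as.numeric(profile_loglik(tm, spec2, reml = TRUE))) / (2 * eps)
    expect_equal(g[j], num, tolerance = 1e-4)
  }
})

test_that("heritability is recovered on a small simulated study", {
  # modest-size check; the full-replicate recovery runs in the acceptance suite
  cfg <- sim_config(n_families = 10, n_probes = 2, trait_heritability = 0.5,
                    n_replicates = 12, seed = 45)
  st <- simulate_study(cfg)
  K <- unclass(st$kinship)
  h2 <- vapply(seq_len(12), function(r)
    fit_ml(mixed_model_spec(st$phenotypes[r, ], kernels = list(kin = K)))$h2,
    numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 0.15)
})
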