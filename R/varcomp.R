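#' Specify a variance-component mixed model
#'
#' The model is y = X beta + sum_k u_k + e with u_k ~ N(0, sigma2_k K_k) and
#' e ~ N(0, sigma2_e I), so V(theta) = sum_k sigma2_k K_k + sigma2_e I. The
#' first kernel is conventionally the pedigree 2*phi matrix (the polygenic
#' component); an optional second kernel is a pathway similarity matrix.
#' Kernels are standardized to unit mean diagonal before fitting so
#' variance components are on comparable scales.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (default intercept only); collinear
#'   columns are pruned with a warning.
#' @param kernels named list of symmetric PSD matrices conformable with `y`.
#' @param standardize scale each kernel to mean diagonal 1 (default TRUE).
#' @return an object of class `mixed_model_spec`.
#' @export
mixed_model_spec <- function(y, X = NULL, kernels = list(),
                             standardize = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X rows must match length(y)")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("collinear fixed-effect columns dropped: ",
            paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  if (length(kernels) > 0 && is.null(names(kernels)))
    names(kernels) <- paste0("K", seq_along(kernels))
  kernels <- lapply(kernels, function(K) {
    K <- as.matrix(K)
    if (nrow(K) != n || ncol(K) != n) stop("kernel dimensions must match length(y)")
    if (max(abs(K - t(K))) > 1e-8) stop("kernel not symmetric")
    if (standardize) K <- K * (n / sum(diag(K)))
    unclass(K)
  })
  structure(list(y = y, X = X, kernels = kernels, n = n),
            class = "mixed_model_spec")
}

#' Profile log-likelihood of the variance parameters
#'
#' Evaluates the Gaussian log-likelihood at variance parameters `theta`
#' (one sigma2 per kernel, residual sigma2_e last) with the fixed effects
#' profiled out by generalized least squares:
#' loglik = -(log|V| + r' V^-1 r + n log 2pi)/2 with r = y - X beta_hat(theta).
#' Computation is by Cholesky factorization of V.
#'
#' With `reml = TRUE` the restricted likelihood is returned instead
#' (the fixed-effect dimension is projected out, adding
#' \eqn{-\log|X'V^{-1}X|/2} and replacing n by n - p in the constant), which
#' removes the downward bias of ML variance estimates; e.g. with an
#' intercept-only design and no kernels the REML maximum is the usual
#' n - 1 denominator sample variance.
#'
#' @param theta numeric vector `c(sigma2_kernels..., sigma2_e)`, all >= 0.
#' @param spec a [mixed_model_spec].
#' @param gradient also return the analytic gradient as attribute `"gradient"`.
#' @param reml return the restricted (REML) log-likelihood.
#' @return the log-likelihood (numeric scalar), with attributes `beta` and
#'   optionally `gradient`.
#' @export
profile_loglik <- function(theta, spec, gradient = FALSE, reml = FALSE) {
  k <- length(spec$kernels)
  if (length(theta) != k + 1) stop("theta must have one entry per kernel plus sigma2_e")
  n <- spec$n
  V <- diag(theta[k + 1], n)
  for (j in seq_len(k)) V <- V + theta[j] * spec$kernels[[j]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    bad <- if (k > 0) paste(names(spec$kernels), collapse = ", ") else "residual"
    stop("V(theta) is not positive definite (kernels: ", bad,
         "); increase sigma2_e or repair the kernels")
  }
  logdet <- 2 * sum(log(diag(ch)))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), spec$X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), spec$y))
  XtViX <- crossprod(spec$X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, spec$y))
  r <- spec$y - spec$X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  quad <- sum(r * Vi_r)
  p <- ncol(spec$X)
  ll <- if (reml) {
    -0.5 * (logdet + as.numeric(determinant(XtViX)$modulus) + quad +
              (n - p) * log(2 * pi))
  } else {
    -0.5 * (logdet + quad + n * log(2 * pi))
  }
  attr(ll, "beta") <- drop(beta)
  if (gradient) {
    Vi <- chol2inv(ch)
    B <- if (reml) solve(XtViX) else NULL
    g <- numeric(k + 1)
    for (j in seq_len(k)) {
      g[j] <- -0.5 * (sum(Vi * spec$kernels[[j]]) -
                        sum(Vi_r * (spec$kernels[[j]] %*% Vi_r)))
      if (reml)
        g[j] <- g[j] + 0.5 * sum(B * crossprod(Vi_X, spec$kernels[[j]] %*% Vi_X))
    }
    g[k + 1] <- -0.5 * (sum(diag(Vi)) - sum(Vi_r^2))
    if (reml) g[k + 1] <- g[k + 1] + 0.5 * sum(B * crossprod(Vi_X))
    attr(ll, "gradient") <- g
  }
  ll
}

#' Fit a variance-component model by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B with analytic gradients) over the
#' non-negative variance components, run from three starting points (equal
#' split of the phenotypic variance; kinship-heavy; last-kernel-heavy) plus
#' an optional warm start; the best converged solution is kept. ML rather
#' than REML is the default so that likelihood-ratio tests between nested
#' models sharing the same fixed effects are directly comparable.
#'
#' @param spec a [mixed_model_spec].
#' @param start optional warm-start vector `c(sigma2..., sigma2_e)` (used,
#'   e.g., to start the pathway-augmented model at the null solution so the
#'   alternative maximum can never fall below the null's).
#' @param n_starts number of default starting points (1-3).
#' @param reml maximize the restricted likelihood instead of ML; use ML fits
#'   for likelihood-ratio testing (the default here and the convention for
#'   these tests), REML when unbiased variance estimates themselves are the
#'   target.
#' @return an object of class `varcomp_fit` with elements `beta`, `sigma2`
#'   (named, residual `"e"` last), `loglik`, `h2` (first-kernel proportion),
#'   `pathway_var` (last non-kinship kernel proportion, NA if absent),
#'   `proportions`, `converged`, `n_iter`.
#' @export
fit_ml <- function(spec, start = NULL, n_starts = 3, reml = FALSE) {
  k <- length(spec$kernels)
  vy <- stats::var(spec$y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  p <- k + 1
  lower <- c(rep(0, k), 1e-8 * vy)
  upper <- rep(20 * vy, p)
  starts <- list(rep(vy / p, p))
  if (k >= 1 && n_starts >= 2) {
    s <- rep(0.05 * vy, p); s[1] <- 0.7 * vy; s[p] <- 0.25 * vy
    starts <- c(starts, list(s))
  }
  if (k >= 1 && n_starts >= 3) {
    s <- rep(0.05 * vy, p); s[k] <- 0.7 * vy; s[p] <- 0.25 * vy
    starts <- c(starts, list(s))
  }
  if (!is.null(start)) starts <- c(list(pmax(start, lower)), starts)

  negll <- function(th) -as.numeric(profile_loglik(th, spec, reml = reml))
  neggr <- function(th) -attr(profile_loglik(th, spec, gradient = TRUE,
                                             reml = reml), "gradient")
  best <- NULL
  n_iter <- 0L
  any_conv <- FALSE
  for (s0 in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s0, lower), upper), negll, neggr,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e7, maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_iter <- n_iter + fit$counts[1]
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta <- best$par
  theta[theta < 0] <- 0
  ll <- profile_loglik(theta, spec, reml = reml)
  sig <- stats::setNames(theta, c(names(spec$kernels), "e"))
  tot <- sum(sig)
  prop <- if (tot > 0) sig / tot else sig * 0
  kin_name <- if (k >= 1) names(spec$kernels)[1] else NA_character_
  path_name <- if (k >= 2) names(spec$kernels)[k] else NA_character_
  structure(list(
    beta = attr(ll, "beta"),
    sigma2 = sig,
    loglik = as.numeric(ll),
    h2 = if (k >= 1) unname(prop[1]) else NA_real_,
    pathway_var = if (k >= 2) unname(prop[k]) else NA_real_,
    proportions = prop,
    converged = any_conv,
    n_iter = as.integer(n_iter),
    reml = reml,
    spec = spec
  ), class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("varcomp_fit: loglik =", format(x$loglik, digits = 6),
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat("  sigma2:", paste(sprintf("%s=%.4g", names(x$sigma2), x$sigma2),
                         collapse = ", "), "\n")
  if (!is.na(x$h2)) cat("  h2 =", format(x$h2, digits = 3), "\n")
  if (!is.na(x$pathway_var))
    cat("  pathway proportion =", format(x$pathway_var, digits = 3), "\n")
  invisible(x)
}

#' Likelihood-ratio test for one extra variance component
#'
#' Compares a null fit to an alternative fit with one additional kernel
#' (same phenotype and fixed effects). Because the extra variance component
#' is tested on the boundary of its parameter space, the default null
#' distribution is the 50:50 mixture of a point mass at zero and chi-squared
#' with 1 df: p = P(chi2_1 > LRT)/2 for a positive statistic and p = 0.5 at
#' zero. `null_dist = "chi2_1"` gives the naive full chi-squared p value for
#' comparison.
#'
#' @param null_fit,alt_fit `varcomp_fit` objects; `alt_fit` must nest
#'   `null_fit` with exactly one extra kernel.
#' @param null_dist `"mixture"` (default) or `"chi2_1"`.
#' @return list with `statistic` (2 * delta-loglik clipped at zero),
#'   `p_value`, and `null_distribution`.
#' @export
lrt <- function(null_fit, alt_fit, null_dist = c("mixture", "chi2_1")) {
  null_dist <- match.arg(null_dist)
  if (!isTRUE(all.equal(null_fit$spec$y, alt_fit$spec$y)) ||
      !isTRUE(all.equal(unname(null_fit$spec$X), unname(alt_fit$spec$X))))
    stop("null and alternative fits must share y and X")
  if (length(alt_fit$spec$kernels) != length(null_fit$spec$kernels) + 1)
    stop("alternative must have exactly one extra kernel")
  stat <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  p <- if (null_dist == "mixture") {
    if (stat > 0) 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) else 0.5
  } else {
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, null_distribution = null_dist)
}

#' Variance proportions per component
#'
#' The proportion of phenotypic variance attributed to each kernel plus the
#' residual: sigma2_k / sum(sigma2). Proportions sum to 1.
#'
#' @param fit a `varcomp_fit`.
#' @export
variance_explained <- function(fit) {
  s <- fit$sigma2
  tot <- sum(s)
  if (tot <= 0) return(s * 0)
  s / tot
}
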