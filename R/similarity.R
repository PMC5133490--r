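#' Similarity metrics
#'
#' The 16 supported metric names. Three are direct similarities
#' (`corr`, `cosine`, `ejac`); the rest are distances that are converted to
#' similarities as s = 1/(1 + d).
#'
#' @format character vector of metric names.
#' @export
SIMILARITY_METHODS <- c("corr", "cosine", "ejac",
                        "bhja", "bray", "canberra", "chebyshev", "chord",
                        "dive", "eucl", "geodesic", "hellinger",
                        "mahalanobis", "manhattan", "soergel", "whittaker")

DIRECT_METHODS <- c("corr", "cosine", "ejac")

# Pairwise formulas, pinned here and mirrored by the double-loop test oracle.
# x, y are one individual's profile across the pathway's probes:
#   bhja        sqrt(sum (sqrt(x) - sqrt(y))^2)
#   bray        sum|x - y| / sum(x + y)
#   canberra    sum |x - y| / (|x| + |y|)          (0-denominator terms -> 0)
#   chebyshev   max |x - y|
#   chord       || x/||x|| - y/||y|| ||
#   dive        sum (x - y)^2 / (x + y)^2           (0-denominator terms -> 0)
#   eucl        sqrt(sum (x - y)^2)
#   geodesic    arccos(cosine(x, y))
#   hellinger   bhja on L1-normalized x, y
#   mahalanobis sqrt((x - y)' C^-1 (x - y)), C = probe covariance
#   manhattan   sum |x - y|
#   soergel     sum |x - y| / sum max(x, y)
#   whittaker   sum |x/sum(x) - y/sum(y)| / 2
#   corr        Pearson correlation of profiles (each centered by its own mean)
#   cosine      xy / (||x|| ||y||)
#   ejac        xy / (xx + yy - xy)                 (extended Jaccard/Tanimoto)

#' Pairwise distance matrix between individual expression profiles
#'
#' Rows of `X` are individuals, columns are the probes of one pathway,
#' typically scaled to \[0, 1\]. Bhattacharyya, Hellinger and divergence
#' require non-negative values. Divergence and Canberra terms with a zero
#' denominator contribute 0. The Mahalanobis probe covariance is estimated
#' across all individuals and ridge-regularized
#' (eps = 1e-6 x mean diagonal) when its condition number exceeds 1e10,
#' with a warning.
#'
#' @param X numeric matrix, individuals x probes; rownames are individual
#'   ids.
#' @param method one of the distance-type names in [SIMILARITY_METHODS].
#' @return symmetric N x N matrix with zero diagonal.
#' @export
pairwise_distance <- function(X, method) {
  X <- as.matrix(X)
  if (!method %in% SIMILARITY_METHODS) stop("unknown method: ", method)
  if (method %in% DIRECT_METHODS)
    stop("'", method, "' is a direct similarity; use direct_similarity()")
  if (ncol(X) == 1)
    warning("single-probe profile set: distances collapse to 1-D differences")
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  if (method %in% c("bhja", "hellinger", "dive") && any(X < 0))
    stop("'", method, "' requires non-negative values")

  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

  if (method == "eucl") {
    D[] <- as.matrix(stats::dist(X, method = "euclidean"))
  } else if (method == "manhattan") {
    D[] <- as.matrix(stats::dist(X, method = "manhattan"))
  } else if (method == "chebyshev") {
    D[] <- as.matrix(stats::dist(X, method = "maximum"))
  } else if (method == "bhja") {
    D[] <- as.matrix(stats::dist(sqrt(X), method = "euclidean"))
  } else if (method %in% c("chord", "geodesic")) {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0))
      warning("all-zero profile(s); treated as the zero direction")
    Xu <- X / ifelse(nrm == 0, 1, nrm)
    if (method == "chord") {
      D[] <- as.matrix(stats::dist(Xu, method = "euclidean"))
    } else {
      cs <- pmin(pmax(tcrossprod(Xu), -1), 1)
      diag(cs) <- 1
      D[] <- acos(cs)
    }
  } else if (method %in% c("hellinger", "whittaker")) {
    s <- rowSums(X)
    if (any(s == 0))
      warning("profile(s) with zero total; left as all-zero after L1 normalization")
    Xn <- X / ifelse(s == 0, 1, s)
    if (method == "hellinger") {
      D[] <- as.matrix(stats::dist(sqrt(Xn), method = "euclidean"))
    } else {
      D[] <- as.matrix(stats::dist(Xn, method = "manhattan")) / 2
    }
  } else if (method == "mahalanobis") {
    C <- stats::cov(X)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.eps) > 1e10) {
      warning("singular/ill-conditioned probe covariance; ridge-regularized")
      C <- C + diag(1e-6 * mean(diag(C)) + 1e-12, ncol(C))
    }
    Ci <- solve(C)
    # d^2(i,j) = m_ii + m_jj - 2 m_ij with M = X Ci X'
    M <- X %*% Ci %*% t(X)
    d2 <- outer(diag(M), diag(M), "+") - 2 * M
    D[] <- sqrt(pmax(d2, 0))
  } else if (method %in% c("bray", "soergel", "canberra", "dive")) {
    for (i in seq_len(n - 1L)) {
      jj <- (i + 1L):n
      Xi <- rep(1, length(jj)) %o% X[i, ]
      Xj <- X[jj, , drop = FALSE]
      ad <- abs(Xi - Xj)
      val <- switch(method,
        bray = safe_div(rowSums(ad), rowSums(Xi + Xj)),
        soergel = safe_div(rowSums(ad), rowSums(pmax(Xi, Xj))),
        canberra = rowSums(safe_div(ad, abs(Xi) + abs(Xj))),
        dive = rowSums(safe_div((Xi - Xj)^2, (Xi + Xj)^2)))
      D[i, jj] <- D[jj, i] <- val
    }
  } else stop("unknown method: ", method)
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Convert a distance matrix to a similarity matrix
#'
#' Applies s = 1/(1 + d) elementwise, so zero distance maps to similarity 1
#' and similarity decreases monotonically towards 0 as distance grows.
#'
#' @param D symmetric non-negative distance matrix.
#' @param method metric label to record on the result.
#' @return a `similarity_matrix` (see [similarity_matrix]).
#' @export
distance_to_similarity <- function(D, method = "distance") {
  if (any(D < 0)) stop("negative distances")
  if (max(abs(D - t(D))) > 1e-10) stop("distance matrix not symmetric")
  new_similarity(1 / (1 + D), method)
}

new_similarity <- function(S, method, psd_repaired = FALSE,
                           min_eig_before = NA_real_) {
  structure(S, class = c("similarity_matrix", "matrix", "array"),
            method = method, psd_repaired = psd_repaired,
            min_eigenvalue_before_repair = min_eig_before)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d x %d, method = %s%s\n",
              nrow(x), ncol(x), attr(x, "method"),
              if (isTRUE(attr(x, "psd_repaired"))) " (PSD-repaired)" else ""))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))], ...)
  invisible(x)
}

#' Direct similarity matrices (correlation, cosine, extended Jaccard)
#'
#' These three metrics are similarities already and receive no 1/(1 + d)
#' transform. `corr` is the Pearson correlation between two individuals'
#' profiles, each centered by its own mean across the pathway's probes;
#' `cosine` is xy/(||x|| ||y||); `ejac` is the extended Jaccard (Tanimoto)
#' coefficient xy/(xx + yy - xy). Degenerate rows (constant for `corr`,
#' all-zero for `cosine`/`ejac`) get off-diagonal entries 0 and diagonal 1,
#' with a warning.
#'
#' @inheritParams pairwise_distance
#' @param method `"corr"`, `"cosine"` or `"ejac"`.
#' @return a `similarity_matrix` with unit diagonal.
#' @export
direct_similarity <- function(X, method = c("corr", "cosine", "ejac")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (ncol(X) == 1)
    warning("single-probe profile set: similarities are degenerate")
  if (method == "corr") {
    Xc <- X - rowMeans(X)
    nrm <- sqrt(rowSums(Xc^2))
    bad <- nrm == 0
    if (any(bad)) warning(sum(bad), " constant profile(s): correlation entries set to 0")
    Xu <- Xc / ifelse(bad, 1, nrm)
    S <- tcrossprod(Xu)
    S[bad, ] <- 0; S[, bad] <- 0
  } else if (method == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    bad <- nrm == 0
    if (any(bad)) warning(sum(bad), " all-zero profile(s): cosine entries set to 0")
    Xu <- X / ifelse(bad, 1, nrm)
    S <- tcrossprod(Xu)
    S[bad, ] <- 0; S[, bad] <- 0
  } else {
    G <- tcrossprod(X)
    q <- diag(G)
    den <- outer(q, q, "+") - G
    bad <- q == 0
    if (any(bad)) warning(sum(bad), " all-zero profile(s): extended Jaccard entries set to 0")
    S <- ifelse(den == 0, 0, G / den)
    S[bad, ] <- 0; S[, bad] <- 0
  }
  diag(S) <- 1
  dimnames(S) <- list(rownames(X), rownames(X))
  new_similarity(pmin(pmax((S + t(S)) / 2, -1), 1), method)
}

#' Compute a pathway similarity matrix under any supported metric
#'
#' Dispatches to [direct_similarity] for `corr`/`cosine`/`ejac` and to
#' [pairwise_distance] + [distance_to_similarity] for the thirteen
#' distance-type metrics.
#'
#' @inheritParams pairwise_distance
#' @param method one of [SIMILARITY_METHODS].
#' @export
similarity_matrix <- function(X, method) {
  method <- match.arg(method, SIMILARITY_METHODS)
  if (method %in% DIRECT_METHODS) direct_similarity(X, method)
  else distance_to_similarity(pairwise_distance(X, method), method)
}

#' Repair a similarity matrix to positive semidefiniteness
#'
#' The mixed-model likelihood requires a valid covariance structure, so
#' negative eigenvalues are clipped to zero and the matrix reassembled
#' (symmetry restored). Already-PSD input (smallest eigenvalue >= -tol) is
#' returned unchanged; the pre-repair minimum eigenvalue is always recorded.
#'
#' @param S symmetric matrix (typically a `similarity_matrix`).
#' @param tol eigenvalues above `-tol` are considered nonnegative.
#' @return a `similarity_matrix` with `psd_repaired` and
#'   `min_eigenvalue_before_repair` attributes set.
#' @export
make_psd <- function(S, tol = 1e-8) {
  method <- attr(S, "method") %||% "unknown"
  M <- unclass(S); attributes(M)[setdiff(names(attributes(M)),
                                         c("dim", "dimnames"))] <- NULL
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  min_eig <- min(e$values)
  if (min_eig >= -tol)
    return(new_similarity(M, method, psd_repaired = FALSE,
                          min_eig_before = min_eig))
  vals <- pmax(e$values, 0)
  R <- e$vectors %*% (vals * t(e$vectors))
  R <- (R + t(R)) / 2
  dimnames(R) <- dimnames(M)
  new_similarity(R, method, psd_repaired = TRUE, min_eig_before = min_eig)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scale a variance-component matrix to unit mean diagonal
#'
#' Rescales S so that trace(S)/N = 1, putting pathway kernels on the same
#' scale as the kinship matrix so fitted variance components are comparable.
#'
#' @param S symmetric matrix with positive trace.
#' @export
standardize_vc_matrix <- function(S) {
  tr <- sum(diag(S))
  if (tr <= 0) stop("matrix trace must be positive")
  out <- S * (nrow(S) / tr)
  if (inherits(S, "similarity_matrix"))
    out <- new_similarity(unclass(out), attr(S, "method"),
                          attr(S, "psd_repaired"),
                          attr(S, "min_eigenvalue_before_repair"))
  out
}

#' Write / read a similarity matrix as TSV
#'
#' @param S matrix with individual ids as dimnames.
#' @param path file path; ids are written as header and first column.
#' @export
write_similarity_tsv <- function(S, path) {
  df <- data.frame(individual_id = rownames(S), as.data.frame(unclass(S)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
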