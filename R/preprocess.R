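#' Construct an expression matrix object
#'
#' Probes x individuals abundance values together with the probe-to-gene
#' annotation. Missing values are not supported: analyses assume complete
#' data and the constructor errors with a count of offending cells.
#'
#' @param values numeric matrix, probes x individuals.
#' @param probe_ids,individual_ids character vectors matching the matrix
#'   dimensions; default to the dimnames of `values`.
#' @param probe_to_gene named character vector mapping probe id -> gene id.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `probe_ids`, `individual_ids`, `probe_to_gene`.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              individual_ids = colnames(values),
                              probe_to_gene = NULL) {
  values <- as.matrix(values)
  if (is.null(probe_ids) || is.null(individual_ids))
    stop("probe and individual ids are required")
  probe_ids <- as.character(probe_ids)
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(probe_ids)) stop("duplicate probe ids")
  if (anyDuplicated(individual_ids)) stop("duplicate individual ids")
  if (nrow(values) != length(probe_ids) || ncol(values) != length(individual_ids))
    stop("dimension mismatch between values and ids")
  nbad <- sum(!is.finite(values))
  if (nbad > 0) stop("expression matrix contains ", nbad,
                     " missing/non-finite cells; complete data required")
  dimnames(values) <- list(probe_ids, individual_ids)
  if (is.null(probe_to_gene))
    probe_to_gene <- stats::setNames(probe_ids, probe_ids)
  if (!all(probe_ids %in% names(probe_to_gene)))
    stop("probe_to_gene does not cover all probes")
  structure(list(values = values, probe_ids = probe_ids,
                 individual_ids = individual_ids,
                 probe_to_gene = probe_to_gene[probe_ids]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d individuals (%d genes)\n",
              length(x$probe_ids), length(x$individual_ids),
              length(unique(x$probe_to_gene))))
  invisible(x)
}

replace_values <- function(expr, values) {
  expr$values <- values
  expr
}

#' Shift to minimum 1 and log2-transform
#'
#' Adds a global constant so the smallest abundance value becomes exactly
#' 1.0, then takes log base 2; the output minimum is therefore 0.
#'
#' @param expr an [expression_matrix].
#' @export
shift_log2 <- function(expr) {
  v <- expr$values
  replace_values(expr, log2(v - min(v) + 1))
}

#' Quantile normalization across individuals
#'
#' Forces every individual's column to the same distribution (the row-wise
#' mean of the sorted columns) while preserving within-column rank order;
#' ties share the mean of the corresponding reference values. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param expr an [expression_matrix].
#' @export
quantile_normalize <- function(expr) {
  replace_values(expr, limma::normalizeQuantiles(expr$values, ties = TRUE))
}

covariate_design <- function(cov) {
  stopifnot(all(c("sex", "age") %in% names(cov)))
  X <- cbind(intercept = 1, sex = as.numeric(cov$sex),
             age = as.numeric(cov$age), age2 = as.numeric(cov$age)^2,
             sex_age = as.numeric(cov$sex) * as.numeric(cov$age))
  X
}

#' Residualize expression on sex and age covariates
#'
#' Per probe, ordinary least-squares residuals from the regression of
#' abundance on intercept, sex, age, age^2 and the sex x age interaction.
#' Output probe rows are orthogonal to the design columns. A rank-deficient
#' design (e.g. a single-sex sample) drops the collinear columns with a
#' warning.
#'
#' @param expr an [expression_matrix].
#' @param covariates data.frame with columns `individual_id`, `sex`
#'   (1/2 or 0/1) and `age` (years), one row per individual in `expr`.
#' @export
adjust_covariates <- function(expr, covariates) {
  m <- match(expr$individual_ids, covariates$individual_id)
  if (anyNA(m)) stop("covariates missing for ",
                     sum(is.na(m)), " individual(s)")
  X <- covariate_design(covariates[m, , drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("rank-deficient covariate design; dropping: ",
            paste(dropped, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- t(qr.resid(qx, t(expr$values)))
  replace_values(expr, res)
}

#' Select one representative probe per gene
#'
#' Genes with a single probe keep it. With exactly two probes the one with
#' greater variance is kept. With three or more, the probe with the highest
#' mean pairwise Pearson correlation to the gene's other probes is kept.
#' Zero-variance probes are excluded from the correlation computation; if
#' every candidate is zero-variance the first by probe-id order is kept with
#' a warning. All ties break by lexicographic probe id. Values are never
#' altered, only rows dropped.
#'
#' @param expr an [expression_matrix] whose `probe_to_gene` covers all
#'   probes.
#' @export
select_representative_probes <- function(expr) {
  p2g <- expr$probe_to_gene
  keep <- character(0)
  for (g in unique(p2g)) {
    probes <- sort(names(p2g)[p2g == g])
    if (length(probes) == 1) { keep <- c(keep, probes); next }
    v <- expr$values[probes, , drop = FALSE]
    vars <- apply(v, 1, stats::var)
    if (all(vars == 0)) {
      warning("gene ", g, ": all candidate probes have zero variance; keeping ",
              probes[1])
      keep <- c(keep, probes[1]); next
    }
    if (length(probes) == 2) {
      keep <- c(keep, probes[order(-vars, probes)[1]])
      next
    }
    ok <- probes[vars > 0]
    if (length(ok) == 1) { keep <- c(keep, ok); next }
    cm <- stats::cor(t(v[ok, , drop = FALSE]))
    avg <- (rowSums(cm) - 1) / (length(ok) - 1)
    keep <- c(keep, ok[order(-avg, ok)[1]])
  }
  keep <- expr$probe_ids[expr$probe_ids %in% keep]
  expression_matrix(expr$values[keep, , drop = FALSE], keep,
                    expr$individual_ids, expr$probe_to_gene[keep])
}

#' Scale each probe to the unit interval
#'
#' Per probe row, (x - min)/(max - min) so every probe ranges from 0 to 1
#' and contributes equally to similarity computation. Optional per-probe
#' weights multiply the scaled rows (default 1). A constant probe maps to
#' all zeros with a warning: it then contributes nothing to any distance.
#'
#' @param expr an [expression_matrix], one probe per gene.
#' @param weights optional numeric vector, one weight per probe.
#' @export
scale_unit_interval <- function(expr, weights = NULL) {
  v <- expr$values
  rng <- apply(v, 1, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  if (any(const)) {
    warning(sum(const), " constant probe(s) mapped to all zeros")
    span[const] <- 1
  }
  out <- (v - rng[1, ]) / span
  out[const, ] <- 0
  if (!is.null(weights)) {
    if (length(weights) != nrow(v)) stop("one weight per probe required")
    out <- out * weights
  }
  replace_values(expr, out)
}

#' Full preprocessing pipeline
#'
#' Fixed order: shift/log2, quantile normalization, covariate
#' residualization, representative-probe selection, unit-interval scaling.
#' Probe selection operates on the covariate-adjusted residuals. Because the
#' residuals can be negative, the scaling step is what restores the
#' non-negativity that the Bhattacharyya-family metrics require.
#'
#' @inheritParams adjust_covariates
#' @param weights optional per-probe weights applied at the scaling stage.
#' @return an [expression_matrix] of unit-scaled, one-probe-per-gene
#'   profiles.
#' @export
preprocess_expression <- function(expr, covariates, weights = NULL) {
  expr <- shift_log2(expr)
  expr <- quantile_normalize(expr)
  expr <- adjust_covariates(expr, covariates)
  expr <- select_representative_probes(expr)
  scale_unit_interval(expr, weights)
}

#' Read / write expression data as TSV
#'
#' The expression TSV has probe ids in the first column and a header row of
#' individual ids. The annotation TSV has columns `probe_id`, `gene_id`;
#' the covariates TSV has `individual_id`, `sex`, `age`.
#'
#' @param path expression TSV path.
#' @param annotation_path optional probe-to-gene TSV path.
#' @export
read_expression_tsv <- function(path, annotation_path = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- as.character(df[[1]])
  p2g <- NULL
  if (!is.null(annotation_path)) {
    ann <- utils::read.table(annotation_path, sep = "\t", header = TRUE,
                             colClasses = "character")
    p2g <- stats::setNames(ann$gene_id, ann$probe_id)
  }
  expression_matrix(v, probe_to_gene = p2g)
}

#' @rdname read_expression_tsv
#' @param expr an [expression_matrix].
#' @export
write_expression_tsv <- function(expr, path, annotation_path = NULL) {
  df <- data.frame(probe_id = expr$probe_ids,
                   as.data.frame(expr$values, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path))
    utils::write.table(data.frame(probe_id = expr$probe_ids,
                                  gene_id = unname(expr$probe_to_gene)),
                       annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
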