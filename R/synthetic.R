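#' Configuration for the family-data simulator
#'
#' Defines the study conditions for a simulated family expression study:
#' extended pedigrees, probes with familial (heritable) expression, and
#' replicate phenotypes with a known additive-genetic fraction. The default
#' condition is 20 three-generation families of 17 individuals (340 total),
#' a trait heritability of 0.33, and 200 phenotype replicates; a null trait
#' is obtained with `trait_heritability = 0` and `n_causal_probes = 0`.
#'
#' @param n_families number of independent families.
#' @param founders_per_family founders in the first generation (paired into
#'   matings; use an even number).
#' @param n_generations generations of offspring below the founder
#'   generation (the default 2 gives three generational levels:
#'   grandparents, parents, children).
#' @param sibs_per_mating offspring per mating.
#' @param n_probes number of expression probes.
#' @param probe_heritability additive fraction of each probe's variance in
#'   \[0, 1\].
#' @param trait_heritability additive fraction of the phenotype's variance
#'   in \[0, 1\].
#' @param n_causal_probes number of probes whose genetic values feed the
#'   phenotype.
#' @param effect_sizes numeric vector of length `n_causal_probes`.
#' @param n_replicates number of phenotype replicates.
#' @param seed integer seed; every generator sub-stream derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 20, founders_per_family = 2,
                       n_generations = 2, sibs_per_mating = 3,
                       n_probes = 100, probe_heritability = 0.5,
                       trait_heritability = 0.33, n_causal_probes = 0,
                       effect_sizes = numeric(0), n_replicates = 200,
                       seed = 1L) {
  stopifnot(n_families >= 1, founders_per_family >= 1, n_generations >= 1,
            sibs_per_mating >= 1, n_probes >= 1, n_replicates >= 1,
            probe_heritability >= 0, probe_heritability <= 1,
            trait_heritability >= 0, trait_heritability <= 1,
            n_causal_probes >= 0, n_causal_probes <= n_probes)
  if (length(effect_sizes) != n_causal_probes)
    stop("effect_sizes must have length n_causal_probes")
  structure(list(n_families = n_families,
                 founders_per_family = founders_per_family,
                 n_generations = n_generations,
                 sibs_per_mating = sibs_per_mating,
                 n_probes = n_probes,
                 probe_heritability = probe_heritability,
                 trait_heritability = trait_heritability,
                 n_causal_probes = n_causal_probes,
                 effect_sizes = effect_sizes,
                 n_replicates = n_replicates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic sub-stream seeds below 2^31
substream_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + stream * 7919L) %% 2147483629L
}

#' Simulate an extended pedigree
#'
#' Founders are paired within each family; every mating produces
#' `sibs_per_mating` offspring. From the third generation on, each offspring
#' of the previous generation mates with a newly introduced married-in
#' founder, so the pedigree realizes the standard 2*phi values
#' (1, 0.5, 0.25, 0.125) for self, first-, second- and third-degree
#' relatives. The final generation is left unmated. Offspring sex is
#' Bernoulli(0.5); married-in spouses take the opposite sex.
#'
#' @param config a [sim_config].
#' @return a [pedigree].
#' @export
simulate_pedigree <- function(config) {
  set.seed(substream_seed(config$seed, 1L))
  fam <- chr_id <- fa <- mo <- sx <- character(0)
  sex <- integer(0)
  rows <- list()
  add <- function(f, id, father, mother, s)
    rows[[length(rows) + 1L]] <<- c(f, id, father, mother, s)
  for (f in seq_len(config$n_families)) {
    fid <- sprintf("F%02d", f)
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("%s_I%03d", fid, counter)
    }
    founders <- character(config$founders_per_family)
    for (i in seq_len(config$founders_per_family)) {
      founders[i] <- new_id()
      add(fid, founders[i], "0", "0", if (i %% 2 == 1) 1L else 2L)
    }
    # pair consecutive founders into matings
    n_pairs <- floor(config$founders_per_family / 2)
    matings <- lapply(seq_len(n_pairs), function(p)
      c(founders[2 * p - 1], founders[2 * p]))
    for (g in seq_len(config$n_generations)) {
      children <- list()
      for (m in matings) {
        father <- m[1]; mother <- m[2]
        for (s in seq_len(config$sibs_per_mating)) {
          id <- new_id()
          child_sex <- if (stats::runif(1) < 0.5) 1L else 2L
          add(fid, id, father, mother, child_sex)
          children[[length(children) + 1L]] <- c(id, child_sex)
        }
      }
      if (g == config$n_generations) break
      # each child marries a new founder for the next generation
      matings <- lapply(children, function(ch) {
        spouse <- new_id()
        sp_sex <- if (ch[2] == "1") 2L else 1L
        add(fid, spouse, "0", "0", sp_sex)
        if (ch[2] == "1") c(ch[1], spouse) else c(spouse, ch[1])
      })
    }
  }
  m <- do.call(rbind, rows)
  pedigree(m[, 1], m[, 2], m[, 3], m[, 4], as.integer(m[, 5]))
}

#' Simulate heritable probe expression on a pedigree
#'
#' Each probe is the sum of an additive-genetic value drawn multivariate
#' normal with covariance `probe_heritability * Phi2` (exact, per pedigree
#' block, not gene-dropping) and independent environmental noise, so the
#' probe variance is approximately 1. By default each probe maps to its own
#' gene; `duplicate_probes > 0` adds that many extra probes duplicating the
#' expression (plus noise) of randomly chosen genes, to exercise
#' representative-probe selection downstream.
#'
#' @param ped a [pedigree].
#' @param config a [sim_config].
#' @param kinship optional precomputed 2*phi matrix for `ped`.
#' @param duplicate_probes number of extra, redundant probes to append.
#' @return an [expression_matrix]; the additive-genetic component of every
#'   probe is kept in attribute `"genetic_values"` (probes x individuals)
#'   for use by [simulate_phenotype].
#' @export
simulate_expression <- function(ped, config, kinship = NULL,
                                duplicate_probes = 0) {
  if (is.null(kinship)) kinship <- compute_kinship(ped)
  ids <- ped$individual_id
  if (!identical(rownames(kinship), ids))
    stop("kinship matrix does not match the pedigree")
  set.seed(substream_seed(config$seed, 2L))
  n <- length(ids)
  p <- config$n_probes
  h2 <- config$probe_heritability
  ek <- eigen(unclass(kinship), symmetric = TRUE)
  L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)), n)
  G <- matrix(stats::rnorm(p * n), p, n) %*% t(L) * sqrt(h2)
  E <- G + matrix(stats::rnorm(p * n), p, n) * sqrt(1 - h2)
  probe_ids <- sprintf("P%05d", seq_len(p))
  gene_ids <- sprintf("G%05d", seq_len(p))
  p2g <- stats::setNames(gene_ids, probe_ids)
  if (duplicate_probes > 0) {
    src <- sample.int(p, duplicate_probes, replace = TRUE)
    dup <- E[src, , drop = FALSE] +
      matrix(stats::rnorm(duplicate_probes * n, sd = 0.1), duplicate_probes, n)
    dup_ids <- sprintf("P%05dd", seq_len(duplicate_probes))
    E <- rbind(E, dup)
    probe_ids <- c(probe_ids, dup_ids)
    p2g <- c(p2g, stats::setNames(gene_ids[src], dup_ids))
    G <- rbind(G, G[src, , drop = FALSE])
  }
  dimnames(E) <- list(probe_ids, ids)
  out <- expression_matrix(E, probe_ids, ids, p2g)
  dimnames(G) <- dimnames(E)
  attr(out, "genetic_values") <- G
  out
}

#' Simulate replicate phenotypes with known heritability
#'
#' The phenotype is built from three parts: a causal-transcript term (the
#' chosen effect sizes applied to the causal probes' additive-genetic
#' values, not their noisy observed expression), a residual polygenic term
#' drawn with covariance `Phi2`, and independent environmental noise. The
#' residual polygenic variance is sized so the total additive fraction of
#' the unit phenotypic variance equals `trait_heritability`; if the causal
#' term alone exceeds that target, the effects are rescaled down with a
#' warning. The causal genetic values are fixed across replicates (the
#' expression data is one realized study), while polygenic and environmental
#' draws are fresh per replicate. With `trait_heritability = 0` the
#' phenotype is pure independent noise.
#'
#' @param ped a [pedigree].
#' @param expr the [expression_matrix] from [simulate_expression] (must
#'   carry the `"genetic_values"` attribute).
#' @param config a [sim_config].
#' @param kinship optional precomputed 2*phi matrix.
#' @return list with `phenotypes` (n_replicates x N matrix, columns in
#'   pedigree order), `causal_probe_ids`, and `covariates` (data.frame of
#'   `individual_id`, `sex` (1/2), `age` drawn uniform 20-80).
#' @export
simulate_phenotype <- function(ped, expr, config, kinship = NULL) {
  if (is.null(kinship)) kinship <- compute_kinship(ped)
  ids <- ped$individual_id
  n <- length(ids)
  h2 <- config$trait_heritability
  set.seed(substream_seed(config$seed, 3L))
  nc <- config$n_causal_probes
  eff <- config$effect_sizes
  if (length(eff) != nc) stop("effect_sizes must have length n_causal_probes")
  G <- attr(expr, "genetic_values")
  causal <- character(0)
  c_term <- numeric(n)
  v_c <- 0
  if (nc > 0) {
    if (is.null(G)) stop("expression matrix lacks genetic values; use simulate_expression()")
    base <- expr$probe_ids[seq_len(min(nc, length(expr$probe_ids)))]
    causal <- base
    v_c <- config$probe_heritability * sum(eff^2)
    if (v_c > h2 && v_c > 0) {
      warning("causal variance exceeds trait heritability; effects rescaled")
      eff <- eff * sqrt(h2 / v_c)
      v_c <- h2
    }
    c_term <- drop(crossprod(G[causal, ids, drop = FALSE], eff))
  }
  sig2_poly <- max(0, h2 - v_c)
  sig2_e <- 1 - h2
  ek <- eigen(unclass(kinship), symmetric = TRUE)
  L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)), n)
  R <- config$n_replicates
  Y <- matrix(0, R, n, dimnames = list(paste0("rep", seq_len(R)), ids))
  for (r in seq_len(R)) {
    a <- if (sig2_poly > 0) drop(L %*% stats::rnorm(n)) * sqrt(sig2_poly) else 0
    e <- stats::rnorm(n, sd = sqrt(sig2_e))
    Y[r, ] <- c_term + a + e
  }
  set.seed(substream_seed(config$seed, 4L))
  covariates <- data.frame(
    individual_id = ids,
    sex = ped$sex,
    age = stats::runif(n, 20, 80),
    stringsAsFactors = FALSE)
  list(phenotypes = Y, causal_probe_ids = causal, covariates = covariates)
}

#' Simulate a complete family expression study
#'
#' Convenience wrapper running [simulate_pedigree], [compute_kinship],
#' [simulate_expression] and [simulate_phenotype] under one configuration.
#'
#' @param config a [sim_config].
#' @param duplicate_probes passed to [simulate_expression].
#' @return list with `pedigree`, `kinship`, `expression`, `phenotypes`,
#'   `causal_probe_ids`, `covariates`, `config`.
#' @export
simulate_study <- function(config, duplicate_probes = 0) {
  ped <- simulate_pedigree(config)
  kin <- compute_kinship(ped)
  expr <- simulate_expression(ped, config, kinship = kin,
                              duplicate_probes = duplicate_probes)
  ph <- simulate_phenotype(ped, expr, config, kinship = kin)
  c(list(pedigree = ped, kinship = kin, expression = expr, config = config),
    ph)
}

#' Positive-control pathways from association-count deciles
#'
#' Ranks probes in descending order of how many replicate phenotypes each
#' probe was associated with and splits them into `n_deciles` near-equal
#' bins; bin 1 holds the most-associated probes. Ties in the counts break by
#' ascending probe id. Returned gene sets use the probes' gene ids.
#'
#' @param assoc_counts named integer vector: per-probe association counts.
#' @param n_deciles number of bins.
#' @param probe_to_gene optional named map probe id -> gene id; defaults to
#'   the probe ids themselves.
#' @return named list (`decile_1` ... ) of character vectors of gene ids.
#' @export
build_decile_pathways <- function(assoc_counts, n_deciles = 10,
                                  probe_to_gene = NULL) {
  if (any(assoc_counts < 0)) stop("association counts must be >= 0")
  p <- length(assoc_counts)
  if (p < n_deciles) stop("fewer probes (", p, ") than deciles (", n_deciles, ")")
  ids <- names(assoc_counts)
  if (is.null(ids)) stop("assoc_counts must be named by probe id")
  ord <- ids[order(-assoc_counts, ids)]
  sizes <- rep(p %/% n_deciles, n_deciles)
  extra <- p %% n_deciles
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  if (is.null(probe_to_gene)) probe_to_gene <- stats::setNames(ids, ids)
  out <- vector("list", n_deciles)
  at <- 1L
  for (d in seq_len(n_deciles)) {
    probes <- ord[at:(at + sizes[d] - 1L)]
    out[[d]] <- unname(probe_to_gene[probes])
    at <- at + sizes[d]
  }
  names(out) <- paste0("decile_", seq_len(n_deciles))
  out
}

#' Write a simulated study to disk
#'
#' Emits the standard plain-text artifacts: ped file, expression +
#' annotation TSV, phenotype TSV (replicates x individuals), covariates
#' TSV, and optionally gene sets as GMT.
#'
#' @param study result of [simulate_study].
#' @param dir output directory (created if needed).
#' @param pathways optional named list of gene-id vectors written as GMT.
#' @export
write_study <- function(study, dir, pathways = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ped(study$pedigree, file.path(dir, "pedigree.ped"))
  write_expression_tsv(study$expression, file.path(dir, "expression.tsv"),
                       file.path(dir, "annotation.tsv"))
  ph <- data.frame(replicate = rownames(study$phenotypes),
                   as.data.frame(study$phenotypes, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(ph, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pathways))
    write_gmt(pathways, file.path(dir, "pathways.gmt"))
  invisible(dir)
}
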