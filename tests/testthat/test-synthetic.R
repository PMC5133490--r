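test_that("simulate_pedigree builds the advertised family structure", {
  # 1 family, 2 founders, 1 offspring generation, 2 sibs: 4 individuals
  cfg <- sim_config(n_families = 1, founders_per_family = 2,
                    n_generations = 1, sibs_per_mating = 2, n_probes = 1,
                    n_replicates = 1, seed = 2)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 4)
  expect_equal(sum(ped$father_id == "0" & ped$mother_id == "0"), 2)
  # every non-founder has a male father and female mother
  nf <- ped[ped$father_id != "0", ]
  sex_of <- setNames(ped$sex, ped$individual_id)
  expect_true(all(sex_of[nf$father_id] == 1))
  expect_true(all(sex_of[nf$mother_id] == 2))
  # determinism under a fixed seed
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))

  # families are disjoint: kinship is block-diagonal with one block per family
  cfg20 <- sim_config(n_families = 20, n_generations = 2, sibs_per_mating = 2,
                      n_probes = 1, n_replicates = 1, seed = 3)
  ped20 <- simulate_pedigree(cfg20)
  k <- compute_kinship(ped20)
  g <- igraph::graph_from_adjacency_matrix(unclass(k) > 0, mode = "undirected")
  expect_equal(igraph::components(g)$no, 20)
})

test_that("simulated expression carries the requested familial correlation", {
  # heritability 0: sib pairs are uncorrelated on average
  cfg0 <- sim_config(n_families = 8, n_generations = 1, sibs_per_mating = 3,
                     n_probes = 400, probe_heritability = 0,
                     n_replicates = 1, seed = 7)
  st0 <- simulate_study(cfg0)
  k <- unclass(st0$kinship)
  sibs <- which(k == 0.5 & upper.tri(k), arr.ind = TRUE)
  E <- st0$expression$values
  r0 <- mean(vapply(seq_len(nrow(sibs)), function(i)
    cor(E[, sibs[i, 1]], E[, sibs[i, 2]]), numeric(1)))
  expect_lt(abs(r0), 0.05)

  # heritability 0.8: regressing pairwise probe covariance on 2phi
  # recovers slope ~ sigma2_g = 0.8 (profile variance ~ 1)
  cfg8 <- sim_config(n_families = 8, n_generations = 2, sibs_per_mating = 2,
                     n_probes = 2500, probe_heritability = 0.8,
                     n_replicates = 1, seed = 8)
  st8 <- simulate_study(cfg8)
  k8 <- unclass(st8$kinship)
  E8 <- st8$expression$values
  up <- which(upper.tri(k8), arr.ind = TRUE)
  keep <- sample(nrow(up), min(4000, nrow(up)))
  Ec <- E8 - rowMeans(E8)
  covs <- vapply(keep, function(i)
    mean(Ec[, up[i, 1]] * Ec[, up[i, 2]]), numeric(1))
  slope <- coef(lm(covs ~ k8[up[keep, , drop = FALSE]]))[2]
  expect_lt(abs(slope - 0.8), 0.05 * 2)  # slope on 2phi; +/- 0.1 at this size
  # half the slope is the covariance increment per 0.5 of relatedness (~0.4)
  expect_lt(abs(slope / 2 - 0.4), 0.05)

  # fixed-seed reproducibility
  st8b <- simulate_expression(st8$pedigree, cfg8, kinship = st8$kinship)
  expect_identical(st8b$values, st8$expression$values)
})

test_that("null phenotypes are noise and causal effects stay heritability-bounded", {
  # trait_heritability = 0: phenotype uncorrelated with kinship structure
  st <- small_study(seed = 51, trait_h2 = 0, n_replicates = 6)
  expect_equal(length(st$causal_probe_ids), 0)
  K <- unclass(st$kinship)
  h2 <- vapply(1:6, function(r)
    fit_ml(mixed_model_spec(st$phenotypes[r, ], kernels = list(kin = K)))$h2,
    numeric(1))
  expect_lt(median(h2), 0.1)

  # zero effects with positive heritability: heritable but causal-free
  cfgz <- sim_config(n_families = 6, n_generations = 2, sibs_per_mating = 2,
                     n_probes = 10, trait_heritability = 0.33,
                     n_causal_probes = 3, effect_sizes = c(0, 0, 0),
                     n_replicates = 50, seed = 52)
  stz <- simulate_study(cfgz)
  G <- attr(stz$expression, "genetic_values")
  # per-replicate correlations with the causal probe average out to ~0
  # (each is noisy at the effective family-level sample size)
  r <- cor(t(stz$phenotypes), G[stz$causal_probe_ids[1], ])
  expect_lt(abs(mean(r)), 0.1)
  # ...but the trait is still heritable via the residual polygenic term
  Kz <- unclass(stz$kinship)
  h2z <- vapply(1:8, function(i)
    fit_ml(mixed_model_spec(stz$phenotypes[i, ], kernels = list(kin = Kz)))$h2,
    numeric(1))
  expect_gt(mean(h2z), 0.1)

  # oversized effects are rescaled down to the heritability budget
  cfgo <- sim_config(n_families = 2, n_generations = 1, sibs_per_mating = 2,
                     n_probes = 4, trait_heritability = 0.2,
                     n_causal_probes = 2, effect_sizes = c(2, 2),
                     n_replicates = 1, seed = 53)
  ped <- simulate_pedigree(cfgo)
  expr <- simulate_expression(ped, cfgo)
  expect_warning(simulate_phenotype(ped, expr, cfgo), "rescaled")
})

test_that("phenotype matrices align with the pedigree and are reproducible", {
  st <- small_study(seed = 54, trait_h2 = 0.33, n_replicates = 4)
  expect_equal(colnames(st$phenotypes), st$pedigree$individual_id)
  expect_equal(nrow(st$phenotypes), 4)
  expect_equal(st$covariates$individual_id, st$pedigree$individual_id)
  expect_true(all(st$covariates$age >= 20 & st$covariates$age <= 80))
  expect_true(all(st$covariates$sex %in% 1:2))
  st2 <- simulate_study(st$config)
  expect_identical(st2$phenotypes, st$phenotypes)
})

test_that("decile pathways partition probes by association count", {
  # 10 probes with distinct counts: singleton bins in descending count order
  counts <- setNames(10:1, paste0("P", 1:10))
  d <- build_decile_pathways(counts, 10)
  expect_equal(lengths(d), setNames(rep(1L, 10), paste0("decile_", 1:10)))
  expect_equal(d$decile_1, "P1")
  expect_equal(d$decile_10, "P10")

  # 277 probes in 10 bins: sizes differ by at most 1 and sum to 277
  set.seed(55)
  c277 <- setNames(rpois(277, 20), sprintf("P%03d", 1:277))
  d277 <- build_decile_pathways(c277, 10)
  expect_equal(sum(lengths(d277)), 277)
  expect_lte(diff(range(lengths(d277))), 1)

  # ties break by ascending probe id
  tied <- setNames(c(5, 5, 5, 1), c("Pb", "Pa", "Pc", "Pd"))
  dt <- build_decile_pathways(tied, 2)
  expect_equal(dt$decile_1, c("Pa", "Pb"))
  expect_equal(dt$decile_2, c("Pc", "Pd"))

  expect_error(build_decile_pathways(setNames(1:3, c("a", "b", "c")), 5),
               "fewer probes")
})

test_that("write_study emits the full set of plain-text artifacts", {
  st <- small_study(seed = 56, n_probes = 6, n_replicates = 2)
  dir <- withr::local_tempdir()
  pw <- list(setA = unname(st$expression$probe_to_gene[1:3]))
  write_study(st, dir, pathways = pw)
  expect_true(all(file.exists(file.path(dir,
    c("pedigree.ped", "expression.tsv", "annotation.tsv",
      "phenotypes.tsv", "covariates.tsv", "pathways.gmt")))))
  ped <- read_ped(file.path(dir, "pedigree.ped"))
  expect_equal(nrow(ped), nrow(st$pedigree))
  gmt <- load_gmt(file.path(dir, "pathways.gmt"))
  expect_equal(gmt$setA, pw$setA)
})
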