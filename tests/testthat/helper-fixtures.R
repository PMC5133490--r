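# Small pedigrees and study fixtures built in code.

# trio: two founders and one child
trio_ped <- function() {
  pedigree(family_id = c("F1", "F1", "F1"),
           individual_id = c("dad", "mom", "kid"),
           father_id = c("0", "0", "dad"),
           mother_id = c("0", "0", "mom"),
           sex = c(1, 2, 1))
}

# three generations: grandparents, two full sibs + spouses, first cousins,
# plus a half-sib and an inbred child of the full sibs
bench_ped <- function(inbred = FALSE, half_sib = FALSE) {
  fam <- data.frame(
    id = c("gp1", "gp2", "s1", "s2", "sp1", "sp2", "c1", "c2"),
    fa = c("0", "0", "gp1", "gp1", "0", "0", "s1", "s2"),
    mo = c("0", "0", "gp2", "gp2", "0", "0", "sp1", "sp2"),
    sex = c(1, 2, 1, 2, 2, 1, 1, 2),
    stringsAsFactors = FALSE)
  if (half_sib)
    fam <- rbind(fam, data.frame(id = "h1", fa = "gp1", mo = "sp1", sex = 1))
  if (inbred)
    fam <- rbind(fam, data.frame(id = "ib", fa = "s1", mo = "s2", sex = 2))
  pedigree("F1", fam$id, fam$fa, fam$mo, fam$sex)
}

# small, fast study: 6 families of 9 (n = 54)
small_study <- function(seed = 5, n_probes = 12, trait_h2 = 0,
                        n_causal = 0, effects = numeric(0),
                        n_replicates = 3, sibs = 2) {
  cfg <- sim_config(n_families = 6, founders_per_family = 2,
                    n_generations = 2, sibs_per_mating = sibs,
                    n_probes = n_probes, probe_heritability = 0.5,
                    trait_heritability = trait_h2,
                    n_causal_probes = n_causal, effect_sizes = effects,
                    n_replicates = n_replicates, seed = seed)
  simulate_study(cfg)
}

random_profiles <- function(n = 5, p = 4, seed = 42) {
  set.seed(seed)
  X <- matrix(stats::runif(n * p), n, p)
  rownames(X) <- paste0("ind", seq_len(n))
  X
}
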