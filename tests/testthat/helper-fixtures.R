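# Shared in-code fixtures: tiny populations built by hand plus small
# simulated data sets.

# 3 lines, 2 families, 2 markers; minimal valid population.
toy_pop <- function() {
  map <- genetic_map(c("m1", "m2"), 1, c(0, 10))
  g <- matrix(c(-1, 1, -1,
                 1, 1, -1), nrow = 3,
              dimnames = list(c("l1", "l2", "l3"), c("m1", "m2")))
  nam_population(g, c("f1", "f1", "f2"), map)
}

# Write a population + phenotype to CSVs in a temp dir; returns paths.
toy_files <- function(pop = toy_pop(), y = c(1, 2, 3),
                      dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_population(pop, y, dir)
}

# One-family-at-a-time population with identical genotype structure in all
# families (used to check the recoding collapses to the raw biallelic code).
mirrored_pop <- function(n_per = 20, k = 2, seed = 1) {
  set.seed(seed)
  map <- genetic_map("m1", 1, 0)
  g_one <- sample(c(-1, 1), n_per, replace = TRUE)
  g <- matrix(rep(g_one, k), ncol = 1,
              dimnames = list(NULL, "m1"))
  nam_population(g, rep(paste0("f", seq_len(k)), each = n_per), map)
}

# Small simulated data set with a single strong QTL.
single_qtl_sim <- function(seed = 1, n_per = 80, k = 3, m = 21,
                           qtl = as.integer(ceiling(m / 2)), h2 = 0.3) {
  design <- nam_sim_design(scenario = "heritability", k = k,
                           n_per_subpop = n_per, n_markers = m,
                           length_cM = 100, n_qtl = 1, qtl_markers = qtl,
                           h2 = h2)
  simulate_nam(design, seed = seed)
}
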