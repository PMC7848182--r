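test_that("RIL genotypes follow the Haldane/RIL recombination model", {
  # tightly linked markers are (almost surely) identical
  map0 <- genetic_map(c("a", "b"), 1, c(0, 1e-9))
  G0 <- simulate_ril_genotypes(map0, 500, seed = 1)
  expect_identical(G0[, 1], G0[, 2])

  # empirical recombinant fraction matches R = 2r/(1+2r) within binomial error
  d <- 20
  map1 <- genetic_map(c("a", "b"), 1, c(0, d))
  n <- 20000
  G1 <- simulate_ril_genotypes(map1, n, seed = 2)
  r <- (1 - exp(-2 * d / 100)) / 2
  R <- 2 * r / (1 + 2 * r)
  obs <- mean(G1[, 1] != G1[, 2])
  expect_lt(abs(obs - R), 4 * sqrt(R * (1 - R) / n))

  # distant markers decorrelate
  map2 <- genetic_map(c("a", "b"), 1, c(0, 1e4))
  G2 <- simulate_ril_genotypes(map2, 5000, seed = 3)
  expect_lt(abs(cor(G2[, 1], G2[, 2])), 0.05)

  # allele frequency 1/2 at every marker
  G3 <- simulate_ril_genotypes(uniform_map(5, 40), 10000, seed = 4)
  freq <- colMeans(G3 == 1)
  expect_true(all(abs(freq - 0.5) < 0.02))
})

test_that("fixed effects hit the target additive variance and sum to zero", {
  # h2 = 0.05 each of 10 QTLs, sigma2_e = 1: sigma2_ai = 0.05/0.5 = 0.1
  alpha <- fixed_effects_from_heritability(rep(0.05, 10), k = 5, seed = 1)
  expect_equal(rowSums(alpha), rep(0, 10))                  # machine precision
  expect_equal(unname(rowMeans(alpha^2)), rep(0.1, 10))
  # zero-heritability QTL contributes nothing
  a0 <- fixed_effects_from_heritability(c(0, 0.1), k = 4, seed = 2)
  expect_equal(a0[1, ], rep(0, 4))
  # infeasible heritabilities rejected
  expect_error(fixed_effects_from_heritability(rep(0.2, 6), k = 5),
               "infeasible")

  # Monte-Carlo check on an effectively unlinked map: realised genetic
  # variance matches the target sum of per-QTL variances within 5%
  map <- genetic_map(paste0("q", 1:10), 1, seq(0, 9e4, length.out = 10))
  G <- simulate_ril_genotypes(map, 10000, seed = 5)
  al <- fixed_effects_from_heritability(rep(0.03, 10), k = 5, seed = 6)
  subpop <- factor(rep(paste0("P", 1:5), each = 2000))
  sim <- simulate_phenotypes(G, subpop, al, 1:10, sigma2_e = 1, seed = 7)
  target <- sum(rep(0.03, 10)) / (1 - 0.3)
  expect_lt(abs(var(sim$a) - target) / target, 0.05)
})

test_that("random effects recover the rho-power covariance", {
  al <- random_effects(5, rho = 0.8, seed = 8, n_fixed = 0, n_random = 10000)
  expect_lt(abs(cor(al[, 1], al[, 2]) - 0.8), 0.05)
  expect_lt(abs(cor(al[, 2], al[, 3]) - 0.8), 0.05)
  expect_lt(abs(cor(al[, 1], al[, 3]) - 0.64), 0.05)
  expect_equal(mean(al), 1.5, tolerance = 0.05)
  al0 <- random_effects(5, rho = 0, seed = 9, n_fixed = 0, n_random = 10000)
  expect_lt(abs(cor(al0[, 1], al0[, 2])), 0.05)
  # the power-banded covariance is symmetric positive definite
  for (rho in c(0.2, 0.8)) {
    S <- rho^abs(outer(1:5, 1:5, "-"))
    expect_true(isSymmetric(S))
    expect_true(all(eigen(S, only.values = TRUE)$values > 0))
  }
  # fixed block is constant at the common effect
  alf <- random_effects(5, rho = 0.2, seed = 10)
  expect_true(all(alf[1:5, ] == 1.5))
})

test_that("phenotype simulation is exact in degenerate cases and seeded", {
  map <- uniform_map(4, 30)
  G <- simulate_ril_genotypes(map, 40, seed = 11)
  subpop <- factor(rep(c("a", "b"), each = 20))
  z <- simulate_phenotypes(G, subpop, matrix(0, 2, 2), c(1, 3),
                           sigma2_e = 0, seed = 12)
  expect_equal(z$y, rep(0, 40))
  y1 <- simulate_phenotypes(G, subpop, matrix(1, 2, 2), c(1, 3),
                            sigma2_e = 1, seed = 13)$y
  y2 <- simulate_phenotypes(G, subpop, matrix(1, 2, 2), c(1, 3),
                            sigma2_e = 1, seed = 13)$y
  expect_identical(y1, y2)
})

test_that("whole replicates are bit-reproducible and hit target heritability", {
  d <- nam_sim_design(scenario = "heritability", k = 5, n_per_subpop = 1000,
                      n_markers = 10, length_cM = 9e4, n_qtl = 10,
                      qtl_markers = 1:10, h2 = 0.03)
  s1 <- simulate_nam(d, seed = 99)
  s2 <- simulate_nam(d, seed = 99)
  expect_identical(s1$pop$genotypes, s2$pop$genotypes)
  expect_identical(s1$y, s2$y)
  # broad-sense h2 near the target 0.3 at n = 5000 on an unlinked map
  # (with tight linkage, LD covariance makes the realised value wobble)
  expect_lt(abs(s1$truth$realized_h2 - 0.3), 0.03)

  # random-effect scenario: residual calibrated from the analytic additive
  # variance (LD covariance between linked QTLs not counted)
  dr <- nam_sim_design(scenario = "random_effect", rho = 0.2)
  sr <- simulate_nam(dr, seed = 100)
  s2a <- sum(rowMeans(sr$truth$alpha^2))
  expect_equal(sr$truth$sigma2_e, s2a * (1 - 0.6) / 0.6)
  expect_equal(dim(sr$truth$alpha), c(10L, 5L))
  expect_true(all(sr$truth$alpha[1:5, ] == 1.5))

  # population sizes split evenly: 964 into 5 families
  expect_equal(as.numeric(table(s1$pop$subpop)), rep(1000, 5))
  d964 <- nam_sim_design(scenario = "heritability", h2 = 0.05)
  s964 <- simulate_nam(d964, seed = 101)
  sizes <- as.numeric(table(s964$pop$subpop))
  expect_equal(sum(sizes), 964)
  expect_lte(diff(range(sizes)), 1)
})

test_that("replicates round-trip through the CSV layout with truth", {
  d <- nam_sim_design(scenario = "heritability", k = 2, n_per_subpop = 10,
                      n_markers = 6, length_cM = 50, n_qtl = 2,
                      qtl_markers = c(2L, 5L), h2 = 0.1)
  sim <- simulate_nam(d, seed = 42)
  dir <- withr::local_tempdir()
  paths <- write_replicate(sim, dir)
  expect_true(all(file.exists(paths)))
  tr <- read_truth(paths["truth"])
  expect_equal(tr$qtl_index, sim$truth$qtl_index)
  expect_equal(tr$position_cM, sim$truth$position_cM)
  expect_equal(unname(tr$alpha), unname(sim$truth$alpha))
})
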