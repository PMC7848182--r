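test_that("omega profile equals class mean minus grand mean", {
  # one family polymorphic, hand-computable: grand mean 1
  map <- genetic_map("m1", 1, 0)
  g <- matrix(c(-1, -1, 1, 1, -1, 1), ncol = 1, dimnames = list(NULL, "m1"))
  pop <- nam_population(g, c("a", "a", "a", "a", "b", "b"), map)
  y <- c(0, 0, 2, 2, 1, 1)
  prof <- omega_profile(pop, y, 1)
  expect_equal(prof$omega[prof$subpop == "a" & prof$genotype == -1], -1)
  expect_equal(prof$omega[prof$subpop == "a" & prof$genotype == 1], 1)
  expect_equal(prof$omega[prof$subpop == "b"], c(0, 0))
  expect_equal(prof$count, c(2L, 2L, 1L, 1L))

  # constant phenotype: all deviations zero
  prof0 <- omega_profile(pop, rep(3.7, 6), 1)
  expect_equal(prof0$omega, rep(0, 4))

  # permuting lines leaves the profile unchanged
  perm <- c(3, 6, 1, 5, 2, 4)
  pop_p <- nam_population(g[perm, , drop = FALSE], c("a", "b", "a", "b", "a", "a")[order(perm)][perm], map)
  pop_p <- nam_population(g[perm, , drop = FALSE],
                          as.character(pop$subpop)[perm], map)
  prof_p <- omega_profile(pop_p, y[perm], 1)
  expect_equal(as.data.frame(prof_p), as.data.frame(prof))

  # an empty class (monomorphic family) is flagged, not an error
  g2 <- matrix(c(-1, 1, 1, 1), ncol = 1, dimnames = list(NULL, "m1"))
  pop2 <- nam_population(g2, c("a", "a", "b", "b"), map)
  prof2 <- omega_profile(pop2, 1:4, 1)
  empty <- prof2$subpop == "b" & prof2$genotype == -1
  expect_equal(prof2$count[empty], 0L)
  expect_true(is.na(prof2$omega[empty]))
})

test_that("rank recoding assigns order-faithful codes", {
  # 2 families, 4 classes, omega spread (-2, -1, 1, 2) by construction
  map <- genetic_map("m1", 1, 0)
  g <- matrix(rep(c(-1, 1), 4), ncol = 1, dimnames = list(NULL, "m1"))
  pop <- nam_population(g, rep(c("a", "b"), each = 4)[c(1, 5, 2, 6, 3, 7, 4, 8)], map)
  pop <- nam_population(matrix(c(-1, -1, 1, 1, -1, -1, 1, 1), ncol = 1,
                               dimnames = list(NULL, "m1")),
                        rep(c("a", "b"), each = 4), map)
  # class means: a/AA=1, a/aa=5, b/AA=2, b/aa=4; grand mean 3
  y <- c(1, 1, 5, 5, 2, 2, 4, 4)
  prof <- omega_profile(pop, y, 1)
  zr <- recode_snp(prof, pop, 1, scheme = "rank")
  tab <- attr(zr, "recode_table")
  expect_equal(tab$omega, c(-2, 2, -1, 1))
  expect_equal(tab$code_raw, c(1, 4, 2, 3))
  expect_false(attr(zr, "degenerate"))
  # column is centered and unit-scaled
  expect_equal(mean(zr), 0)
  expect_equal(stats::sd(zr), 1)
  # codes are monotone in omega for every scheme
  for (sch in c("omega", "rank", "segmented")) {
    z <- recode_snp(prof, pop, 1, scheme = sch, y = y)
    t2 <- attr(z, "recode_table")
    o <- order(t2$omega)
    expect_true(all(diff(t2$code_raw[o]) >= 0))
  }
})

test_that("all-equal omegas give a degenerate constant column", {
  map <- genetic_map("m1", 1, 0)
  pop <- nam_population(matrix(c(-1, 1, -1, 1), ncol = 1,
                               dimnames = list(NULL, "m1")),
                        c("a", "a", "b", "b"), map)
  y <- rep(2, 4)
  prof <- omega_profile(pop, y, 1)
  for (sch in c("omega", "segmented")) {
    z <- recode_snp(prof, pop, 1, scheme = sch, y = y)
    expect_true(attr(z, "degenerate"))
    expect_equal(as.numeric(z), rep(0, 4))
  }
})

test_that("recoding collapses to the biallelic coding when families agree", {
  # same genotype-phenotype structure in both families: the recoded column
  # must equal the centered raw +/-1 coding up to positive scaling
  set.seed(11)
  map <- genetic_map("m1", 1, 0)
  g1 <- sample(c(-1, 1), 40, replace = TRUE)
  g <- matrix(c(g1, g1), ncol = 1, dimnames = list(NULL, "m1"))
  pop <- nam_population(g, rep(c("a", "b"), each = 40), map)
  y <- rep(0.8 * g1, 2) + rnorm(80, sd = 0.1)
  prof <- omega_profile(pop, y, 1)
  raw <- g[, 1] - mean(g[, 1])
  for (sch in c("omega", "segmented")) {
    z <- as.numeric(recode_snp(prof, pop, 1, scheme = sch, y = y))
    expect_gt(abs(cor(z, raw)), 0.99)
  }
  # rank codes force the near-identical AA classes of the two families onto
  # distinct ranks, so the collapse is only approximate under "rank"
  z_rank <- as.numeric(recode_snp(prof, pop, 1, scheme = "rank"))
  expect_gt(abs(cor(z_rank, raw)), 0.85)
})

test_that("build_design excludes degenerate columns but keeps indexing", {
  sim <- single_qtl_sim(seed = 5, n_per = 30, k = 2, m = 10)
  pop <- sim$pop
  # force marker 4 monomorphic across all families
  pop$genotypes[, 4] <- 1
  des <- build_design(pop, sim$y)
  expect_equal(dim(des$Z), c(pop$n_total, 10))
  expect_true(des$degenerate[4])
  expect_equal(sum(des$Z[, 4]), 0)
  expect_equal(length(des$recode_tables), 10)
  # deterministic given the same inputs
  des2 <- build_design(pop, sim$y)
  expect_identical(des$Z, des2$Z)
  # active columns have zero mean
  act <- which(!des$degenerate)
  expect_true(all(abs(colMeans(des$Z[, act])) < 1e-12))
})

test_that("design shape matches the study dimensions", {
  d <- nam_sim_design(scenario = "heritability", h2 = 0.05)
  sim <- simulate_nam(d, seed = 9)
  expect_equal(sim$pop$n_total, 964L)
  expect_equal(sim$pop$k, 5L)
  des <- build_design(sim$pop, sim$y)
  expect_equal(dim(des$Z), c(964L, 100L))
})

test_that("back-transformed effects agree with per-family OLS", {
  sim <- single_qtl_sim(seed = 21, n_per = 400, k = 3, m = 3, qtl = 2L,
                        h2 = 0.25)
  pop <- sim$pop
  y <- sim$y
  des <- build_design(pop, y)
  # fit gamma for the QTL column by OLS given family intercepts
  X <- subpopulation_design(pop)
  W <- cbind(X, des$Z[, 2])
  coefs <- qr.coef(qr(W), y)
  eff <- backtransform_effects(coefs[length(coefs)], des$recode_tables[[2]])
  # oracle: per-family OLS slope on the raw +/-1 coding
  for (j in seq_len(3)) {
    rows <- pop$subpop == levels(pop$subpop)[j]
    ols <- coef(lm(y[rows] ~ pop$genotypes[rows, 2]))[2]
    expect_equal(unname(eff[j]), unname(ols), tolerance = 0.08)
  }
  # gamma of zero back-transforms to all-zero effects
  expect_equal(unname(backtransform_effects(0, des$recode_tables[[2]])),
               rep(0, 3))
})
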