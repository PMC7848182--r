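# Monte-Carlo simulator for half-sib RIL family (NAM) designs: RIL
# genotypes on a genetic map, QTL effect matrices (fixed zero-sum or
# correlated random across families), and phenotypes.

#' Uniformly spaced single-chromosome map
#'
#' @param n_markers number of markers (default 100).
#' @param length_cM chromosome length in cM (default 153.4).
#' @param chromosome chromosome label.
#' @return a [genetic_map()].
#' @export
uniform_map <- function(n_markers = 100, length_cM = 153.4, chromosome = "1") {
  genetic_map(sprintf("m%03d", seq_len(n_markers)), chromosome,
              seq(0, length_cM, length.out = n_markers))
}

#' Simulate RIL genotypes along a map
#'
#' Each RIL is an independent realisation of a biparental cross selfed to
#' fixation: along each chromosome the +/-1 genotype is a two-state Markov
#' chain whose switch probability between adjacent markers is the RIL
#' recombination frequency `R = 2r / (1 + 2r)`, with `r` from Haldane's map
#' function `r = (1 - exp(-2 d / 100)) / 2` for inter-marker distance `d`
#' cM (no interference).  Expected allele frequency is 1/2 at every marker.
#'
#' @param map a [genetic_map()].
#' @param n number of lines.
#' @param seed optional RNG seed.
#' @return n x m matrix of codes in `{-1, +1}`.
#' @export
simulate_ril_genotypes <- function(map, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  G <- matrix(0L, n, m, dimnames = list(NULL, map$marker_id))
  for (chr in unique(map$chromosome)) {
    cols <- which(map$chromosome == chr)
    d <- diff(map$position_cM[cols])
    r <- (1 - exp(-2 * d / 100)) / 2
    R <- 2 * r / (1 + 2 * r)
    g <- sample(c(-1L, 1L), n, replace = TRUE)
    G[, cols[1]] <- g
    for (j in seq_along(d)) {
      flip <- stats::runif(n) < R[j]
      g <- ifelse(flip, -g, g)
      G[, cols[j + 1]] <- g
    }
  }
  G
}

#' Zero-sum fixed QTL effects from per-QTL heritabilities
#'
#' For QTL i with heritability `h2[i]` (share of total phenotypic variance),
#' the target additive variance is `sigma2_ai = h2[i] * sigma2_e /
#' (1 - sum(h2))`.  Family effects follow an equally spaced pattern
#' symmetric about zero (for k = 5, proportional to (-2, -1, 0, 1, 2)),
#' independently permuted across families for each QTL so that the QTLs
#' carry different family profiles, then rescaled so that with genotype
#' variance 1 and equal family sizes the QTL contributes exactly
#' `sigma2_ai`: the scale solves `mean_j(alpha_ij^2) = sigma2_ai`.  Every
#' row sums to zero by construction.
#'
#' @param h2 vector of per-QTL heritabilities, `sum(h2) < 1`.
#' @param k number of families.
#' @param sigma2_e residual variance.
#' @param seed optional RNG seed (drives the per-QTL permutations).
#' @return `length(h2)` x k effect matrix.
#' @export
fixed_effects_from_heritability <- function(h2, k, sigma2_e = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(h2 < 0) || sum(h2) >= 1)
    stop("infeasible heritabilities: need h2 >= 0 and sum(h2) < 1")
  pattern <- seq_len(k) - (k + 1) / 2
  msq <- mean(pattern^2)
  alpha <- matrix(0, length(h2), k)
  for (i in seq_along(h2)) {
    if (h2[i] == 0) next
    s2a <- h2[i] * sigma2_e / (1 - sum(h2))
    alpha[i, ] <- sample(pattern) * sqrt(s2a / msq)
  }
  alpha
}

#' Random QTL effects correlated across neighbouring families
#'
#' The first `n_fixed` QTLs share one fixed effect (`mean`, default 1.5) in
#' every family; each of the remaining `n_random` QTLs draws its k family
#' effects from a multivariate normal with mean `mean` and covariance
#' `Sigma[a, b] = rho^|a - b|` (power-banded: rho is the effect correlation
#' between nearest families).
#'
#' @param k number of families.
#' @param rho nearest-family effect correlation, `|rho| < 1`.
#' @param mean common effect mean.
#' @param n_fixed,n_random number of fixed- and random-effect QTLs.
#' @param seed optional RNG seed.
#' @return `(n_fixed + n_random)` x k effect matrix.
#' @export
random_effects <- function(k, rho, mean = 1.5, n_fixed = 5, n_random = 5,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(rho) < 1)
  Sigma <- rho^abs(outer(seq_len(k), seq_len(k), "-"))
  alpha <- matrix(mean, n_fixed + n_random, k)
  if (n_random > 0)
    alpha[n_fixed + seq_len(n_random), ] <-
      MASS::mvrnorm(n_random, mu = rep(mean, k), Sigma = Sigma)
  alpha
}

#' Simulate phenotypes from genotypes and family-specific QTL effects
#'
#' `y = sum_q G[, qtl_q] * alpha[q, family] + e`, `e ~ N(0, sigma2_e)` iid.
#'
#' @param genotypes n x m genotype matrix.
#' @param subpop family factor, length n.
#' @param alpha n_qtl x k effect matrix (columns in `levels(subpop)` order).
#' @param qtl_markers marker column indices of the QTLs.
#' @param sigma2_e residual variance.
#' @param seed optional RNG seed.
#' @return List: `y` (phenotypes), `a` (breeding values).
#' @export
simulate_phenotypes <- function(genotypes, subpop, alpha, qtl_markers,
                                sigma2_e = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subpop <- factor(subpop)
  stopifnot(ncol(alpha) == nlevels(subpop),
            nrow(alpha) == length(qtl_markers))
  Gq <- genotypes[, qtl_markers, drop = FALSE]
  a <- rowSums(Gq * t(alpha)[as.integer(subpop), , drop = FALSE])
  e <- stats::rnorm(length(a), 0, sqrt(sigma2_e))
  list(y = a + e, a = a)
}

#' Simulation design for the Monte-Carlo scenarios
#'
#' Three scenarios on a 100-marker, 153.4 cM chromosome with 10 QTLs placed
#' on evenly spaced markers:
#' * `"heritability"`: k = 5 families, 964 RILs in total, each QTL
#'   explaining the same share `h2` of phenotypic variance via zero-sum
#'   family-specific fixed effects; residual variance `sigma2_e = 1`.
#' * `"sample_size"`: as above but k families of `n_per_subpop` RILs each
#'   (defaults: 100 per family, per-QTL `h2 = 0.07`).
#' * `"random_effect"`: 5 QTLs with a common fixed effect 1.5 plus 5 QTLs
#'   with MVN(1.5, rho-power covariance) family effects; the residual
#'   variance is set from the analytic additive variance (sum of per-QTL
#'   family-average squared effects) so the nominal total heritability
#'   equals `total_h2` (default 0.6).
#'
#' @param scenario one of `"heritability"`, `"sample_size"`,
#'   `"random_effect"`.
#' @param k number of families.
#' @param n_total total number of RILs (split as evenly as possible);
#'   ignored when `n_per_subpop` is given.
#' @param n_per_subpop RILs per family (vector or scalar), optional.
#' @param n_markers,length_cM map geometry (see [uniform_map()]).
#' @param map explicit [genetic_map()] overriding the geometry.
#' @param n_qtl number of QTLs.
#' @param qtl_markers QTL marker indices; default evenly spaced,
#'   `round((i - 0.5) * m / n_qtl)`.
#' @param h2 per-QTL heritability (scalar or length `n_qtl`), fixed-effect
#'   scenarios.
#' @param sigma2_e residual variance, fixed-effect scenarios.
#' @param rho nearest-family effect correlation, random-effect scenario.
#' @param total_h2 total heritability, random-effect scenario.
#' @param fixed_effect common effect of the fixed QTLs, random-effect
#'   scenario.
#' @return list of class `nam_sim_design`.
#' @export
nam_sim_design <- function(scenario = c("heritability", "sample_size",
                                        "random_effect"),
                           k = 5, n_total = 964, n_per_subpop = NULL,
                           n_markers = 100, length_cM = 153.4, map = NULL,
                           n_qtl = 10, qtl_markers = NULL,
                           h2 = 0.05, sigma2_e = 1,
                           rho = 0.2, total_h2 = 0.6, fixed_effect = 1.5) {
  scenario <- match.arg(scenario)
  if (is.null(map)) map <- uniform_map(n_markers, length_cM)
  m <- nrow(map)
  if (is.null(qtl_markers))
    qtl_markers <- round((seq_len(n_qtl) - 0.5) * m / n_qtl)
  stopifnot(length(qtl_markers) == n_qtl, !anyDuplicated(qtl_markers),
            all(qtl_markers >= 1 & qtl_markers <= m))
  if (scenario == "sample_size" && is.null(n_per_subpop)) n_per_subpop <- 100
  if (is.null(n_per_subpop)) {
    n_per_subpop <- diff(round(seq(0, n_total, length.out = k + 1)))
  } else if (length(n_per_subpop) == 1L) {
    n_per_subpop <- rep(n_per_subpop, k)
  }
  stopifnot(length(n_per_subpop) == k, all(n_per_subpop >= 1))
  if (length(h2) == 1L) h2 <- rep(h2, n_qtl)
  structure(list(scenario = scenario, k = k, n_per_subpop = n_per_subpop,
                 map = map, n_qtl = n_qtl, qtl_markers = qtl_markers,
                 h2 = h2, sigma2_e = sigma2_e, rho = rho,
                 total_h2 = total_h2, fixed_effect = fixed_effect),
            class = "nam_sim_design")
}

#' Simulate one NAM replicate
#'
#' Draws RIL genotypes family by family, an effect matrix per the design's
#' scenario, and phenotypes.  All randomness flows from `seed`, so the
#' output is bit-reproducible from `(design, seed)`.
#'
#' @param design a [nam_sim_design()].
#' @param seed integer RNG seed.
#' @return List: `pop` (a [nam_population()]), `y` (phenotypes), `truth`
#'   (class `sim_truth`: `qtl_index`, `position_cM`, `alpha` n_qtl x k,
#'   `sigma2_e`, `realized_h2`).
#' @export
simulate_nam <- function(design, seed = 1L) {
  stopifnot(inherits(design, "nam_sim_design"))
  set.seed(seed)
  k <- design$k
  fams <- sprintf("P%02d", seq_len(k))
  n <- sum(design$n_per_subpop)
  subpop <- factor(rep(fams, design$n_per_subpop), levels = fams)
  G <- simulate_ril_genotypes(design$map, n)
  rownames(G) <- paste0(as.character(subpop), "_",
                        unlist(lapply(design$n_per_subpop,
                                      function(ni) sprintf("%04d", seq_len(ni)))))
  if (design$scenario == "random_effect") {
    n_fixed <- floor(design$n_qtl / 2)
    alpha <- random_effects(k, design$rho, mean = design$fixed_effect,
                            n_fixed = n_fixed,
                            n_random = design$n_qtl - n_fixed)
    # analytic additive variance: sum over QTLs of the family-average
    # squared effect (genotype variance 1, equal family weights); LD
    # covariance between linked QTLs is deliberately not counted, matching
    # the per-QTL variance accounting of the fixed-effect scenarios
    s2a <- sum(rowMeans(alpha^2))
    sigma2_e <- s2a * (1 - design$total_h2) / design$total_h2
  } else {
    alpha <- fixed_effects_from_heritability(design$h2, k, design$sigma2_e)
    sigma2_e <- design$sigma2_e
  }
  sim <- simulate_phenotypes(G, subpop, alpha, design$qtl_markers, sigma2_e)
  pop <- nam_population(G, subpop, design$map)
  truth <- structure(list(qtl_index = design$qtl_markers,
                          position_cM = design$map$position_cM[design$qtl_markers],
                          alpha = alpha, sigma2_e = sigma2_e,
                          realized_h2 = stats::var(sim$a) /
                            stats::var(sim$y)),
                     class = "sim_truth")
  list(pop = pop, y = sim$y, truth = truth)
}

#' Write one simulated replicate to a directory
#'
#' Writes `genotypes.csv`, `map.csv`, `phenotypes.csv` (see
#' [read_population()]) and `truth.csv` (QTL marker, position, one effect
#' column per family).
#'
#' @param sim a [simulate_nam()] result.
#' @param dir output directory.
#' @return Invisibly, the file paths.
#' @export
write_replicate <- function(sim, dir) {
  paths <- write_population(sim$pop, sim$y, dir)
  tr <- data.frame(qtl_index = sim$truth$qtl_index,
                   position_cM = sim$truth$position_cM)
  eff <- as.data.frame(sim$truth$alpha)
  names(eff) <- paste0("effect_", levels(sim$pop$subpop))
  tpath <- file.path(dir, "truth.csv")
  utils::write.csv(cbind(tr, eff), tpath, row.names = FALSE, quote = FALSE)
  invisible(c(paths, truth = tpath))
}

#' Read a truth table written by [write_replicate()]
#'
#' @param path path to `truth.csv`.
#' @return object of class `sim_truth`.
#' @export
read_truth <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  eff_cols <- grep("^effect_", names(tr))
  structure(list(qtl_index = tr$qtl_index, position_cM = tr$position_cM,
                 alpha = as.matrix(tr[, eff_cols, drop = FALSE]),
                 sigma2_e = NA_real_, realized_h2 = NA_real_),
            class = "sim_truth")
}
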