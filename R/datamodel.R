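#' nammap: multi-locus QTL mapping for NAM populations
#'
#' Joint multi-family association mapping for nested association mapping
#' (NAM) populations of recombinant inbred lines (RILs).  A NAM design
#' crosses k founder lines to one common parent; each cross is selfed into a
#' half-sib RIL family ("subpopulation").  The same locus may carry a
#' different additive effect in every family (genetic heterogeneity), so the
#' per-family model has k effect columns per SNP.  `nammap` collapses those
#' k columns into a single recoded incidence vector per SNP (see
#' [build_design()]), fits all SNPs jointly with an empirical-Bayes EM
#' shrinkage estimator ([ebayes_fit()]), and validates surviving effects
#' with likelihood-ratio tests on a maximum-likelihood refit
#' ([nam_scan()]).  A RIL simulator ([simulate_nam()]) and an evaluation
#' layer ([run_power_study()]) support power / false-positive-rate studies.
#'
#' @docType package
#' @name nammap-package
#' @aliases nammap
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Core types: genetic map, NAM population, phenotype vector
# ---------------------------------------------------------------------------

#' Construct and validate a genetic map
#'
#' A genetic map is a data frame with one row per marker: marker identifier,
#' chromosome, and position in centiMorgans.  Positions must be strictly
#' increasing within a chromosome and marker ids unique.
#'
#' @param marker_id character vector of unique marker names.
#' @param chromosome chromosome label per marker (character or integer).
#' @param position_cM non-negative numeric map position in cM.
#' @return A `data.frame` of class `genetic_map` with columns
#'   `marker_id`, `chromosome`, `position_cM`.
#' @examples
#' genetic_map(paste0("m", 1:3), 1, c(0, 1.5, 3))
#' @export
genetic_map <- function(marker_id, chromosome, position_cM) {
  marker_id <- as.character(marker_id)
  chromosome <- as.character(chromosome)
  position_cM <- as.numeric(position_cM)
  if (length(marker_id) != length(position_cM) ||
      (length(chromosome) != 1L && length(chromosome) != length(marker_id)))
    stop("map error: marker_id, chromosome and position_cM lengths differ")
  if (length(chromosome) == 1L)
    chromosome <- rep(chromosome, length(marker_id))
  map <- data.frame(marker_id = marker_id, chromosome = chromosome,
                    position_cM = position_cM, stringsAsFactors = FALSE)
  validate_genetic_map(map)
}

#' @rdname genetic_map
#' @param map a data frame with the three map columns.
#' @export
validate_genetic_map <- function(map) {
  need <- c("marker_id", "chromosome", "position_cM")
  if (!all(need %in% names(map)))
    stop("map error: missing columns ", paste(setdiff(need, names(map)), collapse = ", "))
  if (anyDuplicated(map$marker_id))
    stop("map error: duplicated marker ids")
  if (any(!is.finite(map$position_cM)) || any(map$position_cM < 0))
    stop("map error: positions must be finite and non-negative")
  for (chr in unique(map$chromosome)) {
    p <- map$position_cM[map$chromosome == chr]
    if (any(diff(p) <= 0))
      stop("map error: positions not strictly increasing on chromosome ", chr)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Construct a NAM population object
#'
#' Bundles the RIL genotype matrix, the subpopulation (family) membership and
#' the genetic map.  Genotypes are coded -1 for the common-parent (e.g. B73)
#' allele homozygote and +1 for the founder-allele homozygote; residual
#' heterozygotes in RILs are treated as missing (`NA`).  Missing codes are
#' mean-imputed per family and marker at model-fitting time, which preserves
#' the within-family allele frequency.
#'
#' @param genotypes numeric matrix, lines x markers, values in `{-1, 1, NA}`;
#'   rownames are line ids.
#' @param subpop vector of family labels, one per line (coerced to factor).
#' @param map a [genetic_map()] with one row per genotype column.
#' @return An object of class `nam_population`: a list with elements
#'   `genotypes`, `subpop` (factor), `map`, `n_total`, `k`, `m`.
#' @examples
#' map <- genetic_map(c("m1", "m2"), 1, c(0, 10))
#' g <- matrix(c(-1, 1, -1, 1, 1, -1), nrow = 3,
#'             dimnames = list(c("l1", "l2", "l3"), c("m1", "m2")))
#' nam_population(g, c("f1", "f1", "f2"), map)
#' @export
nam_population <- function(genotypes, subpop, map) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  map <- validate_genetic_map(map)
  if (ncol(genotypes) != nrow(map))
    stop("format error: genotype columns (", ncol(genotypes),
         ") do not match map markers (", nrow(map), ")")
  if (nrow(genotypes) != length(subpop))
    stop("alignment error: genotype rows do not match subpop labels")
  bad <- !(genotypes %in% c(-1, 1) | is.na(genotypes))
  if (any(bad))
    stop("format error: genotype codes outside {-1, 1, NA}: found ",
         paste(utils::head(unique(genotypes[bad]), 3), collapse = ", "))
  subpop <- factor(subpop)
  if (nlevels(subpop) < 2L)
    stop("format error: a NAM population needs at least 2 subpopulations")
  if (any(table(subpop) == 0L))
    stop("format error: empty subpopulation")
  structure(list(genotypes = genotypes, subpop = subpop, map = map,
                 n_total = nrow(genotypes), k = nlevels(subpop),
                 m = ncol(genotypes)),
            class = "nam_population")
}

#' @export
print.nam_population <- function(x, ...) {
  cat("NAM population:", x$n_total, "RILs in", x$k, "subpopulations,",
      x$m, "markers on", length(unique(x$map$chromosome)), "chromosome(s)\n")
  invisible(x)
}

#' Validate a phenotype vector against a population
#'
#' @param y numeric trait values, one per line, in population row order.
#' @param pop a [nam_population()].
#' @return `y` as a plain numeric vector.
#' @export
phenotype_vector <- function(y, pop) {
  y <- as.numeric(y)
  if (length(y) != pop$n_total)
    stop("alignment error: phenotype length ", length(y),
         " does not match population size ", pop$n_total)
  if (any(!is.finite(y)))
    stop("format error: non-finite phenotype values")
  y
}

# ---------------------------------------------------------------------------
# File I/O
# ---------------------------------------------------------------------------

#' Read a NAM population and phenotype from CSV files
#'
#' File layouts: `genotypes.csv` has a header `line_id,<marker ids...>` with
#' cells in `{-1, 1, NA}`; `map.csv` has header
#' `marker_id,chromosome,position_cM`; `phenotypes.csv` has header
#' `line_id,subpop,trait`.  Rows are aligned across files by `line_id`;
#' any mismatch in the id sets is an error.
#'
#' @param genotype_path,map_path,phenotype_path paths to the three CSVs.
#' @return A list with elements `pop` (a [nam_population()]) and `y`
#'   (numeric phenotype vector aligned to the population rows).
#' @export
read_population <- function(genotype_path, map_path, phenotype_path) {
  for (p in c(genotype_path, map_path, phenotype_path))
    if (!file.exists(p)) stop("file error: ", p, " does not exist")
  gen <- utils::read.csv(genotype_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  phe <- utils::read.csv(phenotype_path, stringsAsFactors = FALSE)
  if (names(gen)[1] != "line_id")
    stop("format error: genotype file must start with a line_id column")
  need <- c("line_id", "subpop", "trait")
  if (!all(need %in% names(phe)))
    stop("format error: phenotype file needs columns ",
         paste(need, collapse = ", "))
  if (!setequal(gen$line_id, phe$line_id) ||
      anyDuplicated(gen$line_id) || anyDuplicated(phe$line_id))
    stop("alignment error: line ids do not match 1:1 between genotype and phenotype files")
  phe <- phe[match(gen$line_id, phe$line_id), ]
  g <- as.matrix(gen[, -1, drop = FALSE])
  rownames(g) <- gen$line_id
  map <- validate_genetic_map(map)
  if (!identical(colnames(g), map$marker_id))
    stop("alignment error: genotype marker columns do not match map marker_id order")
  pop <- nam_population(g, phe$subpop, map)
  y <- phenotype_vector(phe$trait, pop)
  list(pop = pop, y = y)
}

#' Write a NAM population and phenotype to CSV files
#'
#' Inverse of [read_population()]; integer genotype codes round-trip
#' bit-identically.
#'
#' @param pop a [nam_population()].
#' @param y phenotype vector aligned to `pop`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths written.
#' @export
write_population <- function(pop, y, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- rownames(pop$genotypes)
  if (is.null(ids)) ids <- paste0("line", seq_len(pop$n_total))
  gpath <- file.path(dir, "genotypes.csv")
  mpath <- file.path(dir, "map.csv")
  ppath <- file.path(dir, "phenotypes.csv")
  gen <- data.frame(line_id = ids, pop$genotypes, check.names = FALSE)
  utils::write.csv(gen, gpath, row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(pop$map), mpath, row.names = FALSE, quote = FALSE)
  phe <- data.frame(line_id = ids, subpop = as.character(pop$subpop), trait = y)
  utils::write.csv(phe, ppath, row.names = FALSE, quote = FALSE)
  invisible(c(genotypes = gpath, map = mpath, phenotypes = ppath))
}

# ---------------------------------------------------------------------------
# Design helpers
# ---------------------------------------------------------------------------

#' Subpopulation incidence matrix
#'
#' Returns the n x k 0/1 indicator matrix relating each line to its family;
#' used as the fixed-covariate block (per-family intercepts) in the joint
#' model.  Each row has exactly one 1, so rows sum to 1 and the cross-product
#' is diagonal with the family sizes.
#'
#' @param pop a [nam_population()].
#' @return numeric matrix, `n_total` x `k`, columns named by family.
#' @export
subpopulation_design <- function(pop) {
  lambda <- stats::model.matrix(~ 0 + pop$subpop)
  colnames(lambda) <- levels(pop$subpop)
  rownames(lambda) <- rownames(pop$genotypes)
  attr(lambda, "assign") <- NULL
  attr(lambda, "contrasts") <- NULL
  lambda
}

#' Impute missing genotype codes within families
#'
#' Missing codes at a marker are replaced by the within-family mean code,
#' which preserves the family allele frequency.  A family with no observed
#' genotype at a marker falls back to the marker's overall mean (0 if the
#' whole column is missing).
#'
#' @param pop a [nam_population()].
#' @return A `nam_population` with no missing genotypes.
#' @export
impute_genotypes <- function(pop) {
  g <- pop$genotypes
  if (!anyNA(g)) return(pop)
  for (fam in levels(pop$subpop)) {
    rows <- which(pop$subpop == fam)
    sub <- g[rows, , drop = FALSE]
    na_cols <- which(colSums(is.na(sub)) > 0L)
    for (j in na_cols) {
      mu <- mean(sub[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- mean(g[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- 0
      sub[is.na(sub[, j]), j] <- mu
    }
    g[rows, ] <- sub
  }
  pop$genotypes <- g
  pop
}
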