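# Genotype-class recoding: collapse the k per-family effect columns of each
# SNP into a single incidence vector whose codes follow the ordering of the
# family-specific phenotype deviations (the "omega" profile).

#' Per-family genotype-class phenotype deviations for one SNP
#'
#' For SNP `snp`, computes omega(family, genotype class) = mean phenotype of
#' the class minus the grand mean, for both genotype classes (-1 = AA,
#' common-parent homozygote; +1 = aa, founder homozygote) in each of the k
#' families.  These 2k deviations order the genotype classes for
#' [recode_snp()].  Classes with no observed lines (e.g. a family
#' monomorphic at the SNP) are flagged empty, not an error.
#'
#' @param pop a [nam_population()].
#' @param y phenotype vector aligned to `pop`.
#' @param snp marker column index.
#' @return An object of class `omega_profile`: a data frame with one row per
#'   (family, genotype class): `subpop`, `genotype` (-1/1), `omega`, `count`;
#'   attributes `snp_index` and `grand_mean`.
#' @export
omega_profile <- function(pop, y, snp) {
  if (snp < 1L || snp > pop$m) stop("snp index out of range")
  y <- phenotype_vector(y, pop)
  g <- pop$genotypes[, snp]
  ybar <- mean(y)
  fams <- levels(pop$subpop)
  k <- length(fams)
  out <- data.frame(
    subpop   = rep(fams, each = 2L),
    genotype = rep(c(-1, 1), times = k),
    omega    = NA_real_,
    count    = 0L,
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(out))) {
    sel <- pop$subpop == out$subpop[r] & !is.na(g) & g == out$genotype[r]
    n <- sum(sel)
    out$count[r] <- n
    if (n > 0L) out$omega[r] <- mean(y[sel]) - ybar
  }
  structure(out, snp_index = snp, grand_mean = ybar,
            class = c("omega_profile", "data.frame"))
}

# Order non-empty classes by (omega, family index, genotype class); stable,
# so equal omegas break deterministically.
.sort_classes <- function(profile) {
  keep <- which(profile$count > 0L)
  keep[order(profile$omega[keep],
             match(profile$subpop[keep], unique(profile$subpop)),
             profile$genotype[keep])]
}

#' Recode one SNP into a single incidence column
#'
#' The non-empty (family, genotype) classes are sorted by their omega
#' deviation and assigned codes that are a monotone function of that
#' order: under `scheme = "omega"` (the default) each class is coded by its
#' own omega deviation, so the codes carry the order and the spacing of the
#' class means; under `scheme = "rank"` the codes are the ranks
#' 1..(#classes); under `scheme = "segmented"` adjacent sorted classes
#' whose omega gap is below `0.1 * sd(y)` share a code (segment index).
#' All three are order-faithful.  Every line receives
#' its class code; lines with a missing genotype receive the count-weighted
#' mean of their family's class codes.  The column is centered to mean zero
#' and scaled to unit standard deviation.  A column with a single
#' segment (or any zero-variance column) carries no information and is
#' flagged degenerate.
#'
#' @param profile an [omega_profile()] for this SNP.
#' @param pop a [nam_population()].
#' @param snp marker column index (must match the profile).
#' @param scheme `"omega"` (default), `"rank"`, or `"segmented"`.
#' @param y phenotype vector; only needed for the segmented gap tolerance.
#' @return Numeric column of length `n_total` with attributes
#'   `recode_table` (data frame: `subpop`, `genotype`, `omega`, `count`,
#'   `code_raw`, `code` on the centered/scaled column scale) and
#'   `degenerate` (logical).
#' @export
recode_snp <- function(profile, pop, snp,
                       scheme = c("omega", "rank", "segmented"), y = NULL) {
  scheme <- match.arg(scheme)
  if (attr(profile, "snp_index") != snp)
    stop("profile was computed for a different SNP")
  tab <- as.data.frame(profile)
  ord <- .sort_classes(profile)
  tab$code_raw <- NA_real_
  if (length(ord) > 0L) {
    if (scheme == "omega") {
      tab$code_raw[ord] <- tab$omega[ord]
    } else if (scheme == "rank") {
      tab$code_raw[ord] <- seq_along(ord)
    } else {
      if (is.null(y)) stop("segmented scheme needs the phenotype vector")
      tol <- 0.1 * stats::sd(y)
      om <- tab$omega[ord]
      gap <- diff(om)
      # tied omegas always share a code, even when sd(y) = 0
      seg <- cumsum(c(1, as.numeric(gap > 0 & gap >= tol)))
      tab$code_raw[ord] <- seg
    }
  }
  g <- pop$genotypes[, snp]
  fams <- levels(pop$subpop)
  z <- rep(NA_real_, pop$n_total)
  for (fam in fams) {
    rows <- which(pop$subpop == fam)
    frows <- tab$subpop == fam & tab$count > 0L
    for (r in which(frows)) {
      sel <- rows[!is.na(g[rows]) & g[rows] == tab$genotype[r]]
      z[sel] <- tab$code_raw[r]
    }
    # mean-imputed code for lines missing this genotype
    miss <- rows[is.na(g[rows])]
    if (length(miss) > 0L) {
      cw <- tab$count[frows]
      z[miss] <- if (sum(cw) > 0L)
        sum(tab$code_raw[frows] * cw) / sum(cw) else 0
    }
  }
  s <- stats::sd(z)
  # a column with no *within-family* code variation (all omegas equal, or a
  # SNP monomorphic in every family) is collinear with the family
  # intercepts and carries no QTL information
  wf_range <- tapply(z, pop$subpop, function(v) diff(range(v)))
  degenerate <- isTRUE(all(wf_range <= 1e-12 * max(1, max(abs(z))))) ||
    !is.finite(s) || s < .Machine$double.eps^0.5
  if (degenerate) {
    tab$code <- 0
    zc <- rep(0, pop$n_total)
  } else {
    mu <- mean(z)
    zc <- (z - mu) / s
    tab$code <- (tab$code_raw - mu) / s
  }
  structure(zc, recode_table = tab, degenerate = degenerate)
}

#' Build the transformed design for all SNPs
#'
#' Applies [omega_profile()] + [recode_snp()] to every marker, giving an
#' n x m design with one column per SNP in place of the k x m columns of the
#' fully family-specific model.  Degenerate columns (monomorphic SNPs or a
#' single omega segment) are recorded and excluded from estimation but keep
#' their index.  The transform uses the phenotype once, on the full data;
#' there is no resampling.
#'
#' @param pop a [nam_population()]; missing genotypes are handled per class.
#' @param y phenotype vector aligned to `pop`.
#' @param scheme recoding scheme, see [recode_snp()].
#' @return An object of class `transformed_design`: list with `Z` (n x m
#'   matrix, zero columns where degenerate), `recode_tables` (list of m
#'   data frames), `degenerate` (logical m), `scheme`, `map`.
#' @export
build_design <- function(pop, y, scheme = c("omega", "rank", "segmented")) {
  scheme <- match.arg(scheme)
  y <- phenotype_vector(y, pop)
  m <- pop$m
  Z <- matrix(0, pop$n_total, m,
              dimnames = list(rownames(pop$genotypes), pop$map$marker_id))
  tables <- vector("list", m)
  degenerate <- logical(m)
  for (j in seq_len(m)) {
    prof <- omega_profile(pop, y, j)
    zj <- recode_snp(prof, pop, j, scheme = scheme, y = y)
    Z[, j] <- as.numeric(zj)
    tables[[j]] <- attr(zj, "recode_table")
    degenerate[j] <- attr(zj, "degenerate")
  }
  structure(list(Z = Z, recode_tables = tables, degenerate = degenerate,
                 scheme = scheme, map = pop$map),
            class = "transformed_design")
}

#' @export
print.transformed_design <- function(x, ...) {
  cat("Transformed design:", nrow(x$Z), "lines x", ncol(x$Z), "SNP columns (",
      sum(x$degenerate), "degenerate ), scheme =", x$scheme, "\n")
  invisible(x)
}

#' Back-transform a fitted column effect to per-family allele effects
#'
#' A coefficient gamma on a recoded column implies, for family j, an
#' additive effect per allele substitution of
#' `gamma * (code(j, aa) - code(j, AA)) / 2` in trait units (the codes are
#' on the centered/scaled column scale, so the column scaling cancels).
#' Families where either genotype class was empty get `NA` (not estimable).
#'
#' @param gamma_hat fitted coefficient for the recoded column.
#' @param recode_table the `recode_table` attribute from [recode_snp()] (or
#'   an element of `recode_tables` from [build_design()]).
#' @return Named numeric vector of length k: additive effect per family.
#' @export
backtransform_effects <- function(gamma_hat, recode_table) {
  fams <- unique(recode_table$subpop)
  eff <- stats::setNames(rep(NA_real_, length(fams)), fams)
  for (fam in fams) {
    aa  <- recode_table[recode_table$subpop == fam & recode_table$genotype == 1, ]
    AA  <- recode_table[recode_table$subpop == fam & recode_table$genotype == -1, ]
    if (nrow(aa) == 1L && nrow(AA) == 1L && aa$count > 0L && AA$count > 0L)
      eff[fam] <- gamma_hat * (aa$code - AA$code) / 2
  }
  eff
}
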