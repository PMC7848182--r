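# Second stage: screen the shrinkage fit, refit the reduced model by
# maximum likelihood, and test each retained effect by a likelihood-ratio
# test reported on the LOD scale (LOD = LR / 4.61, critical value 3.0).

#' Screen SNPs from an E-Bayes fit
#'
#' Keeps columns with `|gamma_hat| / sqrt(sigma2_k_hat) > threshold_t`.
#' Columns whose effect variance was shrunk to the zero floor are excluded
#' outright.  The default threshold 1e-4 is deliberately permissive: the
#' likelihood-ratio stage makes the inclusion decision.
#'
#' @param fit an [ebayes_fit()].
#' @param threshold_t t-ratio threshold.
#' @return Integer vector of retained column indices (possibly empty).
#' @export
screen_snps <- function(fit, threshold_t = 1e-4) {
  ok <- fit$active & fit$sigma2_k_hat > 0
  t_ratio <- rep(0, length(fit$gamma_hat))
  t_ratio[ok] <- abs(fit$gamma_hat[ok]) / sqrt(fit$sigma2_k_hat[ok])
  which(ok & t_ratio > threshold_t)
}

# Gaussian ML log-likelihood of an OLS fit with residual sum of squares rss.
.gauss_loglik <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)

#' Maximum-likelihood refit of the reduced model
#'
#' Ordinary multiple regression of y on the fixed covariates plus the
#' screened SNP columns; under Gaussian errors the OLS fit maximises the
#' likelihood.  Collinear screened columns are dropped (later index loses)
#' with a warning.
#'
#' @param Z_screened n x s matrix of screened columns (s may be 0).
#' @param X fixed-covariate matrix.
#' @param y phenotype vector.
#' @return List of class `ml_refit`: `coef_X`, `coef_Z` (length s, NA for
#'   dropped columns), `kept` (logical s), `rss`, `loglik`, `n`,
#'   `fitted`.
#' @export
ml_refit <- function(Z_screened, X, y) {
  X <- as.matrix(X)
  n <- length(y)
  s <- if (is.null(Z_screened)) 0L else NCOL(Z_screened)
  if (s > 0L) Z_screened <- as.matrix(Z_screened)
  if (s >= n - ncol(X))
    stop("screened set too large for ML refit (", s, " columns, n = ", n, ")")
  W <- if (s > 0L) cbind(X, Z_screened) else X
  qrW <- qr(W)
  kept_cols <- qrW$pivot[seq_len(qrW$rank)]
  dropped <- setdiff(seq_len(ncol(W)), kept_cols)
  dropped_z <- dropped[dropped > ncol(X)]
  if (length(dropped_z) > 0L)
    warning("dropping ", length(dropped_z), " collinear screened column(s)")
  if (any(dropped <= ncol(X)))
    stop("covariate block rank deficient in ML refit")
  fit <- stats::lm.fit(W[, sort(kept_cols), drop = FALSE], y)
  coefs <- stats::setNames(rep(NA_real_, ncol(W)),
                           c(colnames(X), colnames(Z_screened)))
  coefs[sort(kept_cols)] <- fit$coefficients
  rss <- sum(fit$residuals^2)
  kept <- rep(TRUE, s)
  if (length(dropped_z) > 0L) kept[dropped_z - ncol(X)] <- FALSE
  structure(list(coef_X = coefs[seq_len(ncol(X))],
                 coef_Z = if (s > 0L) coefs[-seq_len(ncol(X))] else numeric(0),
                 kept = kept, rss = rss,
                 loglik = .gauss_loglik(rss, n), n = n,
                 fitted = drop(W[, sort(kept_cols), drop = FALSE] %*%
                                 fit$coefficients)),
            class = "ml_refit")
}

#' Likelihood-ratio test of each screened SNP
#'
#' For each screened column j, `LR_j = -2 ln[L(theta_{-j}) / L(theta)]`
#' with `theta` the joint ML estimate of the reduced model.  Two readings
#' of `theta_{-j}` are supported:
#'
#' * `method = "drop"` (default): `theta_{-j}` is `theta` with the tested
#'   effect removed and **every other parameter kept at its joint
#'   estimate** (including the residual variance).  Because the full-model
#'   residuals are orthogonal to column j, this evaluates to
#'   `LR_j = gamma_j^2 ||Z_j||^2 / sigma2_hat`.
#' * `method = "refit"`: the remaining coefficients are re-estimated by a
#'   full nested ML refit (the textbook likelihood-ratio test).
#'
#' `"drop"` does not charge the tested column for signal that correlated
#' neighbours could absorb, which is what a multi-locus scan wants when
#' markers are in strong LD; `"refit"` is more conservative.
#' `LOD = LR / 4.61`; columns with LOD at or above `lod_threshold` are
#' retained.
#'
#' @param Z_screened,X,y as in [ml_refit()].
#' @param lod_threshold LOD critical value (default 3.0).
#' @param method `"drop"` (default) or `"refit"`, see above.
#' @return data frame, one row per screened column: `col`, `gamma_ml`, `LR`,
#'   `LOD`, `retain`.
#' @export
lrt_each <- function(Z_screened, X, y, lod_threshold = 3.0,
                     method = c("drop", "refit")) {
  method <- match.arg(method)
  s <- NCOL(Z_screened)
  full <- ml_refit(Z_screened, X, y)
  n <- full$n
  out <- data.frame(col = seq_len(s), gamma_ml = full$coef_Z,
                    LR = NA_real_, LOD = NA_real_, retain = FALSE)
  for (j in seq_len(s)) {
    if (!full$kept[j]) { out$LR[j] <- 0; next }
    if (method == "drop") {
      rss_red <- full$rss + full$coef_Z[j]^2 * sum(Z_screened[, j]^2)
      out$LR[j] <- (rss_red - full$rss) / (full$rss / n)
    } else {
      red <- ml_refit(Z_screened[, -j, drop = FALSE], X, y)
      out$LR[j] <- max(0, -2 * (red$loglik - full$loglik))
    }
  }
  out$LOD <- out$LR / 4.61
  out$retain <- !is.na(out$LOD) & out$LOD >= lod_threshold & full$kept
  attr(out, "full_fit") <- full
  out
}

#' Select QTL by iterated LRT pruning
#'
#' Starting from the screened set, the reduced model is refit by ML and each
#' column is tested by [lrt_each()]; columns failing the LOD threshold are
#' removed and the refit + test repeated until the retained set is stable
#' (at most `max_rounds` rounds), so the final set is self-consistent.
#'
#' @param design a [build_design()] result.
#' @param fit an [ebayes_fit()] on that design.
#' @param X,y as in [ebayes_fit()].
#' @param threshold_t screening t-ratio, see [screen_snps()].
#' @param lod_threshold LOD critical value.
#' @param lr_method LR computation, see [lrt_each()].
#' @param max_rounds maximum pruning rounds.
#' @return data frame of class `qtl_calls`, one row per retained SNP:
#'   `snp_index`, `marker_id`, `chromosome`, `position_cM`, `gamma_ml`,
#'   `LR`, `LOD`, `r2`, and one `effect_<family>` column per family.
#' @export
select_qtl <- function(design, fit, X, y, threshold_t = 1e-4,
                       lod_threshold = 3.0, lr_method = c("drop", "refit"),
                       max_rounds = 10L) {
  lr_method <- match.arg(lr_method)
  idx <- screen_snps(fit, threshold_t)
  rounds <- 0L
  res <- NULL
  while (length(idx) > 0L && rounds < max_rounds) {
    rounds <- rounds + 1L
    res <- lrt_each(design$Z[, idx, drop = FALSE], X, y, lod_threshold,
                    method = lr_method)
    keep <- res$retain
    if (all(keep)) break
    idx <- idx[keep]
    res <- NULL
  }
  if (length(idx) == 0L) return(.empty_calls(design, X))
  if (is.null(res))
    res <- lrt_each(design$Z[, idx, drop = FALSE], X, y, lod_threshold,
                    method = lr_method)
  full <- attr(res, "full_fit")
  vy <- stats::var(y)
  eff <- t(vapply(seq_along(idx), function(i) {
    backtransform_effects(res$gamma_ml[i], design$recode_tables[[idx[i]]])
  }, numeric(ncol(X))))
  colnames(eff) <- paste0("effect_", colnames(X))
  r2 <- vapply(seq_along(idx), function(i) {
    contrib <- design$Z[, idx[i]] * res$gamma_ml[i]
    if (stats::sd(contrib) == 0) 0 else stats::cor(contrib, y)^2
  }, numeric(1))
  calls <- data.frame(snp_index = idx,
                      marker_id = design$map$marker_id[idx],
                      chromosome = design$map$chromosome[idx],
                      position_cM = design$map$position_cM[idx],
                      gamma_ml = res$gamma_ml, LR = res$LR, LOD = res$LOD,
                      r2 = r2, stringsAsFactors = FALSE)
  calls <- cbind(calls, eff)
  class(calls) <- c("qtl_calls", "data.frame")
  calls
}

.empty_calls <- function(design, X) {
  eff <- matrix(numeric(0), 0, ncol(X),
                dimnames = list(NULL, paste0("effect_", colnames(X))))
  calls <- data.frame(snp_index = integer(0), marker_id = character(0),
                      chromosome = character(0), position_cM = numeric(0),
                      gamma_ml = numeric(0), LR = numeric(0),
                      LOD = numeric(0), r2 = numeric(0),
                      stringsAsFactors = FALSE)
  calls <- cbind(calls, as.data.frame(eff))
  class(calls) <- c("qtl_calls", "data.frame")
  calls
}

#' Full two-stage mapping scan
#'
#' Runs the whole pipeline on one data set: recoding transform
#' ([build_design()]) -> joint E-Bayes shrinkage ([ebayes_fit()]) ->
#' t-ratio screen -> iterated ML refit + LRT ([select_qtl()]).
#'
#' @param pop a [nam_population()].
#' @param y phenotype vector.
#' @param scheme recoding scheme, see [recode_snp()].
#' @param cfg an [ebayes_config()].
#' @param threshold_t screening t-ratio.
#' @param lod_threshold LOD critical value.
#' @param lr_method LR computation, see [lrt_each()].
#' @return List of class `nam_scan`: `design`, `fit`, `calls`.
#' @examples
#' sim <- simulate_nam(nam_sim_design(scenario = "heritability", k = 3,
#'                                    n_total = 150, n_markers = 30,
#'                                    n_qtl = 2, h2 = 0.2), seed = 1)
#' scan <- nam_scan(sim$pop, sim$y)
#' scan$calls[, c("marker_id", "position_cM", "LOD")]
#' @export
nam_scan <- function(pop, y, scheme = c("omega", "rank", "segmented"),
                     cfg = ebayes_config(), threshold_t = 1e-4,
                     lod_threshold = 3.0, lr_method = c("drop", "refit")) {
  scheme <- match.arg(scheme)
  lr_method <- match.arg(lr_method)
  pop <- impute_genotypes(pop)
  y <- phenotype_vector(y, pop)
  X <- subpopulation_design(pop)
  design <- build_design(pop, y, scheme)
  fit <- ebayes_fit(design, X, y, cfg)
  calls <- select_qtl(design, fit, X, y, threshold_t, lod_threshold,
                      lr_method)
  structure(list(design = design, fit = fit, calls = calls),
            class = "nam_scan")
}

#' @export
print.nam_scan <- function(x, ...) {
  cat("NAM scan:", nrow(x$calls), "QTL called\n")
  if (nrow(x$calls) > 0L)
    print(as.data.frame(x$calls)[, c("marker_id", "chromosome",
                                     "position_cM", "LOD", "r2")])
  invisible(x)
}
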