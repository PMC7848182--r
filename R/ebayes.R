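# Empirical-Bayes EM shrinkage over all recoded SNP columns jointly.
#
# Model: y = X beta + sum_k Z_k gamma_k + e,  e ~ N(0, sigma2 I),
# gamma_k ~ N(0, sigma2_k), sigma2_k ~ scaled Inv-chi2(tau, omega).
# Marginally V = sum_k Z_k Z_k' sigma2_k + I sigma2; the EM alternates the
# conditional moments of gamma_k (E-step) with updates of sigma2_k, beta and
# sigma2 (M-step).  Small effects are shrunk to zero (their sigma2_k hits a
# numerical floor and the column is dropped); large effects are nearly
# unshrunk.

#' E-Bayes fitting configuration
#'
#' @param tau,omega hyperparameters of the scaled inverse-chi-squared prior
#'   on each effect variance (defaults 0, 0, the improper prior under which
#'   the variance update is `E(gamma_k^2) / 3`).  This `omega` is the prior
#'   hyperparameter, unrelated to the class deviations of [omega_profile()].
#' @param max_iter maximum EM iterations.
#' @param tol convergence threshold on the maximum absolute change across
#'   beta, sigma2 and all sigma2_k.
#' @param var_floor_frac sigma2_k below `var_floor_frac * var(y)` is set to
#'   exactly zero and the column is permanently dropped from V.
#' @param init_floor_frac floor on the initial sigma2_k, as a fraction of
#'   `var(y)`.
#' @return list of class `ebayes_config`.
#' @export
ebayes_config <- function(tau = 0, omega = 0, max_iter = 200, tol = 1e-6,
                          var_floor_frac = 1e-8, init_floor_frac = 1e-6) {
  stopifnot(max_iter >= 1, tol > 0)
  structure(list(tau = tau, omega = omega, max_iter = as.integer(max_iter),
                 tol = tol, var_floor_frac = var_floor_frac,
                 init_floor_frac = init_floor_frac),
            class = "ebayes_config")
}

# M-step update of one effect variance under the scaled Inv-chi2(tau, omega)
# prior: (E(gamma'gamma) + omega) / (tau + 2 + 1).
.sigma2k_update <- function(Egg, tau, omega) (Egg + omega) / (tau + 2 + 1)

#' Apply the inverse of the marginal covariance V to a vector
#'
#' `V = Z diag(sigma2_k) Z' + I sigma2` for the active columns.  Uses the
#' Woodbury identity so the cost scales with the number of active SNPs, not
#' with n^2:
#' `V^{-1} u = (u - Z (sigma2 D^{-1} + Z'Z)^{-1} Z'u) / sigma2`.
#' Falls back to a dense solve (with a warning) if the inner matrix is
#' numerically singular.
#'
#' @param Z_active n x m_active matrix of active columns.
#' @param sigma2_k positive effect variances of the active columns.
#' @param sigma2 residual variance.
#' @param rhs vector (or matrix) to which V^{-1} is applied.
#' @return `V^{-1} rhs`, same shape as `rhs`.
#' @export
marginal_solve <- function(Z_active, sigma2_k, sigma2, rhs) {
  rhs <- as.matrix(rhs)
  if (is.null(Z_active) || NCOL(Z_active) == 0L || length(sigma2_k) == 0L) {
    out <- rhs / sigma2
    return(if (ncol(out) == 1L) drop(out) else out)
  }
  Z <- as.matrix(Z_active)
  stopifnot(length(sigma2_k) == ncol(Z), all(sigma2_k > 0), sigma2 > 0)
  C <- crossprod(Z)
  diag(C) <- diag(C) + sigma2 / sigma2_k
  Zr <- crossprod(Z, rhs)
  w <- tryCatch(solve(C, Zr), error = function(e) NULL)
  if (is.null(w)) {
    warning("inner Woodbury matrix singular; falling back to dense solve")
    V <- Z %*% (t(Z) * sigma2_k)
    diag(V) <- diag(V) + sigma2
    out <- solve(V, rhs)
  } else {
    out <- (rhs - Z %*% w) / sigma2
  }
  if (ncol(out) == 1L) drop(out) else out
}

#' Fit all SNP effects jointly by empirical-Bayes EM shrinkage
#'
#' First stage of the two-stage mapping pipeline.  Initialisation: beta by
#' OLS of y on X, sigma2 from its residuals, gamma_k = 0, and sigma2_k from
#' the squared marginal OLS slope of each column (floored).  Then EM:
#'
#' * E-step: `E(gamma_k) = sigma2_k Z_k' V^{-1} (y - X beta)`,
#'   `var(gamma_k) = sigma2_k - sigma2_k^2 Z_k' V^{-1} Z_k`,
#'   `E(gamma_k^2) = E(gamma_k)^2 + var(gamma_k)`.
#' * M-step: `sigma2_k = (E(gamma_k^2) + omega) / (tau + 3)`,
#'   `beta = (X'V^{-1}X)^{-1} X'V^{-1} y`,
#'   `sigma2 = (y - X beta)' (y - X beta - sum_k Z_k E(gamma_k)) / n`.
#'
#' Columns whose sigma2_k falls below the floor are set to exactly zero and
#' dropped from V for all later iterations (single monotone pruning; dropped
#' columns never re-enter).  All V^{-1} products are computed in the
#' m_active-dimensional Woodbury form (see [marginal_solve()]).
#'
#' @param design a [build_design()] result, or a plain numeric matrix Z
#'   (then no columns are flagged degenerate a priori).
#' @param X fixed-covariate matrix (typically [subpopulation_design()]),
#'   full column rank.
#' @param y phenotype vector.
#' @param cfg an [ebayes_config()].
#' @return Object of class `ebayes_fit`: list with `beta_hat`, `sigma2_hat`,
#'   `gamma_hat` (length m; 0 for dropped columns), `sigma2_k_hat` (length
#'   m; exact 0 for dropped columns), `active` (logical m), `n_iter`,
#'   `converged`.
#' @export
ebayes_fit <- function(design, X, y, cfg = ebayes_config()) {
  Z <- if (inherits(design, "transformed_design")) design$Z else as.matrix(design)
  degenerate <- if (inherits(design, "transformed_design"))
    design$degenerate else rep(FALSE, ncol(Z))
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(Z) == n, nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix X is rank deficient")
  m <- ncol(Z)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  floor_k <- cfg$var_floor_frac * vy

  # precomputed cross-products: all V^{-1} algebra lives in m_active space
  G   <- crossprod(Z)
  ZtX <- crossprod(Z, X)
  Zty <- drop(crossprod(Z, y))
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))

  beta <- drop(solve(XtX, Xty))
  r0 <- y - drop(X %*% beta)
  sigma2 <- sum(r0^2) / n
  dG <- diag(G)
  slope <- ifelse(dG > 0, drop(crossprod(Z, r0)) / pmax(dG, 1e-12), 0)
  d <- pmax(slope^2, cfg$init_floor_frac * vy)
  d[degenerate] <- 0
  gamma <- numeric(m)
  active <- d > 0

  n_iter <- 0L
  converged <- FALSE
  sigma2_floor <- 1e-12 * vy
  for (it in seq_len(cfg$max_iter)) {
    n_iter <- it
    A <- which(active)
    d_old <- d; beta_old <- beta; sigma2_old <- sigma2
    if (length(A) == 0L) {
      beta <- drop(solve(XtX, Xty))
      r <- y - drop(X %*% beta)
      sigma2 <- sum(r^2) / n
      gamma <- numeric(m)
      if (max(abs(beta - beta_old), abs(sigma2 - sigma2_old)) < cfg$tol) {
        converged <- TRUE; break
      }
      next
    }
    GA <- G[A, A, drop = FALSE]
    C <- GA
    diag(C) <- diag(C) + sigma2 / d[A]
    tA <- Zty[A] - drop(ZtX[A, , drop = FALSE] %*% beta)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) {
      warning("E-Bayes: ill-conditioned system; applying variance floor")
      sigma2 <- max(sigma2, sigma2_floor)
      diag(C) <- diag(C) + sigma2 / d[A]
      ch <- chol(C)
    }
    Csolve <- function(B) backsolve(ch, forwardsolve(t(ch), B))
    w <- Csolve(tA)
    # E-step
    e <- d[A] * (tA - drop(GA %*% w)) / sigma2
    Mq <- Csolve(GA)
    qA <- (diag(GA) - colSums(GA * Mq)) / sigma2
    varA <- pmax(d[A] - d[A]^2 * qA, 0)
    Egg <- e^2 + varA
    # M-step: effect variances, with monotone pruning at the floor
    dA_new <- .sigma2k_update(Egg, cfg$tau, cfg$omega)
    drop_now <- dA_new < floor_k
    d[A] <- ifelse(drop_now, 0, dA_new)
    gamma <- numeric(m)
    gamma[A] <- ifelse(drop_now, 0, e)
    active[A[drop_now]] <- FALSE
    A2 <- which(active)
    # M-step: beta by GLS under updated V, then sigma2
    if (length(A2) > 0L) {
      C2 <- G[A2, A2, drop = FALSE]
      diag(C2) <- diag(C2) + sigma2 / d[A2]
      ch2 <- tryCatch(chol(C2), error = function(e) NULL)
      if (is.null(ch2)) { diag(C2) <- diag(C2) + sigma2_floor; ch2 <- chol(C2) }
      H <- ZtX[A2, , drop = FALSE]
      CH <- backsolve(ch2, forwardsolve(t(ch2), H))
      Cy <- backsolve(ch2, forwardsolve(t(ch2), Zty[A2]))
      XtVX <- (XtX - crossprod(H, CH)) / sigma2
      XtVy <- (Xty - drop(crossprod(H, Cy))) / sigma2
      beta <- drop(solve(XtVX, XtVy))
    } else {
      beta <- drop(solve(XtX, Xty))
    }
    r <- y - drop(X %*% beta)
    fit_g <- if (length(A2) > 0L)
      drop(Z[, A2, drop = FALSE] %*% gamma[A2]) else numeric(n)
    sigma2 <- sum(r * (r - fit_g)) / n
    if (!is.finite(sigma2) || sigma2 < sigma2_floor) {
      warning("E-Bayes: residual variance collapsed; numerical floor applied")
      sigma2 <- sigma2_floor
    }
    delta <- max(abs(beta - beta_old), abs(sigma2 - sigma2_old),
                 abs(d - d_old))
    if (delta < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("E-Bayes EM did not converge in ", cfg$max_iter, " iterations")
  structure(list(beta_hat = stats::setNames(beta, colnames(X)),
                 sigma2_hat = sigma2,
                 gamma_hat = stats::setNames(gamma, colnames(Z)),
                 sigma2_k_hat = stats::setNames(d, colnames(Z)),
                 active = active, n_iter = n_iter, converged = converged,
                 config = cfg),
            class = "ebayes_fit")
}

#' @export
print.ebayes_fit <- function(x, ...) {
  cat("E-Bayes fit:", sum(x$active), "of", length(x$gamma_hat),
      "columns active after", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  residual variance:", format(x$sigma2_hat, digits = 4), "\n")
  invisible(x)
}
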