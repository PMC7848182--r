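# Scoring detections against simulated truth: per-QTL power, false positive
# rate, and position/effect bias.

#' Match QTL calls to true simulated QTLs
#'
#' Each call is assigned to the nearest true QTL within `window_cM`
#' (closed interval); at most one call per QTL is accepted per replicate —
#' the nearest wins, ties going to the lower call index.  Calls left
#' unassigned are false positives.
#'
#' @param calls a `qtl_calls` data frame (see [select_qtl()]).
#' @param truth a `sim_truth` (see [simulate_nam()]).
#' @param window_cM matching window in cM (default 5).
#' @return List: `assignments` (data frame `qtl`, `call`, `distance_cM`)
#'   and `false_positives` (integer call rows).
#' @export
match_calls <- function(calls, truth, window_cM = 5.0) {
  n_call <- nrow(calls)
  n_qtl <- length(truth$position_cM)
  if (n_call == 0L)
    return(list(assignments = data.frame(qtl = integer(0), call = integer(0),
                                         distance_cM = numeric(0)),
                false_positives = integer(0)))
  D <- abs(outer(calls$position_cM, truth$position_cM, "-"))
  nearest <- apply(D, 1L, which.min)
  nearest_d <- D[cbind(seq_len(n_call), nearest)]
  eligible <- nearest_d <= window_cM
  assigned <- rep(NA_integer_, n_qtl)
  for (q in seq_len(n_qtl)) {
    cand <- which(eligible & nearest == q)
    if (length(cand) > 0L)
      assigned[q] <- cand[order(nearest_d[cand], cand)][1L]
  }
  hit <- which(!is.na(assigned))
  list(assignments = data.frame(qtl = hit, call = assigned[hit],
                                distance_cM = nearest_d[assigned[hit]]),
       false_positives = setdiff(seq_len(n_call), assigned[hit]))
}

# Score one replicate: detection flags, biases, false-positive count.
.score_replicate <- function(calls, truth, window_cM = 5.0) {
  n_qtl <- length(truth$position_cM)
  mm <- match_calls(calls, truth, window_cM)
  detected <- rep(FALSE, n_qtl)
  pos_bias <- rep(NA_real_, n_qtl)
  eff_bias <- rep(NA_real_, n_qtl)
  eff_bias_abs <- rep(NA_real_, n_qtl)
  eff_cols <- grep("^effect_", names(calls))
  for (r in seq_len(nrow(mm$assignments))) {
    q <- mm$assignments$qtl[r]
    cl <- mm$assignments$call[r]
    detected[q] <- TRUE
    pos_bias[q] <- mm$assignments$distance_cM[r]
    if (length(eff_cols) > 0L && !is.null(truth$alpha)) {
      est <- as.numeric(calls[cl, eff_cols])
      tru <- as.numeric(truth$alpha[q, ])
      ok <- is.finite(est)
      if (any(ok)) {
        eff_bias[q] <- mean(est[ok] - tru[ok])
        eff_bias_abs[q] <- mean(abs(est[ok] - tru[ok]))
      }
    }
  }
  list(detected = detected, pos_bias = pos_bias, eff_bias = eff_bias,
       eff_bias_abs = eff_bias_abs,
       n_false_positives = length(mm$false_positives),
       n_calls = nrow(calls))
}

#' Summarise replicate scores into an evaluation report
#'
#' Power per QTL is the fraction of replicates detecting it; average power
#' is the mean over QTLs.  The false positive rate is the number of
#' unmatched calls divided by the number of non-QTL markers, averaged over
#' replicates.  Position bias is the mean absolute distance (cM) between a
#' matched call and its QTL, over true positives; effect bias is the mean
#' signed (and mean absolute) difference between back-transformed and true
#' family effects over true positives.  With zero true positives a bias is
#' `NA`, not zero.
#'
#' @param scores list of per-replicate scores (internal; produced by
#'   [run_power_study()] or [cmd_evaluate()]).
#' @param n_markers total marker count (FPR denominator is
#'   `n_markers - n_qtl`).
#' @return Object of class `eval_report`: `per_qtl_power`, `avg_power`,
#'   `fpr` (proportion), `pos_bias_cM` (overall mean), `per_qtl_pos_bias`,
#'   `per_qtl_effect_bias` (signed), `per_qtl_effect_bias_abs`,
#'   `effect_bias_abs` (overall mean), `n_replicates`.
#' @export
summarize_scores <- function(scores, n_markers) {
  stopifnot(length(scores) >= 1L)
  n_qtl <- length(scores[[1L]]$detected)
  det <- sapply(scores, function(s) s$detected)
  per_qtl_power <- rowMeans(det)
  fp <- sapply(scores, function(s) s$n_false_positives)
  fpr <- mean(fp / (n_markers - n_qtl))
  nanmean <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  pb <- sapply(scores, function(s) s$pos_bias)
  eb <- sapply(scores, function(s) s$eff_bias)
  eba <- sapply(scores, function(s) s$eff_bias_abs)
  per_qtl_pos_bias <- apply(pb, 1L, nanmean)
  per_qtl_eff_bias <- apply(eb, 1L, nanmean)
  per_qtl_eff_bias_abs <- apply(eba, 1L, nanmean)
  structure(list(per_qtl_power = per_qtl_power,
                 avg_power = mean(per_qtl_power),
                 fpr = fpr,
                 pos_bias_cM = nanmean(as.numeric(pb)),
                 per_qtl_pos_bias = per_qtl_pos_bias,
                 per_qtl_effect_bias = per_qtl_eff_bias,
                 per_qtl_effect_bias_abs = per_qtl_eff_bias_abs,
                 effect_bias_abs = nanmean(as.numeric(eba)),
                 n_replicates = length(scores)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation over", x$n_replicates, "replicates\n")
  cat(sprintf("  average power:        %.1f%%\n", 100 * x$avg_power))
  cat(sprintf("  false positive rate:  %.2f%%\n", 100 * x$fpr))
  cat(sprintf("  position bias:        %s cM\n",
              format(x$pos_bias_cM, digits = 3)))
  cat(sprintf("  |effect bias|:        %s\n",
              format(x$effect_bias_abs, digits = 3)))
  cat("  per-QTL power (%):   ",
      paste(sprintf("%.0f", 100 * x$per_qtl_power), collapse = " "), "\n")
  invisible(x)
}

#' Run a full simulate -> map -> score power study
#'
#' Simulates `n_reps` replicates under `design`, runs the two-stage mapping
#' pipeline ([nam_scan()]) on each, matches calls to the simulated truth,
#' and summarises power, FPR and biases.  Replicate seeds are drawn once
#' from `seed`, so the study is reproducible end to end.
#'
#' @param design a [nam_sim_design()].
#' @param n_reps number of Monte-Carlo replicates.
#' @param seed master seed.
#' @param window_cM matching window (see [match_calls()]).
#' @param scheme,cfg,lod_threshold passed to [nam_scan()].
#' @return An `eval_report` (see [summarize_scores()]); attribute
#'   `rep_seeds` records the per-replicate seeds.
#' @export
run_power_study <- function(design, n_reps = 100, seed = 1,
                            window_cM = 5.0, scheme = "rank",
                            cfg = ebayes_config(), lod_threshold = 3.0) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  scores <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    sim <- simulate_nam(design, seed = rep_seeds[i])
    scan <- nam_scan(sim$pop, sim$y, scheme = scheme, cfg = cfg,
                     lod_threshold = lod_threshold)
    scores[[i]] <- .score_replicate(scan$calls, sim$truth, window_cM)
  }
  rep <- summarize_scores(scores, n_markers = nrow(design$map))
  attr(rep, "rep_seeds") <- rep_seeds
  rep
}
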