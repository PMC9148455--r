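#' Empirical FDR and power at an adjusted-p threshold
#'
#' Declares genes with adjusted p below `alpha` significant, then computes
#' FDR = FP / max(1, declared) (so zero declarations give FDR 0) and
#' power = TP / (number of truly DE genes among the computable genes).
#' Missing adjusted p-values (non-computable genes) are excluded from both
#' numerator and denominator.
#'
#' @param p_adj Adjusted p-values (NA for non-computable genes).
#' @param is_de Logical truth labels, aligned with `p_adj`.
#' @param alpha Significance threshold (default 0.05).
#' @return List with `fdr`, `power` (NA when no computable DE genes),
#'   `n_declared`, `n_computable`.
#' @export
fdr_power <- function(p_adj, is_de, alpha = 0.05) {
  stopifnot(length(p_adj) == length(is_de))
  ok <- !is.na(p_adj)
  declared <- ok & p_adj < alpha
  fp <- sum(declared & !is_de)
  tp <- sum(declared & is_de)
  n_de <- sum(ok & is_de)
  list(fdr = fp / max(1, fp + tp),
       power = if (n_de > 0) tp / n_de else NA_real_,
       n_declared = fp + tp,
       n_computable = sum(ok))
}

#' Convergence accounting over per-gene fits
#'
#' @param converged Logical vector: full model converged and not singular.
#' @param reduced_failed Optional logical vector: full model converged but at
#'   least one reduced model failed (LRT paths).
#' @return List with `nonconvergence_rate` and `reduced_failure_rate`.
#' @export
convergence_rate <- function(converged, reduced_failed = NULL) {
  out <- list(nonconvergence_rate = mean(!converged))
  out$reduced_failure_rate <- if (is.null(reduced_failed)) 0
    else mean(converged & reduced_failed)
  out
}

#' Average evaluation summaries over replicate datasets
#'
#' @param summaries A list of data frames as returned by [evaluate_run()]
#'   (same method/test/sample-size layout in each).
#' @return One data frame of class `eval_summary` with rate columns averaged
#'   and `n_replicates` recorded.
#' @export
aggregate_replicates <- function(summaries) {
  if (length(summaries) == 0) stop("no summaries to aggregate")
  all <- do.call(rbind, summaries)
  rate_cols <- intersect(c("fdr", "power", "nonconvergence_rate",
                           "reduced_failure_rate", "n_declared",
                           "n_computable"), names(all))
  agg <- stats::aggregate(all[rate_cols],
                          by = all[c("method", "test")],
                          FUN = function(x) mean(x, na.rm = TRUE))
  agg$n_replicates <- length(summaries)
  class(agg) <- c("eval_summary", "data.frame")
  agg
}

#' Per-timepoint predicted expression from fixed effects
#'
#' Evaluates the fixed-effect linear predictor (random intercept at zero) at
#' the design rows of one group across timepoints, giving the model-predicted
#' log-scale expression profile used for clustering.
#'
#' @param coef Coefficient vector (or a fit with a `coef` element).
#' @param design A `study_design`.
#' @param group `"reference"` or `"treatment"`.
#' @param timepoints Which timepoints to evaluate (default all).
#' @return Named numeric vector of predicted values per timepoint.
#' @export
predicted_expression <- function(coef, design, group = c("reference", "treatment"),
                                 timepoints = NULL) {
  group <- match.arg(group)
  if (is.list(coef)) coef <- coef$coef
  nT <- design$n_timepoints
  if (is.null(timepoints)) timepoints <- seq_len(nT)
  p <- 2L * nT
  stopifnot(length(coef) == p)
  pred <- vapply(timepoints, function(tp) {
    x <- numeric(p)
    x[1] <- 1
    if (group == "treatment") x[2] <- 1
    if (tp > 1) {
      x[1L + tp] <- 1
      if (group == "treatment") x[nT + tp] <- 1
    }
    sum(x * coef)
  }, numeric(1))
  names(pred) <- paste0("T", timepoints)
  pred
}

#' Hierarchical clustering of expression profiles
#'
#' Row-scales each profile, computes the correlation distance 1 - Pearson r,
#' and cuts a complete-linkage tree into `k` clusters. Constant profiles
#' (correlation undefined) are dropped with a warning and reported as NA.
#'
#' @param profiles Numeric matrix, one row per gene (e.g. predicted
#'   expression per timepoint).
#' @param k Number of clusters (default 7).
#' @param scale_rows Center/scale each row before clustering (default TRUE).
#' @return Integer cluster labels named by row (NA for dropped rows), with
#'   the `hclust` tree as attribute `"tree"`.
#' @export
hierarchical_cluster <- function(profiles, k = 7, scale_rows = TRUE) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("g", seq_len(nrow(profiles)))
  sds <- apply(profiles, 1, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warning(sum(!keep), " constant profile(s) dropped (correlation undefined)")
  m <- profiles[keep, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 non-constant profiles")
  if (scale_rows) m <- t(scale(t(m)))
  d <- stats::as.dist(1 - stats::cor(t(m)))
  tree <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(tree, k = min(k, nrow(m)))
  out <- rep(NA_integer_, nrow(profiles))
  names(out) <- rownames(profiles)
  out[keep] <- cl
  attr(out, "tree") <- tree
  out
}
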