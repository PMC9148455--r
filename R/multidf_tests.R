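#' Contrast matrices for the four multiple-DF hypotheses
#'
#' Builds the contrast matrix over the model coefficients
#' (intercept, group, time indicators, group-by-time interactions) for one of
#' the four joint hypotheses of a two-group multi-timepoint design:
#'
#' * `between`: no group difference at any timepoint
#'   (rows group, group+each interaction; rank T).
#' * `within`: no change over time within one group
#'   (rows time_k + interaction_k for the treatment group, or time_k alone
#'   for the reference group; rank T-1). The pairwise timepoint differences
#'   are linear combinations of these rows, so the matrix spans the full
#'   within-group null space at full row rank.
#' * `interaction`: all group-by-time interaction coefficients zero
#'   (rank T-1).
#' * `global`: all non-intercept coefficients zero (rank 2T-1).
#'
#' @param test One of `"between"`, `"within"`, `"interaction"`, `"global"`.
#' @param design A `study_design` (default: 4 timepoints, 8 coefficients).
#' @param within_group Which group the within-subject test targets
#'   (`"treatment"`, matching the simulation truth, or `"reference"`).
#' @return A full-row-rank contrast matrix with `rank` and `test` attributes.
#' @export
contrast_matrix <- function(test = c("between", "within", "interaction", "global"),
                            design = NULL,
                            within_group = c("treatment", "reference")) {
  test <- match.arg(test)
  within_group <- match.arg(within_group)
  nT <- if (is.null(design)) 4L else design$n_timepoints
  p <- 2L * nT
  cn <- if (!is.null(design)) colnames(design$X) else
    c("(Intercept)", "group", paste0("time", 2:nT), paste0("group:time", 2:nT))
  ee <- function(k) { v <- numeric(p); v[k] <- 1; v }
  i_grp <- 2L
  i_time <- 2L + seq_len(nT - 1L)
  i_int <- 1L + nT + seq_len(nT - 1L)
  L <- switch(test,
    between = rbind(ee(i_grp),
                    t(vapply(i_int, function(k) ee(i_grp) + ee(k), numeric(p)))),
    within = if (within_group == "treatment") {
      t(vapply(seq_len(nT - 1L),
               function(j) ee(i_time[j]) + ee(i_int[j]), numeric(p)))
    } else {
      t(vapply(i_time, ee, numeric(p)))
    },
    interaction = t(vapply(i_int, ee, numeric(p))),
    global = t(vapply(2:p, ee, numeric(p)))
  )
  colnames(L) <- cn
  rownames(L) <- NULL
  attr(L, "rank") <- nrow(L)
  attr(L, "test") <- test
  L
}

## reduced-model design under H0: L beta = 0, i.e. X restricted to the null
## space of L (reparameterized, since between/within are not
## coordinate-dropping in reference coding)
reduced_design_matrix <- function(X, L) {
  N <- MASS::Null(t(L))
  Xr <- X %*% N
  colnames(Xr) <- paste0("r", seq_len(ncol(Xr)))
  attr(Xr, "nullbasis") <- N
  Xr
}

test_row <- function(gene = NA_character_, test = NA_character_,
                     statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p = NA_real_, computable = FALSE) {
  data.frame(gene = gene, test = test, statistic = statistic, df1 = df1,
             df2 = df2, p = p, computable = computable,
             stringsAsFactors = FALSE)
}

#' Wald chi-square test of a joint linear hypothesis
#'
#' W = (L beta)' (L V L')^-1 (L beta), compared to a chi-square with rank(L)
#' degrees of freedom. For a `gee_fit` the covariance is selected by
#' `covariance` (Wang-Long small-sample correction by default); any list with
#' `coef` and `coef_cov` elements is also accepted.
#'
#' @param fit Model fit (e.g. a `gee_fit`), or list with `coef`, `coef_cov`.
#' @param L Contrast matrix or vector.
#' @param covariance For GEE fits: `"wang-long"`, `"robust"`, or `"naive"`.
#' @return One-row data frame: statistic, df1, df2 (Inf), p, computable.
#' @export
wald_chisq_test <- function(fit, L,
                            covariance = c("wang-long", "robust", "naive")) {
  covariance <- match.arg(covariance)
  tn <- if (is.null(attr(L, "test"))) NA_character_ else attr(L, "test")
  L <- rbind(L)
  if (!isTRUE(fit$converged)) return(test_row(test = tn))
  V <- if (inherits(fit, "gee_fit")) {
    switch(covariance, "wang-long" = fit$wl_cov, robust = fit$robust_cov,
           naive = fit$naive_cov)
  } else fit$coef_cov
  q <- nrow(L)
  Lb <- as.vector(L %*% fit$coef)
  LVL <- L %*% V %*% t(L)
  LVLi <- tryCatch(solve(LVL), error = function(e) NULL)
  if (is.null(LVLi)) {
    warning("singular contrast covariance; using a pseudo-inverse with reduced DF")
    e <- eigen((LVL + t(LVL)) / 2, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    q <- sum(pos)
    LVLi <- e$vectors[, pos, drop = FALSE] %*%
      (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  }
  W <- as.vector(t(Lb) %*% LVLi %*% Lb)
  test_row(test = tn, statistic = W, df1 = q, df2 = Inf,
           p = stats::pchisq(W, df = q, lower.tail = FALSE), computable = TRUE)
}

#' F test with Satterthwaite denominator degrees of freedom
#'
#' F = W / rank(L) with W the Wald quadratic form under the model-based
#' coefficient covariance, and denominator degrees of freedom from
#' [satterthwaite_df()]. Used for the LMM and pseudo-likelihood NBMM paths.
#'
#' @param fit An `lmm_fit` (or `nbmm_pl_fit`).
#' @param L Contrast matrix or vector.
#' @return One-row data frame: statistic, df1, df2, p, computable.
#' @export
f_test_satterthwaite <- function(fit, L) {
  tn <- if (is.null(attr(L, "test"))) NA_character_ else attr(L, "test")
  L <- rbind(L)
  if (!isTRUE(fit$converged)) return(test_row(test = tn))
  q <- nrow(L)
  Lb <- as.vector(L %*% fit$coef)
  LVL <- L %*% fit$coef_cov %*% t(L)
  W <- tryCatch(as.vector(t(Lb) %*% solve(LVL, Lb)), error = function(e) NA_real_)
  if (!is.finite(W)) return(test_row(test = tn))
  df2 <- satterthwaite_df(fit, L)
  Fstat <- W / q
  test_row(test = tn, statistic = Fstat, df1 = q, df2 = df2,
           p = stats::pf(Fstat, q, df2, lower.tail = FALSE), computable = TRUE)
}

#' Likelihood ratio test of nested model fits
#'
#' stat = 2 (loglik_full - loglik_reduced), referred to a chi-square with
#' `df` degrees of freedom. If either model failed to converge the result is
#' marked not computable (the hypothesis test cannot be calculated); a
#' reduced log-likelihood exceeding the full one by more than 1e-6 signals an
#' optimization failure and the statistic is clipped to zero with a warning.
#'
#' @param full,reduced Fits with `loglik` and `converged` elements; `reduced`
#'   must be nested in `full`.
#' @param df Degrees of freedom (number of independent constraints).
#' @param test Optional test label.
#' @return One-row data frame: statistic, df1, df2 (Inf), p, computable.
#' @export
lrt_test <- function(full, reduced, df, test = NA_character_) {
  if (!isTRUE(full$converged) || !isTRUE(reduced$converged))
    return(test_row(test = test, df1 = df))
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6)
    warning("reduced model log-likelihood exceeds the full model; ",
            "optimization failure, statistic clipped to 0")
  stat <- max(stat, 0)
  test_row(test = test, statistic = stat, df1 = df, df2 = Inf,
           p = stats::pchisq(stat, df = df, lower.tail = FALSE),
           computable = TRUE)
}

#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Step-up FDR adjustment applied to the non-missing p-values only (missing
#' entries, e.g. genes whose model did not converge, are excluded from the
#' adjustment and reinserted as missing).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}
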