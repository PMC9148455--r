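#' Fit one method to every gene of a dataset and run the multiple-DF tests
#'
#' The per-gene analysis mirrors the simulation-study protocol: size factors
#' by the median-ratio method enter as log offsets (count models) or through
#' the variance-stabilizing transformation (LMM), each gene is fitted by the
#' chosen correlated-data method, and each requested joint hypothesis is
#' tested by the method's test class: Satterthwaite F (lmm, nbmm-pl),
#' likelihood ratio against the reparameterized reduced model (nbmm-agq), or
#' Wald chi-square on the chosen sandwich covariance (gee). Benjamini-
#' Hochberg adjustment is applied per test across computable genes. Genes
#' whose full fit failed or was singular are reported with `computable =
#' FALSE`; for LRTs a converged full fit with a failed reduced fit is not
#' computable for that test only.
#'
#' @param counts A [count_matrix()] (or plain matrix), typically CPM-filtered.
#' @param design A `study_design` aligned with the count columns.
#' @param method One of `"lmm"`, `"nbmm-agq"`, `"nbmm-pl"`, `"gee"`.
#' @param tests Subset of `c("between", "within", "interaction", "global")`.
#' @param size_factors Optional per-sample size factors (median-of-ratios
#'   when omitted).
#' @param n_nodes Quadrature nodes for `nbmm-agq`.
#' @param gee_cov Covariance used by the GEE Wald test.
#' @param transform Transformation feeding the LMM (`"vst"` or `"log2"`).
#' @param within_group Group targeted by the within-subject test.
#' @return List of class `mdseq_result`: `fits` (per-gene data frame with
#'   convergence flags and variance components), `tests` (gene x test rows
#'   with statistic, df, p, BH-adjusted p, computable), `coef` (gene x
#'   coefficient matrix), `method`.
#' @export
analyze_dataset <- function(counts, design,
                            method = c("lmm", "nbmm-agq", "nbmm-pl", "gee"),
                            tests = c("between", "within", "interaction", "global"),
                            size_factors = NULL, n_nodes = 11,
                            gee_cov = c("wang-long", "robust", "naive"),
                            transform = c("vst", "log2"),
                            within_group = c("treatment", "reference")) {
  method <- match.arg(method)
  gee_cov <- match.arg(gee_cov)
  transform <- match.arg(transform)
  within_group <- match.arg(within_group)
  tests <- match.arg(tests, several.ok = TRUE)
  cm <- as_count_matrix(counts)
  stopifnot(ncol(cm$counts) == nrow(design$X))
  G <- nrow(cm$counts)
  genes <- cm$gene_ids
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(cm)
  offsets <- log(size_factors)
  Ls <- lapply(tests, contrast_matrix, design = design,
               within_group = within_group)
  names(Ls) <- tests

  if (method == "lmm") {
    M <- vst_transform(cm, size_factors, transform = transform)
  }
  if (method == "nbmm-agq") {
    Xr <- lapply(Ls, function(L) reduced_design_matrix(design$X, L))
  }

  fit_rows <- vector("list", G)
  test_rows <- vector("list", G)
  p8 <- design$p
  coef_mat <- matrix(NA_real_, G, p8, dimnames = list(genes, colnames(design$X)))
  for (g in seq_len(G)) {
    gene <- genes[g]
    fit <- tryCatch(switch(method,
      "lmm" = fit_lmm_reml(M[g, ], design),
      "nbmm-pl" = fit_nbmm_pl(cm$counts[g, ], design, offsets = offsets),
      "nbmm-agq" = fit_nbmm_agq(cm$counts[g, ], design, offsets = offsets,
                                n_nodes = n_nodes, hessian = FALSE),
      "gee" = fit_gee_exchangeable(cm$counts[g, ], design, offsets = offsets)
    ), error = function(e) list(converged = FALSE, singular = FALSE))
    singular <- isTRUE(fit$singular)
    ok <- isTRUE(fit$converged) && !singular
    if (ok) coef_mat[g, ] <- fit$coef
    rows <- lapply(tests, function(tn) {
      L <- Ls[[tn]]
      if (!ok) {
        tr <- test_row(test = tn, df1 = nrow(L))
      } else {
        tr <- tryCatch(switch(method,
          "lmm" = f_test_satterthwaite(fit, L),
          "nbmm-pl" = f_test_satterthwaite(fit, L),
          "gee" = wald_chisq_test(fit, L, covariance = gee_cov),
          "nbmm-agq" = {
            st <- list(beta = as.vector(crossprod(attr(Xr[[tn]], "nullbasis"),
                                                  fit$coef)),
                       alpha = fit$alpha, s2b = fit$sigma2_b)
            red <- tryCatch(
              fit_nbmm_agq(cm$counts[g, ],
                           list(X = Xr[[tn]], subject = design$subject),
                           offsets = offsets, n_nodes = n_nodes,
                           start = st, hessian = FALSE),
              error = function(e) list(converged = FALSE))
            if (isTRUE(red$singular)) red$converged <- FALSE
            suppressWarnings(lrt_test(fit, red, df = nrow(L), test = tn))
          }), error = function(e) test_row(test = tn, df1 = nrow(L)))
        tr$test <- tn
      }
      tr
    })
    tr <- do.call(rbind, rows)
    tr$gene <- gene
    test_rows[[g]] <- tr
    fit_rows[[g]] <- data.frame(
      gene = gene, method = method, converged = isTRUE(fit$converged),
      singular = singular,
      sigma2_b = if (ok && !is.null(fit$sigma2_b)) fit$sigma2_b else NA_real_,
      dispersion = if (!ok) NA_real_ else if (method == "lmm") fit$sigma2_e
        else if (method == "gee") fit$phi else fit$alpha,
      loglik = if (ok && !is.null(fit$loglik)) fit$loglik else NA_real_,
      n_iter = if (!is.null(fit$n_iter)) fit$n_iter else NA_integer_,
      stringsAsFactors = FALSE)
  }
  fits <- do.call(rbind, fit_rows)
  tests_df <- do.call(rbind, test_rows)
  tests_df$p_adj <- NA_real_
  for (tn in tests) {
    sel <- tests_df$test == tn
    tests_df$p_adj[sel] <- bh_adjust(tests_df$p[sel])
  }
  structure(list(fits = fits, tests = tests_df, coef = coef_mat,
                 method = method),
            class = "mdseq_result")
}

#' @export
print.mdseq_result <- function(x, ...) {
  ok <- x$fits$converged & !x$fits$singular
  cat(sprintf("mdseq_result (%s): %d genes, %.1f%% converged, tests: %s\n",
              x$method, nrow(x$fits), 100 * mean(ok),
              paste(unique(x$tests$test), collapse = ", ")))
  invisible(x)
}

#' Evaluate one analyzed dataset against simulation truth
#'
#' Joins per-gene test results to the truth labels and computes, per test,
#' the empirical FDR and power at BH-adjusted `alpha`, together with the full
#' model non-convergence rate (singular fits counted as non-converged) and
#' the rate of converged genes whose reduced model failed for at least one
#' test.
#'
#' @param result An `mdseq_result` from [analyze_dataset()].
#' @param truth Data frame with columns `gene` and `is_de`.
#' @param alpha Significance threshold on adjusted p-values.
#' @return Data frame with one row per test: fdr, power, convergence rates.
#' @export
evaluate_run <- function(result, truth, alpha = 0.05) {
  fits <- result$fits
  ok <- fits$converged & !fits$singular
  reduced_failed <- tapply(!result$tests$computable, result$tests$gene, any)
  reduced_failed <- as.logical(reduced_failed[fits$gene])
  conv <- convergence_rate(ok, reduced_failed)
  rows <- lapply(unique(result$tests$test), function(tn) {
    td <- result$tests[result$tests$test == tn, ]
    m <- match(td$gene, truth$gene)
    fp <- fdr_power(td$p_adj, truth$is_de[m], alpha)
    data.frame(method = result$method, test = tn, fdr = fp$fdr,
               power = fp$power, n_declared = fp$n_declared,
               n_computable = fp$n_computable,
               nonconvergence_rate = conv$nonconvergence_rate,
               reduced_failure_rate = conv$reduced_failure_rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end simulate / filter / fit / test /
#' evaluate pipeline with the study defaults: 4 timepoints, 20% DE genes
#' with interaction effects (1/3, 2/3, 1), CPM > 1 in at least `n_per_group`
#' samples, BH threshold 0.05.
#'
#' @param seed Master seed.
#' @param n_genes Genes per simulated dataset.
#' @param n_per_group Subjects per group.
#' @param n_datasets Replicate datasets.
#' @param prop_de Proportion of DE genes.
#' @param methods Methods to fit (subset of lmm, nbmm-agq, nbmm-pl, gee).
#' @param tests Joint hypotheses to evaluate.
#' @param alpha BH significance threshold.
#' @param n_nodes AGQ quadrature nodes.
#' @param gee_cov GEE covariance for Wald tests.
#' @param transform LMM input transformation.
#' @param dist Gene-parameter distribution.
#' @param effect_sign_rule DE sign rule (`"joint"` or `"independent"`).
#' @param cpm_threshold CPM filter threshold.
#' @param out_dir Optional directory for per-stage TSV artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_genes = 2000, n_per_group = 10,
                            n_datasets = 3, prop_de = 0.2,
                            methods = "lmm",
                            tests = c("between", "within", "interaction", "global"),
                            alpha = 0.05, n_nodes = 11,
                            gee_cov = "wang-long", transform = "vst",
                            dist = surrogate_param_dist(),
                            effect_sign_rule = "joint",
                            cpm_threshold = 1, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1, n_genes >= 1, n_datasets >= 1)
  methods <- match.arg(methods, c("lmm", "nbmm-agq", "nbmm-pl", "gee"),
                       several.ok = TRUE)
  tests <- match.arg(tests, c("between", "within", "interaction", "global"),
                     several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full simulation-and-evaluation pipeline
#'
#' Simulates `n_datasets` replicate datasets under the configured study
#' conditions, CPM-filters each, fits every configured method, runs the
#' multiple-DF tests with BH adjustment, computes FDR / power / convergence
#' per replicate, and averages across replicates. Reproducible given
#' `config$seed`; per-stage TSVs are written when `out_dir` is set.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print progress lines.
#' @return List with `summary` (replicate-averaged `eval_summary`),
#'   `replicates` (per-replicate evaluation rows) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  sims <- simulate_study(config$n_genes, config$n_per_group,
                         config$n_datasets, config$prop_de,
                         dist = config$dist, seed = config$seed,
                         effect_sign_rule = config$effect_sign_rule)
  out_dir <- config$out_dir
  per_rep <- vector("list", config$n_datasets)
  for (d in seq_along(sims)) {
    sim <- sims[[d]]
    filt <- cpm_filter(sim$counts, config$cpm_threshold,
                       min_samples = config$n_per_group)
    sf <- median_ratio_size_factors(filt)
    if (!is.null(out_dir)) {
      rep_dir <- file.path(out_dir, sprintf("replicate%02d", d))
      write_dataset(sim, rep_dir)
    }
    evals <- lapply(config$methods, function(m) {
      if (verbose) message(sprintf("replicate %d: fitting %s (%d genes)",
                                   d, m, nrow(filt$counts)))
      res <- analyze_dataset(filt, sim$design, method = m,
                             tests = config$tests, size_factors = sf,
                             n_nodes = config$n_nodes,
                             gee_cov = config$gee_cov,
                             transform = config$transform)
      if (!is.null(out_dir)) {
        utils::write.table(res$tests,
                           file.path(out_dir, sprintf("replicate%02d", d),
                                     paste0("tests_", m, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      evaluate_run(res, sim$truth, alpha = config$alpha)
    })
    per_rep[[d]] <- do.call(rbind, evals)
  }
  summary <- aggregate_replicates(per_rep)
  summary$n_per_group <- config$n_per_group
  if (!is.null(out_dir)) {
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summary = summary, replicates = per_rep, config = config)
}
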