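#' Surrogate distribution for per-gene generative parameters
#'
#' Per-gene simulation parameters are drawn as triplets of (mean CPM, NB
#' dispersion, random-intercept variance). Real repeated-measures triplet
#' tables can be supplied via [empirical_param_dist()]; this parametric
#' surrogate reproduces the familiar features of bulk RNA-seq: a roughly
#' log-normal expression distribution, a dispersion trend that decays with the
#' mean towards an asymptote, and subject-level intraclass correlation spread
#' over a wide range.
#'
#' Defaults: log2(mean CPM) ~ Normal(3, 2^2) truncated at CPM > 0.1;
#' dispersion alpha = (a0 + a1/mu) * LogNormal(0, 0.4^2) with a0 = 0.05,
#' a1 = 2 and mu the expected count; sigma2_b ~ LogNormal(log 0.2, 0.8^2).
#'
#' @param log2_cpm_mean,log2_cpm_sd Mean and SD of log2 mean-CPM.
#' @param cpm_floor Truncation floor for mean CPM.
#' @param disp_a0,disp_a1 Dispersion-trend coefficients in alpha(mu) = a0 + a1/mu.
#' @param disp_sdlog Log-normal jitter SD applied to the dispersion trend.
#' @param s2b_meanlog,s2b_sdlog Log-normal parameters of the random-intercept
#'   variance.
#' @param library_size Expected total library size per sample.
#' @return An object of class `param_dist`.
#' @export
surrogate_param_dist <- function(log2_cpm_mean = 3, log2_cpm_sd = 2,
                                 cpm_floor = 0.1,
                                 disp_a0 = 0.05, disp_a1 = 2, disp_sdlog = 0.4,
                                 s2b_meanlog = log(0.2), s2b_sdlog = 0.8,
                                 library_size = 25e6) {
  if (log2_cpm_sd <= 0 || disp_sdlog < 0 || s2b_sdlog < 0 ||
      disp_a0 < 0 || disp_a1 < 0 || (disp_a0 == 0 && disp_a1 == 0) ||
      cpm_floor <= 0 || library_size <= 0)
    stop("invalid surrogate distribution parameters")
  structure(list(type = "parametric", log2_cpm_mean = log2_cpm_mean,
                 log2_cpm_sd = log2_cpm_sd, cpm_floor = cpm_floor,
                 disp_a0 = disp_a0, disp_a1 = disp_a1, disp_sdlog = disp_sdlog,
                 s2b_meanlog = s2b_meanlog, s2b_sdlog = s2b_sdlog,
                 library_size = library_size),
            class = "param_dist")
}

#' Empirical parameter distribution from a triplet table
#'
#' @param triplets A data frame (or path to a TSV) with columns `mean_cpm`,
#'   `dispersion`, `sigma2_b`; rows are resampled with replacement.
#' @param library_size Expected total library size per sample.
#' @return An object of class `param_dist`.
#' @export
empirical_param_dist <- function(triplets, library_size = 25e6) {
  if (is.character(triplets))
    triplets <- utils::read.table(triplets, header = TRUE, sep = "\t")
  required <- c("mean_cpm", "dispersion", "sigma2_b")
  if (!all(required %in% names(triplets)))
    stop("triplet table must have columns: ", paste(required, collapse = ", "))
  triplets <- as.data.frame(triplets)[required]
  if (any(!is.finite(as.matrix(triplets))) ||
      any(triplets$mean_cpm <= 0) || any(triplets$dispersion <= 0) ||
      any(triplets$sigma2_b < 0))
    stop("triplets must satisfy mean_cpm > 0, dispersion > 0, sigma2_b >= 0")
  structure(list(type = "empirical", triplets = triplets,
                 library_size = library_size),
            class = "param_dist")
}

#' Intercept coefficient from a scaled mean-CPM value
#'
#' The fixed-effect intercept is the log expected count for a reference
#' (control, first timepoint) sample: scaled CPM x library size / 1e6.
#'
#' @param scaled_cpm Mean CPM after scaling all genes to sum to one million.
#' @param library_size Total library size (default 25 million).
#' @return Natural-log intercept value(s).
#' @export
beta0_from_cpm <- function(scaled_cpm, library_size = 25e6) {
  log(scaled_cpm * library_size / 1e6)
}

#' Draw per-gene generative parameters
#'
#' Draws `n_genes` (mean CPM, dispersion, random-intercept variance) triplets
#' from `dist`, rescales the CPM values to sum to one million, and sets the
#' intercept beta0 to the log expected count under the common library size.
#' All other coefficients are 0 until [assign_de_effects()] is applied.
#'
#' @param n_genes Number of genes.
#' @param dist A `param_dist` from [surrogate_param_dist()] or
#'   [empirical_param_dist()].
#' @param seed Optional integer seed (deterministic draws when supplied).
#' @return A data frame of class `gene_params` with columns `gene`,
#'   `mean_cpm`, `scaled_cpm`, `beta0`..`beta7`, `alpha`, `sigma2_b`, `is_de`.
#' @export
draw_gene_params <- function(n_genes, dist = surrogate_param_dist(),
                             seed = NULL) {
  stopifnot(n_genes >= 1)
  if (!inherits(dist, "param_dist")) stop("`dist` must be a param_dist object")
  if (!is.null(seed)) set.seed(seed)
  if (dist$type == "parametric") {
    cpm <- 2^stats::rnorm(n_genes, dist$log2_cpm_mean, dist$log2_cpm_sd)
    while (any(low <- cpm <= dist$cpm_floor)) {
      cpm[low] <- 2^stats::rnorm(sum(low), dist$log2_cpm_mean, dist$log2_cpm_sd)
    }
    scaled_cpm <- cpm / sum(cpm) * 1e6
    mu0 <- scaled_cpm * dist$library_size / 1e6
    alpha <- (dist$disp_a0 + dist$disp_a1 / mu0) *
      stats::rlnorm(n_genes, 0, dist$disp_sdlog)
    sigma2_b <- stats::rlnorm(n_genes, dist$s2b_meanlog, dist$s2b_sdlog)
  } else {
    rows <- sample.int(nrow(dist$triplets), n_genes, replace = TRUE)
    cpm <- dist$triplets$mean_cpm[rows]
    scaled_cpm <- cpm / sum(cpm) * 1e6
    alpha <- dist$triplets$dispersion[rows]
    sigma2_b <- dist$triplets$sigma2_b[rows]
  }
  params <- data.frame(
    gene = sprintf("gene%05d", seq_len(n_genes)),
    mean_cpm = cpm,
    scaled_cpm = scaled_cpm,
    beta0 = beta0_from_cpm(scaled_cpm, dist$library_size),
    beta1 = 0, beta2 = 0, beta3 = 0, beta4 = 0,
    beta5 = 0, beta6 = 0, beta7 = 0,
    alpha = alpha,
    sigma2_b = sigma2_b,
    is_de = FALSE,
    stringsAsFactors = FALSE
  )
  class(params) <- c("gene_params", "data.frame")
  params
}

#' Assign differential-expression effects to a fraction of genes
#'
#' Flags `round(prop_de * n_genes)` genes as differentially expressed and sets
#' their group-by-time interaction coefficients to magnitudes (1/3, 2/3, 1)
#' for timepoints 2, 3 and 4. Signs follow `effect_sign_rule`: `"joint"`
#' applies one Rademacher sign per gene to all three effects (a monotone
#' time-trend per gene); `"independent"` draws a sign per effect.
#'
#' @param params A `gene_params` data frame.
#' @param prop_de Proportion of DE genes in \[0, 1\].
#' @param effect_sign_rule `"joint"` (default) or `"independent"`.
#' @param seed Optional integer seed.
#' @param effect_sizes Interaction effect magnitudes (natural-log scale).
#' @return `params` with `beta5`..`beta7` and `is_de` filled in.
#' @export
assign_de_effects <- function(params, prop_de,
                              effect_sign_rule = c("joint", "independent"),
                              seed = NULL, effect_sizes = c(1/3, 2/3, 1)) {
  stopifnot(prop_de >= 0, prop_de <= 1, length(effect_sizes) == 3)
  effect_sign_rule <- match.arg(effect_sign_rule)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(params)
  params$beta5 <- params$beta6 <- params$beta7 <- 0
  params$is_de <- FALSE
  n_de <- round(prop_de * n)
  if (n_de > 0) {
    idx <- sample.int(n, n_de)
    signs <- if (effect_sign_rule == "joint") {
      matrix(sample(c(-1, 1), n_de, replace = TRUE), n_de, 3)
    } else {
      matrix(sample(c(-1, 1), 3 * n_de, replace = TRUE), n_de, 3)
    }
    params$beta5[idx] <- signs[, 1] * effect_sizes[1]
    params$beta6[idx] <- signs[, 2] * effect_sizes[2]
    params$beta7[idx] <- signs[, 3] * effect_sizes[3]
    params$is_de[idx] <- TRUE
  }
  params
}

#' Simulate one negative binomial repeated-measures count dataset
#'
#' For each gene g and subject i a random intercept b_gi ~ N(0, sigma2_b[g])
#' is drawn; the conditional mean is mu = exp(X beta + b) and counts are drawn
#' from NB(mu, alpha) with Var = mu + alpha mu^2 (alpha = 0 is drawn as exact
#' Poisson). Genes whose linear predictor would overflow are capped and
#' reported in the `overflow_genes` element rather than crashing the run.
#'
#' @param params A `gene_params` data frame (8 beta columns).
#' @param design A `study_design` with 4 timepoints (8 coefficients).
#' @param seed Optional integer seed.
#' @param lib_size_factors Optional per-sample multiplicative library-size
#'   factors (e.g. `runif(n, 0.7, 1.3)`); default is a common library size.
#' @return A list of class `sim_data` with elements `counts`
#'   ([count_matrix()]), `truth` (gene, is_de, beta5..beta7), `params`,
#'   `design`, `overflow_genes`.
#' @export
simulate_dataset <- function(params, design, seed = NULL,
                             lib_size_factors = NULL) {
  if (!inherits(design, "study_design"))
    stop("`design` must be a study_design")
  beta_cols <- paste0("beta", 0:7)
  if (design$p != 8 || !all(beta_cols %in% names(params)))
    stop("params (8 beta columns) and design (8 coefficients) are inconsistent")
  if (!is.null(seed)) set.seed(seed)
  G <- nrow(params)
  N <- nrow(design$X)
  S <- design$n_subjects
  B <- as.matrix(params[, beta_cols])
  eta <- B %*% t(design$X)                      # G x N fixed-effect predictor
  b <- matrix(stats::rnorm(G * S, 0, sqrt(params$sigma2_b)), G, S)
  eta <- eta + b[, as.integer(design$subject), drop = FALSE]
  if (!is.null(lib_size_factors)) {
    stopifnot(length(lib_size_factors) == N, all(lib_size_factors > 0))
    eta <- sweep(eta, 2, log(lib_size_factors), "+")
  }
  cap <- log(1e12)
  overflow <- which(apply(eta, 1, max) > cap)
  if (length(overflow)) eta[eta > cap] <- cap
  mu <- exp(eta)
  avec <- rep(params$alpha, times = N)          # column-major recycling
  muv <- as.vector(mu)
  yv <- numeric(length(muv))
  pois <- avec == 0
  if (any(pois)) yv[pois] <- stats::rpois(sum(pois), muv[pois])
  if (any(!pois)) yv[!pois] <- stats::rnbinom(sum(!pois), size = 1 / avec[!pois],
                                              mu = muv[!pois])
  counts <- matrix(yv, G, N, dimnames = list(params$gene, design$samples$sample))
  structure(list(
    counts = count_matrix(counts),
    truth = data.frame(gene = params$gene, is_de = params$is_de,
                       beta5 = params$beta5, beta6 = params$beta6,
                       beta7 = params$beta7, stringsAsFactors = FALSE),
    params = params,
    design = design,
    overflow_genes = params$gene[overflow]
  ), class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("sim_data:", nrow(x$counts$counts), "genes,", ncol(x$counts$counts),
      "samples,", sum(x$truth$is_de), "DE genes\n")
  invisible(x)
}

#' Filter lowly expressed genes by CPM
#'
#' Keeps genes whose CPM exceeds `cpm_threshold` in at least `min_samples`
#' samples; in the simulation study `min_samples` is the number of samples in
#' a single group-by-timepoint cell. CPM is computed against the library
#' sizes of the unfiltered matrix.
#'
#' @param counts A [count_matrix()] (or plain matrix).
#' @param cpm_threshold CPM threshold (default 1).
#' @param min_samples Minimum number of samples above threshold.
#' @return A filtered [count_matrix()] (library sizes recomputed).
#' @export
cpm_filter <- function(counts, cpm_threshold = 1, min_samples) {
  cm <- as_count_matrix(counts)
  stopifnot(cpm_threshold > 0, min_samples >= 1,
            min_samples <= ncol(cm$counts))
  cpm <- cpm_matrix(cm)
  keep <- rowSums(cpm > cpm_threshold) >= min_samples
  if (!any(keep)) warning("all genes removed by the CPM filter")
  count_matrix(cm$counts[keep, , drop = FALSE])
}

#' Simulate a replicate set of study datasets
#'
#' Generates `n_datasets` independent datasets under the stated study
#' conditions: parameters redrawn per dataset from `dist`, a `prop_de`
#' fraction of genes given the (1/3, 2/3, 1) interaction effects, and counts
#' drawn under the random-intercept NB model. A single master seed drives
#' per-dataset sub-seeds so individual replicates are reproducible.
#'
#' @param n_genes Genes per dataset.
#' @param n_per_group Subjects per group.
#' @param n_datasets Number of replicate datasets.
#' @param prop_de Proportion of DE genes (default 0.2).
#' @param dist Parameter distribution (default [surrogate_param_dist()]).
#' @param seed Master seed.
#' @param n_timepoints Observations per subject (default 4).
#' @param effect_sign_rule Passed to [assign_de_effects()].
#' @return A list of `sim_data` objects.
#' @export
simulate_study <- function(n_genes, n_per_group, n_datasets, prop_de = 0.2,
                           dist = surrogate_param_dist(), seed = NULL,
                           n_timepoints = 4,
                           effect_sign_rule = "joint") {
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_datasets),
                      n_datasets, 3)
  design <- study_design(n_per_group, n_timepoints)
  lapply(seq_len(n_datasets), function(d) {
    params <- draw_gene_params(n_genes, dist, seed = sub_seeds[d, 1])
    params <- assign_de_effects(params, prop_de,
                                effect_sign_rule = effect_sign_rule,
                                seed = sub_seeds[d, 2])
    simulate_dataset(params, design, seed = sub_seeds[d, 3])
  })
}

#' Write a simulated dataset to TSV files
#'
#' Emits `counts.tsv` (genes x samples), `metadata.tsv` (sample, subject,
#' group, time) and `truth.tsv` (gene, is_de, beta5..beta7) under `dir`.
#'
#' @param sim A `sim_data` object.
#' @param dir Output directory (created if needed).
#' @param prefix Optional filename prefix.
#' @export
write_dataset <- function(sim, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, paste0(prefix, "counts.tsv")))
  write_metadata(sim$design, file.path(dir, paste0(prefix, "metadata.tsv")))
  utils::write.table(sim$truth, file.path(dir, paste0(prefix, "truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
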