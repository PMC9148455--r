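test_that("intercepts follow the scaled-CPM to log-count rule", {
  # a gene whose scaled CPM is 10 has expected count 10/1e6 * 25e6 = 250
  expect_equal(beta0_from_cpm(10), log(250))
  expect_equal(beta0_from_cpm(10), 5.5215, tolerance = 1e-4)
  p <- draw_gene_params(50, seed = 1)
  expect_equal(sum(p$scaled_cpm), 1e6)
  expect_equal(p$beta0, log(p$scaled_cpm * 25))
})

test_that("parameter draws are seeded, valid, and start with null effects", {
  d <- surrogate_param_dist()
  p1 <- draw_gene_params(200, d, seed = 42)
  p2 <- draw_gene_params(200, d, seed = 42)
  expect_identical(p1, p2)
  p3 <- draw_gene_params(200, d, seed = 43)
  expect_false(identical(p1$mean_cpm, p3$mean_cpm))
  expect_true(all(as.matrix(p1[paste0("beta", 1:7)]) == 0))
  expect_true(all(p1$alpha > 0))
  expect_true(all(p1$sigma2_b >= 0))
  expect_true(all(p1$mean_cpm > d$cpm_floor))
  expect_error(surrogate_param_dist(disp_a0 = 0, disp_a1 = 0),
               "invalid surrogate")
})

test_that("empirical triplet tables are resampled and validated", {
  tr <- data.frame(mean_cpm = c(5, 50, 500), dispersion = c(0.3, 0.1, 0.05),
                   sigma2_b = c(0.1, 0.2, 0.4))
  d <- empirical_param_dist(tr)
  p <- draw_gene_params(300, d, seed = 9)
  expect_true(all(p$alpha %in% tr$dispersion))
  expect_true(all(p$sigma2_b %in% tr$sigma2_b))
  expect_error(empirical_param_dist(data.frame(mean_cpm = -1,
                                               dispersion = 1, sigma2_b = 0)),
               "mean_cpm > 0")
})

test_that("DE assignment flags the requested fraction with the study effect sizes", {
  p <- draw_gene_params(100, seed = 7)
  p <- assign_de_effects(p, 0.2, seed = 8)
  expect_equal(sum(p$is_de), 20)
  de <- p[p$is_de, ]
  expect_true(all(abs(de$beta5) == 1 / 3))
  expect_true(all(abs(de$beta6) == 2 / 3))
  expect_true(all(abs(de$beta7) == 1))
  # joint sign rule keeps one sign per gene
  expect_true(all(sign(de$beta5) == sign(de$beta6)))
  expect_true(all(sign(de$beta6) == sign(de$beta7)))
  expect_true(all(as.matrix(p[!p$is_de, c("beta5", "beta6", "beta7")]) == 0))
  expect_true(all(as.matrix(p[paste0("beta", 1:4)]) == 0))
  p0 <- assign_de_effects(p, 0, seed = 8)
  expect_false(any(p0$is_de))
  expect_true(all(as.matrix(p0[c("beta5", "beta6", "beta7")]) == 0))
})

test_that("a positively signed DE gene has beta vector (beta0,0,0,0,0,1/3,2/3,1)", {
  p <- fixed_params(50)
  p <- assign_de_effects(p, 1, seed = 3)
  pos <- p[p$beta7 > 0, ][1, ]
  expect_equal(unlist(pos[paste0("beta", 1:7)], use.names = FALSE),
               c(0, 0, 0, 0, 1 / 3, 2 / 3, 1))
})

test_that("null-gene counts are Poisson when sigma2_b = 0 and alpha = 0", {
  des <- study_design(1250)                      # 10^4 samples
  p <- fixed_params(1, beta0 = log(250), alpha = 0, sigma2_b = 0)
  sim <- simulate_dataset(p, des, seed = 2)
  y <- as.vector(sim$counts$counts)
  expect_lt(abs(mean(y) - 250), 3 * sqrt(250 / length(y)))
  expect_lt(abs(stats::var(y) / mean(y) - 1), 0.06)   # index of dispersion -> 1
})

test_that("counts reproduce the NB variance identity Var = mu + alpha mu^2", {
  des <- study_design(5000)                      # 4e4 draws
  p <- fixed_params(1, beta0 = log(100), alpha = 0.5, sigma2_b = 0)
  sim <- simulate_dataset(p, des, seed = 4)
  y <- as.vector(sim$counts$counts)
  expect_lt(abs(mean(y) - 100) / 100, 0.03)
  expect_lt(abs(stats::var(y) - 5100) / 5100, 0.12)
})

test_that("a beta7 = 1 gene shows an e-fold interaction ratio at timepoint 4", {
  des <- study_design(2000)
  p <- fixed_params(1, beta0 = log(200), alpha = 0.01, sigma2_b = 0)
  p$beta7 <- 1
  p$is_de <- TRUE
  sim <- simulate_dataset(p, des, seed = 5)
  s <- des$samples
  treat_t4 <- mean(sim$counts$counts[1, s$group == "treatment" & s$time == 4])
  ctrl_t4 <- mean(sim$counts$counts[1, s$group == "control" & s$time == 4])
  expect_equal(treat_t4 / ctrl_t4, exp(1), tolerance = 0.03)
  # null-gene marginal means are invariant across groups and timepoints
  p0 <- fixed_params(1, beta0 = log(200), alpha = 0.05, sigma2_b = 0.2)
  sim0 <- simulate_dataset(p0, des, seed = 6)
  cell_means <- tapply(sim0$counts$counts[1, ],
                       interaction(s$group, s$time), mean)
  expect_lt(diff(range(cell_means)) / mean(cell_means), 0.15)
})

test_that("datasets are bit-identical under a common seed and differ otherwise", {
  des <- study_design(3)
  p <- draw_gene_params(40, seed = 10)
  p <- assign_de_effects(p, 0.2, seed = 11)
  s1 <- simulate_dataset(p, des, seed = 12)
  s2 <- simulate_dataset(p, des, seed = 12)
  expect_identical(s1$counts$counts, s2$counts$counts)
  s3 <- simulate_dataset(p, des, seed = 13)
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("within-subject correlation rises with the random-intercept variance", {
  des <- study_design(10)
  s <- des$samples
  icc_hat <- vapply(c(0.02, 0.3, 1.5), function(s2b) {
    p <- fixed_params(250, beta0 = log(500), alpha = 0.1, sigma2_b = s2b,
                      seed = 20)
    sim <- simulate_dataset(p, des, seed = round(100 * s2b) + 7)
    lc <- log1p(sim$counts$counts)
    mean(vapply(seq_len(nrow(lc)), function(g) {
      stats::cor(lc[g, s$time == 1], lc[g, s$time == 2])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(icc_hat) > 0))
})

test_that("overflowing linear predictors are capped and reported, not fatal", {
  des <- study_design(2)
  p <- fixed_params(2, beta0 = c(40, log(100)), alpha = 0.1, sigma2_b = 0)
  sim <- simulate_dataset(p, des, seed = 1)
  expect_equal(sim$overflow_genes, p$gene[1])
  expect_true(all(is.finite(sim$counts$counts)))
})

test_that("the CPM filter applies the per-cell sample rule", {
  # 4 samples with library size 1e6 each; gene A has CPM (2,2,2,0)
  counts <- rbind(geneA = c(2, 2, 2, 0),
                  geneB = rep(0, 4),
                  filler = c(999998, 999998, 999998, 1e6))
  colnames(counts) <- paste0("s", 1:4)
  cm <- count_matrix(counts)
  expect_equal(unname(cm$library_sizes), rep(1e6, 4))
  kept3 <- cpm_filter(cm, cpm_threshold = 1, min_samples = 3)
  expect_true("geneA" %in% kept3$gene_ids)
  expect_false("geneB" %in% kept3$gene_ids)     # all-zero gene always removed
  kept4 <- cpm_filter(cm, cpm_threshold = 1, min_samples = 4)
  expect_false("geneA" %in% kept4$gene_ids)
  expect_warning(cpm_filter(count_matrix(rbind(g = c(1, 1))), 2e6, 1),
                 "all genes removed")
})

test_that("the replicate generator respects prop_de exactly and is reproducible", {
  sims <- simulate_study(n_genes = 150, n_per_group = 3, n_datasets = 2,
                         prop_de = 0.2, seed = 99)
  expect_length(sims, 2)
  expect_equal(vapply(sims, function(s) sum(s$truth$is_de), numeric(1)),
               c(30, 30))
  sims2 <- simulate_study(n_genes = 150, n_per_group = 3, n_datasets = 2,
                          prop_de = 0.2, seed = 99)
  expect_identical(sims[[1]]$counts$counts, sims2[[1]]$counts$counts)
  expect_false(identical(sims[[1]]$counts$counts, sims[[2]]$counts$counts))
})
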