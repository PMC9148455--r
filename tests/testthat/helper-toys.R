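## small builders shared across test files

# gene_params data frame with fixed generative values (overrides the surrogate)
fixed_params <- function(n, beta0 = log(500), alpha = 0.1, sigma2_b = 0.3,
                         seed = 1) {
  p <- draw_gene_params(n, seed = seed)
  p$beta0 <- rep_len(beta0, n)
  p$alpha <- rep_len(alpha, n)
  p$sigma2_b <- rep_len(sigma2_b, n)
  p
}

# paired one-group toy: n subjects x 2 timepoints, X = (intercept, time2)
paired_design <- function(n_subjects) {
  list(X = cbind(`(Intercept)` = 1, time2 = rep(c(0, 1), n_subjects)),
       subject = factor(rep(seq_len(n_subjects), each = 2)))
}
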