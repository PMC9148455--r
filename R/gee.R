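#' Fit a Poisson GEE with exchangeable working correlation
#'
#' Solves the generalized estimating equations for an overdispersed Poisson
#' marginal model (log link, variance phi * mu) with an exchangeable working
#' correlation within subjects. The scale phi is updated from the Pearson
#' chi-square and the working correlation rho from products of within-subject
#' Pearson residual pairs. Per-subject ingredients (D_i, V_i^-1, residuals)
#' are retained so the sandwich and small-sample covariances can be computed
#' from the fit.
#'
#' @param y Integer count vector for one gene.
#' @param design `study_design` or list with `X` and `subject`.
#' @param offsets Per-sample log offsets (default 0).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the coefficient update.
#' @return A list of class `gee_fit`: `coef`, `naive_cov`, `robust_cov`,
#'   `wl_cov`, `phi`, `rho`, `converged`, `n_iter` and per-subject internals.
#' @export
fit_gee_exchangeable <- function(y, design, offsets = NULL, max_iter = 100,
                                 tol = 1e-8) {
  di <- fit_inputs(design)
  X <- di$X
  subj <- di$subject
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (is.null(offsets)) offsets <- rep(0, n)
  idx <- split(seq_len(n), subj)
  g0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                        offset = offsets))
  beta <- g0$coefficients
  beta[!is.finite(beta)] <- 0
  phi <- 1
  rho <- 0
  converged <- FALSE
  iter <- 0
  max_ni <- max(lengths(idx))
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta) + offsets
    mu <- pmax(exp(pmin(eta, 30)), 1e-10)
    r <- (y - mu) / sqrt(mu)
    phi <- sum(r^2) / (n - p)
    # moment update of rho from within-subject residual pairs
    pair_sum <- sum(vapply(idx, function(ix) {
      (sum(r[ix])^2 - sum(r[ix]^2)) / 2
    }, numeric(1)))
    npairs <- sum(lengths(idx) * (lengths(idx) - 1) / 2)
    if (npairs > 0) {
      denom <- if (npairs - p > 0) npairs - p else npairs
      rho <- pair_sum / (denom * phi)
      rho <- min(max(rho, -1 / (max_ni - 1) + 1e-6), 0.99)
    }
    B <- matrix(0, p, p)
    U <- numeric(p)
    for (ix in idx) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      mui <- mu[ix]
      Di <- Xi * mui
      # R^-1 for exchangeable: (I - rho/(1+(ni-1)rho) J) / (1-rho)
      sm <- sqrt(mui)
      Eh <- sweep(Di, 1, sm, "/")        # A^{-1/2} D
      if (ni > 1 && rho != 0) {
        cfac <- rho / ((1 - rho) * (1 + (ni - 1) * rho))
        VinvD <- (Eh / (1 - rho) - cfac * matrix(colSums(Eh), ni, p, byrow = TRUE))
      } else VinvD <- Eh
      VinvD <- sweep(VinvD, 1, sm, "/") / phi   # V^-1 D
      B <- B + crossprod(Di, VinvD)
      U <- U + as.vector(crossprod(VinvD, y[ix] - mui))
    }
    delta <- tryCatch(solve(B, U), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) {
      return(structure(list(coef = rep(NA_real_, p), converged = FALSE,
                            method = "gee"), class = "gee_fit"))
    }
    beta <- beta + delta
    if (max(abs(delta)) < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  names(beta) <- colnames(X)
  eta <- as.vector(X %*% beta) + offsets
  mu <- pmax(exp(pmin(eta, 30)), 1e-10)
  fit <- structure(list(
    coef = beta, phi = phi, rho = rho, converged = converged, n_iter = iter,
    y = y, X = X, subject = subj, offsets = offsets, mu = mu, idx = idx,
    method = "gee"
  ), class = "gee_fit")
  pieces <- gee_pieces(fit)
  fit$naive_cov <- pieces$naive
  fit$robust_cov <- robust_sandwich(fit, pieces)
  fit$wl_cov <- tryCatch(small_sample_covariance(fit, pieces),
                         error = function(e) fit$robust_cov)
  fit
}

#' @export
print.gee_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("gee_fit: not converged\n")
    return(invisible(x))
  }
  cat(sprintf("gee_fit: phi = %.4g, rho = %.4g (exchangeable), %d iterations\n",
              x$phi, x$rho, x$n_iter))
  invisible(x)
}

## Per-subject D_i, V_i^-1 D_i, residuals, bread, and naive covariance.
gee_pieces <- function(fit) {
  p <- ncol(fit$X)
  B <- matrix(0, p, p)
  sub <- lapply(fit$idx, function(ix) {
    ni <- length(ix)
    Xi <- fit$X[ix, , drop = FALSE]
    mui <- fit$mu[ix]
    Di <- Xi * mui
    sm <- sqrt(mui)
    Eh <- sweep(Di, 1, sm, "/")
    if (ni > 1 && fit$rho != 0) {
      cfac <- fit$rho / ((1 - fit$rho) * (1 + (ni - 1) * fit$rho))
      VinvD <- Eh / (1 - fit$rho) - cfac * matrix(colSums(Eh), ni, p, byrow = TRUE)
    } else VinvD <- Eh
    VinvD <- sweep(VinvD, 1, sm, "/") / fit$phi
    list(Di = Di, VinvD = VinvD, e = fit$y[ix] - mui, mu = mui, ni = ni)
  })
  for (s in sub) B <- B + crossprod(s$Di, s$VinvD)
  Binv <- solve(B)
  list(sub = sub, B = B, Binv = Binv, naive = Binv)
}

#' Robust (sandwich) covariance of GEE coefficients
#'
#' A^-1 M A^-1 with bread A = sum_i D_i' V_i^-1 D_i and meat
#' M = sum_i D_i' V_i^-1 e_i e_i' V_i^-1 D_i over subjects.
#'
#' @param fit A converged `gee_fit`.
#' @param pieces Internal per-subject pieces (recomputed when omitted).
#' @return Robust covariance matrix of the coefficients.
#' @export
robust_sandwich <- function(fit, pieces = NULL) {
  if (!isTRUE(fit$converged)) stop("robust_sandwich requires a converged fit")
  if (is.null(pieces)) pieces <- gee_pieces(fit)
  p <- ncol(fit$X)
  M <- matrix(0, p, p)
  for (s in pieces$sub) {
    u <- as.vector(crossprod(s$VinvD, s$e))
    M <- M + tcrossprod(u)
  }
  V <- pieces$Binv %*% M %*% pieces$Binv
  (V + t(V)) / 2
}

#' Small-sample corrected GEE covariance (Wang-Long)
#'
#' Implements the bias-corrected sandwich estimator of Wang and Long (2011):
#' each subject's residual cross-product is replaced by a covariance pooled
#' across all subjects (on the standardized scale), and each contribution is
#' first inflated by the leverage adjustment (I - H_i)^-1 with
#' H_i = D_i A^-1 D_i' V_i^-1. Pooling requires equal cluster sizes; a
#' subject with singular (I - H_i) falls back to its uncorrected residual
#' with a warning.
#'
#' @param fit A converged `gee_fit` with at least 3 subjects.
#' @param pieces Internal per-subject pieces (recomputed when omitted).
#' @return Corrected covariance matrix (symmetric PSD).
#' @export
small_sample_covariance <- function(fit, pieces = NULL) {
  if (!isTRUE(fit$converged))
    stop("small_sample_covariance requires a converged fit")
  if (is.null(pieces)) pieces <- gee_pieces(fit)
  sub <- pieces$sub
  K <- length(sub)
  if (K < 3) stop("the small-sample correction requires at least 3 subjects")
  ni <- vapply(sub, `[[`, numeric(1), "ni")
  if (length(unique(ni)) != 1)
    stop("the pooled small-sample correction requires equal cluster sizes")
  m <- ni[1]
  p <- ncol(fit$X)
  # pooled standardized residual covariance with leverage inflation
  Sig <- matrix(0, m, m)
  for (s in sub) {
    Hi <- s$Di %*% pieces$Binv %*% t(s$VinvD)   # D A^-1 (V^-1 D)' = H_i
    ei <- tryCatch(solve(diag(m) - Hi, s$e), error = function(e) NULL)
    if (is.null(ei)) {
      warning("(I - H_i) singular for a subject; using its uncorrected residual")
      ei <- s$e
    }
    Sig <- Sig + tcrossprod(ei / sqrt(s$mu))
  }
  Sig <- Sig / K
  M <- matrix(0, p, p)
  for (s in sub) {
    G <- sweep(s$VinvD, 1, sqrt(s$mu), "*")     # D' V^-1 A^{1/2}, transposed
    M <- M + t(G) %*% Sig %*% G
  }
  V <- pieces$Binv %*% M %*% pieces$Binv
  (V + t(V)) / 2
}
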