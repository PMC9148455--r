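#' Median-of-ratios size factors
#'
#' Computes per-sample size factors by the median-ratio method: each sample's
#' counts are divided by the per-gene geometric mean over samples, and the
#' size factor is the median of those ratios over reference genes (genes with
#' no zero count). By default the factors are rescaled so their geometric
#' mean is 1.
#'
#' @param counts A [count_matrix()] or plain matrix.
#' @param rescale_geomean Rescale so the geometric mean of the factors is 1.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
median_ratio_size_factors <- function(counts, rescale_geomean = TRUE) {
  cm <- as_count_matrix(counts)
  x <- cm$counts
  log_geo <- rowMeans(log(x))            # -Inf for genes with any zero
  ref <- is.finite(log_geo)
  if (!any(ref))
    stop("no gene has all-positive counts; supply size factors computed from ",
         "a pseudo-reference instead")
  sf <- apply(x[ref, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_geo[ref])))
  if (rescale_geomean) sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, cm$sample_ids)
}

#' Counts per million
#'
#' @param counts A [count_matrix()] or plain matrix.
#' @return Matrix of CPM values (count / library size x 1e6).
#' @export
cpm_matrix <- function(counts) {
  cm <- as_count_matrix(counts)
  if (any(cm$library_sizes <= 0)) stop("zero library size")
  sweep(cm$counts, 2, cm$library_sizes, "/") * 1e6
}

#' Fit a mean-dispersion trend
#'
#' Estimates per-gene NB dispersions by method of moments on size-factor
#' normalized counts, alpha_g = (var - mean) / mean^2, and fits the trend
#' alpha(mu) = a0 + a1/mu by robust regression on 1/mean. Negative fitted
#' components are clipped to a small positive floor so the downstream
#' variance-stabilizing transform is always defined.
#'
#' @param counts A [count_matrix()] or plain matrix.
#' @param size_factors Per-sample size factors (default: median-of-ratios).
#' @return A list of class `dispersion_trend` with elements `a0`, `a1`, and
#'   the per-gene `mean` / `dispersion` estimates used in the fit.
#' @export
fit_dispersion_trend <- function(counts, size_factors = NULL) {
  cm <- as_count_matrix(counts)
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(cm)
  norm <- sweep(cm$counts, 2, size_factors, "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  ok <- is.finite(m) & m > 0 & is.finite(v)
  m <- m[ok]
  disp <- (v[ok] - m) / m^2
  if (all(disp <= 0)) {
    warning("all moment dispersion estimates <= 0; returning a near-Poisson trend")
    return(structure(list(a0 = 1e-4, a1 = 0, mean = m, dispersion = disp),
                     class = "dispersion_trend"))
  }
  fit <- tryCatch(MASS::rlm(disp ~ I(1 / m), maxit = 100),
                  error = function(e) stats::lm(disp ~ I(1 / m)))
  co <- stats::coef(fit)
  structure(list(a0 = max(co[1], 1e-4), a1 = max(co[2], 0),
                 mean = m, dispersion = disp),
            class = "dispersion_trend")
}

#' @export
print.dispersion_trend <- function(x, ...) {
  cat(sprintf("dispersion_trend: alpha(mu) = %.4g + %.4g/mu  (%d genes)\n",
              x$a0, x$a1, length(x$mean)))
  invisible(x)
}

## Closed-form VST core under the trend alpha(mu) = a0 + a1/mu:
## Var(mu) = (1 + a1) mu + a0 mu^2, and the antiderivative of 1/sqrt(Var) is
## (2/sqrt(a0)) asinh(sqrt(a0 x / (1 + a1))).
vst_core <- function(x, a0, a1) {
  (2 / sqrt(a0)) * asinh(sqrt(a0 * x / (1 + a1)))
}

#' Variance-stabilizing transformation of counts
#'
#' Applies the closed-form variance-stabilizing transform implied by the
#' fitted dispersion trend alpha(mu) = a0 + a1/mu to size-factor normalized
#' counts: the transform integrates 1/sqrt(v(mu)) with
#' v(mu) = (1 + a1) mu + a0 mu^2, is monotone increasing, and on the default
#' `scale = "log2"` is affinely calibrated so that large counts map to
#' approximately log2(normalized count). `scale = "integral"` returns the raw
#' antiderivative (useful for checking against numeric quadrature), and
#' `transform = "log2"` falls back to log2(normalized + 0.5) without using
#' the trend.
#'
#' @param counts A [count_matrix()] or plain matrix.
#' @param size_factors Per-sample size factors (default: median-of-ratios).
#' @param trend A `dispersion_trend` (default: fitted from the data).
#' @param transform `"vst"` (default) or `"log2"` fallback.
#' @param scale `"log2"` calibration or raw `"integral"` scale.
#' @return Matrix of transformed values, genes x samples.
#' @export
vst_transform <- function(counts, size_factors = NULL, trend = NULL,
                          transform = c("vst", "log2"),
                          scale = c("log2", "integral")) {
  transform <- match.arg(transform)
  scale <- match.arg(scale)
  cm <- as_count_matrix(counts)
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(cm)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  norm <- sweep(cm$counts, 2, size_factors, "/")
  if (transform == "log2") return(log2(norm + 0.5))
  if (is.null(trend)) trend <- fit_dispersion_trend(cm, size_factors)
  a0 <- trend$a0
  a1 <- trend$a1
  out <- vst_core(norm, a0, a1)
  if (scale == "log2") {
    # large-x behaviour of the core is (1/sqrt(a0)) log(4 a0 x / (1+a1)); an
    # affine map turns that into log2(x)
    out <- out * sqrt(a0) / log(2) - log2(4 * a0 / (1 + a1))
  }
  out
}
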