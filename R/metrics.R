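#' Input-reconstruction Pearson correlations
#'
#' The shared accuracy measure for VAE and LFA: the Pearson correlation
#' between observed and reconstructed item scores, computed per item
#' (`axis = "variable"`, one value per column) or per respondent
#' (`axis = "sample"`, one value per row). Missing cells are excluded from
#' every correlation; a correlation with fewer than 3 paired observations
#' or against a constant vector is 0.
#'
#' @param x observed N x M matrix (or `standardized_matrix`).
#' @param v reconstructed N x M matrix.
#' @param mask N x M logical observation mask (taken from `x` when it is a
#'   `standardized_matrix`).
#' @param axis `"variable"` or `"sample"`.
#' @return object of class `correlation_profile`: `values`, `axis`, `mean`,
#'   `sd` (the mean/SD pair used in "mean (SD)" summary tables).
#' @export
reconstruction_correlation <- function(x, v, mask = NULL,
                                       axis = c("variable", "sample")) {
  axis <- match.arg(axis)
  if (inherits(x, "standardized_matrix")) {
    if (is.null(mask)) mask <- x$missing_mask
    x <- x$x
  }
  v <- as.matrix(v)
  stopifnot(all(dim(x) == dim(v)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  vals <- if (axis == "variable") {
    vapply(seq_len(ncol(x)), function(m) {
      obs <- mask[, m]
      safe_cor(x[obs, m], v[obs, m])
    }, 0)
  } else {
    vapply(seq_len(nrow(x)), function(n) {
      obs <- mask[n, ]
      safe_cor(x[n, obs], v[n, obs])
    }, 0)
  }
  structure(list(values = vals, axis = axis, mean = mean(vals),
                 sd = stats::sd(vals)),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("%s-wise input-reconstruction correlation: %.3f (%.3f), n = %d\n",
              x$axis, x$mean, x$sd, length(x$values)))
  invisible(x)
}

#' Per-item R-squared of a reconstruction
#'
#' `R2_m = 1 - Var(x_m - v_m) / Var(x_m)` over observed cells: one minus
#' the error variance divided by the sample variance. The VAE-side analogue
#' of LFA communality (explained variance per item).
#'
#' @inheritParams reconstruction_correlation
#' @return M-vector of R-squared values.
#' @export
reconstruction_r2 <- function(x, v, mask = NULL) {
  if (inherits(x, "standardized_matrix")) {
    if (is.null(mask)) mask <- x$missing_mask
    x <- x$x
  }
  v <- as.matrix(v)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  vapply(seq_len(ncol(x)), function(m) {
    obs <- mask[, m]
    xm <- x[obs, m]; vm <- v[obs, m]
    if (length(xm) < 3 || stats::var(xm) == 0) {
      warning("degenerate item ", m, "; R2 set to 0")
      return(0)
    }
    1 - stats::var(xm - vm) / stats::var(xm)
  }, 0)
}

#' Correlation-based VAE loadings
#'
#' The VAE analogue of factor loadings: the Pearson correlation of each
#' latent factor's posterior-mean vector with each *reconstructed* item
#' over respondents (the reconstruction is used because decoding the
#' posterior means has removed observation noise). Computed on training
#' respondents in the standard pipeline. A collapsed factor (constant
#' posterior mean) gets zero loadings and is flagged.
#'
#' @param ps posterior stats from [vae_encode()] (needs `mu`), or a bare
#'   N x d matrix of posterior means.
#' @param v N x M reconstruction from [vae_reconstruct()].
#' @param item_ids optional item labels.
#' @return a [loading_matrix()] with `source = "vae"` and attribute
#'   `"collapsed"` (logical per factor).
#' @export
vae_loadings <- function(ps, v, item_ids = colnames(v)) {
  mu <- if (is.list(ps)) ps$mu else as.matrix(ps)
  v <- as.matrix(v)
  stopifnot(nrow(mu) == nrow(v))
  d <- ncol(mu); M <- ncol(v)
  collapsed <- vapply(seq_len(d), function(i) stats::sd(mu[, i]) < 1e-10,
                      logical(1))
  L <- matrix(0, M, d)
  for (i in seq_len(d)) {
    if (collapsed[i]) next
    for (m in seq_len(M)) L[m, i] <- safe_cor(mu[, i], v[, m])
  }
  out <- loading_matrix(L, rotation = "none", source = "vae",
                        item_ids = item_ids, sign_normalize = FALSE)
  attr(out, "collapsed") <- collapsed
  out
}
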