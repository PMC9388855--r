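#' Items-by-factors loading matrix
#'
#' Shared container for LFA loadings (principal-axis solution) and VAE
#' loadings (correlations between posterior factor means and reconstructed
#' items). Columns are sign-normalised so each factor's largest-|loading|
#' entry is positive, which makes multi-run reports reproducible.
#'
#' @param loadings M x d numeric matrix.
#' @param rotation `"none"` or `"varimax"`.
#' @param source `"lfa"` or `"vae"`.
#' @param item_ids item labels; `factor_labels` factor labels.
#' @param sign_normalize flip each column so its largest-|value| entry is
#'   positive (default TRUE).
#' @return an object of class `loading_matrix`.
#' @export
loading_matrix <- function(loadings, rotation = c("none", "varimax"),
                           source = c("lfa", "vae"),
                           item_ids = rownames(loadings),
                           factor_labels = colnames(loadings),
                           sign_normalize = TRUE) {
  loadings <- as.matrix(loadings)
  rotation <- match.arg(rotation)
  source <- match.arg(source)
  if (is.null(item_ids)) item_ids <- sprintf("item%02d", seq_len(nrow(loadings)))
  if (is.null(factor_labels)) factor_labels <- sprintf("F%d", seq_len(ncol(loadings)))
  if (sign_normalize) {
    for (j in seq_len(ncol(loadings))) {
      col <- loadings[, j]
      if (any(col != 0) && col[which.max(abs(col))] < 0) loadings[, j] <- -col
    }
  }
  dimnames(loadings) <- list(item_ids, factor_labels)
  structure(list(loadings = loadings, rotation = rotation, source = source,
                 item_ids = as.character(item_ids),
                 factor_labels = as.character(factor_labels)),
            class = "loading_matrix")
}

#' @export
print.loading_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("loading_matrix (%s, rotation: %s): %d items x %d factors\n",
              x$source, x$rotation, nrow(x$loadings), ncol(x$loadings)))
  print(round(utils::head(x$loadings, 10), digits))
  if (nrow(x$loadings) > 10) cat("...\n")
  invisible(x)
}

#' Per-item communalities
#'
#' The share of an item's (unit) variance explained by the common factors:
#' the row sum of squared loadings, invariant under orthogonal rotation.
#'
#' @param lm a [loading_matrix()].
#' @return M-vector of h^2 values.
#' @export
communalities <- function(lm) {
  stopifnot(inherits(lm, "loading_matrix"))
  rowSums(lm$loadings^2)
}

# Pearson correlation matrix of the standardized (0-imputed) item matrix,
# matching the preprocessing order used throughout: impute, then correlate.
item_correlation <- function(sm) {
  stopifnot(inherits(sm, "standardized_matrix"))
  R <- stats::cor(sm$x)
  if (any(!is.finite(R))) stop("non-finite item correlations (constant item?)")
  R
}

#' Eigenvalue spectrum of the item correlation matrix
#'
#' The scree-plot input: eigenvalues in descending order plus the count of
#' eigenvalues above 1 (the Kaiser retention rule).
#'
#' @param sm a `standardized_matrix`.
#' @return an object of class `eigen_spectrum` with fields `eigenvalues` and
#'   `n_gt_one`.
#' @export
eigen_spectrum <- function(sm) {
  R <- item_correlation(sm)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  structure(list(eigenvalues = ev, n_gt_one = sum(ev > 1)),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat(sprintf("eigen_spectrum: %d eigenvalues, %d greater than 1\n",
              length(x$eigenvalues), x$n_gt_one))
  invisible(x)
}

#' Principal-axis factor extraction
#'
#' Iterated principal-axis factoring: the correlation matrix with current
#' communalities on its diagonal is eigen-decomposed, loadings are the top-d
#' eigenvectors scaled by the square roots of their eigenvalues, and the
#' implied communalities are fed back until they stabilise. Initial
#' communalities are squared multiple correlations.
#'
#' @param sm a `standardized_matrix`.
#' @param d number of factors, `1 <= d < M`.
#' @param tol convergence tolerance on the max absolute communality change.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   last change.
#' @return an unrotated [loading_matrix()] with attribute `"iterations"`.
#' @export
fit_principal_factors <- function(sm, d, tol = 1e-4, max_iter = 100L) {
  R <- item_correlation(sm)
  M <- ncol(R)
  if (d < 1 || d >= M) stop("d must satisfy 1 <= d < M")
  smc <- tryCatch(1 - 1 / diag(solve(R)),
                  error = function(e) apply(abs(R - diag(M)), 1, max))
  h2 <- pmin(pmax(smc, 0), 1)
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(d)], 0)
    L <- e$vectors[, seq_len(d), drop = FALSE] %*% diag(sqrt(lam), d)
    h2_new <- rowSums(L^2)
    if (any(h2_new > 1)) {
      warning("Heywood case: communality > 1 clamped for item(s) ",
              paste(sm$item_ids[h2_new > 1], collapse = ", "))
      h2_new <- pmin(h2_new, 1)
    }
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) {
      out <- loading_matrix(L, rotation = "none", source = "lfa",
                            item_ids = sm$item_ids)
      attr(out, "iterations") <- it
      return(out)
    }
  }
  stop(sprintf("principal-axis iteration did not converge in %d iterations (last max communality change %.3g)",
               max_iter, delta))
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximising the variance of squared loadings per
#' factor (Kaiser-normalised), which drives the solution toward simple
#' structure. Communalities are preserved exactly. A single-factor matrix is
#' returned unchanged.
#'
#' @param lm a [loading_matrix()].
#' @return the rotated [loading_matrix()] (sign-normalised).
#' @export
rotate_varimax <- function(lm) {
  stopifnot(inherits(lm, "loading_matrix"))
  if (ncol(lm$loadings) < 2) {
    out <- lm
    out$rotation <- "varimax"
    return(out)
  }
  rot <- stats::varimax(lm$loadings, normalize = TRUE, eps = 1e-8)
  loading_matrix(unclass(rot$loadings), rotation = "varimax",
                 source = lm$source, item_ids = lm$item_ids,
                 factor_labels = lm$factor_labels)
}

#' Factor scores by the Thurstone or Bartlett estimator
#'
#' Thurstone (regression) scores use weights `W = R^-1 L`; Bartlett
#' (weighted least squares) scores use `W = Psi^-1 L (L' Psi^-1 L)^-1` with
#' `Psi = diag(1 - h^2)` floored at `ridge` to survive (near-)Heywood items.
#'
#' @param sm a `standardized_matrix` over the same items the loadings were
#'   fitted on.
#' @param lm a [loading_matrix()].
#' @param method `"thurstone"` or `"bartlett"`.
#' @param R optional item correlation matrix (Thurstone); defaults to the
#'   correlation of `sm` itself. Pass the training-set correlation when
#'   scoring held-out respondents.
#' @param ridge lower floor for unique variances / ridge for a singular R.
#' @return an object of class `factor_scores` with fields `z` (N x d) and
#'   `method`.
#' @export
factor_scores <- function(sm, lm, method = c("thurstone", "bartlett"),
                          R = NULL, ridge = 1e-6) {
  stopifnot(inherits(sm, "standardized_matrix"), inherits(lm, "loading_matrix"))
  method <- match.arg(method)
  if (!identical(sm$item_ids, lm$item_ids)) {
    stop("loading matrix and data have different items")
  }
  L <- lm$loadings
  if (method == "thurstone") {
    if (is.null(R)) R <- item_correlation(sm)
    W <- tryCatch(solve(R, L), error = function(e) {
      solve(R + ridge * diag(ncol(R)), L)
    })
  } else {
    psi <- pmax(1 - communalities(lm), ridge)
    Lp <- L / psi
    W <- Lp %*% solve(crossprod(L, Lp))
  }
  z <- sm$x %*% W
  if (any(!is.finite(z))) stop("non-finite factor scores")
  colnames(z) <- lm$factor_labels
  structure(list(z = z, method = method, factor_labels = lm$factor_labels),
            class = "factor_scores")
}

#' Linear reconstruction of item scores from factor scores
#'
#' Under the common-factor model x = Lz + unique parts, the model-implied
#' reconstruction (unique parts having zero mean) is `v = z L'`.
#'
#' @param fs a [factor_scores()] (or a bare N x d matrix).
#' @param lm a [loading_matrix()].
#' @return N x M reconstructed matrix.
#' @export
reconstruct_lfa <- function(fs, lm) {
  z <- if (inherits(fs, "factor_scores")) fs$z else as.matrix(fs)
  stopifnot(inherits(lm, "loading_matrix"), ncol(z) == ncol(lm$loadings))
  v <- z %*% t(lm$loadings)
  colnames(v) <- lm$item_ids
  v
}

#' Correlation loadings from factor scores
#'
#' Loadings defined as the Pearson correlation between each factor's score
#' vector and each observed item over respondents — the same definition used
#' for VAE loadings, here applied to the linear baseline.
#'
#' @param fs a [factor_scores()].
#' @param sm the `standardized_matrix` the scores were computed from.
#' @return a [loading_matrix()] with `source = "lfa"`.
#' @export
lfa_loadings_from_scores <- function(fs, sm) {
  stopifnot(inherits(fs, "factor_scores"), inherits(sm, "standardized_matrix"))
  d <- ncol(fs$z); M <- ncol(sm$x)
  L <- matrix(0, M, d)
  for (i in seq_len(d)) {
    for (m in seq_len(M)) {
      obs <- sm$missing_mask[, m]
      L[m, i] <- safe_cor(fs$z[obs, i], sm$x[obs, m])
    }
  }
  loading_matrix(L, rotation = "none", source = "lfa", item_ids = sm$item_ids,
                 factor_labels = fs$factor_labels, sign_normalize = FALSE)
}

#' Brute-force optimal matching of two loading matrices
#'
#' Enumeration oracle: finds the column permutation (and signs) of `B`
#' maximising the mean |congruence| with the columns of `A`. Intended for
#' small d (<= 7) as an independent check of recovery and clustering.
#'
#' @param A,B M x d loading matrices (bare matrices or [loading_matrix()]).
#' @return list with `permutation`, `signs`, `congruences` (per matched
#'   pair, after sign alignment) and `mean_congruence`.
#' @export
match_factors <- function(A, B) {
  if (inherits(A, "loading_matrix")) A <- A$loadings
  if (inherits(B, "loading_matrix")) B <- B$loadings
  d <- ncol(A)
  stopifnot(ncol(B) == d, nrow(A) == nrow(B))
  C <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) C[i, j] <- safe_cor(A[, i], B[, j])
  best <- NULL; best_val <- -Inf
  for (p in all_permutations(d)) {
    val <- mean(abs(C[cbind(seq_len(d), p)]))
    if (val > best_val) { best_val <- val; best <- p }
  }
  cong <- C[cbind(seq_len(d), best)]
  list(permutation = unlist(best), signs = ifelse(cong >= 0, 1, -1),
       congruences = abs(cong), mean_congruence = best_val)
}
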