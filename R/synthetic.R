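#' Specification of a synthetic questionnaire dataset
#'
#' Describes a latent-factor generative model for questionnaire-like data:
#' independent standard-normal latent factors, block-structured loadings, a
#' linear or saturating (tanh) link per item, additive Gaussian noise,
#' optional Likert discretisation and uniformly random missing cells.
#'
#' @param n_samples number of respondents N.
#' @param n_items number of items M (ignored when `loadings` is given).
#' @param d_true number of latent factors.
#' @param loadings optional explicit M x d_true loading matrix; when omitted a
#'   block structure is built: items are divided into `d_true` near-equal
#'   contiguous blocks and each item loads `loading_strength` on its block's
#'   factor and 0 elsewhere.
#' @param blocks optional integer vector of length M mapping items to factors
#'   (used only when `loadings` is NULL).
#' @param link `"linear"` (x = Lz + e), `"saturating"`
#'   (x_m = a_m tanh(l_m'z) + e with gain a_m setting the pre-noise variance
#'   to 1) or `"mixed"` (blocks alternate linear/saturating).
#' @param loading_strength on-block loading when `loadings` is NULL.
#' @param noise_sd per-item Gaussian noise SD.
#' @param likert_levels `NULL` for continuous scores, or an integer >= 2 for
#'   discretisation into equal-probability bins `1..likert_levels`.
#' @param missing_rate probability in `[0, 1)` that a cell is missing (MCAR).
#' @param seed integer seed; the dataset is a pure function of the spec.
#' @return an object of class `questionnaire_spec`.
#' @export
questionnaire_spec <- function(n_samples, n_items = NULL, d_true,
                               loadings = NULL, blocks = NULL,
                               link = c("linear", "saturating", "mixed"),
                               loading_strength = 0.8, noise_sd = 0.6,
                               likert_levels = NULL, missing_rate = 0,
                               seed = 1L) {
  link <- match.arg(link)
  if (is.null(loadings)) {
    if (is.null(n_items)) stop("either n_items or loadings must be given")
    if (is.null(blocks)) {
      blocks <- sort(rep_len(seq_len(d_true), n_items))
    }
    if (length(blocks) != n_items) stop("blocks must have length n_items")
    if (!all(seq_len(d_true) %in% blocks)) {
      stop("every factor must own at least one item")
    }
    loadings <- matrix(0, n_items, d_true)
    loadings[cbind(seq_len(n_items), blocks)] <- loading_strength
  } else {
    loadings <- as.matrix(loadings)
    n_items <- nrow(loadings)
    if (ncol(loadings) != d_true) stop("loadings must have d_true columns")
    if (is.null(blocks)) blocks <- max.col(abs(loadings))
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!is.null(likert_levels) && likert_levels < 2) {
    stop("likert_levels must be >= 2 or NULL")
  }
  structure(list(n_samples = as.integer(n_samples), n_items = as.integer(n_items),
                 d_true = as.integer(d_true), loadings = loadings,
                 blocks = as.integer(blocks), link = link,
                 loading_strength = loading_strength, noise_sd = noise_sd,
                 likert_levels = likert_levels, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "questionnaire_spec")
}

#' Generate a synthetic questionnaire dataset with known latent structure
#'
#' Draws latent factors z ~ N(0, I), maps them through the spec's link
#' functions, adds item noise, optionally discretises to Likert categories
#' and removes cells at random. Fully reproducible from the spec's seed.
#'
#' @param spec a [questionnaire_spec()].
#' @return a list with `responses` (a [response_matrix()]) and `truth`
#'   (latent scores `z`, the loading matrix, item blocks, the pre-noise
#'   systematic part, and the per-item tanh gains for saturating links).
#' @export
simulate_questionnaire <- function(spec) {
  stopifnot(inherits(spec, "questionnaire_spec"))
  N <- spec$n_samples; M <- spec$n_items; d <- spec$d_true
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(N * d), N, d)
  u <- z %*% t(spec$loadings)
  item_link <- switch(spec$link,
    linear = rep("linear", M),
    saturating = rep("saturating", M),
    mixed = c("linear", "saturating")[1 + spec$blocks %% 2])
  gains <- rep(NA_real_, M)
  sys <- u
  for (m in seq_len(M)) {
    if (item_link[m] == "saturating") {
      tm <- tanh(u[, m])
      s <- sqrt(mean((tm - mean(tm))^2))
      gains[m] <- if (s > 0) 1 / s else 1
      sys[, m] <- gains[m] * tm
    }
  }
  x <- sys + spec$noise_sd * matrix(stats::rnorm(N * M), N, M)
  if (!is.null(spec$likert_levels)) {
    K <- spec$likert_levels
    for (m in seq_len(M)) {
      mu <- mean(x[, m]); s <- sqrt(mean((x[, m] - mu)^2))
      br <- stats::qnorm(seq(0, 1, length.out = K + 1), mean = mu,
                         sd = if (s > 0) s else 1)
      x[, m] <- as.numeric(cut(x[, m], breaks = br, labels = FALSE,
                               include.lowest = TRUE))
    }
  }
  mask <- matrix(TRUE, N, M)
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(N * M) >= spec$missing_rate, N, M)
  }
  x[!mask] <- NA_real_
  item_ids <- sprintf("item%02d", seq_len(M))
  rm <- response_matrix(x, item_ids = item_ids,
                        respondent_ids = sprintf("s%05d", seq_len(N)))
  list(responses = rm,
       truth = list(z = z, loadings = spec$loadings, blocks = spec$blocks,
                    systematic = sys, link = item_link, gains = gains))
}

#' Block loading matrix with discrimination heterogeneity
#'
#' Builds an items-by-factors loading matrix with disjoint blocks in which
#' items differ in strength the way real questionnaire items differ in
#' discrimination/extremity: the first few items of every block are strong
#' "anchor" items (under a saturating link they are the extreme statements
#' that saturate hard) and the rest load mildly. Used as the package's
#' standard nonlinear study condition.
#'
#' @param sizes integer vector of block sizes (one block per factor).
#' @param anchor_strengths loadings given to the first items of each block.
#' @param mild_range range the remaining loadings are drawn from, uniformly.
#' @param seed seed for the mild-loading draw.
#' @return list with `loadings` (M x d matrix) and `blocks` (item-to-factor
#'   map).
#' @export
block_loadings <- function(sizes, anchor_strengths = c(4.0, 2.5, 1.6),
                           mild_range = c(0.3, 0.7), seed = 1L) {
  blocks <- rep(seq_along(sizes), sizes)
  M <- length(blocks)
  set.seed(as.integer(seed))
  a <- stats::runif(M, mild_range[1], mild_range[2])
  for (b in seq_along(sizes)) {
    i <- which(blocks == b)
    k <- min(length(anchor_strengths), length(i))
    a[i[seq_len(k)]] <- anchor_strengths[seq_len(k)]
  }
  L <- matrix(0, M, length(sizes))
  L[cbind(seq_len(M), blocks)] <- a
  list(loadings = L, blocks = blocks)
}

#' Best achievable input-reconstruction correlation under a linear spec
#'
#' For the linear, non-discretised generative model x_m = l_m'z + e the
#' reconstruction that any method can at best produce is E[x_m | z] = l_m'z,
#' whose correlation with x_m is the attenuation factor
#' r*_m = sqrt(||l_m||^2 / (||l_m||^2 + noise_sd^2)).
#'
#' @param spec a [questionnaire_spec()] with `link = "linear"` and no Likert
#'   discretisation.
#' @return per-item vector of maximal correlations.
#' @export
oracle_reconstruction_correlation <- function(spec) {
  stopifnot(inherits(spec, "questionnaire_spec"))
  if (spec$link != "linear" || !is.null(spec$likert_levels)) {
    stop("the closed-form oracle supports only linear, non-discretised specs")
  }
  h <- rowSums(spec$loadings^2)
  ifelse(h == 0, 0, sqrt(h / (h + spec$noise_sd^2)))
}
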