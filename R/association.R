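#' Correlation reduction from muting one latent factor
#'
#' The muting probe for factor-variable association: reconstruct once from
#' the full posterior means, then zero the investigated factor's
#' posterior-mean column and reconstruct again. The per-item reduction is
#' the variable-wise input-reconstruction correlation before muting minus
#' the correlation after muting; items whose reconstruction depends on the
#' factor lose correlation. Decoding is deterministic (no sampling), and a
#' constant reconstructed column correlates 0 by convention.
#'
#' @param p a `vae_model` or `vae_params`.
#' @param sm a `standardized_matrix` (the test set in the standard
#'   pipeline).
#' @param factor index of the latent factor to mute.
#' @param e optional precomputed [vae_encode()] result for `sm`.
#' @param before optional precomputed baseline correlation vector.
#' @return M-vector of correlation reductions.
#' @export
mute_factor_reduction <- function(p, sm, factor, e = NULL, before = NULL) {
  d <- as_vae_params(p)$arch$n_latent
  if (factor < 1 || factor > d) stop("factor index out of range")
  if (is.null(e)) e <- vae_encode(p, sm)
  if (is.null(before)) {
    before <- reconstruction_correlation(sm, vae_decode(p, e$mu))$values
  }
  mu_muted <- e$mu
  mu_muted[, factor] <- 0
  after <- reconstruction_correlation(sm, vae_decode(p, mu_muted))$values
  before - after
}

#' Noise-factor classification rule
#'
#' A factor is noise-like when its maximum correlation reduction is below
#' `max_reduction` *and* fewer than `min_items` items reach the per-item
#' association threshold. Both conditions are required.
#'
#' @param reductions M-vector from [mute_factor_reduction()].
#' @param max_reduction ceiling on the largest reduction (default 0.1).
#' @param min_items minimum associated-item count of a real factor
#'   (default 5).
#' @param item_threshold per-item association cutoff (default 0.1).
#' @return TRUE when the factor is noise-like.
#' @export
is_noise_factor <- function(reductions, max_reduction = 0.1, min_items = 5L,
                            item_threshold = 0.1) {
  max(reductions) < max_reduction &&
    sum(reductions >= item_threshold) < min_items
}

#' Factor-variable association profile
#'
#' Runs the muting probe for every latent factor, lists each factor's
#' associated items (reduction at or above `item_threshold`) in descending
#' reduction order (ties broken by item order), and attaches the noise-like
#' classification.
#'
#' @param p a `vae_model` or `vae_params`.
#' @param sm a `standardized_matrix`.
#' @param item_threshold per-item association cutoff.
#' @param max_reduction,min_items noise-rule parameters, see
#'   [is_noise_factor()].
#' @return object of class `association_profile`: `reductions` (d x M),
#'   `associated` (list of per-factor item-id vectors, sorted), `noise`
#'   (logical per factor), `item_threshold`, `table` (long-format data frame
#'   of factor / item / reduction rows for reporting).
#' @export
association_profile <- function(p, sm, item_threshold = 0.1,
                                max_reduction = 0.1, min_items = 5L) {
  pp <- as_vae_params(p)
  d <- pp$arch$n_latent
  e <- vae_encode(pp, sm)
  before <- reconstruction_correlation(sm, vae_decode(pp, e$mu))$values
  red <- matrix(0, d, ncol(sm$x),
                dimnames = list(sprintf("F%d", seq_len(d)), sm$item_ids))
  for (f in seq_len(d)) {
    red[f, ] <- mute_factor_reduction(pp, sm, f, e = e, before = before)
  }
  associated <- lapply(seq_len(d), function(f) {
    sel <- which(red[f, ] >= item_threshold)
    sel <- sel[order(-red[f, sel], sel)]
    sm$item_ids[sel]
  })
  noise <- vapply(seq_len(d), function(f) {
    is_noise_factor(red[f, ], max_reduction, min_items, item_threshold)
  }, logical(1))
  tab <- do.call(rbind, lapply(seq_len(d), function(f) {
    ord <- order(-red[f, ], seq_len(ncol(red)))
    data.frame(factor = sprintf("F%d", f), item = sm$item_ids[ord],
               reduction = red[f, ord], noise_factor = noise[f],
               row.names = NULL)
  }))
  structure(list(reductions = red, associated = associated, noise = noise,
                 item_threshold = item_threshold, table = tab,
                 baseline_correlation = before),
            class = "association_profile")
}

#' @export
print.association_profile <- function(x, ...) {
  d <- nrow(x$reductions)
  cat(sprintf("association_profile: %d factors (%d noise-like), item threshold %.2f\n",
              d, sum(x$noise), x$item_threshold))
  for (f in seq_len(d)) {
    cat(sprintf("  F%d%s: %s\n", f, if (x$noise[f]) " [noise]" else "",
                paste(utils::head(x$associated[[f]], 8), collapse = " ")))
  }
  invisible(x)
}

#' Significant factor limit search (SFLS)
#'
#' Chooses the number of latent factors by widening the bottleneck along a
#' grid and counting the significant (non-noise; when `R > 1` also stable)
#' factors each width produces. The recommendation is the smallest grid
#' point whose count equals the count at every larger grid point — the
#' start of the plateau where adding capacity only adds noise-like factors.
#'
#' @param pool_rm training-pool [response_matrix()] (test respondents held
#'   out).
#' @param test_sm `standardized_matrix` of the test respondents (used for
#'   the association probe).
#' @param d_grid strictly increasing vector of bottleneck widths.
#' @param config a [vae_config()].
#' @param hidden_sizes hidden layout passed to [vae_architecture()]; the
#'   default doubles the item count.
#' @param R runs per grid point; with `R > 1` a factor must additionally be
#'   stable across runs (via the congruence clustering) to count.
#' @param val_frac validation fraction of the pool.
#' @param item_threshold,max_reduction,min_items association/noise
#'   parameters.
#' @param threshold_start,threshold_step congruence-threshold grid (used
#'   when `R > 1`).
#' @return object of class `sfls_result`: `d_grid`, `counts`,
#'   `mean_correlation` (test-set variable-wise mean per d),
#'   `recommended_d`, `plateau_count`, `inconclusive`, `degenerate` flags,
#'   and the per-d `profiles`.
#' @export
sfls <- function(pool_rm, test_sm, d_grid, config = vae_config(),
                 hidden_sizes = NULL, R = 1L, val_frac = 0.2,
                 item_threshold = 0.1, max_reduction = 0.1, min_items = 5L,
                 threshold_start = 0.85, threshold_step = 0.005) {
  stopifnot(inherits(pool_rm, "response_matrix"), length(d_grid) >= 1,
            all(diff(d_grid) > 0))
  M <- ncol(pool_rm$scores)
  if (is.null(hidden_sizes)) hidden_sizes <- 2L * M
  counts <- integer(length(d_grid))
  mean_corr <- numeric(length(d_grid))
  profiles <- vector("list", length(d_grid))
  for (k in seq_along(d_grid)) {
    d <- d_grid[k]
    arch <- vae_architecture(M, d, hidden_sizes)
    if (R > 1) {
      runs <- fit_vae_runs(pool_rm, arch, config, R = R, val_frac = val_frac)
      cm <- build_congruence_matrix(runs$loadings)
      thr <- search_congruence_threshold(cm, threshold_start, threshold_step,
                                         seed = config$seed)
      cl <- cluster_factors(cm, thr, seed = config$seed)
      prof <- association_profile(runs$models[[1]], test_sm, item_threshold,
                                  max_reduction, min_items)
      stable_first_run <- unlist(lapply(cl$clusters[cl$stable], function(x) {
        x$factor[x$run == 1]
      }))
      counts[k] <- sum(!prof$noise[stable_first_run])
      model_for_corr <- runs$models[[1]]
    } else {
      cfg <- config
      cfg$seed <- fan_seed(config$seed, 1000L + d)
      set.seed(cfg$seed)
      sp <- local({
        perm <- sample.int(nrow(pool_rm$scores))
        n_val <- max(1L, round(val_frac * length(perm)))
        list(val = sort(perm[seq_len(n_val)]), train = sort(perm[-seq_len(n_val)]))
      })
      m <- fit_vae(standardize(pool_rm[sp$train, ]),
                   standardize(pool_rm[sp$val, ]), arch, cfg)
      prof <- association_profile(m, test_sm, item_threshold,
                                  max_reduction, min_items)
      counts[k] <- sum(!prof$noise)
      model_for_corr <- m
    }
    profiles[[k]] <- prof
    mean_corr[k] <- reconstruction_correlation(
      test_sm, vae_reconstruct(model_for_corr, test_sm))$mean
  }
  # plateau: first grid point whose count matches all later counts
  plateau_idx <- length(d_grid)
  for (k in seq_along(d_grid)) {
    if (all(counts[k:length(counts)] == counts[k])) { plateau_idx <- k; break }
  }
  degenerate <- max(counts) == 0
  inconclusive <- length(d_grid) < 2 || plateau_idx == length(d_grid) ||
    degenerate
  structure(list(d_grid = d_grid, counts = counts,
                 mean_correlation = mean_corr,
                 recommended_d = if (degenerate) 0L else d_grid[plateau_idx],
                 plateau_count = if (degenerate) 0L else counts[plateau_idx],
                 inconclusive = inconclusive, degenerate = degenerate,
                 profiles = profiles),
            class = "sfls_result")
}

#' @export
print.sfls_result <- function(x, ...) {
  cat("SFLS over bottleneck widths:\n")
  print(data.frame(d = x$d_grid, significant = x$counts,
                   mean_correlation = round(x$mean_correlation, 3)))
  cat(sprintf("recommended d = %d (plateau count %d)%s\n", x$recommended_d,
              x$plateau_count,
              if (x$inconclusive) " [inconclusive]" else ""))
  invisible(x)
}
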