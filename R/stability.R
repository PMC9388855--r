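#' Congruence score between two loading vectors
#'
#' The Pearson correlation of two factors' loading vectors across items,
#' used to decide whether factors from different training runs are the same
#' factor. Constant vectors (collapsed factors) give 0.
#'
#' @param l_i,l_j loading vectors of equal length.
#' @return a correlation in `[-1, 1]`.
#' @export
factor_congruence <- function(l_i, l_j) safe_cor(l_i, l_j)

#' Collection of per-run loading matrices
#'
#' Bundles the varimax-rotated, sign-normalised loading matrices of R
#' training runs for stability analysis.
#'
#' @param runs list of [loading_matrix()] objects sharing items and d.
#' @param run_seeds optional per-run seeds (bookkeeping).
#' @return an object of class `run_collection`.
#' @export
run_collection <- function(runs, run_seeds = NULL) {
  stopifnot(length(runs) >= 2)
  ids <- runs[[1]]$item_ids; d <- ncol(runs[[1]]$loadings)
  for (r in runs) {
    stopifnot(inherits(r, "loading_matrix"))
    if (!identical(r$item_ids, ids) || ncol(r$loadings) != d) {
      stop("all runs must share item ids and factor count")
    }
  }
  structure(list(runs = runs, R = length(runs), d = d, item_ids = ids,
                 run_seeds = run_seeds),
            class = "run_collection")
}

#' Congruence matrix over all (run, factor) pairs
#'
#' All pairwise congruence scores between the dR rotated factors of an
#' R-run collection, including within-run pairs (the threshold-search
#' stopping rule watches those).
#'
#' @param rc a [run_collection()].
#' @return object of class `congruence_matrix`: `C` (dR x dR, symmetric,
#'   unit diagonal), `run` and `factor` label vectors, `threshold` (NA until
#'   one is applied).
#' @export
build_congruence_matrix <- function(rc) {
  stopifnot(inherits(rc, "run_collection"))
  stack <- do.call(cbind, lapply(rc$runs, function(r) r$loadings))
  k <- ncol(stack)
  C <- diag(1, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      C[i, j] <- C[j, i] <- safe_cor(stack[, i], stack[, j])
    }
  }
  labels <- sprintf("r%d.f%d", rep(seq_len(rc$R), each = rc$d),
                    rep(seq_len(rc$d), rc$R))
  dimnames(C) <- list(labels, labels)
  structure(list(C = C, run = rep(seq_len(rc$R), each = rc$d),
                 factor = rep(seq_len(rc$d), rc$R), R = rc$R, d = rc$d,
                 threshold = NA_real_),
            class = "congruence_matrix")
}

apply_threshold <- function(cm, threshold) {
  C <- cm$C
  C[C < threshold] <- 0
  diag(C) <- 1
  cm$C <- C
  cm$threshold <- threshold
  cm
}

#' Cluster factors across runs on the thresholded congruence graph
#'
#' Builds the weighted graph whose edges are congruence scores at or above
#' the threshold and partitions it with the Leiden algorithm (modularity
#' objective), or with connected components as a deterministic fallback.
#' Factors matched to nothing remain singletons.
#'
#' @param cm a [build_congruence_matrix()] result.
#' @param threshold congruence cutoff; entries below it are removed.
#' @param method `"leiden"` or `"components"`.
#' @param seed seed for the Leiden refinement randomness.
#' @return object of class `congruence_clusters`: a list `clusters` of data
#'   frames (columns `run`, `factor`, `node`), per-cluster `avg_congruence`
#'   and `stable` flags, plus the threshold used.
#' @export
cluster_factors <- function(cm, threshold, method = c("leiden", "components"),
                            seed = 1L) {
  stopifnot(inherits(cm, "congruence_matrix"))
  method <- match.arg(method)
  cmt <- apply_threshold(cm, threshold)
  A <- cmt$C
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  membership <- if (method == "leiden") {
    set.seed(as.integer(seed))
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = 1,
      weights = igraph::E(g)$weight, n_iterations = 5))
  } else {
    igraph::components(g)$membership
  }
  ids <- sort(unique(membership))
  clusters <- lapply(ids, function(k) {
    nodes <- which(membership == k)
    data.frame(run = cm$run[nodes], factor = cm$factor[nodes], node = nodes)
  })
  avg <- vapply(clusters, function(cl) {
    if (nrow(cl) < 2) return(NA_real_)
    pairs <- utils::combn(cl$node, 2)
    mean(cm$C[t(pairs)])
  }, 0)
  stable <- vapply(clusters, function(cl) {
    nrow(cl) == cm$R && length(unique(cl$run)) == cm$R
  }, logical(1))
  structure(list(clusters = clusters, avg_congruence = avg, stable = stable,
                 threshold = threshold, R = cm$R, d = cm$d, method = method),
            class = "congruence_clusters")
}

#' @export
print.congruence_clusters <- function(x, ...) {
  cat(sprintf("congruence_clusters: %d clusters at threshold %.3f (%d stable)\n",
              length(x$clusters), x$threshold, sum(x$stable)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d [%s%s]: %s\n", i,
                if (x$stable[i]) "stable" else "not stable",
                if (is.na(x$avg_congruence[i])) ""
                else sprintf(", avg congruence %.3f", x$avg_congruence[i]),
                paste(sprintf("r%d.f%d", cl$run, cl$factor), collapse = " ")))
  }
  invisible(x)
}

# TRUE when some cluster contains two factors of one run.
has_same_run_pair <- function(clusters) {
  any(vapply(clusters$clusters, function(cl) anyDuplicated(cl$run) > 0,
             logical(1)))
}

#' Search the congruence threshold
#'
#' Raises the threshold along the grid `start, start + step, ...` until
#' clustering the thresholded graph no longer places two factors of the
#' same run in one cluster, and returns the first such grid point. (With a
#' bottleneck wider than the number of real factors, surplus factors
#' correlate with real ones within a run; the threshold is raised until
#' those spurious within-run matches disappear.)
#'
#' @param cm a [build_congruence_matrix()] result.
#' @param start grid origin (default 0.85).
#' @param step grid spacing (default 0.005).
#' @inheritParams cluster_factors
#' @return the selected threshold.
#' @export
search_congruence_threshold <- function(cm, start = 0.85, step = 0.005,
                                        method = c("leiden", "components"),
                                        seed = 1L) {
  stopifnot(start >= 0, start < 1, step > 0)
  method <- match.arg(method)
  for (t in seq(start, 1, by = step)) {
    cl <- cluster_factors(cm, t, method = method, seed = seed)
    if (!has_same_run_pair(cl)) return(t)
  }
  stop("no threshold <= 1 separates same-run factors; the run collection is degenerate")
}

#' Report stable factors
#'
#' A factor is stable when its cluster contains exactly one factor from
#' every run. Returns the stable subset with the average within-cluster
#' congruence as the overall factor congruence.
#'
#' @param cs a [cluster_factors()] result.
#' @return data frame with one row per stable cluster: `cluster`, `size`,
#'   `avg_congruence`, and a members string.
#' @export
stable_factors <- function(cs) {
  stopifnot(inherits(cs, "congruence_clusters"))
  idx <- which(cs$stable)
  data.frame(
    cluster = idx,
    size = vapply(cs$clusters[idx], nrow, 0L),
    avg_congruence = cs$avg_congruence[idx],
    members = vapply(cs$clusters[idx], function(cl) {
      paste(sprintf("r%d.f%d", cl$run, cl$factor), collapse = " ")
    }, ""))
}

#' Consensus loading vectors of stable clusters
#'
#' For each stable cluster, sign-aligns every member's loading vector to the
#' member from the lowest-numbered run and averages them elementwise,
#' yielding one representative loading vector per stable factor.
#'
#' @param cs a [cluster_factors()] result.
#' @param rc the [run_collection()] the clusters came from.
#' @return a [loading_matrix()] with one column per stable cluster (labels
#'   `"S<cluster>"`), or NULL when no cluster is stable.
#' @export
consensus_loadings <- function(cs, rc) {
  stopifnot(inherits(cs, "congruence_clusters"), inherits(rc, "run_collection"))
  idx <- which(cs$stable)
  if (!length(idx)) return(NULL)
  cols <- lapply(idx, function(k) {
    cl <- cs$clusters[[k]]
    cl <- cl[order(cl$run), ]
    ref <- rc$runs[[cl$run[1]]]$loadings[, cl$factor[1]]
    vecs <- lapply(seq_len(nrow(cl)), function(i) {
      v <- rc$runs[[cl$run[i]]]$loadings[, cl$factor[i]]
      if (safe_cor(v, ref) < 0) -v else v
    })
    rowMeans(do.call(cbind, vecs))
  })
  L <- do.call(cbind, cols)
  loading_matrix(L, rotation = "varimax", source = rc$runs[[1]]$source,
                 item_ids = rc$item_ids,
                 factor_labels = sprintf("S%d", idx))
}

#' Brute-force clustering oracle by pairwise assignment matching
#'
#' Independent reference for [cluster_factors()]: for every pair of runs the
#' optimal factor permutation is found by enumeration, matches below the
#' threshold are discarded, and the transitive closure of the surviving
#' matches defines the clusters.
#'
#' @param rc a [run_collection()] with d <= 7.
#' @param threshold congruence cutoff for accepting a pairwise match.
#' @return integer membership vector over the dR (run, factor) nodes, in
#'   the same node order as [build_congruence_matrix()].
#' @export
match_clusters_oracle <- function(rc, threshold) {
  stopifnot(inherits(rc, "run_collection"))
  d <- rc$d; R <- rc$R
  node <- function(r, f) (r - 1L) * d + f
  n <- d * R
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r1 in seq_len(R - 1)) {
    for (r2 in (r1 + 1):R) {
      mt <- match_factors(rc$runs[[r1]], rc$runs[[r2]])
      for (f in seq_len(d)) {
        if (mt$congruences[f] >= threshold) {
          a <- find(node(r1, f)); b <- find(node(r2, mt$permutation[f]))
          if (a != b) parent[b] <- a
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  as.integer(factor(roots, levels = unique(roots)))
}

#' Train R VAE runs and collect rotated loadings
#'
#' The multi-run protocol behind the stability analysis: R models are
#' trained on R re-seeded train/validation resamples of the same training
#' pool (weight initialisation, shuffling and sampling are re-seeded per
#' run), loadings are computed on each run's training respondents from the
#' MAP reconstruction, varimax-rotated and sign-normalised.
#'
#' @param pool_rm a [response_matrix()] of the training pool (test set
#'   already held out).
#' @param arch a [vae_architecture()].
#' @param config a [vae_config()]; its seed is the master seed the per-run
#'   seeds fan out from.
#' @param R number of runs.
#' @param val_frac validation fraction of the pool per run.
#' @param resample `"split"` re-draws the train/validation split per run;
#'   `"init"` keeps one split and re-seeds only the weights/shuffling.
#' @return list with `models` (the fitted `vae_model`s), `loadings` (a
#'   [run_collection()]), `run_seeds`.
#' @export
fit_vae_runs <- function(pool_rm, arch, config, R = 10L, val_frac = 0.2,
                         resample = c("split", "init")) {
  stopifnot(inherits(pool_rm, "response_matrix"), R >= 2)
  resample <- match.arg(resample)
  N <- nrow(pool_rm$scores)
  models <- vector("list", R)
  loadings <- vector("list", R)
  run_seeds <- vapply(seq_len(R), function(r) fan_seed(config$seed, r), 0L)
  base_split <- NULL
  for (r in seq_len(R)) {
    split_seed <- if (resample == "split") run_seeds[r] else config$seed
    sp <- local({
      set.seed(split_seed)
      perm <- sample.int(N)
      n_val <- max(1L, round(val_frac * N))
      list(val = sort(perm[seq_len(n_val)]), train = sort(perm[-seq_len(n_val)]))
    })
    if (resample == "init" && is.null(base_split)) base_split <- sp
    if (resample == "init") sp <- base_split
    train_sm <- standardize(pool_rm[sp$train, ])
    val_sm <- standardize(pool_rm[sp$val, ])
    cfg_r <- config
    cfg_r$seed <- run_seeds[r]
    m <- fit_vae(train_sm, val_sm, arch, cfg_r)
    e <- vae_encode(m, train_sm)
    v <- vae_decode(m, e$mu)
    lm <- vae_loadings(e, v, item_ids = train_sm$item_ids)
    lm <- rotate_varimax(lm)
    models[[r]] <- m
    loadings[[r]] <- lm
  }
  list(models = models,
       loadings = run_collection(loadings, run_seeds = run_seeds),
       run_seeds = run_seeds)
}
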