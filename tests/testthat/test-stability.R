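# Build a run_collection of R noisy copies of a base loading matrix with
# per-run column permutations (ground truth: one cluster per base column).
noisy_runs <- function(R = 3, d = 4, items_per_block = 50, noise = 0.08,
                       seed = 42, extra_noise_factor = FALSE) {
  M <- d * items_per_block
  set.seed(seed)
  base <- kronecker(diag(d), matrix(0.8, items_per_block, 1)) +
    matrix(rnorm(M * d), M, d) * 0.3
  runs <- lapply(seq_len(R), function(r) {
    L <- base + matrix(rnorm(M * d), M, d) * noise
    if (extra_noise_factor && r == 1) L[, d] <- rnorm(M) * 0.2
    loading_matrix(L[, sample(d)], source = "vae")
  })
  run_collection(runs)
}

test_that("congruence is the Pearson correlation of loading vectors", {
  a <- c(0.9, 0.1, 0.0); b <- c(0.8, 0.2, 0.1)
  expect_equal(factor_congruence(a, a), 1)
  expect_equal(factor_congruence(a, -a), -1)
  expect_equal(factor_congruence(a, b), 0.99952203, tolerance = 1e-8)
  expect_equal(factor_congruence(rep(1, 3), b), 0)
})

test_that("identical runs give a permutation-like off-diagonal block", {
  set.seed(1)
  L <- loading_matrix(matrix(rnorm(40), 20, 2), source = "vae")
  rc <- run_collection(list(L, L))
  cm <- build_congruence_matrix(rc)
  expect_equal(diag(cm$C), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$C, t(cm$C))
  off <- cm$C[1:2, 3:4]
  expect_equal(sort(diag(off)), c(1, 1))
})

test_that("independent random loadings rarely exceed congruence 0.3", {
  set.seed(2)
  runs <- lapply(1:4, function(r) {
    loading_matrix(matrix(rnorm(200 * 3), 200, 3), source = "vae")
  })
  cm <- build_congruence_matrix(run_collection(runs))
  off <- abs(cm$C[upper.tri(cm$C)])
  expect_lt(quantile(off, 0.95), 0.3)
})

test_that("clustering exact permuted copies recovers the factor identity", {
  set.seed(3)
  L <- matrix(rnorm(60), 30, 2)
  runs <- lapply(1:3, function(r) loading_matrix(L[, sample(2)], source = "vae"))
  cm <- build_congruence_matrix(run_collection(runs))
  cl <- cluster_factors(cm, 0.9, seed = 1)
  expect_length(cl$clusters, 2)
  expect_true(all(vapply(cl$clusters, nrow, 0L) == 3))
  expect_true(all(cl$stable))
})

test_that("Leiden clustering matches the brute-force assignment oracle", {
  rc <- noisy_runs(R = 3, d = 4)
  cm <- build_congruence_matrix(rc)
  cl <- cluster_factors(cm, 0.9, method = "leiden", seed = 1)
  memb <- integer(12)
  for (k in seq_along(cl$clusters)) memb[cl$clusters[[k]]$node] <- k
  oracle <- match_clusters_oracle(rc, 0.9)
  tab <- table(memb, oracle)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("an unmatched noise factor stays a singleton", {
  rc <- noisy_runs(R = 3, d = 4, extra_noise_factor = TRUE, seed = 5)
  cm <- build_congruence_matrix(rc)
  cl <- cluster_factors(cm, 0.85, seed = 1)
  sizes <- vapply(cl$clusters, nrow, 0L)
  expect_equal(sum(sizes == 3), 3)
  expect_equal(sum(cl$stable), 3)
  expect_gte(sum(sizes == 1), 1)
})

test_that("clustering is invariant to run and factor order", {
  rc <- noisy_runs(R = 3, d = 3, seed = 6)
  part_of <- function(rc) {
    cl <- cluster_factors(build_congruence_matrix(rc), 0.9, seed = 1)
    sets <- lapply(cl$clusters, function(x) sort(paste(x$run, x$factor)))
    sets[order(vapply(sets, paste, "", collapse = ";"))]
  }
  p1 <- part_of(rc)
  rc2 <- run_collection(rc$runs[c(2, 1, 3)])
  cl2 <- cluster_factors(build_congruence_matrix(rc2), 0.9, seed = 1)
  run_map <- c(2, 1, 3)
  sets2 <- lapply(cl2$clusters, function(x) sort(paste(run_map[x$run], x$factor)))
  sets2 <- sets2[order(vapply(sets2, paste, "", collapse = ";"))]
  expect_identical(p1, sets2)
})

test_that("threshold search stops at the first clean grid point", {
  # construct congruences: true matches at 0.95, one contaminating
  # same-run link at 0.80 between r1.f1 and r1.f2 via a shared item subset
  set.seed(7)
  base <- kronecker(diag(2), matrix(1, 30, 1)) + matrix(rnorm(120), 60, 2) * 0.05
  runs <- lapply(1:2, function(r) {
    L <- base + matrix(rnorm(120), 60, 2) * 0.05
    loading_matrix(L, source = "vae")
  })
  rc <- run_collection(runs)
  cm <- build_congruence_matrix(rc)
  # inject the contamination directly into the congruence matrix
  cm$C[1, 2] <- cm$C[2, 1] <- 0.90
  thr <- search_congruence_threshold(cm, start = 0.85, step = 0.005,
                                     method = "components")
  expect_equal(thr, 0.905, tolerance = 1e-9)

  # an already-clean matrix returns the grid origin
  cm$C[1, 2] <- cm$C[2, 1] <- 0.2
  expect_equal(search_congruence_threshold(cm, method = "components"), 0.85)
})

test_that("stable cluster count never increases as the threshold rises", {
  rc <- noisy_runs(R = 4, d = 4, noise = 0.25, seed = 8)
  cm <- build_congruence_matrix(rc)
  counts <- vapply(seq(0.5, 0.99, by = 0.05), function(t) {
    sum(cluster_factors(cm, t, method = "components")$stable)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("stable factors need exactly one member from every run", {
  rc <- noisy_runs(R = 3, d = 3, seed = 9)
  cm <- build_congruence_matrix(rc)
  cl <- cluster_factors(cm, 0.9, seed = 1)
  st <- stable_factors(cl)
  expect_equal(nrow(st), 3)
  expect_true(all(st$size == 3))
  expect_true(all(st$avg_congruence > 0.9))
  # drop one run member -> no longer stable
  cl2 <- cl
  cl2$clusters[[st$cluster[1]]] <- cl$clusters[[st$cluster[1]]][-1, ]
  cl2$stable[st$cluster[1]] <-
    nrow(cl2$clusters[[st$cluster[1]]]) == cl$R
  expect_false(cl2$stable[st$cluster[1]])
})

test_that("consensus loadings align signs and denoise members", {
  set.seed(10)
  # a dominant entry keeps the sign-normalisation anchor stable across the
  # noisy copies
  truth <- c(3, rnorm(99))
  runs <- lapply(1:4, function(r) {
    loading_matrix(cbind(truth + rnorm(100) * 0.15), source = "vae")
  })
  # identical members -> consensus equals any member
  same <- run_collection(lapply(1:3, function(r) runs[[1]]))
  cl_s <- cluster_factors(build_congruence_matrix(same), 0.9,
                          method = "components")
  cons_s <- consensus_loadings(cl_s, same)
  expect_equal(unname(cons_s$loadings[, 1]), unname(runs[[1]]$loadings[, 1]))

  rc <- run_collection(runs)
  cm <- build_congruence_matrix(rc)
  cl <- cluster_factors(cm, 0.8, method = "components")
  # flip one member after clustering: consensus must re-align, not cancel
  rc_flipped <- rc
  rc_flipped$runs[[2]]$loadings[, 1] <- -rc$runs[[2]]$loadings[, 1]
  cons_f <- consensus_loadings(cl, rc_flipped)
  cons <- consensus_loadings(cl, rc)
  expect_equal(abs(cons_f$loadings[, 1]), abs(cons$loadings[, 1]),
               tolerance = 1e-12)
  expect_gt(abs(factor_congruence(cons$loadings[, 1], truth)), 0.9)
  # consensus is at least as congruent with truth as the average member
  member_cong <- vapply(runs, function(r) {
    abs(factor_congruence(r$loadings[, 1], truth))
  }, 0)
  expect_gte(abs(factor_congruence(cons$loadings[, 1], truth)),
             mean(member_cong))
})
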