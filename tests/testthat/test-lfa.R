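test_that("eigen spectrum matches closed forms and sums to M", {
  set.seed(1)
  sm <- as_sm(matrix(rnorm(6000), 2000, 3))
  es <- eigen_spectrum(sm)
  expect_equal(es$eigenvalues, rep(1, 3), tolerance = 0.1)
  expect_equal(sum(es$eigenvalues), 3, tolerance = 1e-6)

  # two items with correlation r have eigenvalues 1 +/- r
  z <- rnorm(5000)
  x <- cbind(z + rnorm(5000), z + rnorm(5000))
  r <- cor(x)[1, 2]
  es2 <- eigen_spectrum(as_sm(scale(x)))
  expect_equal(es2$eigenvalues, c(1 + r, 1 - r), tolerance = 1e-8)
  expect_equal(es2$n_gt_one, 1L)
})

test_that("leading eigenvalue of one-factor data matches the population value", {
  spec <- questionnaire_spec(10000, 6, 1, link = "linear",
                             loading_strength = 0.8, noise_sd = 0.6, seed = 2)
  sim <- simulate_questionnaire(spec)
  es <- eigen_spectrum(standardize(sim$responses))
  # population correlation matrix: diag 1, off-diagonal 0.64 -> lead 1 + 5*0.64
  expect_equal(es$eigenvalues[1], 1 + 5 * 0.64, tolerance = 0.15)
})

test_that("principal axes recover a noiseless loading structure", {
  spec <- questionnaire_spec(20000, 12, 3, blocks = rep(1:3, each = 4),
                             link = "linear", loading_strength = 0.8,
                             noise_sd = 0.05, seed = 3)
  sim <- simulate_questionnaire(spec)
  lmv <- rotate_varimax(fit_principal_factors(standardize(sim$responses), 3))
  mt <- match_factors(lmv, spec$loadings)
  expect_gte(mt$mean_congruence, 0.999)
})

test_that("white noise yields near-zero communalities at d = M - 1", {
  set.seed(4)
  sm <- as_sm(matrix(rnorm(8000 * 8), 8000, 8))
  lm <- fit_principal_factors(sm, 7)
  expect_lt(max(communalities(lm)), 0.05)
})

test_that("two perfectly correlated items give unit loadings at d = 1", {
  z <- rnorm(500)
  suppressWarnings(lm <- fit_principal_factors(as_sm(cbind(z, z)), 1))
  expect_equal(abs(unname(lm$loadings[, 1])), c(1, 1), tolerance = 1e-6)
})

test_that("varimax preserves communalities and finds simple structure", {
  set.seed(5)
  # near-simple structure: small cross loadings keep the Kaiser-normalised
  # rows distinct (exact zeros make whole blocks collinear after
  # normalisation and the rotation criterion degenerate)
  simple <- rbind(cbind(runif(4, 0.6, 0.9), runif(4, 0, 0.08)),
                  cbind(runif(4, 0, 0.08), runif(4, 0.6, 0.9)))
  theta <- pi / 5          # exactly 45 deg is a stationary point of varimax
  Rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  mixed <- loading_matrix(simple %*% Rot)
  rotated <- rotate_varimax(mixed)
  expect_equal(communalities(rotated), communalities(mixed), tolerance = 1e-8)
  mt <- match_factors(rotated, simple)
  expect_gte(mt$mean_congruence, 0.999)

  # a simple-structure matrix is a fixed point up to sign/permutation
  fixed <- rotate_varimax(loading_matrix(simple))
  expect_gte(match_factors(fixed, simple)$mean_congruence, 0.9999)

  # d = 1 passes through
  one <- loading_matrix(matrix(runif(5, 0.4, 0.9), 5, 1))
  expect_equal(rotate_varimax(one)$loadings, one$loadings)
})

test_that("Thurstone scores reduce to xL when R = I and L is orthonormal", {
  set.seed(6)
  x <- matrix(rnorm(40), 10, 4)
  L <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  lm <- loading_matrix(L, sign_normalize = FALSE)
  fs <- factor_scores(as_sm(x), lm, method = "thurstone", R = diag(4))
  expect_equal(unname(fs$z), x %*% L, tolerance = 1e-10)
})

test_that("Bartlett scores reproduce the latent factors on noiseless data", {
  set.seed(7)
  z <- matrix(rnorm(600), 200, 3)
  L <- matrix(0, 9, 3)
  L[cbind(1:9, rep(1:3, each = 3))] <- 0.8
  x <- z %*% t(L)
  fs <- factor_scores(as_sm(x), loading_matrix(L, sign_normalize = FALSE),
                      method = "bartlett")
  expect_equal(unname(fs$z), z, tolerance = 1e-6)
})

test_that("linear reconstruction multiplies out as v = z L'", {
  lm <- loading_matrix(matrix(c(0.6, 0.8), 2, 1), sign_normalize = FALSE)
  v <- reconstruct_lfa(matrix(2, 1, 1), lm)
  expect_equal(unname(v[1, ]), c(1.2, 1.6))

  id <- loading_matrix(diag(3), sign_normalize = FALSE)
  z <- matrix(rnorm(15), 5, 3)
  expect_equal(unname(reconstruct_lfa(z, id)), z)
  expect_equal(unname(reconstruct_lfa(matrix(0, 4, 1), lm)),
               matrix(0, 4, 2))
})

test_that("communalities follow the Pythagorean identity", {
  lm <- loading_matrix(rbind(c(0.6, 0.8), c(0, 0)), sign_normalize = FALSE)
  expect_equal(unname(communalities(lm)), c(1, 0))
})

test_that("correlation loadings hit the +/-1 and independence limits", {
  set.seed(8)
  z <- rnorm(10000)
  x <- cbind(z, -z, rnorm(10000))
  fs <- structure(list(z = matrix(z, ncol = 1), method = "thurstone",
                       factor_labels = "F1"), class = "factor_scores")
  lm <- lfa_loadings_from_scores(fs, as_sm(x))
  expect_equal(unname(lm$loadings[1:2, 1]), c(1, -1), tolerance = 1e-12)
  expect_lt(abs(lm$loadings[3, 1]), 0.05)
})

test_that("principal-axis recovery meets the congruence oracle on noisy data", {
  spec <- linear_spec(n = 20000, seed = 9)
  sim <- simulate_questionnaire(spec)
  lmv <- rotate_varimax(fit_principal_factors(standardize(sim$responses), 3))
  mt <- match_factors(lmv, spec$loadings)
  expect_gte(mt$mean_congruence, 0.98)
})
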