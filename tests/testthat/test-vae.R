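test_that("a zero-weight encoder outputs the prior posterior", {
  p <- manual_vae(4, 2)
  e <- vae_encode(p, matrix(rnorm(20), 5, 4))
  expect_equal(e$mu, matrix(0, 5, 2))
  expect_equal(e$sigma, matrix(1, 5, 2))
})

test_that("posterior SDs are strictly positive and encoding is deterministic", {
  p <- init_vae_params(vae_architecture(6, 3), seed = 2)
  x <- matrix(rnorm(60), 10, 6)
  e1 <- vae_encode(p, x)
  expect_true(all(e1$sigma > 0))
  expect_identical(e1, vae_encode(p, x))
  expect_error(vae_encode(p, matrix(0, 2, 5)), "architecture expects")
})

test_that("reparameterised samples follow mu + sigma * eps", {
  ps <- list(mu = matrix(1:6 / 2, 3, 2), sigma = matrix(1e-12, 3, 2))
  expect_equal(vae_sample_latent(ps, seed = 1), ps$mu, tolerance = 1e-9)

  ps2 <- list(mu = matrix(2, 1e5, 1), sigma = matrix(0.5, 1e5, 1))
  z <- vae_sample_latent(ps2, seed = 3)
  expect_identical(z, vae_sample_latent(ps2, seed = 3))
  expect_lt(abs(mean(z) - 2), 3 * 0.5 / sqrt(1e5))
})

test_that("a single-layer linear decoder multiplies weights exactly", {
  W <- matrix(rnorm(8), 2, 4)
  p <- manual_vae(4, 2, dec_Wout = W, dec_bout = rep(0.5, 4))
  z <- matrix(rnorm(10), 5, 2)
  expect_equal(vae_decode(p, z), z %*% W + 0.5)
  expect_equal(vae_decode(manual_vae(4, 2), z), matrix(0, 5, 4))
})

test_that("the ELBO terms match their closed forms", {
  M <- 3; d <- 1
  x <- matrix(rnorm(6), 2, 3)
  # prior-matching posterior -> KL = 0
  expect_equal(vae_elbo(manual_vae(M, d), x, sample = FALSE)$kl, 0)
  # mu = 1, sigma = 1, d = 1 -> KL = 0.5 per respondent
  p <- manual_vae(M, d, enc_bmu = 1)
  expect_equal(vae_elbo(p, x, sample = FALSE)$kl, 0.5)
  # perfect reconstruction on observed cells -> recon term 0
  pid <- manual_vae(2, 2, enc_Wmu = diag(2), dec_Wout = diag(2))
  x2 <- matrix(rnorm(8), 4, 2)
  expect_equal(vae_elbo(pid, x2, sample = FALSE)$recon, 0)
  # a fully masked row adds nothing to the reconstruction term
  mask <- matrix(TRUE, 4, 2); mask[2, ] <- FALSE
  x3 <- x2; x3[2, ] <- 100
  l_masked <- vae_elbo(manual_vae(2, 2), x3, mask, sample = FALSE)
  l_clean <- vae_elbo(manual_vae(2, 2), x2, mask, sample = FALSE)
  expect_equal(l_masked$recon, l_clean$recon)
  # all-true mask equals no mask
  pr <- init_vae_params(vae_architecture(2, 2), seed = 5)
  expect_equal(vae_elbo(pr, x2, matrix(TRUE, 4, 2), sample = FALSE),
               vae_elbo(pr, x2, sample = FALSE))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(6)
  arch <- vae_architecture(4, 2, 3L)
  p <- init_vae_params(arch, seed = 7)
  x <- matrix(rnorm(20), 5, 4)
  mask <- matrix(TRUE, 5, 4); mask[1, 2] <- FALSE
  eps <- matrix(rnorm(10), 5, 2)
  g <- vae_grad(p, x, mask, eps)
  h <- 1e-6
  for (nm in c("enc_W1", "enc_Wmu", "enc_Wlv", "dec_W1", "dec_Wout",
               "enc_b1", "dec_bout")) {
    w <- p$weights[[nm]]
    i <- if (is.matrix(w)) cbind(1, min(2, ncol(w))) else 1
    p_up <- p; p_dn <- p
    if (is.matrix(w)) {
      p_up$weights[[nm]][i] <- w[i] + h
      p_dn$weights[[nm]][i] <- w[i] - h
    } else {
      p_up$weights[[nm]][1] <- w[1] + h
      p_dn$weights[[nm]][1] <- w[1] - h
    }
    num <- (vae_grad(p_up, x, mask, eps)$loss -
              vae_grad(p_dn, x, mask, eps)$loss) / (2 * h)
    ana <- if (is.matrix(w)) g$grads[[nm]][i] else g$grads[[nm]][1]
    expect_equal(ana, num, tolerance = 1e-4)
  }
})

test_that("training is deterministic and the loss trend decreases", {
  fit <- cached_linear_fit()
  cfg <- vae_config(max_epochs = 30, patience = 30, seed = 7)
  m1 <- fit_vae(fit$parts$train, fit$parts$val, vae_architecture(20, 3), cfg)
  m2 <- fit_vae(fit$parts$train, fit$parts$val, vae_architecture(20, 3), cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params$weights, m2$params$weights)

  tl <- fit$model$log$train_loss
  win <- split(tl, ceiling(seq_along(tl) / 10))
  meds <- vapply(win, stats::median, 0)
  expect_true(all(diff(meds) < 0.05))
  expect_lt(meds[length(meds)], meds[1])
})

test_that("a matched bottleneck beats an undersized one on held-out loss", {
  fit <- cached_linear_fit()
  cfg <- vae_config(max_epochs = 80, patience = 80, seed = 11)
  m3 <- fit_vae(fit$parts$train, fit$parts$val, vae_architecture(20, 3), cfg)
  m2 <- fit_vae(fit$parts$train, fit$parts$val, vae_architecture(20, 2), cfg)
  r3 <- vae_elbo(m3, fit$parts$val, sample = FALSE)$recon
  r2 <- vae_elbo(m2, fit$parts$val, sample = FALSE)$recon
  expect_lt(r3, r2)
})

test_that("a hand-built identity autoencoder reconstructs its input", {
  p <- manual_vae(3, 3, enc_Wmu = diag(3), dec_Wout = diag(3))
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(vae_reconstruct(p, x), x)
  # MAP reconstruction is deterministic
  fit <- cached_linear_fit()
  v1 <- vae_reconstruct(fit$model, fit$parts$test)
  v2 <- vae_reconstruct(fit$model, fit$parts$test)
  expect_identical(v1, v2)
})

test_that("a one-factor model yields an essentially rank-one reconstruction", {
  spec <- questionnaire_spec(2000, 8, 1, link = "linear",
                             loading_strength = 0.8, noise_sd = 0.6, seed = 21)
  sim <- simulate_questionnaire(spec)
  parts <- split_standardize(sim$responses)
  m <- fit_vae(parts$train, parts$val, vae_architecture(8, 1),
               vae_config(max_epochs = 80, patience = 80, seed = 3))
  sv <- svd(vae_reconstruct(m, parts$test))$d
  expect_lt(sv[2] / sv[1], 0.05)
})

test_that("reconstruction accuracy is non-decreasing in the bottleneck width", {
  fit <- cached_linear_fit()
  means <- vapply(1:5, function(d) {
    m <- fit_vae(fit$parts$train, fit$parts$val, vae_architecture(20, d),
                 vae_config(max_epochs = 80, patience = 80, seed = 13))
    reconstruction_correlation(fit$parts$test,
                               vae_reconstruct(m, fit$parts$test))$mean
  }, 0)
  expect_true(all(diff(means) > -0.01))
})

test_that("checkpoints survive a save/load round trip at full precision", {
  fit <- cached_linear_fit()
  path <- withr::local_tempfile(fileext = ".json")
  save_vae(fit$model, path)
  m2 <- load_vae(path)
  expect_equal(m2$params$weights, fit$model$params$weights,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(vae_reconstruct(m2, fit$parts$test),
               vae_reconstruct(fit$model, fit$parts$test), tolerance = 1e-10)
})

test_that("a linear VAE spans the principal subspace of the data", {
  spec <- questionnaire_spec(10000, 10, 2, link = "linear",
                             loading_strength = 0.8, noise_sd = 0.6, seed = 3)
  sim <- simulate_questionnaire(spec)
  parts <- split_standardize(sim$responses, seed = 2)
  m <- fit_vae(parts$train, parts$val, vae_architecture(10, 2, integer(0)),
               vae_config(max_epochs = 250, patience = 250, seed = 4))
  W <- t(m$params$weights$dec_Wout)                 # M x d decoder map
  pcs <- eigen(cov(parts$train$x))$vectors[, 1:2]
  qW <- qr.Q(qr(W))
  angles <- acos(pmin(svd(crossprod(qW, pcs))$d, 1)) * 180 / pi
  expect_lt(max(angles), 10)
})
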