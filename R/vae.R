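#' VAE architecture specification
#'
#' Mirror-image encoder/decoder multilayer perceptrons. The encoder maps an
#' item vector to the mean and log-variance of a diagonal-Gaussian posterior
#' over d latent factors; the decoder maps latent vectors back to item
#' means. Hidden layers use ReLU; the bottleneck (Gaussian parameters) and
#' the output layer are linear, so latent factors and reconstructed scores
#' are unbounded. The default single hidden layer has twice as many nodes as
#' there are items.
#'
#' @param n_items number of items M.
#' @param n_latent number of latent factors d (bottleneck width).
#' @param hidden_sizes integer vector of hidden-layer widths, outermost
#'   first (the decoder uses the reversed order). `integer(0)` gives a
#'   linear encoder/decoder.
#' @return an object of class `vae_architecture`.
#' @export
vae_architecture <- function(n_items, n_latent,
                             hidden_sizes = 2L * n_items) {
  n_items <- as.integer(n_items); n_latent <- as.integer(n_latent)
  hidden_sizes <- as.integer(hidden_sizes)
  if (n_latent < 1) stop("n_latent must be >= 1")
  if (length(hidden_sizes) && any(hidden_sizes < 1)) {
    stop("hidden sizes must be >= 1")
  }
  structure(list(n_items = n_items, n_latent = n_latent,
                 hidden_sizes = hidden_sizes),
            class = "vae_architecture")
}

#' VAE training configuration
#'
#' Adam optimisation of the negative ELBO with minibatches and early
#' stopping on the validation loss. The KL weight is fixed at 1 (the plain
#' VAE objective). One reparameterisation sample per datum per step. All
#' randomness (weight init, shuffling, sampling) derives from `seed`.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch rows.
#' @param max_epochs epoch cap.
#' @param patience epochs without validation improvement before stopping.
#' @param seed master seed for the run.
#' @return an object of class `vae_config`.
#' @export
vae_config <- function(learning_rate = 1e-3, batch_size = 256L,
                       max_epochs = 500L, patience = 20L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 beta = 1, seed = as.integer(seed)),
            class = "vae_config")
}

#' Initialise VAE weights
#'
#' Seeded uniform fan-in initialisation: every weight matrix is drawn from
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`, biases start at zero. Also the
#' entry point for building hand-crafted networks: overwrite entries of the
#' returned `weights` list to pin specific maps.
#'
#' @param arch a [vae_architecture()].
#' @param seed optional integer seed.
#' @return an object of class `vae_params` (fields `weights`, `arch`).
#' @export
init_vae_params <- function(arch, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  mk <- function(n_in, n_out) {
    lim <- 1 / sqrt(n_in)
    matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  p <- list()
  sizes <- c(arch$n_items, arch$hidden_sizes)
  for (l in seq_along(arch$hidden_sizes)) {
    p[[paste0("enc_W", l)]] <- mk(sizes[l], sizes[l + 1])
    p[[paste0("enc_b", l)]] <- numeric(sizes[l + 1])
  }
  last <- sizes[length(sizes)]
  p$enc_Wmu <- mk(last, arch$n_latent); p$enc_bmu <- numeric(arch$n_latent)
  p$enc_Wlv <- mk(last, arch$n_latent); p$enc_blv <- numeric(arch$n_latent)
  dsizes <- c(arch$n_latent, rev(arch$hidden_sizes))
  for (l in seq_along(arch$hidden_sizes)) {
    p[[paste0("dec_W", l)]] <- mk(dsizes[l], dsizes[l + 1])
    p[[paste0("dec_b", l)]] <- numeric(dsizes[l + 1])
  }
  dlast <- dsizes[length(dsizes)]
  p$dec_Wout <- mk(dlast, arch$n_items); p$dec_bout <- numeric(arch$n_items)
  structure(list(weights = p, arch = arch), class = "vae_params")
}

add_bias <- function(h, b) h + rep(b, each = nrow(h))

# Encoder forward pass; returns posterior stats and (optionally) the
# layer activations needed for backpropagation.
encode_full <- function(p, x, keep_cache = FALSE) {
  w <- p$weights; arch <- p$arch
  acts <- list(x); pres <- list()
  h <- x
  for (l in seq_along(arch$hidden_sizes)) {
    pre <- add_bias(h %*% w[[paste0("enc_W", l)]], w[[paste0("enc_b", l)]])
    h <- pre * (pre > 0)
    pres[[l]] <- pre; acts[[l + 1]] <- h
  }
  mu <- add_bias(h %*% w$enc_Wmu, w$enc_bmu)
  lv <- add_bias(h %*% w$enc_Wlv, w$enc_blv)
  lv <- pmin(pmax(lv, -12), 12)          # numeric guard on log-variance
  out <- list(mu = mu, logvar = lv, sigma = exp(0.5 * lv))
  if (keep_cache) { out$acts <- acts; out$pres <- pres }
  out
}

# Decoder forward pass.
decode_full <- function(p, z, keep_cache = FALSE) {
  w <- p$weights; arch <- p$arch
  acts <- list(z); pres <- list()
  h <- z
  for (l in seq_along(arch$hidden_sizes)) {
    pre <- add_bias(h %*% w[[paste0("dec_W", l)]], w[[paste0("dec_b", l)]])
    h <- pre * (pre > 0)
    pres[[l]] <- pre; acts[[l + 1]] <- h
  }
  out_x <- add_bias(h %*% w$dec_Wout, w$dec_bout)
  out <- list(mu_x = out_x)
  if (keep_cache) { out$acts <- acts; out$pres <- pres }
  out
}

#' Encode data to posterior statistics
#'
#' Deterministic forward pass of the inference network: per respondent the
#' mean and SD of the diagonal-Gaussian approximate posterior over the
#' latent factors. The SD is `exp(logvar / 2)` and therefore strictly
#' positive.
#'
#' @param p a `vae_params` object (or a fitted `vae_model`).
#' @param x N x M standardized matrix (or a `standardized_matrix`).
#' @return list with `mu` and `sigma`, both N x d.
#' @export
vae_encode <- function(p, x) {
  p <- as_vae_params(p)
  x <- as_x_matrix(x)
  if (ncol(x) != p$arch$n_items) {
    stop("x has ", ncol(x), " columns but the architecture expects ",
         p$arch$n_items)
  }
  e <- encode_full(p, x)
  list(mu = e$mu, sigma = e$sigma, logvar = e$logvar)
}

#' Decode latent vectors to item means
#'
#' Deterministic forward pass of the generative network. The output layer
#' is linear, so reconstructed z-scores are unbounded.
#'
#' @param p a `vae_params` object (or fitted `vae_model`).
#' @param z N x d latent matrix.
#' @return N x M matrix of reconstructed item means.
#' @export
vae_decode <- function(p, z) {
  p <- as_vae_params(p)
  z <- as.matrix(z)
  if (ncol(z) != p$arch$n_latent) {
    stop("z has ", ncol(z), " columns but the architecture expects ",
         p$arch$n_latent)
  }
  decode_full(p, z)$mu_x
}

#' Draw latent samples by the reparameterisation trick
#'
#' `z = mu + sigma * eps`, `eps ~ N(0, 1)`, seeded.
#'
#' @param ps posterior stats as returned by [vae_encode()].
#' @param seed integer seed.
#' @return N x d latent sample matrix.
#' @export
vae_sample_latent <- function(ps, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  eps <- matrix(stats::rnorm(length(ps$mu)), nrow(ps$mu), ncol(ps$mu))
  ps$mu + ps$sigma * eps
}

#' Negative ELBO of a batch
#'
#' `loss = recon + kl`, averaged per respondent, where the reconstruction
#' term is the masked Gaussian negative log-likelihood up to a constant
#' (half the squared error over *observed* cells; missing cells are
#' excluded) and the KL term is the closed-form divergence of the diagonal
#' Gaussian posterior from the standard-normal prior,
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param p a `vae_params` object (or fitted `vae_model`).
#' @param x N x M standardized matrix (or `standardized_matrix`; its mask is
#'   used when `mask` is NULL).
#' @param mask N x M logical, TRUE = observed. NULL means all observed.
#' @param seed seed for the reparameterisation draw (when `sample = TRUE`).
#' @param sample draw z stochastically (training objective) or use `z = mu`
#'   (the deterministic objective used for validation monitoring).
#' @return list with `loss`, `recon`, `kl` (all per-respondent averages).
#' @export
vae_elbo <- function(p, x, mask = NULL, seed = NULL, sample = TRUE) {
  p <- as_vae_params(p)
  if (inherits(x, "standardized_matrix")) {
    if (is.null(mask)) mask <- x$missing_mask
    x <- x$x
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  e <- encode_full(p, x)
  z <- if (sample) vae_sample_latent(e, seed) else e$mu
  v <- decode_full(p, z)$mu_x
  n <- nrow(x)
  recon <- 0.5 * sum(((v - x)^2)[mask]) / n
  kl <- 0.5 * sum(e$mu^2 + exp(e$logvar) - 1 - e$logvar) / n
  list(loss = recon + kl, recon = recon, kl = kl)
}

# One forward+backward pass on a minibatch; returns loss components and the
# gradient list (same shapes as p$weights). eps is the pre-drawn N(0,1)
# matrix for the reparameterisation sample.
vae_grad <- function(p, x, mask, eps) {
  w <- p$weights; arch <- p$arch
  n <- nrow(x); nh <- length(arch$hidden_sizes)
  e <- encode_full(p, x, keep_cache = TRUE)
  sigma <- exp(0.5 * e$logvar)
  z <- e$mu + sigma * eps
  dcc <- decode_full(p, z, keep_cache = TRUE)
  v <- dcc$mu_x
  recon <- 0.5 * sum(((v - x)^2)[mask]) / n
  kl <- 0.5 * sum(e$mu^2 + exp(e$logvar) - 1 - e$logvar) / n
  g <- list()
  # --- decoder backward ---
  dout <- (v - x) / n
  dout[!mask] <- 0
  hlast <- dcc$acts[[nh + 1]]
  g$dec_Wout <- crossprod(hlast, dout)
  g$dec_bout <- colSums(dout)
  dh <- dout %*% t(w$dec_Wout)
  for (l in rev(seq_len(nh))) {
    dpre <- dh * (dcc$pres[[l]] > 0)
    g[[paste0("dec_W", l)]] <- crossprod(dcc$acts[[l]], dpre)
    g[[paste0("dec_b", l)]] <- colSums(dpre)
    dh <- dpre %*% t(w[[paste0("dec_W", l)]])
  }
  dz <- dh
  # --- reparameterisation + KL ---
  dmu <- dz + e$mu / n
  dlv <- dz * eps * 0.5 * sigma + 0.5 * (exp(e$logvar) - 1) / n
  hlast <- e$acts[[nh + 1]]
  g$enc_Wmu <- crossprod(hlast, dmu); g$enc_bmu <- colSums(dmu)
  g$enc_Wlv <- crossprod(hlast, dlv); g$enc_blv <- colSums(dlv)
  dh <- dmu %*% t(w$enc_Wmu) + dlv %*% t(w$enc_Wlv)
  for (l in rev(seq_len(nh))) {
    dpre <- dh * (e$pres[[l]] > 0)
    g[[paste0("enc_W", l)]] <- crossprod(e$acts[[l]], dpre)
    g[[paste0("enc_b", l)]] <- colSums(dpre)
    dh <- dpre %*% t(w[[paste0("enc_W", l)]])
  }
  list(loss = recon + kl, recon = recon, kl = kl, grads = g)
}

#' Train a VAE on standardized questionnaire data
#'
#' Minibatch Adam on the negative masked ELBO, monitoring a deterministic
#' validation loss (reconstruction at `z = mu` plus KL) each epoch. Training
#' stops when the validation loss has not improved for `patience` epochs or
#' at `max_epochs`, and the weights from the best validation epoch are
#' returned. Fully deterministic given `config$seed`.
#'
#' @param train_sm,val_sm `standardized_matrix` objects over the same items.
#' @param arch a [vae_architecture()].
#' @param config a [vae_config()].
#' @param verbose print a line per 25 epochs.
#' @return an object of class `vae_model`: `params`, `arch`, `config`,
#'   `log` (per-epoch train/validation loss data frame), `stopped_epoch`,
#'   `best_epoch`.
#' @export
fit_vae <- function(train_sm, val_sm, arch, config = vae_config(),
                    verbose = FALSE) {
  stopifnot(inherits(train_sm, "standardized_matrix"),
            inherits(val_sm, "standardized_matrix"),
            inherits(arch, "vae_architecture"))
  if (!identical(train_sm$item_ids, val_sm$item_ids)) {
    stop("training and validation sets have different items")
  }
  if (ncol(train_sm$x) != arch$n_items) stop("architecture/items mismatch")
  set.seed(config$seed)
  p <- init_vae_params(arch)
  x <- train_sm$x; mask <- train_sm$missing_mask
  N <- nrow(x); B <- min(config$batch_size, N)
  adam_m <- lapply(p$weights, function(w) w * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps_ad <- 1e-8; step <- 0L
  best_val <- Inf; best_w <- p$weights; best_epoch <- 0L; wait <- 0L
  log_train <- numeric(0); log_val <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(N)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, N, by = B)) {
      idx <- perm[start:min(start + B - 1, N)]
      xb <- x[idx, , drop = FALSE]
      eb <- matrix(stats::rnorm(length(idx) * arch$n_latent),
                   length(idx), arch$n_latent)
      gr <- vae_grad(p, xb, mask[idx, , drop = FALSE], eb)
      if (!is.finite(gr$loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      step <- step + 1L
      corr <- config$learning_rate *
        sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(gr$grads)) {
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gr$grads[[nm]]
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gr$grads[[nm]]^2
        p$weights[[nm]] <- p$weights[[nm]] -
          corr * adam_m[[nm]] / (sqrt(adam_v[[nm]]) + eps_ad)
      }
      ep_loss <- ep_loss + gr$loss; nb <- nb + 1L
    }
    vl <- vae_elbo(p, val_sm, sample = FALSE)$loss
    log_train <- c(log_train, ep_loss / nb); log_val <- c(log_val, vl)
    if (verbose && epoch %% 25 == 0) {
      message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                      ep_loss / nb, vl))
    }
    if (vl < best_val - 1e-6) {
      best_val <- vl; best_w <- p$weights; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  p$weights <- best_w
  structure(list(params = p, arch = arch, config = config,
                 log = data.frame(epoch = seq_along(log_train),
                                  train_loss = log_train,
                                  val_loss = log_val),
                 stopped_epoch = length(log_train),
                 best_epoch = best_epoch, best_val_loss = best_val),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf(
    "vae_model: M=%d, d=%d, hidden=[%s]; stopped at epoch %d (best %d, val loss %.4f)\n",
    x$arch$n_items, x$arch$n_latent,
    paste(x$arch$hidden_sizes, collapse = ","),
    x$stopped_epoch, x$best_epoch, x$best_val_loss))
  invisible(x)
}

as_vae_params <- function(p) {
  if (inherits(p, "vae_model")) return(p$params)
  stopifnot(inherits(p, "vae_params"))
  p
}

as_x_matrix <- function(x) {
  if (inherits(x, "standardized_matrix")) x$x else as.matrix(x)
}

#' Deterministic MAP reconstruction
#'
#' Decodes the posterior means (the maximum-a-posteriori latent estimate)
#' without sampling: `v = decoder(mu_z)`. This is the reconstruction used by
#' every accuracy metric and by the muting association analysis.
#'
#' @param p a `vae_model` or `vae_params`.
#' @param sm a `standardized_matrix` (or bare matrix).
#' @return N x M reconstruction.
#' @export
vae_reconstruct <- function(p, sm) {
  x <- as_x_matrix(sm)
  e <- vae_encode(p, x)
  v <- vae_decode(p, e$mu)
  if (inherits(sm, "standardized_matrix")) colnames(v) <- sm$item_ids
  v
}

#' Save / load a VAE model as portable JSON
#'
#' Weights, architecture, config and training log in one versioned JSON
#' container, readable on any platform.
#'
#' @param model a `vae_model`.
#' @param path file path.
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "vae_model"))
  obj <- list(format = "vaefa-vae", version = 1L,
              arch = unclass(model$arch),
              config = unclass(model$config),
              weights = lapply(model$params$weights, function(w) {
                if (is.matrix(w)) list(dim = dim(w), data = as.vector(w))
                else list(dim = length(w), data = as.vector(w))
              }),
              stopped_epoch = model$stopped_epoch,
              best_epoch = model$best_epoch,
              best_val_loss = model$best_val_loss,
              log = model$log)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vae
#' @param path file path of a saved model.
#' @export
load_vae <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "vaefa-vae")) stop("not a vaefa VAE checkpoint")
  hs <- obj$arch$hidden_sizes
  hs <- if (length(hs)) as.integer(unlist(hs)) else integer(0)
  arch <- vae_architecture(obj$arch$n_items, obj$arch$n_latent, hs)
  weights <- lapply(obj$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  cfg <- vae_config(obj$config$learning_rate, obj$config$batch_size,
                    obj$config$max_epochs, obj$config$patience,
                    obj$config$seed)
  structure(list(params = structure(list(weights = weights, arch = arch),
                                    class = "vae_params"),
                 arch = arch, config = cfg,
                 log = as.data.frame(obj$log),
                 stopped_epoch = obj$stopped_epoch,
                 best_epoch = obj$best_epoch,
                 best_val_loss = obj$best_val_loss),
            class = "vae_model")
}
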