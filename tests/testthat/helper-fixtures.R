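# Shared fixtures. Trained models are cached per session so several test
# files can probe the same fit without repeating the training.

.fixture_env <- new.env(parent = emptyenv())

# Linear block design: 3 factors, 20 items (blocks 7/7/6), loading 0.8,
# noise SD 0.6 -> per-item oracle correlation 0.8.
linear_spec <- function(n = 5000, seed = 11, noise_sd = 0.6) {
  questionnaire_spec(n, 20, 3, blocks = rep(1:3, c(7, 7, 6)),
                     link = "linear", loading_strength = 0.8,
                     noise_sd = noise_sd, seed = seed)
}

# Saturating design with discrimination heterogeneity: 3 factors, 30 items
# (blocks 12/10/8), three anchor items per block saturating at gains
# 4.0/2.5/1.6, mild items U(0.3, 0.7), noise SD 0.6.
anchor_spec <- function(n = 6000, seed = 33) {
  bl <- block_loadings(c(12, 10, 8), seed = 7)
  questionnaire_spec(n, d_true = 3, loadings = bl$loadings,
                     blocks = bl$blocks, link = "saturating",
                     noise_sd = 0.6, seed = seed)
}

split_standardize <- function(rm, seed = 5) {
  sb <- split_respondents(rm, seed = seed)
  list(split = sb,
       pool = rm[sort(c(sb$train, sb$validation)), ],
       train = standardize(rm[sb$train, ]),
       val = standardize(rm[sb$validation, ]),
       test = standardize(rm[sb$test, ]))
}

# Small trained VAE on linear data, shared across test files. The blocks
# have distinct strengths (0.95/0.8/0.65) so the factors differ in variance
# footprint, which lets a modest training budget orient the latents.
cached_linear_fit <- function() {
  if (is.null(.fixture_env$linear_fit)) {
    blocks <- rep(1:3, c(7, 7, 6))
    L <- matrix(0, 20, 3)
    L[cbind(1:20, blocks)] <- c(0.95, 0.8, 0.65)[blocks]
    spec <- questionnaire_spec(4000, d_true = 3, loadings = L,
                               blocks = blocks, link = "linear",
                               noise_sd = 0.6, seed = 11)
    sim <- simulate_questionnaire(spec)
    parts <- split_standardize(sim$responses)
    model <- fit_vae(parts$train, parts$val, vae_architecture(20, 3),
                     vae_config(max_epochs = 800, patience = 800, seed = 7))
    .fixture_env$linear_fit <- list(sim = sim, parts = parts, model = model,
                                    spec = spec, blocks = blocks)
  }
  .fixture_env$linear_fit
}

# Hand-built linear VAE (no hidden layers) with fully controlled weights;
# used wherever a test needs exact forward-pass arithmetic.
manual_vae <- function(M, d, enc_Wmu = matrix(0, M, d), enc_bmu = numeric(d),
                       enc_Wlv = matrix(0, M, d), enc_blv = numeric(d),
                       dec_Wout = matrix(0, d, M), dec_bout = numeric(M)) {
  p <- init_vae_params(vae_architecture(M, d, integer(0)), seed = 1)
  p$weights$enc_Wmu <- enc_Wmu; p$weights$enc_bmu <- enc_bmu
  p$weights$enc_Wlv <- enc_Wlv; p$weights$enc_blv <- enc_blv
  p$weights$dec_Wout <- dec_Wout; p$weights$dec_bout <- dec_bout
  p
}

# A standardized_matrix wrapper around a bare matrix (fully observed).
as_sm <- function(x, item_ids = sprintf("item%02d", seq_len(ncol(x)))) {
  colnames(x) <- item_ids
  rm <- response_matrix(x, item_ids = item_ids)
  sm <- rm
  structure(list(x = x, missing_mask = matrix(TRUE, nrow(x), ncol(x)),
                 scaling = NULL, item_ids = item_ids,
                 respondent_ids = rm$respondent_ids),
            class = "standardized_matrix")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
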