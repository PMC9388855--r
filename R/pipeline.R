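## Orchestration layer: resolved YAML configs in, TSV/JSON reports out.
## Every command re-derives its inputs from the config + master seed, so a
## report can always be regenerated from its embedded config.

stop_config <- function(...) {
  stop(structure(class = c("vaefa_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

log_line <- function(cfg, ...) {
  if (isTRUE(cfg$quiet)) return(invisible())
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [seed ", cfg$seed, "] ", ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a pipeline configuration
#'
#' Accepts a YAML file path or an already-parsed list, fills defaults and
#' validates types/ranges before any work starts.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a YAML mapping")
  cfg <- config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "vaefa-out"
  cfg$runs <- as.integer(cfg$runs %||% 1L)
  cfg$quiet <- isTRUE(cfg$quiet)
  cfg$split <- utils::modifyList(list(test_frac = 0.2, val_frac = 0.2),
                                 cfg$split %||% list())
  cfg$vae <- utils::modifyList(
    list(n_latent = NULL, hidden_sizes = NULL, learning_rate = 1e-3,
         batch_size = 256L, max_epochs = 500L, patience = 20L),
    cfg$vae %||% list())
  cfg$stability <- utils::modifyList(
    list(threshold_start = 0.85, threshold_step = 0.005, method = "leiden"),
    cfg$stability %||% list())
  cfg$association <- utils::modifyList(
    list(item_threshold = 0.1, max_reduction = 0.1, min_items = 5L),
    cfg$association %||% list())
  cfg$lfa <- utils::modifyList(list(d = NULL, score_method = "thurstone"),
                               cfg$lfa %||% list())
  if (is.null(cfg$data) || (is.null(cfg$data$path) && is.null(cfg$data$generator))) {
    stop_config("config needs data.path or data.generator")
  }
  with(cfg$split, {
    if (test_frac <= 0 || test_frac >= 1 || val_frac <= 0 || val_frac >= 1) {
      stop_config("split fractions must be in (0, 1)")
    }
  })
  if (cfg$runs < 1) stop_config("runs must be >= 1")
  class(cfg) <- c("run_config", "list")
  cfg
}

ensure_outdir <- function(cfg, force = FALSE) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg$output_dir
}

config_generator_spec <- function(cfg) {
  g <- cfg$data$generator
  questionnaire_spec(
    n_samples = g$n_samples, n_items = g$n_items, d_true = g$d_true,
    link = g$link %||% "linear",
    loading_strength = g$loading_strength %||% 0.8,
    noise_sd = g$noise_sd %||% 0.6,
    likert_levels = g$likert_levels,
    missing_rate = g$missing_rate %||% 0,
    seed = g$seed %||% cfg$seed)
}

load_config_data <- function(cfg) {
  rm <- if (!is.null(cfg$data$path)) {
    load_responses(cfg$data$path, sep = cfg$data$sep %||% ",",
                   id_column = cfg$data$id_column)
  } else {
    simulate_questionnaire(config_generator_spec(cfg))$responses
  }
  if (!is.null(cfg$data$check_items) && length(cfg$data$check_items)) {
    rm <- filter_by_check_items(rm, cfg$data$check_items,
                                cfg$data$required_value %||% 7)
  }
  rm
}

# Shared front half of every analysis command: load, split, standardize
# (train/pool and test scaled separately).
prepare_data <- function(cfg) {
  rm <- load_config_data(cfg)
  sb <- split_respondents(rm, cfg$split$test_frac, cfg$split$val_frac,
                          seed = cfg$seed)
  pool_idx <- sort(c(sb$train, sb$validation))
  list(rm = rm, split = sb,
       pool_rm = rm[pool_idx, ],
       train_sm = standardize(rm[sb$train, ]),
       val_sm = standardize(rm[sb$validation, ]),
       test_sm = standardize(rm[sb$test, ]))
}

embed_config <- function(cfg, path) {
  jsonlite::write_json(list(config = unclass(cfg)), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
}

#' Pipeline commands
#'
#' Each command runs one stage of the questionnaire analysis pipeline from a
#' validated [read_run_config()] configuration and writes plain TSV/JSON
#' reports (with the resolved config embedded) into `output_dir`.
#'
#' * `run_simulate`: generate a synthetic dataset (CSV) plus its
#'   ground-truth bundle.
#' * `run_fit`: split, standardize, train `runs` VAE models, report test-set
#'   correlation and R-squared summaries per run.
#' * `run_lfa`: scree data, principal-axis + varimax loadings,
#'   communalities, Thurstone and Bartlett scores and their reconstruction
#'   metrics.
#' * `run_stability`: multi-run congruence clustering and the stable-factor
#'   report.
#' * `run_associate`: muting-based factor-variable association table.
#' * `run_sfls`: significant-factor-limit search over a bottleneck grid.
#' * `run_compare`: VAE vs LFA correlation summaries at matched d with a
#'   Wilcoxon signed-rank test on the variable-wise correlations.
#'
#' @param config a config path or list, see [read_run_config()].
#' @param force overwrite an existing non-empty output directory.
#' @return the primary result object of the stage, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config, force = FALSE) {
  cfg <- read_run_config(config)
  if (is.null(cfg$data$generator)) stop_config("simulate needs data.generator")
  out <- ensure_outdir(cfg)
  csv <- file.path(out, "dataset.csv")
  if (file.exists(csv) && !force) stop_config(csv, " exists; use force = TRUE")
  spec <- config_generator_spec(cfg)
  sim <- simulate_questionnaire(spec)
  write_responses(sim$responses, csv)
  write_tsv(data.frame(item = sim$responses$item_ids, block = spec$blocks,
                       link = sim$truth$link),
            file.path(out, "truth_blocks.tsv"))
  write_tsv(as.data.frame(sim$truth$z), file.path(out, "truth_factors.tsv"))
  jsonlite::write_json(unclass(spec)[setdiff(names(unclass(spec)), "loadings")],
                       file.path(out, "generator_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  embed_config(cfg, file.path(out, "config.json"))
  log_line(cfg, "simulated ", spec$n_samples, " x ", spec$n_items,
           " dataset -> ", csv)
  invisible(sim)
}

config_arch <- function(cfg, M, d = NULL) {
  d <- d %||% cfg$vae$n_latent
  if (is.null(d)) stop_config("vae.n_latent is required")
  hs <- cfg$vae$hidden_sizes %||% (2L * M)
  vae_architecture(M, d, as.integer(hs))
}

config_vae_config <- function(cfg, seed = cfg$seed) {
  vae_config(cfg$vae$learning_rate, cfg$vae$batch_size, cfg$vae$max_epochs,
             cfg$vae$patience, seed = seed)
}

#' @rdname pipeline
#' @export
run_fit <- function(config, force = FALSE) {
  cfg <- read_run_config(config)
  out <- ensure_outdir(cfg)
  dat <- prepare_data(cfg)
  arch <- config_arch(cfg, ncol(dat$rm$scores))
  summaries <- list(); models <- list()
  for (r in seq_len(cfg$runs)) {
    cc <- config_vae_config(cfg, seed = fan_seed(cfg$seed, r))
    m <- fit_vae(dat$train_sm, dat$val_sm, arch, cc)
    v <- vae_reconstruct(m, dat$test_sm)
    cp_var <- reconstruction_correlation(dat$test_sm, v, axis = "variable")
    cp_sam <- reconstruction_correlation(dat$test_sm, v, axis = "sample")
    r2 <- reconstruction_r2(dat$test_sm, v)
    save_vae(m, file.path(out, sprintf("vae_run%02d.json", r)))
    write_tsv(m$log, file.path(out, sprintf("train_log_run%02d.tsv", r)))
    summaries[[r]] <- data.frame(
      run = r, seed = cc$seed, stopped_epoch = m$stopped_epoch,
      var_corr_mean = cp_var$mean, var_corr_sd = cp_var$sd,
      sample_corr_mean = cp_sam$mean, sample_corr_sd = cp_sam$sd,
      r2_mean = mean(r2), r2_sd = stats::sd(r2))
    models[[r]] <- m
    log_line(cfg, sprintf("run %d: variable-wise corr %.3f (%.3f)", r,
                          cp_var$mean, cp_var$sd))
  }
  tab <- do.call(rbind, summaries)
  write_tsv(tab, file.path(out, "fit_summary.tsv"))
  embed_config(cfg, file.path(out, "config.json"))
  invisible(list(models = models, summary = tab, data = dat))
}

#' @rdname pipeline
#' @export
run_lfa <- function(config, force = FALSE) {
  cfg <- read_run_config(config)
  out <- ensure_outdir(cfg)
  dat <- prepare_data(cfg)
  d <- cfg$lfa$d %||% cfg$vae$n_latent
  if (is.null(d)) stop_config("lfa.d is required")
  es <- eigen_spectrum(dat$train_sm)
  write_tsv(data.frame(index = seq_along(es$eigenvalues),
                       eigenvalue = es$eigenvalues),
            file.path(out, "scree.tsv"))
  lm0 <- fit_principal_factors(dat$train_sm, d)
  lmv <- rotate_varimax(lm0)
  write_tsv(data.frame(item = lmv$item_ids, round(lmv$loadings, 6),
                       communality = communalities(lmv)),
            file.path(out, "lfa_loadings.tsv"))
  R_train <- item_correlation(dat$train_sm)
  res <- lapply(c("thurstone", "bartlett"), function(method) {
    fs <- factor_scores(dat$test_sm, lmv, method = method, R = R_train)
    v <- reconstruct_lfa(fs, lmv)
    cp <- reconstruction_correlation(dat$test_sm, v, axis = "variable")
    list(method = method, scores = fs, corr = cp)
  })
  tab <- data.frame(
    method = vapply(res, function(z) z$method, ""),
    var_corr_mean = vapply(res, function(z) z$corr$mean, 0),
    var_corr_sd = vapply(res, function(z) z$corr$sd, 0),
    n_eigen_gt_one = es$n_gt_one)
  write_tsv(tab, file.path(out, "lfa_summary.tsv"))
  embed_config(cfg, file.path(out, "config.json"))
  log_line(cfg, sprintf("LFA d=%d: %d eigenvalues > 1, thurstone corr %.3f",
                        d, es$n_gt_one, tab$var_corr_mean[1]))
  invisible(list(eigen = es, loadings = lmv, results = res, summary = tab,
                 data = dat))
}

#' @rdname pipeline
#' @export
run_stability <- function(config, force = FALSE) {
  cfg <- read_run_config(config)
  if (cfg$runs < 2) stop_config("stability needs runs >= 2")
  out <- ensure_outdir(cfg)
  dat <- prepare_data(cfg)
  arch <- config_arch(cfg, ncol(dat$rm$scores))
  runs <- fit_vae_runs(dat$pool_rm, arch, config_vae_config(cfg),
                       R = cfg$runs, val_frac = cfg$split$val_frac)
  cm <- build_congruence_matrix(runs$loadings)
  thr <- search_congruence_threshold(cm, cfg$stability$threshold_start,
                                     cfg$stability$threshold_step,
                                     method = cfg$stability$method,
                                     seed = cfg$seed)
  cl <- cluster_factors(cm, thr, method = cfg$stability$method,
                        seed = cfg$seed)
  stab <- stable_factors(cl)
  cons <- consensus_loadings(cl, runs$loadings)
  write_tsv(as.data.frame(cm$C), file.path(out, "congruence_matrix.tsv"))
  write_tsv(stab, file.path(out, "stable_factors.tsv"))
  if (!is.null(cons)) {
    write_tsv(data.frame(item = cons$item_ids, round(cons$loadings, 6)),
              file.path(out, "consensus_loadings.tsv"))
  }
  embed_config(cfg, file.path(out, "config.json"))
  log_line(cfg, sprintf("threshold %.3f: %d stable factors", thr, nrow(stab)))
  invisible(list(runs = runs, congruence = cm, threshold = thr,
                 clusters = cl, stable = stab, consensus = cons, data = dat))
}

#' @rdname pipeline
#' @export
run_associate <- function(config, force = FALSE) {
  cfg <- read_run_config(config)
  out <- ensure_outdir(cfg)
  dat <- prepare_data(cfg)
  arch <- config_arch(cfg, ncol(dat$rm$scores))
  m <- fit_vae(dat$train_sm, dat$val_sm, arch,
               config_vae_config(cfg, seed = fan_seed(cfg$seed, 1L)))
  prof <- association_profile(m, dat$test_sm,
                              item_threshold = cfg$association$item_threshold,
                              max_reduction = cfg$association$max_reduction,
                              min_items = cfg$association$min_items)
  write_tsv(prof$table, file.path(out, "association.tsv"))
  embed_config(cfg, file.path(out, "config.json"))
  log_line(cfg, sprintf("%d/%d factors noise-like", sum(prof$noise),
                        nrow(prof$reductions)))
  invisible(list(model = m, profile = prof, data = dat))
}

#' @rdname pipeline
#' @export
run_sfls <- function(config, force = FALSE) {
  cfg <- read_run_config(config)
  if (is.null(cfg$sfls$d_grid)) stop_config("sfls.d_grid is required")
  out <- ensure_outdir(cfg)
  dat <- prepare_data(cfg)
  res <- sfls(dat$pool_rm, dat$test_sm, as.integer(cfg$sfls$d_grid),
              config = config_vae_config(cfg),
              hidden_sizes = cfg$vae$hidden_sizes,
              R = cfg$runs, val_frac = cfg$split$val_frac,
              item_threshold = cfg$association$item_threshold,
              max_reduction = cfg$association$max_reduction,
              min_items = cfg$association$min_items,
              threshold_start = cfg$stability$threshold_start,
              threshold_step = cfg$stability$threshold_step)
  jsonlite::write_json(
    list(d_grid = res$d_grid, counts = res$counts,
         mean_correlation = res$mean_correlation,
         recommended_d = res$recommended_d,
         plateau_count = res$plateau_count,
         inconclusive = res$inconclusive, degenerate = res$degenerate),
    file.path(out, "sfls.json"), auto_unbox = TRUE, digits = NA)
  embed_config(cfg, file.path(out, "config.json"))
  log_line(cfg, sprintf("SFLS recommended d = %d", res$recommended_d))
  invisible(res)
}

#' @rdname pipeline
#' @export
run_compare <- function(config, force = FALSE) {
  cfg <- read_run_config(config)
  out <- ensure_outdir(cfg)
  dat <- prepare_data(cfg)
  d <- cfg$vae$n_latent %||% cfg$lfa$d
  if (is.null(d)) stop_config("vae.n_latent is required for compare")
  arch <- config_arch(cfg, ncol(dat$rm$scores), d = d)
  m <- fit_vae(dat$train_sm, dat$val_sm, arch,
               config_vae_config(cfg, seed = fan_seed(cfg$seed, 1L)))
  v_vae <- vae_reconstruct(m, dat$test_sm)
  lmv <- rotate_varimax(fit_principal_factors(dat$train_sm, d))
  fs <- factor_scores(dat$test_sm, lmv, method = cfg$lfa$score_method,
                      R = item_correlation(dat$train_sm))
  v_lfa <- reconstruct_lfa(fs, lmv)
  rows <- list()
  for (axis in c("variable", "sample")) {
    for (meth in c("vae", "lfa")) {
      v <- if (meth == "vae") v_vae else v_lfa
      cp <- reconstruction_correlation(dat$test_sm, v, axis = axis)
      rows[[length(rows) + 1]] <- data.frame(
        method = meth, axis = axis, corr_mean = cp$mean, corr_sd = cp$sd)
    }
  }
  cv <- reconstruction_correlation(dat$test_sm, v_vae)$values
  cl <- reconstruction_correlation(dat$test_sm, v_lfa)$values
  wt <- stats::wilcox.test(cv, cl, paired = TRUE, exact = FALSE)
  tab <- do.call(rbind, rows)
  tab$wilcoxon_p_variable <- wt$p.value
  write_tsv(tab, file.path(out, "compare.tsv"))
  embed_config(cfg, file.path(out, "config.json"))
  log_line(cfg, sprintf("VAE %.3f vs LFA %.3f (variable-wise), p = %.3g",
                        tab$corr_mean[1], tab$corr_mean[2], wt$p.value))
  invisible(list(table = tab, wilcoxon = wt, vae = m, lfa = lmv, data = dat))
}

#' Command-line entry point
#'
#' Dispatches `vaefa <command> --config <yaml> [--force] [--quiet]` to the
#' corresponding `run_*` function. Exit status: 0 ok, 2 configuration
#' error, 3 data error, 4 numeric/convergence error.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
vaefa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c(simulate = run_simulate, fit = run_fit, lfa = run_lfa,
            stability = run_stability, associate = run_associate,
            sfls = run_sfls, compare = run_compare)
  usage <- paste0("usage: vaefa <", paste(names(cmds), collapse = "|"),
                  "> --config <yaml> [--force] [--quiet]")
  if (!length(args) || !args[1] %in% names(cmds)) {
    message(usage)
    return(invisible(2L))
  }
  force <- "--force" %in% args
  quiet <- "--quiet" %in% args
  ci <- which(args == "--config")
  if (!length(ci) || ci + 1 > length(args)) {
    message("missing --config; ", usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- read_run_config(args[ci + 1])
    cfg$quiet <- quiet
    cmds[[args[1]]](cfg, force = force)
    0L
  },
  vaefa_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("parse|file not found|empty|item", msg)) 3L else 4L
  })
  invisible(status)
}
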