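#' Respondent-by-item questionnaire matrix
#'
#' Container for raw questionnaire scores: an N x M numeric matrix with a
#' parallel observation mask. Missing cells are stored as `NA` in `scores`
#' and `FALSE` in `missing_mask` (`TRUE` means observed).
#'
#' @param scores N x M numeric matrix; `NA` marks missing cells.
#' @param item_ids unique item labels (defaults to column names).
#' @param respondent_ids respondent labels (defaults to row names).
#' @return an object of class `response_matrix`.
#' @export
response_matrix <- function(scores, item_ids = colnames(scores),
                            respondent_ids = rownames(scores)) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) < 1) stop("scores must have at least one item")
  if (is.null(item_ids)) item_ids <- sprintf("item%02d", seq_len(ncol(scores)))
  if (is.null(respondent_ids)) respondent_ids <- as.character(seq_len(nrow(scores)))
  if (anyDuplicated(item_ids)) stop("item labels must be unique")
  if (length(item_ids) != ncol(scores)) stop("item_ids length mismatch")
  dimnames(scores) <- list(respondent_ids, item_ids)
  structure(list(scores = scores, missing_mask = !is.na(scores),
                 item_ids = as.character(item_ids),
                 respondent_ids = as.character(respondent_ids)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d respondents x %d items (%.1f%% observed)\n",
              nrow(x$scores), ncol(x$scores), 100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$scores)

#' @export
`[.response_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$scores))
  if (missing(j)) j <- seq_len(ncol(x$scores))
  response_matrix(x$scores[i, j, drop = FALSE],
                  item_ids = x$item_ids[j],
                  respondent_ids = x$respondent_ids[i])
}

#' Read a questionnaire matrix from delimited text
#'
#' Expects a header row of item labels and one row per respondent. Cells
#' matching one of the `na` encodings become missing; any other cell must
#' parse as a number.
#'
#' @param path file path.
#' @param sep field delimiter (`","` for CSV, `"\t"` for TSV).
#' @param na character vector of encodings treated as missing.
#' @param id_column optional name of a column holding respondent ids.
#' @return a [response_matrix()].
#' @export
load_responses <- function(path, sep = ",", na = c("", "NA", "NaN"),
                           id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  respondent_ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) stop("id column not found: ", id_column)
    respondent_ids <- df[[id_column]]
    df <- df[setdiff(names(df), id_column)]
  }
  if (anyDuplicated(names(df))) {
    stop("duplicate item labels in header: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  scores <- matrix(NA_real_, nrow(df), ncol(df),
                   dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    raw <- trimws(df[[j]])
    is_na <- raw %in% na
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is_na & is.na(val))
    if (length(bad)) {
      stop(sprintf("cannot parse cell at row %d, column '%s': \"%s\"",
                   bad[1], names(df)[j], raw[bad[1]]))
    }
    val[is_na] <- NA_real_
    scores[, j] <- val
  }
  response_matrix(scores, item_ids = names(df), respondent_ids = respondent_ids)
}

#' Write a questionnaire matrix as delimited text
#'
#' Inverse of [load_responses()]: missing cells are written as empty fields,
#' so a write/load round trip preserves scores and mask exactly.
#'
#' @param rm a [response_matrix()].
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_responses <- function(rm, path, sep = ",") {
  stopifnot(inherits(rm, "response_matrix"))
  utils::write.table(rm$scores, path, sep = sep, na = "", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Keep only respondents who answered verification items correctly
#'
#' Attention/verification items (e.g. "answer 'strongly agree' here") are
#' used to drop careless respondents: only rows where every check item
#' equals `required_value` survive, and the check items themselves are
#' removed from the returned matrix. Surviving rows keep their order.
#'
#' @param rm a [response_matrix()].
#' @param check_items labels of the verification items.
#' @param required_value the score a valid respondent must have given.
#' @return a filtered [response_matrix()] (possibly with zero rows).
#' @export
filter_by_check_items <- function(rm, check_items, required_value) {
  stopifnot(inherits(rm, "response_matrix"))
  if (length(check_items) == 0) return(rm)
  unknown <- setdiff(check_items, rm$item_ids)
  if (length(unknown)) stop("unknown check item(s): ", paste(unknown, collapse = ", "))
  chk <- rm$scores[, check_items, drop = FALSE]
  keep <- rowSums(chk == required_value, na.rm = TRUE) == length(check_items) &
    rowSums(is.na(chk)) == 0
  keep_items <- setdiff(rm$item_ids, check_items)
  out <- rm$scores[keep, keep_items, drop = FALSE]
  if (nrow(out) == 0) {
    out <- matrix(NA_real_, 0, length(keep_items),
                  dimnames = list(NULL, keep_items))
  }
  response_matrix(out, item_ids = keep_items,
                  respondent_ids = rm$respondent_ids[keep])
}

#' Split respondents into train / validation / test sets
#'
#' Nested holdout split: `test_frac` of all respondents form the test set,
#' then `val_frac` of the remainder form the validation set (the default
#' 0.2/0.2 is the usual 80-20% split applied twice). Uniform random over
#' respondents, deterministic given the seed.
#'
#' @param rm a [response_matrix()] (or an integer N).
#' @param test_frac,val_frac proportions in (0, 1).
#' @param seed integer seed.
#' @return an object of class `split_bundle` with sorted integer index
#'   vectors `train`, `validation`, `test` and the `seed`.
#' @export
split_respondents <- function(rm, test_frac = 0.2, val_frac = 0.2, seed = 1L) {
  N <- if (inherits(rm, "response_matrix")) nrow(rm$scores) else as.integer(rm)
  if (test_frac <= 0 || test_frac >= 1 || val_frac <= 0 || val_frac >= 1) {
    stop("fractions must lie strictly between 0 and 1")
  }
  set.seed(as.integer(seed))
  perm <- sample.int(N)
  n_test <- round(test_frac * N)
  n_val <- round(val_frac * (N - n_test))
  if (n_test < 1 || n_val < 1 || N - n_test - n_val < 1) {
    stop("N = ", N, " is too small for non-empty train/validation/test subsets")
  }
  test <- sort(perm[seq_len(n_test)])
  validation <- sort(perm[n_test + seq_len(n_val)])
  train <- sort(perm[(n_test + n_val + 1):N])
  structure(list(train = train, validation = validation, test = test,
                 seed = as.integer(seed)),
            class = "split_bundle")
}

#' @export
print.split_bundle <- function(x, ...) {
  cat(sprintf("split_bundle: train %d / validation %d / test %d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

#' Z-score a questionnaire matrix item by item
#'
#' Each item is centred and scaled by its mean and population SD computed on
#' its observed entries; missing cells are set to exactly 0 *after* scaling,
#' so they sit at the item mean and carry no signal. When `params` is given
#' (e.g. the training set's scaling, for held-out evaluation of another
#' region), those means/SDs are applied instead of refitting.
#'
#' @param rm a [response_matrix()].
#' @param params optional `scaling_params` to reuse.
#' @param on_zero_variance `"error"` (default) to fail on a constant item,
#'   `"drop"` to remove it with a warning.
#' @return an object of class `standardized_matrix` with fields `x` (the
#'   z-scored matrix, 0 at missing cells), `missing_mask`, `scaling`,
#'   `item_ids`, `respondent_ids`.
#' @export
standardize <- function(rm, params = NULL,
                        on_zero_variance = c("error", "drop")) {
  stopifnot(inherits(rm, "response_matrix"))
  on_zero_variance <- match.arg(on_zero_variance)
  if (nrow(rm$scores) == 0) stop("cannot standardize an empty matrix")
  if (is.null(params)) {
    means <- vapply(seq_len(ncol(rm$scores)), function(j)
      mean(rm$scores[, j], na.rm = TRUE), 0)
    sds <- vapply(seq_len(ncol(rm$scores)), function(j) {
      v <- rm$scores[, j]; v <- v[!is.na(v)]
      sqrt(mean((v - mean(v))^2))        # population SD (ddof = 0)
    }, 0)
    params <- structure(list(means = means, sds = sds,
                             item_ids = rm$item_ids),
                        class = "scaling_params")
  } else {
    stopifnot(inherits(params, "scaling_params"))
    if (!identical(params$item_ids, rm$item_ids)) {
      stop("scaling_params were fitted on different items")
    }
  }
  zero <- which(!is.finite(params$sds) | params$sds <= 0)
  if (length(zero)) {
    if (on_zero_variance == "error") {
      stop("zero-variance item(s): ", paste(rm$item_ids[zero], collapse = ", "))
    }
    warning("dropping zero-variance item(s): ",
            paste(rm$item_ids[zero], collapse = ", "))
    keep <- setdiff(seq_along(rm$item_ids), zero)
    return(standardize(rm[, keep],
                       params = structure(list(means = params$means[keep],
                                               sds = params$sds[keep],
                                               item_ids = rm$item_ids[keep]),
                                          class = "scaling_params")))
  }
  x <- sweep(sweep(rm$scores, 2, params$means, "-"), 2, params$sds, "/")
  x[!rm$missing_mask] <- 0
  structure(list(x = x, missing_mask = rm$missing_mask, scaling = params,
                 item_ids = rm$item_ids, respondent_ids = rm$respondent_ids),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat(sprintf("standardized_matrix: %d x %d (%.1f%% observed)\n",
              nrow(x$x), ncol(x$x), 100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.standardized_matrix <- function(x) dim(x$x)
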