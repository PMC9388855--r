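#' @keywords internal
"_PACKAGE"

#' Pearson correlation with a constant-vector convention
#'
#' Everywhere in the package a correlation involving a (near-)constant vector
#' is defined as 0 rather than `NA`: reduction profiles and congruence
#' matrices must stay finite when a latent factor collapses or a decoder
#' output is constant.
#'
#' @param a,b numeric vectors of equal length.
#' @param min_n minimum number of paired values required; below it the
#'   correlation is 0 (with a warning).
#' @return a single correlation in `[-1, 1]`, or 0 under the convention.
#' @export
safe_cor <- function(a, b, min_n = 3L) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < min_n) {
    warning("fewer than ", min_n, " paired observations; correlation set to 0")
    return(0)
  }
  sda <- stats::sd(a); sdb <- stats::sd(b)
  if (!is.finite(sda) || !is.finite(sdb) || sda == 0 || sdb == 0) return(0)
  r <- stats::cor(a, b)
  if (!is.finite(r)) 0 else r
}

# Deterministic fan-out of one master seed into per-purpose sub-seeds.
# Linear-congruential step modulo the Mersenne prime 2^31 - 1 keeps every
# derived seed a valid positive 32-bit integer.
fan_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(2L)) s <- (s * 48271 + as.double(k) * 1299721 + i) %% 2147483647
  as.integer(s + 1)
}

# All permutations of 1..n (n <= 8 guarded); used by the brute-force
# factor-matching oracle.
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
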