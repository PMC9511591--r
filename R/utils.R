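# Internal helpers: seed streams, derangements, argument checks.

#' Derive per-task seeds from a master seed
#'
#' All multi-task randomness in the package (one seed per Stage-1 row, per
#' simulation replicate, ...) flows from a single master seed through this
#' function: the master seed seeds R's RNG once and `n` sub-seeds are drawn
#' as uniform integers.  The scheme is deterministic and documented so that
#' any individual task can be reproduced in isolation from `(master, index)`.
#'
#' @param master integer master seed, or `NULL` for no seeding (sub-seeds
#'   are then drawn from the current RNG state).
#' @param n number of sub-seeds required.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(n >= 1)
  if (!is.null(master)) {
    master <- as.integer(master)
    set.seed(master)
  }
  sample.int(2147483646L, n, replace = TRUE)
}

# Uniform random derangement (permutation with no fixed point) of 1..n by
# rejection from uniform permutations; acceptance probability ~ 1/e.
# n = 2 admits a single derangement (the swap) so a permutation null built
# from it would be degenerate: refuse.
rderange <- function(n) {
  if (n < 3L) {
    stop("derangement resampling needs at least 3 pairs (got ", n, ")")
  }
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) {
      return(p)
    }
  }
}

check_positive <- function(x, name, allow_na = FALSE) {
  bad <- if (allow_na) !is.na(x) & x <= 0 else is.na(x) | x <= 0
  if (any(bad)) {
    stop("'", name, "' must be positive", if (!allow_na) " and non-missing",
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_est_sd <- function(est, sd, digits = 3) {
  s <- if (is.na(sd)) "–" else formatC(sd, digits = digits, format = "f")
  paste0(formatC(est, digits = digits, format = "f"), " (", s, ")")
}
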