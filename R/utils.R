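# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the Mersenne-Twister seed, runs \code{code}, and restores the caller's
#' RNG state, so that seeded operations never perturb global randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Derive the r-th repeat seed from a base seed, kept inside 32-bit range.
derive_seed <- function(seed_base, r) {
  as.integer((as.numeric(seed_base) + as.numeric(r)) %% 2147483646L + 1L)
}

# Dense base-matrix view of a count container's values.
dense_values <- function(x) {
  v <- if (is.list(x) && !is.null(x$values)) x$values else x
  as.matrix(v)
}

# Row-wise sample sd (n-1 denominator) of a dense matrix.
row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2L) stop("need at least 2 columns for a sample sd")
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
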