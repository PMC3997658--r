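#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state so that seeded package internals never disturb
#' user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic per-unit child seed derived from a master seed. Kept below
# 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + 7919 * as.numeric(i)) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Apply an IIR filter (coefficients b, a) along the rows of a matrix,
# column-wise with zero initial conditions. The FIR (numerator) part runs as
# a one-sided convolution on a zero-padded head, the AR (denominator) part
# as a recursive filter; both via stats::filter, which is C-implemented and
# multivariate. x: frames x k.
iir_filter_mat <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- rbind(matrix(0, nb - 1L, ncol(x)), x)
  y <- stats::filter(xp, b, method = "convolution", sides = 1)
  y <- y[nb:nrow(xp), , drop = FALSE]
  if (length(a) > 1L) y <- stats::filter(y, -a[-1], method = "recursive")
  matrix(as.numeric(y), nrow(x), ncol(x))
}

# Zero-phase forward-backward filtering with odd-reflection padding.
# x: frames x k matrix. n_pad is clipped to frames - 1.
filtfilt_mat <- function(b, a, x, n_pad) {
  nt <- nrow(x)
  n_pad <- max(0L, min(as.integer(n_pad), nt - 1L))
  if (n_pad > 0L) {
    first <- matrix(x[1L, ], n_pad, ncol(x), byrow = TRUE)
    last <- matrix(x[nt, ], n_pad, ncol(x), byrow = TRUE)
    top <- 2 * first - x[(n_pad + 1L):2L, , drop = FALSE]
    bot <- 2 * last - x[(nt - 1L):(nt - n_pad), , drop = FALSE]
    x <- rbind(top, x, bot)
  }
  y <- iir_filter_mat(b, a, x)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- iir_filter_mat(b, a, y)
  y <- y[nrow(y):1L, , drop = FALSE]
  if (n_pad > 0L) y <- y[(n_pad + 1L):(n_pad + nt), , drop = FALSE]
  y
}

# Column-standardize a matrix: demean and scale each column to unit sample SD.
standardize_cols <- function(x, tol = 1e-12) {
  x <- sweep(x, 2L, colMeans(x), "-")
  s <- sqrt(colSums(x^2) / (nrow(x) - 1L))
  if (any(s < tol)) stopf("degenerate (zero-variance) series encountered")
  sweep(x, 2L, s, "/")
}

# md5 of a canonical JSON rendering, used for run manifests.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
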