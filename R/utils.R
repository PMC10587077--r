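# Internal helpers shared across modules.

#' @importFrom methods new is validObject slot
#' @importFrom stats rnorm runif rpois sd var median cov t.test lm pt qt
#'   coef fft mvfft predict quantile ave
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so that a `seed` argument is both sufficient and
# non-invasive.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream label, keeping the result
# inside the 32-bit integer range. Used to give each simulated session an
# independent, regenerable RNG stream.
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  # polynomial rolling hash over the label bytes, modulo a prime < 2^31
  bytes <- as.integer(charToRaw(label))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

roi_levels <- function() c("M1", "DLPFC", "Cd")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# min(1, p * m) Bonferroni correction
bonferroni <- function(p, m) pmin(1, p * m)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)
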