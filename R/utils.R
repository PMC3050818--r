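# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's .Random.seed is restored afterwards so library code
# never perturbs user-level randomness. `seed = NULL` runs as-is.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Population standard deviation (divide by N). This convention is used
# everywhere a spread enters a reported statistic, and is stated in the docs.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_2d_numeric <- function(x) is.matrix(x) && is.numeric(x)

check_image <- function(x, what = "image") {
  if (!is_2d_numeric(x)) stopf("%s must be a 2-D numeric matrix", what)
  invisible(x)
}
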