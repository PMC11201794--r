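# Internal helpers shared across modules.

#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' @noRd
is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x) && x >= min
}

#' @noRd
is_number <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x)
}

# Case-insensitive gene key: symbols from different platforms disagree on
# casing; matching is done on the upper-cased symbol, first-seen casing is
# kept for reporting.
#' @noRd
gene_key <- function(x) toupper(x)

# Run code with a private RNG stream so generators are deterministic without
# clobbering the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Inverse of trigamma by Newton iteration on 1/trigamma (monotone, convex),
# used by the empirical-Bayes variance prior fit.
#' @noRd
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}
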