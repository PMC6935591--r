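#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis pnorm pchisq quantile sd var cor rnorm runif rbinom
#'   rbeta lm predict coef residuals optimize setNames complete.cases prcomp
#'   kmeans nls nls.control dnorm integrate ks.test median SSfpl
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL leaves the current stream in place.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed, keeping within 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1009L + as.integer(k) * 9973L) %% .Machine$integer.max
}

assert_scalar_in <- function(x, lo, hi, name, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a single number in %s%g, %g%s.", name,
                  if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]"))
  }
  invisible(x)
}

# Rank with deterministic tie-break: primary key descending (or ascending),
# ties broken by `id` lexicographically. Returns 1..n permutation ranks.
rank_with_id <- function(key, id, decreasing = TRUE) {
  ord <- order(if (decreasing) -key else key, as.character(id))
  rk <- integer(length(key))
  rk[ord] <- seq_along(key)
  rk
}
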