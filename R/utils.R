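#' Package-wide empirical quantile
#'
#' All empirical percentiles in the package (diversity null bounds, beta-score
#' top fraction, distance-binned LD thresholds) use a single convention:
#' linear interpolation between closest order statistics
#' (\code{stats::quantile} type 7).
#'
#' @param x numeric vector; \code{NA}s are dropped.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles.
#' @export
pkg_quantile <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, na.rm = TRUE, type = 7, names = FALSE))
}

## run `code` under `seed`, restoring the caller's RNG state afterwards, so
## generators are pure functions of their seed argument
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
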