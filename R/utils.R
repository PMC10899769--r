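#' @importFrom methods is as new
#' @importFrom stats median quantile sd rnorm rnbinom runif p.adjust
#'   wilcox.test kruskal.test cor.test pnorm complete.cases hclust dist
#'   setNames rlnorm
#' @importFrom utils read.table write.table head tail
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic operations in the
# package funnel through this so a seed argument fully determines output.
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

# Derive a child seed from a base seed and a replicate index, kept within
# the 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 1009 + 12345) %% 2147483647L)
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# half-open [start, end) integer intervals as a two-column matrix helper
interval_overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
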