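# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores
# the caller's RNG state afterwards.  seed = NA means "use the current
# stream" (no isolation).
withSeed <- function(seed, expr) {
  if (is.na(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Split `width` columns into `n` contiguous bands; the remainder
# r = width %% n is given, one extra column each, to the first r bands.
# Returns the integer band widths.  Shared by the subregion partition and
# the phantom's ground-truth band rendering so the two agree by construction.
splitWidths <- function(width, n = 5L) {
  if (width < n) stop("width (", width, ") must be at least ", n)
  base <- width %/% n
  r <- width %% n
  base + c(rep(1L, r), rep(0L, n - r))
}

# Band index (1..n) for 1-based column offsets within a span of `width`.
bandIndex <- function(offset, width, n = 5L) {
  w <- splitWidths(width, n)
  findInterval(offset, cumsum(c(0L, w)) + 1L, rightmost.closed = FALSE)
}

clampInt <- function(x, lo, hi) pmin(pmax(x, lo), hi)

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
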