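# Shared fixtures, built in code.

# Small noiseless phantom: fast default for exactness tests.
noiselessSpec <- function(nSlices = 1L, ...) {
  phantomSpec(nSlices = nSlices, noiseModel = "none", ...)
}

# Elliptical 0/1 mask with given semi-axes and rotation (degrees).
ellipseMask <- function(H, W, cx, cy, a, b, angleDeg = 0) {
  th <- angleDeg * pi / 180
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  dx <- g$x - cx; dy <- g$y - cy
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  m <- matrix(0L, H, W)
  m[cbind(g$y, g$x)[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]] <- 1L
  m
}

# Independent step-up FDR oracle, straight from the definition.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, n * p[o[i]] / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# From-scratch one-way ANOVA ICC(1,1) oracle (loops, no matrix algebra).
iccOracle <- function(m) {
  rows <- list()
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]; v <- v[!is.na(v)]
    if (length(v) > 0) rows[[length(rows) + 1]] <- v
  }
  n <- length(rows)
  N <- sum(lengths(rows))
  grand <- sum(unlist(rows)) / N
  bss <- 0; wss <- 0; sumk2 <- 0
  for (v in rows) {
    mi <- mean(v)
    bss <- bss + length(v) * (mi - grand)^2
    wss <- wss + sum((v - mi)^2)
    sumk2 <- sumk2 + length(v)^2
  }
  bms <- bss / (n - 1); wms <- wss / (N - n)
  k0 <- (N - sumk2 / N) / (n - 1)
  (bms - wms) / (bms + (k0 - 1) * wms)
}

# Simulate a one-way random-effects subjects x sessions matrix.
simSeries <- function(n, k, mu, sdB, sdW) {
  matrix(stats::rnorm(n * k, 0, sdW), n, k) + stats::rnorm(n, 0, sdB) + mu
}

# Apply the package's dropout convention to a complete matrix.
applyDropout <- function(m, dropout) {
  for (j in seq_along(dropout)) if (dropout[j] < nrow(m))
    m[(dropout[j] + 1):nrow(m), j] <- NA
  m
}
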