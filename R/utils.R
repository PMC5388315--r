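## Internal helpers.

## Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Maximize a scalar function on [lo, hi]: coarse grid to bracket the
## global interior maximum, then golden-section refinement to `tol`.
maximize_on <- function(f, lo, hi, tol = 1e-6, grid_n = 2000) {
  grid <- seq(lo, hi, length.out = grid_n)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  a <- grid[max(1, i - 1)]; b <- grid[min(grid_n, i + 1)]
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  xm <- (a + b) / 2
  list(maximum = xm, objective = f(xm))
}

## Adjusted R^2 against observed values, k = number of free parameters.
## NaN when the residual degrees of freedom are zero.
r2_adjusted <- function(observed, fitted, k) {
  n <- length(observed)
  rss <- sum((observed - fitted)^2)
  tss <- sum((observed - mean(observed))^2)
  r2 <- 1 - rss / tss
  if (n - k <= 0) return(list(r2 = r2, r2_adj = NaN))
  list(r2 = r2, r2_adj = 1 - (1 - r2) * (n - 1) / (n - k))
}
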