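# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Composite-trapezoid quadrature weights for the kept points of a uniform
# grid.  `keep` is a logical vector over the grid; each contiguous run of
# kept points gets the usual h*(1/2, 1, ..., 1, 1/2) weights, so masked-out
# regions contribute nothing and segment edges are not double counted.
# A single isolated point degenerates to a rectangle of width h.
trap_weights <- function(grid, keep = NULL) {
  n <- length(grid)
  if (n < 2L) stop("grid must have at least 2 points")
  h <- grid[2L] - grid[1L]
  if (is.null(keep)) keep <- rep(TRUE, n)
  w <- numeric(n)
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    len <- r$lengths[i]
    seg <- if (len == 1L) h else c(h / 2, rep(h, max(0L, len - 2L)), h / 2)
    w[starts[i]:ends[i]] <- seg
  }
  w[keep]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
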