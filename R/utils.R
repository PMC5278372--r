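# Internal numeric and lattice helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Moore-8 neighbour sum of a numeric/logical matrix, zero-padded borders.
neighbor_sum_matrix <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  p[1:nr, 1:nc]           + p[1:nr, 2:(nc + 1L)]           + p[1:nr, 3:(nc + 2L)] +
  p[2:(nr + 1L), 1:nc]                                     + p[2:(nr + 1L), 3:(nc + 2L)] +
  p[3:(nr + 2L), 1:nc]    + p[3:(nr + 2L), 2:(nc + 1L)]    + p[3:(nr + 2L), 3:(nc + 2L)]
}

# Uniform box mean over a (2r+1)^2 window, truncated at borders, via an
# integral image. Used for spatial autocorrelation in synthetic landscapes.
box_smooth <- function(m, radius) {
  r <- as.integer(radius)
  if (r <= 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  cs <- matrix(0, nr + 1L, nc + 1L)
  cs[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  i <- seq_len(nr); j <- seq_len(nc)
  i1 <- pmax(i - r, 1L); i2 <- pmin(i + r, nr)
  j1 <- pmax(j - r, 1L); j2 <- pmin(j + r, nc)
  s <- cs[i2 + 1L, j2 + 1L] - cs[i1, j2 + 1L] - cs[i2 + 1L, j1] + cs[i1, j1]
  s / outer(i2 - i1 + 1L, j2 - j1 + 1L)
}

# Largest-remainder apportionment of `total` integer units proportional to
# nonnegative `x`. Ties on the fractional part go to the larger share, then
# to the earlier index.
largest_remainder <- function(x, total) {
  stopifnot(all(x >= 0), sum(x) > 0, total >= 0)
  q <- x * total / sum(x)
  base <- floor(q)
  rem <- as.integer(round(total - sum(base)))
  out <- base
  if (rem > 0L) {
    pick <- order(-(q - base), -x, seq_along(x))[seq_len(rem)]
    out[pick] <- out[pick] + 1
  }
  as.integer(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
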