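# Independent oracles used across the suite.  They deliberately avoid the
# package's fitting/counting code paths.

# Exhaustive grid-search fit of a symmetric 2D Gaussian + background on a
# small window.  x0/y0/w/h are searched on a regular grid centred on the
# supplied values; the background is solved in closed form (it enters the
# model linearly).  Returns the grid point of minimal residual sum of
# squares.
oracle_grid_fit <- function(window, x0, y0, w0, h0,
                            halfspan = 0.05, step = 0.01) {
  rows <- seq_len(nrow(window)) - 1L
  cols <- seq_len(ncol(window)) - 1L
  ys <- rep(rows, times = length(cols))
  xs <- rep(cols, each = length(rows))
  z <- as.vector(window)
  k <- 4 * log(2)
  gx <- seq(x0 - halfspan, x0 + halfspan, by = step)
  gy <- seq(y0 - halfspan, y0 + halfspan, by = step)
  gw <- seq(w0 - halfspan, w0 + halfspan, by = step)
  gh <- seq(h0 - halfspan, h0 + halfspan, by = step)
  zc <- z - mean(z)
  best <- list(ss = Inf)
  for (xi in gx) for (yi in gy) for (wi in gw) {
    g <- exp(-k * ((xs - xi)^2 + (ys - yi)^2) / wi^2)
    gc <- g - mean(g)
    # SS(h) = sum((zc - h*gc)^2) once the optimal (linear) background is
    # substituted; evaluate the quadratic on the whole h grid at once
    szz <- sum(zc^2); szg <- sum(zc * gc); sgg <- sum(gc^2)
    ss_h <- szz - 2 * gh * szg + gh^2 * sgg
    j <- which.min(ss_h)
    if (ss_h[j] < best$ss) {
      best <- list(ss = ss_h[j], x = xi, y = yi, w = wi, h = gh[j],
                   b = mean(z) - gh[j] * mean(g))
    }
  }
  best
}

# Brute-force codon counter: walks the string three characters at a time.
oracle_codon_counts <- function(seqs) {
  counts <- integer(0)
  for (s in seqs) {
    stopifnot(nchar(s) %% 3 == 0)
    for (i in seq(1, nchar(s), by = 3)) {
      cd <- substr(s, i, i + 2)
      counts[cd] <- (if (is.na(counts[cd])) 0L else counts[cd]) + 1L
    }
  }
  counts
}

# Direct numeric integral of a rendered Gaussian spot (background-free).
oracle_spot_integral <- function(fwhm, h) {
  h * pi * fwhm^2 / (4 * log(2))
}
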