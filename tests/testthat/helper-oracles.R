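# Independent oracles used across the suite. Each reimplements the checked
# operation by a different route than the package code.

# Truncated pseudo-inverse deconvolution via FFT diagonalization of the
# circulant system: eigenvalues are the DFT of the first column, and
# singular values their moduli.
fft_deconvolve_oracle <- function(aif_curve, dt, tissue_curve, threshold) {
  n <- length(aif_curve)
  L <- 2L * n
  lam <- fft(c(aif_curve, numeric(n)) * dt)
  keep <- Mod(lam) >= threshold * max(Mod(lam))
  chat <- fft(c(tissue_curve, numeric(L - length(tissue_curve))))
  khat <- ifelse(keep, chat / lam, 0)
  Re(fft(khat, inverse = TRUE)) / L
}

# Direct O(n^2) discrete convolution, first n samples
direct_convolution_oracle <- function(x, y, dt) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n))
    out[i] <- dt * sum(x[seq_len(i)] * y[i:1])
  out
}

# Flood fill by iterated masked dilation (array shifts), not breadth-first
# search: grow the seed set one dilation at a time until a fixed point.
dilation_flood_oracle <- function(map, seeds, predicate, connectivity = 26L) {
  d <- dim(map)
  pass <- predicate(map)
  pass[!is.finite(map)] <- FALSE
  cur <- array(FALSE, dim = d)
  seeds <- matrix(as.integer(seeds), ncol = 3L)
  cur[seeds] <- TRUE
  cur <- cur & pass
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  if (connectivity == 6L)
    off <- off[abs(off$dx) + abs(off$dy) + abs(off$dz) == 1L, ]
  shift_arr <- function(a, s) {
    out <- array(FALSE, dim = d)
    xs <- max(1, 1 + s[1]):min(d[1], d[1] + s[1])
    ys <- max(1, 1 + s[2]):min(d[2], d[2] + s[2])
    zs <- max(1, 1 + s[3]):min(d[3], d[3] + s[3])
    out[xs, ys, zs] <- a[xs - s[1], ys - s[2], zs - s[3]]
    out
  }
  repeat {
    grown <- cur
    for (o in seq_len(nrow(off)))
      grown <- grown | shift_arr(cur, as.integer(off[o, ]))
    grown <- grown & pass
    if (all(grown == cur)) return(cur)
    cur <- grown
  }
}

# Balanced two-way sums of squares from cell means (independent of lm)
ss_twoway_oracle <- function(y, f1, f2) {
  g <- mean(y)
  m1 <- tapply(y, f1, mean); m2 <- tapply(y, f2, mean)
  mc <- tapply(y, interaction(f1, f2), mean)
  n1 <- tapply(y, f1, length); n2 <- tapply(y, f2, length)
  nc <- tapply(y, interaction(f1, f2), length)
  ss1 <- sum(n1 * (m1 - g)^2)
  ss2 <- sum(n2 * (m2 - g)^2)
  sscells <- sum(nc * (mc - g)^2)
  sse <- sum((y - mc[interaction(f1, f2)])^2)
  list(ss1 = ss1, ss2 = ss2, ss_int = sscells - ss1 - ss2, ss_error = sse,
       ss_total = sum((y - g)^2))
}

# small noiseless phantom shared by several tests
noiseless_phantom <- function(...) phantom_spec(noise_sigma = 0, ...)

# total variation of a curve
total_variation <- function(x) sum(abs(diff(x)))
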