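# Internal helpers: seeded RNG bookkeeping, raster conversions, small math.

# Deterministic 32-bit seed derivation (Lehmer-style fold).  Keeps every
# derived seed in [0, 2^31 - 2] so set.seed() never overflows.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (x in c(...)) {
    # 69621 * m < 2^53, so the double arithmetic below is exact
    s <- (s * 69621 + as.numeric(x) + 1) %% m
  }
  as.integer(s)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# h x w (x ch) array <-> EBImage Image (EBImage puts x on the first margin).
as_ebimage <- function(a) {
  if (length(dim(a)) == 2L) {
    EBImage::Image(t(a))
  } else {
    EBImage::Image(aperm(a, c(2L, 1L, 3L)), colormode = EBImage::Color)
  }
}

from_ebimage <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Quantize [0,1] intensities to the 8-bit grid used by PNG files, so that
# in-memory rasters and write/read round trips agree bit for bit.
quantize8 <- function(x) round(clamp(x, 0, 1) * 255) / 255

# Multi-octave value noise on an h x w grid, values roughly in [-1, 1].
value_noise <- function(h, w, octaves = 3L, seed = 1L) {
  acc <- matrix(0, h, w)
  total <- 0
  for (o in seq_len(octaves)) {
    n <- 2L^o + 1L
    g <- with_seed(derive_seed(seed, 7L, o), matrix(runif(n * n, -1, 1), n, n))
    # bilinear upsample of the coarse grid to the full canvas
    ri <- seq(1, n, length.out = h)
    ci <- seq(1, n, length.out = w)
    r0 <- pmin(floor(ri), n - 1L); fr <- ri - r0
    c0 <- pmin(floor(ci), n - 1L); fc <- ci - c0
    top <- g[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
      g[r0, c0 + 1L, drop = FALSE] * outer(1 - fr, fc)
    bot <- g[r0 + 1L, c0, drop = FALSE] * outer(fr, 1 - fc) +
      g[r0 + 1L, c0 + 1L, drop = FALSE] * outer(fr, fc)
    wgt <- 1 / 2^(o - 1)
    acc <- acc + wgt * (top + bot)
    total <- total + wgt
  }
  acc / total
}

# One-dimensional multi-octave value noise of length n in [-1, 1].
value_noise_1d <- function(n, octaves = 3L, seed = 1L) {
  acc <- numeric(n)
  total <- 0
  for (o in seq_len(octaves)) {
    k <- 2L^o + 1L
    g <- with_seed(derive_seed(seed, 11L, o), runif(k, -1, 1))
    xi <- seq(1, k, length.out = n)
    i0 <- pmin(floor(xi), k - 1L); f <- xi - i0
    wgt <- 1 / 2^(o - 1)
    acc <- acc + wgt * (g[i0] * (1 - f) + g[i0 + 1L] * f)
    total <- total + wgt
  }
  acc / total
}

# Vectorized sRGB (n x 3, in [0,1]) -> HSV (n x 3) and back.
rgb_to_hsv <- function(rgb) {
  t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
}

hsv_to_rgb <- function(hsv) {
  h <- hsv[, 1] * 6
  s <- hsv[, 2]
  v <- hsv[, 3]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t_ <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
    ifelse(i == 3, p, ifelse(i == 4, t_, v)))))
  g <- ifelse(i == 0, t_, ifelse(i == 1, v, ifelse(i == 2, v,
    ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t_,
    ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

lab_to_srgb <- function(lab) {
  clamp(grDevices::convertColor(lab, from = "Lab", to = "sRGB"), 0, 1)
}

srgb_to_lab <- function(rgb) {
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

# 1 - Pearson correlation with the documented zero-variance convention:
# equal sequences -> 0, otherwise the maximum dissimilarity 2.
pearson_dissimilarity <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(as.numeric(x), as.numeric(y)))) 0 else 2)
  }
  1 - stats::cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
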