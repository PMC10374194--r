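# Brute-force O(N^2) DFT oracle, independent of stats::fft.
dft_oracle <- function(s) {
  n <- length(s)
  vapply(0:(n - 1), function(u) {
    sum(s * exp(-2i * pi * (0:(n - 1)) * u / n)) / n
  }, complex(1))
}

wobbly_contour <- function(n = 128, seed = 3) {
  phenosynth:::with_seed(seed, {
    th <- 2 * pi * (0:(n - 1)) / n
    r <- 40 * (1 + 0.15 * cos(3 * th + runif(1, 0, 2 * pi)) +
                 0.08 * cos(5 * th))
    structure(tibble::tibble(x = 100 + r * cos(th), y = 90 + r * sin(th)),
              closed = TRUE,
              class = c("phenosynth_contour", class(tibble::tibble())))
  })
}

test_that("extract_contour resamples the outer boundary at fixed length", {
  s <- disc_sprite()
  ct <- extract_contour(s, 128)
  expect_equal(nrow(ct), 128L)
  r <- sqrt((ct$x - 127.5)^2 + (ct$y - 127.5)^2)
  expect_true(all(abs(r - mean(r)) < 1))  # circle: constant radius

  # square foreground: perimeter within 2% of 4 * side
  px <- array(0, dim = c(128, 128, 4))
  px[40:89, 40:89, 4] <- 1
  sq <- phenosynth:::new_sprite(px, "square")
  ctq <- extract_contour(sq, 256)
  per <- sum(sqrt(diff(c(ctq$x, ctq$x[1]))^2 + diff(c(ctq$y, ctq$y[1]))^2))
  expect_lt(abs(per - 4 * 49) / (4 * 49), 0.02)

  empty <- phenosynth:::new_sprite(array(0, dim = c(32, 32, 4)), "none")
  expect_error(extract_contour(empty), "empty")

  two <- array(0, dim = c(64, 64, 4))
  two[5:20, 5:20, 4] <- 1
  two[40:60, 40:60, 4] <- 1
  expect_warning(ct2 <- extract_contour(phenosynth:::new_sprite(two, "x"), 64),
                 "largest")
  expect_true(all(ct2$x >= 38))  # took the larger component
})

test_that("Fourier coefficients match the single-harmonic disc prediction", {
  n <- 256
  th <- 2 * pi * (0:(n - 1)) / n
  ct <- structure(tibble::tibble(x = 80 + 50 * cos(th), y = 60 + 50 * sin(th)),
                  closed = TRUE,
                  class = c("phenosynth_contour", class(tibble::tibble())))
  d <- shape_descriptor(ct, 16, "paper")
  a <- d$coefficients
  expect_equal(Mod(a[1]), Mod(complex(real = 80, imaginary = 60)),
               tolerance = 1e-9)
  expect_equal(Mod(a[2]), 50, tolerance = 1e-9)
  expect_lt(max(Mod(a[3:(n - 1)])), 1e-10)

  centered <- transform_contour(ct, dx = -80, dy = -60)
  expect_error(shape_descriptor(centered, 16, "paper"), "a\\(0\\)")
})

test_that("fast transform equals the O(N^2) direct-summation oracle", {
  # ellipse with 2:1 axis ratio
  n <- 128
  th <- 2 * pi * (0:(n - 1)) / n
  ct <- structure(tibble::tibble(x = 50 + 60 * cos(th), y = 70 + 30 * sin(th)),
                  closed = TRUE,
                  class = c("phenosynth_contour", class(tibble::tibble())))
  d <- shape_descriptor(ct, 16, "standard")
  s <- complex(real = ct$x, imaginary = ct$y)
  ao <- dft_oracle(s)
  expect_lt(max(Mod(d$coefficients - ao)), 1e-9)
  d_oracle <- Mod(ao[3:18]) / Mod(ao[2])
  expect_lt(max(abs(d$normalized - d_oracle)), 1e-9)
})

test_that("standard-mode descriptors are invariant to rigid motion and start shift", {
  ct <- wobbly_contour()
  d0 <- shape_descriptor(ct, 16, "standard")$normalized
  for (tr in list(c(37, -12), c(-5, 80))) {
    d1 <- shape_descriptor(transform_contour(ct, dx = tr[1], dy = tr[2]),
                           16, "standard")$normalized
    expect_lt(max(abs(d1 - d0)), 1e-6)
  }
  for (ang in c(-170, -45, 13, 90, 137, 222, 301)) {
    d1 <- shape_descriptor(transform_contour(ct, angle = ang),
                           16, "standard")$normalized
    expect_lt(max(abs(d1 - d0)), 1e-6)
  }
  for (sc in c(0.5, 0.77, 1.31, 2)) {
    d1 <- shape_descriptor(transform_contour(ct, scale = sc),
                           16, "standard")$normalized
    expect_lt(max(abs(d1 - d0)), 1e-6)
  }
  for (sh in c(1L, 17L, 64L, 100L)) {
    d1 <- shape_descriptor(transform_contour(ct, shift = sh),
                           16, "standard")$normalized
    expect_lt(max(abs(d1 - d0)), 1e-6)
  }
  # paper mode is not translation invariant (documented contrast)
  p0 <- shape_descriptor(ct, 16, "paper")$normalized
  p1 <- shape_descriptor(transform_contour(ct, dx = 37, dy = -12),
                         16, "paper")$normalized
  expect_gt(max(abs(p1 - p0)), 1e-4)
})

test_that("shape distance is 1 - Pearson with the documented conventions", {
  ct <- wobbly_contour()
  d1 <- shape_descriptor(ct, 16)
  expect_equal(shape_distance(d1, d1), 0)

  d2 <- d1
  d2$normalized <- 3.7 * d1$normalized + 0.4  # positive affine map
  expect_equal(shape_distance(d1, d2), 0, tolerance = 1e-12)

  # direct covariance/sigma arithmetic oracle on fixed vectors
  va <- c(0.9, 0.2, 0.13, 0.08, 0.31, 0.02, 0.11, 0.05,
          0.4, 0.01, 0.22, 0.07, 0.03, 0.18, 0.06, 0.12)
  vb <- rev(va) * 0.8 + 0.05
  rho <- mean(va * vb) - mean(va) * mean(vb)
  rho <- rho / sqrt((mean(va^2) - mean(va)^2) * (mean(vb^2) - mean(vb)^2))
  da <- d1; da$normalized <- va
  db <- d1; db$normalized <- vb
  expect_equal(shape_distance(da, db), 1 - rho, tolerance = 1e-12)

  dz1 <- d1; dz1$normalized <- rep(0.3, 16)
  dz2 <- d1; dz2$normalized <- rep(0.3, 16)
  expect_equal(shape_distance(dz1, dz2), 0)
  dz3 <- d1; dz3$normalized <- va
  expect_equal(shape_distance(dz1, dz3), 2)

  dm <- shape_descriptor(ct, 16, "paper")
  expect_error(shape_distance(d1, dm), "mode")
})
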