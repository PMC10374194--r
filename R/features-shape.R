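#' Extract a closed boundary contour from a sprite
#'
#' Traces the outer boundary of the largest connected foreground component
#' (alpha >= 0.5), orients it so the complex sequence `x + i*y` carries its
#' first-harmonic energy at frequency +1 (positive shoelace area), and
#' resamples it to `n_points` equally spaced arc-length positions, as the
#' Fourier shape descriptor requires equal-length sequences.
#'
#' @param sprite A `phenosynth_sprite`.
#' @param n_points Number of resampled boundary points (>= 8), default 128.
#' @param smooth Half-width of the circular moving average applied to the
#'   traced boundary before resampling (default 1, i.e. a 3-point window).
#'   This suppresses pixel-digitization staircase harmonics while leaving
#'   low-frequency shape content essentially untouched; 0 disables it.
#' @return A tibble of class `phenosynth_contour` with columns `x`, `y`
#'   (0-based pixel coordinates, origin top-left, y down) and attribute
#'   `closed = TRUE`.
#' @export
extract_contour <- function(sprite, n_points = 128L, smooth = 1L) {
  stopifnot(inherits(sprite, "phenosynth_sprite"), n_points >= 8L)
  mask <- sprite_mask(sprite)
  if (!any(mask)) stop("Sprite has an empty foreground.", call. = FALSE)

  lab <- EBImage::bwlabel(as_ebimage(mask * 1))
  counts <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(counts) > 1L) {
    warning("Multiple foreground components; taking the largest.",
            call. = FALSE)
  }
  keep <- which.max(counts)
  oc <- EBImage::ocontour(EBImage::Image(EBImage::imageData(lab) == keep))[[1]]
  # EBImage returns 0-based (x, y) boundary pixel coordinates in trace order
  x <- oc[, 1]; y <- oc[, 2]
  if (smooth > 0 && length(x) > 2 * smooth + 1) {
    x <- circular_smooth(x, smooth)
    y <- circular_smooth(y, smooth)
  }
  pts <- contour_resample(x, y, n_points)
  structure(tibble::tibble(x = pts$x, y = pts$y),
            closed = TRUE, class = c("phenosynth_contour", class(tibble::tibble())))
}

# Circular moving average of half-width k over a closed sequence.
circular_smooth <- function(v, k) {
  n <- length(v)
  ext <- c(v[(n - k + 1):n], v, v[1:k])
  as.numeric(stats::filter(ext, rep(1 / (2 * k + 1), 2 * k + 1))[(k + 1):(k + n)])
}

# Orient to positive shoelace area and resample a closed polygon to n
# equally spaced arc-length positions, keeping the original start point.
contour_resample <- function(x, y, n) {
  stopifnot(length(x) >= 3L)
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 < 0) {
    # reverse, keeping the start point first
    idx <- c(1L, rev(seq_along(x))[-length(x)])
    x <- x[idx]; y <- y[idx]
  }
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  seg <- sqrt(dx^2 + dy^2)
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  t_new <- per * (seq_len(n) - 1) / n
  i <- findInterval(t_new, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(seg))
  f <- (t_new - cum[i]) / seg[i]
  f[!is.finite(f)] <- 0
  xn <- c(x, x[1]); yn <- c(y, y[1])
  list(x = xn[i] + f * (xn[i + 1] - xn[i]),
       y = yn[i] + f * (yn[i + 1] - yn[i]))
}

#' Fourier shape descriptor of a closed contour
#'
#' Treats the boundary as the complex sequence `s(k) = x(k) + i*y(k)` and
#' computes its discrete Fourier coefficients
#' `a(u) = (1/N) * sum_k s(k) exp(-i 2 pi k u / N)`.  Two normalizations are
#' provided.  `mode = "standard"` (default) stores
#' `d(u) = |a(u)| / |a(1)|` for `u = 2 .. n_terms + 1`, which is invariant
#' to translation (drops `a(0)`), rotation and start-point shift (modulus),
#' and uniform scale (division by `|a(1)|`).  `mode = "paper"` stores
#' `|a(u) / a(0)|` for `u = 0 .. n_terms - 1`, the literal centroid-ratio
#' normalization; it is kept for comparability but is not
#' translation-invariant.
#'
#' @param contour A `phenosynth_contour` (or any data frame with `x`, `y`).
#' @param n_terms Number of retained low-frequency terms, default 16.
#' @param mode `"standard"` or `"paper"`.
#' @return A list of class `shape_descriptor` with `coefficients` (complex
#'   `a(u)`, full length), `normalized` (numeric length `n_terms`), `mode`.
#' @export
shape_descriptor <- function(contour, n_terms = 16L,
                             mode = c("standard", "paper")) {
  mode <- match.arg(mode)
  x <- contour$x; y <- contour$y
  n <- length(x)
  stopifnot(n >= 8L, n_terms >= 2L, n_terms + 2L <= n)
  s <- complex(real = x, imaginary = y)
  a <- stats::fft(s) / n

  if (mode == "paper") {
    if (Mod(a[1]) < 1e-9) {
      stop("mode='paper' undefined: |a(0)| ~ 0 (centroid at origin).",
           call. = FALSE)
    }
    d <- Mod(a[seq_len(n_terms)] / a[1])
  } else {
    d <- Mod(a[3:(n_terms + 2L)]) / Mod(a[2])
  }
  structure(list(coefficients = a, normalized = d, mode = mode,
                 n_terms = as.integer(n_terms)),
            class = "shape_descriptor")
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat(sprintf("<shape_descriptor> mode=%s, %d terms: %s ...\n",
              x$mode, x$n_terms,
              paste(signif(utils::head(x$normalized, 4), 3), collapse = ", ")))
  invisible(x)
}

#' Shape dissimilarity between two descriptors
#'
#' `1 - rho`, where `rho` is the Pearson correlation of the two normalized
#' descriptor sequences; range \[0, 2\].  Zero-variance sequences use the
#' documented convention: 0 if equal, else 2.
#'
#' @param d1,d2 `shape_descriptor` objects with identical mode and length.
#' @return A single dissimilarity value in \[0, 2\].
#' @export
shape_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "shape_descriptor"), inherits(d2, "shape_descriptor"))
  if (d1$mode != d2$mode || length(d1$normalized) != length(d2$normalized)) {
    stop("Descriptors must share mode and length.", call. = FALSE)
  }
  pearson_dissimilarity(d1$normalized, d2$normalized)
}

# Rigid-motion helpers used by invariance tests and scene bookkeeping.

#' Transform a contour (translate, rotate, scale, cyclic shift)
#'
#' Utility for probing descriptor invariances: applies, in order, a uniform
#' scale about the centroid, a rotation about the centroid, a translation,
#' and a cyclic shift of the start point.
#'
#' @param contour A `phenosynth_contour`.
#' @param dx,dy Translation in pixels.
#' @param angle Rotation angle in degrees.
#' @param scale Uniform scale factor (> 0).
#' @param shift Integer start-point shift.
#' @return A transformed `phenosynth_contour`.
#' @export
transform_contour <- function(contour, dx = 0, dy = 0, angle = 0,
                              scale = 1, shift = 0L) {
  x <- contour$x; y <- contour$y
  cx <- mean(x); cy <- mean(y)
  th <- angle * pi / 180
  xs <- (x - cx) * scale; ys <- (y - cy) * scale
  xr <- xs * cos(th) - ys * sin(th) + cx + dx
  yr <- xs * sin(th) + ys * cos(th) + cy + dy
  if (shift != 0L) {
    n <- length(xr)
    idx <- ((seq_len(n) - 1 + shift) %% n) + 1
    xr <- xr[idx]; yr <- yr[idx]
  }
  structure(tibble::tibble(x = xr, y = yr),
            closed = TRUE, class = c("phenosynth_contour", class(tibble::tibble())))
}
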