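#' Define a synthetic fruit species
#'
#' A species specification bundles the shape, color, and texture parameters
#' from which [generate_fruit_sprite()] draws deterministic sprite rasters.
#' The shape family is a superellipse with additive low-order radial wobble:
#' its harmonic content is analytically controllable, so the disc limit
#' (`exponent = 2`, `aspect = 1`, `wobble = 0`) yields a single-harmonic
#' boundary that anchors the Fourier shape-descriptor tests.  Color is
#' synthesized CIELAB-first and converted to sRGB last, so planted color
#' centers can be recovered by the color descriptor to within quantization.
#'
#' @param species_id Character tag identifying the species/dataset.
#' @param exponent Superellipse exponent (> 0); 2 gives an ellipse, larger
#'   values give boxier outlines, smaller give pointier ones.
#' @param aspect Horizontal/vertical axis ratio (> 0).
#' @param wobble Amplitude of the additive boundary wobble, as a fraction of
#'   the base radius (0 disables it).
#' @param lab_center Length-3 numeric, the target CIELAB color center
#'   (L in \[0, 100\], a and b in \[-128, 127\]).
#' @param lab_spread Length-3 numeric, per-channel standard deviation of the
#'   sprite-to-sprite CIELAB shift (0 plants the center exactly).
#' @param octaves Integer, octave count of the smooth shading component of
#'   the multiplicative lightness texture noise.
#' @param contrast Grain fraction of the texture noise in \[0, 1\]: 0 gives
#'   pure smooth shading, 1 pure per-pixel grain.  This is the dominant
#'   texture discriminator for the LBP descriptor.
#' @param seed Integer seed; together with the sprite index it fully
#'   determines each sprite.
#' @param size Canvas side in pixels (square RGBA raster), default 256.
#' @return An object of class `species_spec`.
#' @export
#' @examples
#' spec <- species_spec("demo", exponent = 2, aspect = 1, wobble = 0)
#' sprite <- generate_fruit_sprite(spec, 1)
species_spec <- function(species_id,
                         exponent = 2.5,
                         aspect = 1,
                         wobble = 0.04,
                         lab_center = c(60, 45, 40),
                         lab_spread = c(2, 2, 2),
                         octaves = 3L,
                         contrast = 0.4,
                         seed = 1L,
                         size = 256L) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  if (!is.numeric(exponent) || exponent <= 0) {
    stop("`exponent` must be > 0 (degenerate superellipse).", call. = FALSE)
  }
  if (aspect <= 0) stop("`aspect` must be > 0.", call. = FALSE)
  if (wobble < 0) stop("`wobble` must be >= 0.", call. = FALSE)
  stopifnot(length(lab_center) == 3L, length(lab_spread) == 3L,
            all(lab_spread >= 0), size >= 32L)
  if (lab_center[1] < 0 || lab_center[1] > 100 ||
      any(lab_center[2:3] < -128) || any(lab_center[2:3] > 127)) {
    stop("`lab_center` outside the CIELAB channel ranges.", call. = FALSE)
  }
  structure(
    list(species_id = species_id, exponent = exponent, aspect = aspect,
         wobble = wobble, lab_center = as.numeric(lab_center),
         lab_spread = as.numeric(lab_spread), octaves = as.integer(octaves),
         contrast = contrast, seed = as.integer(seed),
         size = as.integer(size)),
    class = "species_spec"
  )
}

#' @export
print.species_spec <- function(x, ...) {
  cat(sprintf(
    "<species_spec '%s'> exponent=%.3g aspect=%.3g wobble=%.3g Lab=(%g,%g,%g) seed=%d\n",
    x$species_id, x$exponent, x$aspect, x$wobble,
    x$lab_center[1], x$lab_center[2], x$lab_center[3], x$seed))
  invisible(x)
}

new_sprite <- function(pixels, species_id, source = "generated") {
  structure(list(pixels = pixels, species_id = species_id, source = source),
            class = "phenosynth_sprite")
}

#' @export
print.phenosynth_sprite <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<sprite '%s'> %dx%d RGBA, source=%s, foreground=%d px\n",
              x$species_id, d[2], d[1], x$source, sum(x$pixels[, , 4] >= 0.5)))
  invisible(x)
}

sprite_mask <- function(sprite) sprite$pixels[, , 4] >= 0.5

# Superellipse polar radius for semi-axes (ax, ay) and exponent n.
superellipse_radius <- function(theta, ax, ay, n) {
  (abs(cos(theta) / ax)^n + abs(sin(theta) / ay)^n)^(-1 / n)
}

#' Generate one fruit sprite
#'
#' Renders a transparent-background RGBA fruit raster: a superellipse blob
#' with seeded radial wobble, filled with a CIELAB-centered color modulated
#' by multiplicative lightness noise.  Output is deterministic in
#' `(spec$seed, index)` and quantized to the 8-bit grid, so identical calls
#' produce byte-identical PNG files.
#'
#' @param spec A [species_spec()].
#' @param index Non-negative integer; sprites with different indices share
#'   species statistics but differ pixel-wise.
#' @return A `phenosynth_sprite` (RGBA array in `$pixels`, values in \[0,1\]).
#' @export
generate_fruit_sprite <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "species_spec"), index >= 0)
  size <- spec$size
  rs <- derive_seed(spec$seed, 1L, index)

  cx <- (size - 1) / 2
  cy <- (size - 1) / 2
  base_r <- 0.34 * size
  ax <- base_r * sqrt(spec$aspect)
  ay <- base_r / sqrt(spec$aspect)

  # per-sprite size jitter and wobble harmonics
  jit <- with_seed(derive_seed(rs, 2L), list(
    scale = if (spec$wobble > 0 || any(spec$lab_spread > 0)) runif(1, 0.92, 1.0) else 1,
    wamp = runif(3, 0.4, 1),
    wph = runif(3, 0, 2 * pi),
    labshift = stats::rnorm(3) * spec$lab_spread
  ))

  xs <- matrix(rep(0:(size - 1), each = size), size, size) - cx  # column -> x
  ys <- matrix(rep(0:(size - 1), times = size), size, size) - cy # row -> y
  rho <- sqrt(xs^2 + ys^2)
  theta <- atan2(ys, xs)

  rb <- superellipse_radius(theta, ax, ay, spec$exponent) * jit$scale
  if (spec$wobble > 0) {
    harm <- jit$wamp / sum(jit$wamp)
    wob <- harm[1] * cos(3 * theta + jit$wph[1]) +
      harm[2] * cos(4 * theta + jit$wph[2]) +
      harm[3] * cos(5 * theta + jit$wph[3])
    rb <- rb * (1 + spec$wobble * wob)
  }
  # keep the footprint strictly inside the canvas
  rb <- pmin(rb, size / 2 - 3)

  alpha <- clamp(rb - rho + 0.5, 0, 1)  # 1-px soft edge
  inside <- alpha > 0

  lab_c <- spec$lab_center + jit$labshift
  lab_c[1] <- clamp(lab_c[1], 5, 95)
  lab_c[2] <- clamp(lab_c[2], -100, 100)
  lab_c[3] <- clamp(lab_c[3], -100, 100)

  lab <- matrix(lab_c, nrow = sum(inside), ncol = 3, byrow = TRUE)
  # multiplicative lightness texture: a smooth shading field mixed with
  # per-pixel grain; `contrast` sets the grain fraction, which is what the
  # LBP descriptor discriminates (LBP is invariant to amplitude alone)
  tex_smooth <- if (spec$octaves >= 1L) {
    value_noise(size, size, spec$octaves, derive_seed(rs, 3L))
  } else {
    matrix(0, size, size)  # octaves = 0: no shading component
  }
  grain <- with_seed(derive_seed(rs, 4L),
                     matrix(stats::runif(size * size, -1, 1), size, size))
  tex <- (1 - spec$contrast) * tex_smooth + spec$contrast * grain
  lab[, 1] <- clamp(lab[, 1] * (1 + 0.15 * tex[inside]), 0, 100)
  rgb_fg <- lab_to_srgb(lab)

  px <- array(0, dim = c(size, size, 4))
  for (ch in 1:3) {
    plane <- matrix(0, size, size)
    plane[inside] <- rgb_fg[, ch]
    px[, , ch] <- plane
  }
  px[, , 4] <- alpha
  px <- quantize8(px)

  new_sprite(px, spec$species_id, "generated")
}

#' Generate one leaf sprite
#'
#' Lanceolate green-hued RGBA sprite used as an occluder component when
#' composing orchard scenes.  The blade points downward at rotation 0 so the
#' placement stage's downward-biased rotation prior reads as leaves hanging
#' from branches.  Deterministic in `(seed, index)`.
#'
#' @param seed Integer seed.
#' @param index Non-negative integer sprite index.
#' @param size Canvas side in pixels, default 256.
#' @return A `phenosynth_sprite` with `species_id = "leaf"`.
#' @export
generate_leaf_sprite <- function(seed = 1L, index = 0L, size = 256L) {
  stopifnot(index >= 0, size >= 32L)
  rs <- derive_seed(seed, 5L, index)
  jit <- with_seed(derive_seed(rs, 2L), list(
    len = runif(1, 0.85, 1.0),
    wid = runif(1, 0.85, 1.15),
    labshift = stats::rnorm(3, sd = c(3, 2, 2))
  ))

  cx <- (size - 1) / 2
  cy <- (size - 1) / 2
  xs <- matrix(rep(0:(size - 1), each = size), size, size) - cx
  ys <- matrix(rep(0:(size - 1), times = size), size, size) - cy

  half_len <- 0.42 * size * jit$len
  max_w <- 0.13 * size * jit$wid
  # lanceolate blade: width profile sin(pi * t)^0.8 along the vertical axis,
  # apex pointing down (+y)
  t <- clamp((ys + half_len) / (2 * half_len), 0, 1)
  wprof <- max_w * sin(pi * t)^0.8
  alpha <- clamp(wprof - abs(xs) + 0.5, 0, 1)
  alpha[ys < -half_len | ys > half_len] <- 0
  inside <- alpha > 0

  lab_c <- c(42, -32, 30) + jit$labshift
  lab <- matrix(lab_c, nrow = sum(inside), ncol = 3, byrow = TRUE)
  tex <- value_noise(size, size, 3L, derive_seed(rs, 3L))
  lab[, 1] <- clamp(lab[, 1] * (1 + 0.10 * tex[inside]), 0, 100)
  # midrib: darken a thin central strip
  rib <- abs(xs[inside]) < max(1, 0.012 * size)
  lab[rib, 1] <- lab[rib, 1] * 0.8
  rgb_fg <- lab_to_srgb(lab)

  px <- array(0, dim = c(size, size, 4))
  for (ch in 1:3) {
    plane <- matrix(0, size, size)
    plane[inside] <- rgb_fg[, ch]
    px[, , ch] <- plane
  }
  px[, , 4] <- alpha
  px <- quantize8(px)
  new_sprite(px, "leaf", "generated")
}

#' Generate a tagged multi-species sprite collection
#'
#' @param specs List of [species_spec()] objects (at least 2).
#' @param n_per_species Number of sprites per species (at least 2).
#' @return A list of `phenosynth_sprite` objects, `n_per_species` per spec,
#'   in spec order, named `<species_id>#<index>`.
#' @export
generate_species_collection <- function(specs, n_per_species) {
  stopifnot(length(specs) >= 2L, n_per_species >= 2L)
  out <- list()
  for (spec in specs) {
    stopifnot(inherits(spec, "species_spec"))
    for (i in seq_len(n_per_species)) {
      out[[sprintf("%s#%d", spec$species_id, i)]] <-
        generate_fruit_sprite(spec, i - 1L)
    }
  }
  out
}

sprite_species <- function(sprites) {
  vapply(sprites, function(s) s$species_id, character(1))
}
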