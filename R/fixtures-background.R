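#' Generate a layered orchard background
#'
#' Procedural stand-in for a real orchard photograph: a sky band on top, a
#' textured tree/canopy band in the middle, and a ground band at the bottom,
#' with noisy band boundaries.  Returns both the RGB image and the
#' ground-truth region mask, so the threshold segmentation used during scene
#' synthesis can be scored against a known labeling.
#'
#' @param width,height Image size in pixels (both >= 128).
#' @param seed Integer seed; output is deterministic in `(width, height, seed)`.
#' @return A list of class `phenosynth_background` with `image` (h x w x 3
#'   array in \[0,1\]) and `region_mask` (h x w integer matrix with levels
#'   1 = sky, 2 = tree, 3 = ground).
#' @export
generate_background <- function(width = 480L, height = 360L, seed = 1L) {
  if (width < 128L || height < 128L) {
    stop("`width` and `height` must both be >= 128.", call. = FALSE)
  }
  w <- as.integer(width); h <- as.integer(height)

  sky_edge <- round(h * (0.18 + 0.05 * value_noise_1d(w, 3L, derive_seed(seed, 21L))))
  gnd_edge <- round(h * (0.80 + 0.05 * value_noise_1d(w, 3L, derive_seed(seed, 22L))))
  sky_edge <- clamp(sky_edge, 2L, round(h * 0.35))
  gnd_edge <- clamp(gnd_edge, round(h * 0.65), h - 2L)

  rows <- matrix(seq_len(h), h, w)
  edge_s <- matrix(sky_edge, h, w, byrow = TRUE)
  edge_g <- matrix(gnd_edge, h, w, byrow = TRUE)
  mask <- matrix(2L, h, w)
  mask[rows <= edge_s] <- 1L
  mask[rows > edge_g] <- 3L

  img <- array(0, dim = c(h, w, 3))
  n1 <- value_noise(h, w, 3L, derive_seed(seed, 23L))
  n2 <- value_noise(h, w, 4L, derive_seed(seed, 24L))

  # sky: bright, low-saturation blue with a vertical gradient
  grad <- matrix((seq_len(h) - 1) / (h - 1), h, w)
  sky_r <- 0.62 + 0.12 * grad + 0.03 * n1
  sky_g <- 0.78 + 0.08 * grad + 0.03 * n1
  sky_b <- 0.95 - 0.04 * grad + 0.02 * n1
  # tree canopy: mid-dark green with strong value noise
  tre_r <- 0.16 + 0.10 * n2 + 0.04 * n1
  tre_g <- 0.38 + 0.14 * n2 + 0.05 * n1
  tre_b <- 0.12 + 0.07 * n2
  # ground: warm brown
  gnd_r <- 0.48 + 0.08 * n2
  gnd_g <- 0.36 + 0.07 * n2
  gnd_b <- 0.22 + 0.05 * n2

  pick <- function(sky, tre, gnd) {
    out <- tre
    out[mask == 1L] <- sky[mask == 1L]
    out[mask == 3L] <- gnd[mask == 3L]
    out
  }
  img[, , 1] <- pick(sky_r, tre_r, gnd_r)
  img[, , 2] <- pick(sky_g, tre_g, gnd_g)
  img[, , 3] <- pick(sky_b, tre_b, gnd_b)
  img <- quantize8(img)

  structure(list(image = img, region_mask = mask),
            class = "phenosynth_background")
}

#' @export
print.phenosynth_background <- function(x, ...) {
  d <- dim(x$image)
  fr <- tabulate(x$region_mask, 3L) / length(x$region_mask)
  cat(sprintf("<background> %dx%d RGB; sky %.2f / tree %.2f / ground %.2f\n",
              d[2], d[1], fr[1], fr[2], fr[3]))
  invisible(x)
}

#' Build a planted multi-group species collection
#'
#' Creates `n_groups` phenotype groups, each containing `species_per_group`
#' species datasets.  Groups are separated by more than 30 CIELAB units,
#' by distinct superellipse exponents, and by texture grain level.  Within
#' a group the species form a symmetric ladder along the CIELAB a channel
#' (offsets `0, -2, -1, +1, +2` times `delta`, center first): a collinear
#' symmetric arrangement whose middle member minimizes the mean distance to
#' its co-members under any affine projection of the feature space, so the
#' planted center is the expected cluster medoid.  Used to exercise
#' source-domain selection end to end.
#'
#' @param n_groups Number of groups (1-3 supported).
#' @param species_per_group Species datasets per group (3-5; the first is
#'   the planted center).
#' @param n_per_species Sprites per species dataset.
#' @param delta Ladder step in CIELAB a units, default 8.
#' @param seed Integer seed.
#' @param size Sprite canvas side, default 256.
#' @return A list with `sprites` (named sprite list), `specs`, `groups`
#'   (tibble: species_id, group, is_center).
#' @export
planted_collection <- function(n_groups = 3L, species_per_group = 5L,
                               n_per_species = 4L, delta = 8, seed = 1L,
                               size = 256L) {
  stopifnot(n_groups >= 1L, n_groups <= 3L, species_per_group >= 3L,
            species_per_group <= 5L, n_per_species >= 2L)
  # texture archetypes: flat (deterministic LBP histogram), weak grain,
  # strong grain; shape archetypes: ellipse, boxy, pointed
  bases <- list(
    list(exponent = 2.0, aspect = 1.35, lab = c(62, 45, 35), contrast = 0,
         octaves = 0L),
    list(exponent = 4.5, aspect = 1.0, lab = c(55, -38, 40), contrast = 0.12,
         octaves = 5L),
    list(exponent = 1.15, aspect = 0.7, lab = c(75, 0, 30), contrast = 0.55,
         octaves = 5L)
  )[seq_len(n_groups)]
  ladder <- c(0, -2, -1, 1, 2)[seq_len(species_per_group)]

  specs <- list()
  rows <- list()
  for (g in seq_len(n_groups)) {
    b <- bases[[g]]
    for (k in seq_len(species_per_group)) {
      id <- sprintf("g%d_s%d", g, k)
      specs[[id]] <- species_spec(
        id,
        exponent = b$exponent,
        aspect = b$aspect,
        wobble = 0.02,
        lab_center = b$lab + c(0, ladder[k] * delta, 0),
        lab_spread = c(1, 1, 1),
        octaves = b$octaves,
        contrast = b$contrast,
        seed = derive_seed(seed, 31L, g, k),
        size = size
      )
      rows[[id]] <- tibble::tibble(species_id = id, group = g,
                                   is_center = k == 1L)
    }
  }
  sprites <- generate_species_collection(specs, n_per_species)
  list(sprites = sprites, specs = specs,
       groups = dplyr::bind_rows(rows))
}
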