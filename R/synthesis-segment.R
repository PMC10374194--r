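#' Threshold-segment an orchard background into sky / tree / ground
#'
#' Fixed HSV-and-position heuristic: sky pixels are bright, low-saturation
#' or blue-dominant pixels in the upper 60% of the image; of the remainder,
#' green-dominant pixels are tree and the rest is ground; everything below
#' the lowest tree row is also ground.  The largest connected tree component
#' is kept as the fruit placement region.
#'
#' @param image An RGB array (h x w x 3, values in \[0,1\]) or a
#'   `phenosynth_background` (its `$image` is used).
#' @return An integer h x w matrix with levels 1 = sky, 2 = tree,
#'   3 = ground and attribute `tree_region`, a logical matrix marking the
#'   largest connected tree component.
#' @export
segment_background <- function(image) {
  if (inherits(image, "phenosynth_background")) image <- image$image
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]

  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  s <- ifelse(v > 0, (v - mn) / v, 0)

  upper <- row(r) <= round(0.6 * h)
  sky <- ((v > 0.7 & s < 0.4) | (b > r & b > g & b > 0.5)) & upper
  tree <- !sky & (g >= r & g >= b)
  mask <- matrix(3L, h, w)
  mask[sky] <- 1L
  mask[tree] <- 2L

  tree_rows <- which(rowSums(mask == 2L) > 0)
  if (length(tree_rows)) {
    below <- row(r) > max(tree_rows)
    mask[below & mask != 1L] <- 3L
  }

  if (!any(mask == 2L)) {
    stop("Empty tree region: background unsuitable for fruit placement.",
         call. = FALSE)
  }
  lab <- EBImage::bwlabel(as_ebimage((mask == 2L) * 1))
  comp <- from_ebimage(lab)
  counts <- tabulate(as.integer(comp))
  tree_region <- comp == which.max(counts)
  attr(mask, "tree_region") <- tree_region
  mask
}

#' Scene synthesis configuration
#'
#' Bundles the tunable parameters of the rule-governed scene compositor.
#' Defaults follow the study conditions where stated (fruit occlusion
#' bounded by 0.5) and otherwise use documented package choices.
#'
#' @param n_fruits Integer range `c(min, max)` of fruits per scene,
#'   default `c(10, 30)`.
#' @param max_occlusion Maximum per-fruit occlusion ratio in \[0, 1),
#'   default 0.5: emitted fruits have occlusion randomly distributed in
#'   \[0, max_occlusion\].
#' @param scale_range Fruit height as a fraction of image height,
#'   default `c(0.10, 0.18)`.
#' @param saturation_jitter,brightness_jitter Multiplicative HSV jitter
#'   ranges, default `c(0.8, 1.2)`.
#' @param rotation_range Fruit rotation range in degrees,
#'   default `c(-180, 180)`.
#' @param leaf_density Leaves placed per fruit, default 1.
#' @param leaf_scale_range Leaf height fraction range, default
#'   `c(0.08, 0.14)`.
#' @param leaf_rotation_range Leaf rotation band in degrees about the
#'   downward direction, default `c(-60, 60)` (growth-direction proxy).
#' @param max_rejections Consecutive placement rejections before a scene is
#'   aborted, default 200.
#' @param seed Integer seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_fruits = c(10L, 30L), max_occlusion = 0.5,
                         scale_range = c(0.10, 0.18),
                         saturation_jitter = c(0.8, 1.2),
                         brightness_jitter = c(0.8, 1.2),
                         rotation_range = c(-180, 180),
                         leaf_density = 1,
                         leaf_scale_range = c(0.08, 0.14),
                         leaf_rotation_range = c(-60, 60),
                         max_rejections = 200L,
                         seed = 1L) {
  stopifnot(length(n_fruits) == 2L, n_fruits[1] <= n_fruits[2],
            n_fruits[1] >= 0)
  if (max_occlusion < 0 || max_occlusion >= 1) {
    stop("`max_occlusion` must be in [0, 1).", call. = FALSE)
  }
  chk_range <- function(r, nm, pos = TRUE) {
    if (length(r) != 2L || r[1] > r[2] || (pos && r[1] <= 0)) {
      stop(sprintf("`%s` must be a nonempty range%s.", nm,
                   if (pos) " of positive values" else ""), call. = FALSE)
    }
  }
  chk_range(scale_range, "scale_range")
  chk_range(saturation_jitter, "saturation_jitter")
  chk_range(brightness_jitter, "brightness_jitter")
  chk_range(rotation_range, "rotation_range", pos = FALSE)
  chk_range(leaf_scale_range, "leaf_scale_range")
  chk_range(leaf_rotation_range, "leaf_rotation_range", pos = FALSE)
  stopifnot(leaf_density >= 0)
  structure(list(n_fruits = as.integer(n_fruits),
                 max_occlusion = max_occlusion,
                 scale_range = scale_range,
                 saturation_jitter = saturation_jitter,
                 brightness_jitter = brightness_jitter,
                 rotation_range = rotation_range,
                 leaf_density = leaf_density,
                 leaf_scale_range = leaf_scale_range,
                 leaf_rotation_range = leaf_rotation_range,
                 max_rejections = as.integer(max_rejections),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Photometric and geometric sprite jitter
#'
#' Applies, in order: HSV saturation and brightness multipliers, a uniform
#' scale, and a rotation, each sampled from the configured ranges (the
#' light-and-size and randomization rules of the scene grammar).  The alpha
#' channel is transformed consistently with the color channels, and the
#' result is trimmed to its foreground bounding box.  Degenerate ranges
#' (single values at the identity) return the input unchanged.
#'
#' @param sprite A `phenosynth_sprite`.
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return A jittered `phenosynth_sprite` with attribute `photometric`
#'   (sampled scale/rotation/saturation/brightness).
#' @export
jitter_sprite <- function(sprite, config, seed = 1L) {
  stopifnot(inherits(config, "scene_config"))
  pars <- with_seed(derive_seed(seed, 71L), list(
    scale = stats::runif(1, config$scale_range[1], config$scale_range[2]),
    rotation = stats::runif(1, config$rotation_range[1], config$rotation_range[2]),
    saturation = stats::runif(1, config$saturation_jitter[1], config$saturation_jitter[2]),
    brightness = stats::runif(1, config$brightness_jitter[1], config$brightness_jitter[2])
  ))
  # `scale` in the config is a fraction of scene height; here interpret the
  # sampled value relative to a 256-px reference so standalone jitter works.
  target_h <- pars$scale * 256
  out <- apply_jitter(sprite, target_h / nrow(sprite$pixels), pars$rotation,
                      pars$saturation, pars$brightness)
  attr(out, "photometric") <- pars
  out
}

# Deterministic core: scale factor, rotation (deg), HSV multipliers.
apply_jitter <- function(sprite, scale, rotation, saturation, brightness) {
  if (scale == 1 && rotation %% 360 == 0 && saturation == 1 &&
      brightness == 1) {
    return(sprite)  # identity jitter: bit-exact passthrough
  }
  px <- sprite$pixels

  if (saturation != 1 || brightness != 1) {
    a <- px[, , 4]
    fg <- a > 0
    if (any(fg)) {
      rgbm <- cbind(px[, , 1][fg], px[, , 2][fg], px[, , 3][fg])
      hsv <- rgb_to_hsv(rgbm)
      hsv[, 2] <- clamp(hsv[, 2] * saturation, 0, 1)
      hsv[, 3] <- clamp(hsv[, 3] * brightness, 0, 1)
      rgbm <- hsv_to_rgb(hsv)
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[fg] <- rgbm[, ch]
        px[, , ch] <- plane
      }
    }
  }

  if (scale != 1) {
    img <- as_ebimage(px)
    img <- EBImage::resize(img, w = max(4L, round(dim(img)[1] * scale)))
    px <- from_ebimage(img)
  }
  if (rotation %% 360 != 0) {
    img <- as_ebimage(px)
    img <- EBImage::rotate(img, rotation, bg.col = 0)
    px <- from_ebimage(img)
  }
  px <- clamp(px, 0, 1)

  fgmask <- px[, , 4] >= 0.5
  if (sum(fgmask) < 4L) {
    stop("Jittered sprite footprint below 4 px.", call. = FALSE)
  }
  rr <- range(which(rowSums(fgmask) > 0))
  cc <- range(which(colSums(fgmask) > 0))
  px <- px[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
  new_sprite(px, sprite$species_id, sprite$source)
}
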