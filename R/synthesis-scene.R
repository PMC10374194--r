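# Placement engine: rule-governed sprite placement with occlusion control.
#
# A placement record keeps the jittered RGBA raster, its canvas offset, the
# linear indices of its binary footprint (alpha >= 0.5), and for fruits a
# parallel logical vector marking footprint pixels covered by any
# later-placed sprite.  All rule checks are logged in the audit trail.

new_placement_state <- function(h, w, tree_region, background_ref = NA_character_) {
  structure(list(h = h, w = w, tree_region = tree_region,
                 placements = list(), audit = list(),
                 background_ref = background_ref,
                 aborted = FALSE),
            class = "scene_placements")
}

#' @export
print.scene_placements <- function(x, ...) {
  kinds <- vapply(x$placements, `[[`, character(1), "category")
  cat(sprintf("<scene_placements> %d fruits, %d leaves on %dx%d canvas\n",
              sum(kinds == "fruit"), sum(kinds == "leaf"), x$w, x$h))
  invisible(x)
}

# Rasterize a jittered sprite at a canvas center; returns NULL if the
# on-canvas footprint is below 4 px.
rasterize_placement <- function(sprite, cx, cy, h, w) {
  px <- sprite$pixels
  sh <- dim(px)[1]; sw <- dim(px)[2]
  x0 <- round(cx - sw / 2) + 1L  # 1-based canvas column of sprite col 1
  y0 <- round(cy - sh / 2) + 1L
  rs <- max(1L, y0):min(h, y0 + sh - 1L)
  cs <- max(1L, x0):min(w, x0 + sw - 1L)
  if (length(rs) < 1L || length(cs) < 1L || rs[1] > rs[length(rs)] ||
      cs[1] > cs[length(cs)]) {
    return(NULL)
  }
  sub_r <- rs - y0 + 1L
  sub_c <- cs - x0 + 1L
  alpha <- px[sub_r, sub_c, 4, drop = TRUE]
  if (!is.matrix(alpha)) alpha <- matrix(alpha, length(sub_r), length(sub_c))
  fg <- alpha >= 0.5
  if (sum(fg) < 4L) return(NULL)
  lin <- as.integer(outer(rs, (cs - 1L) * h, `+`))[as.vector(fg)]
  list(rows = rs, cols = cs, sub_r = sub_r, sub_c = sub_c,
       footprint = lin, n_fg = sum(fg))
}

#' Occlusion ratio of a placement under a set of occluders
#'
#' Brute-force per-pixel count: the fraction of the placement's binary
#' footprint (alpha >= 0.5) covered by the union of the occluders'
#' footprints.  Only occluders composited later (higher z) should be
#' passed; a zero-area footprint is defined as fully occluded (ratio 1).
#'
#' @param placement A placement record (element of
#'   `scene_placements$placements`) or a list with a `footprint` integer
#'   vector.
#' @param occluders List of placement records.
#' @return Occlusion ratio in \[0, 1\].
#' @export
check_occlusion <- function(placement, occluders) {
  fp <- placement$footprint
  if (length(fp) == 0L) return(1)
  if (length(occluders) == 0L) return(0)
  cover <- unique(unlist(lapply(occluders, `[[`, "footprint")))
  mean(fp %in% cover)
}

sample_jittered <- function(sprites, config, kind, canvas_h, seed) {
  with_seed(seed, {
    idx <- sample.int(length(sprites), 1L)
    sp <- sprites[[idx]]
    if (kind == "fruit") {
      frac <- stats::runif(1, config$scale_range[1], config$scale_range[2])
      rot <- stats::runif(1, config$rotation_range[1], config$rotation_range[2])
    } else {
      frac <- stats::runif(1, config$leaf_scale_range[1], config$leaf_scale_range[2])
      rot <- stats::runif(1, config$leaf_rotation_range[1],
                          config$leaf_rotation_range[2])
    }
    sat <- stats::runif(1, config$saturation_jitter[1], config$saturation_jitter[2])
    bri <- stats::runif(1, config$brightness_jitter[1], config$brightness_jitter[2])
    fg_h <- max(1L, diff(range(which(rowSums(sp$pixels[, , 4] >= 0.5) > 0))) + 1L)
    scale <- frac * canvas_h / fg_h
    jit <- try(apply_jitter(sp, scale, rot, sat, bri), silent = TRUE)
    if (inherits(jit, "try-error")) return(NULL)
    list(sprite = jit, sprite_index = idx, scale = scale, rotation = rot,
         saturation = sat, brightness = bri)
  })
}

# Core incremental placement loop shared by fruits and leaves.
place_sprites <- function(state, sprites, config, kind, n_new, seed) {
  h <- state$h; w <- state$w
  tree_idx <- which(state$tree_region)
  if (length(tree_idx) == 0L) {
    stop("Empty tree region: nothing can be placed.", call. = FALSE)
  }
  fruit_ids <- which(vapply(state$placements, `[[`, character(1), "category") == "fruit")
  rejections <- 0L
  attempt <- 0L
  placed <- 0L

  while (placed < n_new) {
    attempt <- attempt + 1L
    if (rejections >= config$max_rejections) {
      state$aborted <- TRUE
      cond <- structure(
        class = c("phenosynth_scene_abort", "error", "condition"),
        list(message = sprintf(
          "Scene aborted: %d consecutive placement rejections (placed %d/%d %s).",
          rejections, placed, n_new, kind),
          call = NULL, audit = dplyr::bind_rows(state$audit)))
      stop(cond)
    }
    sj <- sample_jittered(sprites, config, kind, h,
                          derive_seed(seed, 81L, attempt))
    if (is.null(sj)) { rejections <- rejections + 1L; next }
    center_lin <- with_seed(derive_seed(seed, 82L, attempt),
                            tree_idx[sample.int(length(tree_idx), 1L)])
    cy <- (center_lin - 1L) %% h       # 0-based row
    cx <- (center_lin - 1L) %/% h      # 0-based col
    ras <- rasterize_placement(sj$sprite, cx, cy, h, w)
    reason <- NULL
    new_ratios <- NULL
    if (is.null(ras)) {
      reason <- "footprint"
    } else if (length(fruit_ids)) {
      newmask <- logical(h * w)
      newmask[ras$footprint] <- TRUE
      new_ratios <- vapply(fruit_ids, function(fi) {
        p <- state$placements[[fi]]
        mean(p$covered | newmask[p$footprint])
      }, numeric(1))
      if (any(new_ratios > config$max_occlusion)) reason <- "occlusion"
    }

    state$audit[[length(state$audit) + 1L]] <- tibble::tibble(
      attempt = attempt, category = kind,
      accepted = is.null(reason),
      reason = reason %||% NA_character_,
      rule_N_center_in_tree = TRUE,       # centers are sampled from the tree region
      rule_S2_jitter_applied = TRUE,
      rule_G3_occlusion_ok = is.null(reason) || !identical(reason, "occlusion")
    )

    if (!is.null(reason)) { rejections <- rejections + 1L; next }

    rejections <- 0L
    placed <- placed + 1L
    z <- length(state$placements) + 1L
    rec <- list(
      instance_id = z, category = kind,
      species_id = sj$sprite$species_id,
      sprite_index = sj$sprite_index,
      center_x = cx, center_y = cy,
      scale = sj$scale, rotation = sj$rotation,
      saturation = sj$saturation, brightness = sj$brightness,
      z_order = z,
      pixels = sj$sprite$pixels,
      rows = ras$rows, cols = ras$cols, sub_r = ras$sub_r, sub_c = ras$sub_c,
      footprint = ras$footprint,
      covered = logical(length(ras$footprint))
    )
    # the new sprite occludes everything below it
    if (length(fruit_ids)) {
      newmask <- logical(h * w)
      newmask[ras$footprint] <- TRUE
      for (fi in fruit_ids) {
        p <- state$placements[[fi]]
        state$placements[[fi]]$covered <- p$covered | newmask[p$footprint]
      }
    }
    state$placements[[z]] <- rec
    if (kind == "fruit") fruit_ids <- c(fruit_ids, z)
  }
  state
}

#' Place fruits in the tree region of a background
#'
#' Samples fruit centers uniformly from the (largest connected) tree region,
#' applies per-fruit photometric and geometric jitter, and
#' rejection-resamples any placement that would push any already-placed
#' fruit's occlusion ratio beyond `config$max_occlusion` — this enforces the
#' graded-shading rule that emitted occlusion ratios lie in
#' \[0, max_occlusion\].  Aborts (classed error
#' `phenosynth_scene_abort`) after `config$max_rejections` consecutive
#' rejections.
#'
#' @param background A `phenosynth_background` or RGB array.
#' @param sprites List of fruit `phenosynth_sprite` objects.
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @param n_fruits Optional fruit count; by default sampled uniformly from
#'   `config$n_fruits`.
#' @return A `scene_placements` state object.
#' @export
place_fruits <- function(background, sprites, config, seed = config$seed,
                         n_fruits = NULL) {
  stopifnot(inherits(config, "scene_config"), length(sprites) >= 1L)
  img <- if (inherits(background, "phenosynth_background")) background$image else background
  mask <- segment_background(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  state <- new_placement_state(h, w, attr(mask, "tree_region"))
  state$region_mask <- mask
  state$background <- img
  n <- n_fruits %||% with_seed(derive_seed(seed, 83L),
    config$n_fruits[1] +
      sample.int(config$n_fruits[2] - config$n_fruits[1] + 1L, 1L) - 1L)
  place_sprites(state, sprites, config, "fruit", n, derive_seed(seed, 84L))
}

#' Place occluding leaves over a fruit placement state
#'
#' Places `config$leaf_density` leaves per fruit in the tree region with a
#' downward-biased rotation prior (the branch-growth proxy); leaves may
#' occlude fruits but any leaf that would push a fruit beyond the occlusion
#' bound is rejected and resampled.
#'
#' @param state A `scene_placements` from [place_fruits()].
#' @param leaf_sprites List of leaf `phenosynth_sprite` objects.
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return The updated `scene_placements`.
#' @export
place_leaves <- function(state, leaf_sprites, config, seed = config$seed) {
  stopifnot(inherits(state, "scene_placements"))
  n_fruits <- sum(vapply(state$placements, `[[`, character(1), "category") == "fruit")
  n_leaves <- round(config$leaf_density * n_fruits)
  if (n_leaves == 0L) return(state)
  place_sprites(state, leaf_sprites, config, "leaf", n_leaves,
                derive_seed(seed, 85L))
}

#' Composite a placement state into an annotated synthetic scene
#'
#' Alpha-composites the placed sprites over the background in z order and
#' derives, for every fruit, its visible-pixel mask, the polygon outline of
#' the largest visible component, the tight bounding box of the visible
#' mask, the visible area, and the per-pixel occlusion ratio.
#'
#' @param background A `phenosynth_background` or RGB array (must match the
#'   canvas the placements were made on).
#' @param state A `scene_placements`.
#' @return An object of class `synthetic_scene`: list with `image`,
#'   `region_mask`, `placements` (tibble), `annotations` (tibble with
#'   columns `instance_id`, `category`, `x_min`, `y_min`, `w`, `h`, `area`,
#'   `occlusion_ratio`, list-columns `polygon` and `mask`), and
#'   `rule_audit`.
#' @export
compose_scene <- function(background, state) {
  img <- if (inherits(background, "phenosynth_background")) background$image else background
  stopifnot(inherits(state, "scene_placements"))
  h <- state$h; w <- state$w
  stopifnot(dim(img)[1] == h, dim(img)[2] == w)
  out <- img[, , 1:3, drop = FALSE]

  ord <- order(vapply(state$placements, `[[`, numeric(1), "z_order"))
  for (p in state$placements[ord]) {
    a <- p$pixels[p$sub_r, p$sub_c, 4, drop = TRUE]
    if (!is.matrix(a)) a <- matrix(a, length(p$sub_r), length(p$sub_c))
    for (ch in 1:3) {
      spch <- p$pixels[p$sub_r, p$sub_c, ch, drop = TRUE]
      if (!is.matrix(spch)) spch <- matrix(spch, length(p$sub_r), length(p$sub_c))
      out[p$rows, p$cols, ch] <- a * spch + (1 - a) * out[p$rows, p$cols, ch]
    }
  }
  out <- quantize8(out)

  # visibility by painting from the topmost sprite downward
  claimed <- logical(h * w)
  visible <- vector("list", length(state$placements))
  for (i in rev(ord)) {
    p <- state$placements[[i]]
    visible[[i]] <- p$footprint[!claimed[p$footprint]]
    claimed[p$footprint] <- TRUE
  }

  anns <- list()
  for (i in ord) {
    p <- state$placements[[i]]
    if (p$category != "fruit") next
    vis <- visible[[i]]
    occ <- 1 - length(vis) / length(p$footprint)
    vr <- (vis - 1L) %% h + 1L
    vc <- (vis - 1L) %/% h + 1L
    x_min <- min(vc) - 1L; y_min <- min(vr) - 1L
    bw <- max(vc) - min(vc) + 1L
    bh <- max(vr) - min(vr) + 1L
    vmask <- matrix(FALSE, bh, bw)
    vmask[cbind(vr - y_min, vc - x_min)] <- TRUE
    poly <- visible_polygon(vmask, x_min, y_min)
    anns[[length(anns) + 1L]] <- tibble::tibble(
      instance_id = p$instance_id, category = "fruit",
      x_min = as.numeric(x_min), y_min = as.numeric(y_min),
      w = as.numeric(bw), h = as.numeric(bh),
      area = length(vis), occlusion_ratio = occ,
      polygon = list(poly),
      mask = list(list(x_min = x_min, y_min = y_min, m = vmask))
    )
  }

  placements <- dplyr::bind_rows(lapply(state$placements, function(p) {
    tibble::tibble(instance_id = p$instance_id, category = p$category,
                   species_id = p$species_id, sprite_index = p$sprite_index,
                   center_x = p$center_x, center_y = p$center_y,
                   scale = p$scale, rotation = p$rotation,
                   saturation = p$saturation, brightness = p$brightness,
                   z_order = p$z_order, footprint_px = length(p$footprint))
  }))

  structure(list(image = out,
                 region_mask = state$region_mask,
                 tree_region = state$tree_region,
                 placements = placements,
                 annotations = if (length(anns)) dplyr::bind_rows(anns)
                               else tibble::tibble(),
                 rule_audit = dplyr::bind_rows(state$audit),
                 raw_placements = state$placements),
            class = "synthetic_scene")
}

# Outer polygon (0-based canvas coordinates) of the largest connected
# component of a visible mask.
visible_polygon <- function(vmask, x_min, y_min) {
  lab <- EBImage::bwlabel(as_ebimage(vmask * 1))
  comp <- EBImage::imageData(lab)
  counts <- tabulate(as.integer(comp))
  oc <- EBImage::ocontour(EBImage::Image(comp == which.max(counts)))[[1]]
  cbind(x = oc[, 1] + x_min, y = oc[, 2] + y_min)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %dx%d, %d fruits annotated (max occlusion %.3f), %d placements\n",
              dim(x$image)[2], dim(x$image)[1], nrow(x$annotations),
              if (nrow(x$annotations)) max(x$annotations$occlusion_ratio) else NA,
              nrow(x$placements)))
  invisible(x)
}

#' Synthesize one annotated orchard scene
#'
#' Convenience pipeline: [place_fruits()], [place_leaves()],
#' [compose_scene()] with a single seed.
#'
#' @inheritParams place_fruits
#' @param leaf_sprites List of leaf sprites (may be empty if
#'   `config$leaf_density == 0`).
#' @return A `synthetic_scene`.
#' @export
synthesize_scene <- function(background, sprites, leaf_sprites = list(),
                             config = scene_config(), seed = config$seed) {
  st <- place_fruits(background, sprites, config, seed = seed)
  if (config$leaf_density > 0 && length(leaf_sprites)) {
    st <- place_leaves(st, leaf_sprites, config, seed = derive_seed(seed, 86L))
  }
  compose_scene(background, st)
}

#' Synthesize and write an auto-labeled scene dataset
#'
#' Generates `n_scenes` annotated scenes (cycling over the supplied
#' backgrounds), writes each image as PNG, and writes COCO and/or VOC
#' annotation files plus a JSON manifest with the configuration, seeds, and
#' per-scene audit summary.  Aborted scenes are retried with a fresh
#' derived seed (up to 5 attempts) and logged.
#'
#' @param fruit_sprites,leaf_sprites Sprite lists (or directories readable
#'   by [read_sprites()]).
#' @param backgrounds List of `phenosynth_background` objects (or a
#'   directory of RGB PNGs).
#' @param config A [scene_config()].
#' @param n_scenes Number of scenes to write.
#' @param out_dir Output directory (created if missing).
#' @param format Character subset of `c("coco", "voc")`.
#' @param seed Integer seed.
#' @return Invisibly, a list with `scenes` (list of `synthetic_scene`),
#'   `manifest` (list), and the output paths.
#' @export
synthesize_dataset <- function(fruit_sprites, leaf_sprites, backgrounds,
                               config = scene_config(), n_scenes = 10L,
                               out_dir, format = "coco", seed = config$seed) {
  if (is.character(fruit_sprites)) fruit_sprites <- read_sprites(fruit_sprites)
  if (is.character(leaf_sprites)) leaf_sprites <- read_sprites(leaf_sprites)
  if (is.character(backgrounds)) backgrounds <- read_backgrounds(backgrounds)
  stopifnot(length(fruit_sprites) >= 1L, length(backgrounds) >= 1L,
            all(format %in% c("coco", "voc")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  scenes <- vector("list", n_scenes)
  scene_log <- list()
  for (i in seq_len(n_scenes)) {
    bg <- backgrounds[[(i - 1L) %% length(backgrounds) + 1L]]
    sc <- NULL
    for (try_k in 1:5) {
      sc <- tryCatch(
        synthesize_scene(bg, fruit_sprites, leaf_sprites, config,
                         seed = derive_seed(seed, 91L, i, try_k)),
        phenosynth_scene_abort = function(e) NULL)
      if (!is.null(sc)) break
    }
    if (is.null(sc)) {
      stop(sprintf("Scene %d: aborted after 5 retries.", i), call. = FALSE)
    }
    fn <- sprintf("scene_%04d.png", i)
    png::writePNG(sc$image, file.path(out_dir, fn))
    scenes[[i]] <- sc
    scene_log[[i]] <- list(index = i, file = fn, retries = try_k - 1L,
                           n_fruits = nrow(sc$annotations),
                           max_occlusion = if (nrow(sc$annotations))
                             max(sc$annotations$occlusion_ratio) else 0)
  }

  paths <- list()
  if ("coco" %in% format) {
    paths$coco <- write_coco(scenes,
                             image_files = vapply(scene_log, `[[`, character(1), "file"),
                             path = file.path(out_dir, "annotations_coco.json"))
  }
  if ("voc" %in% format) {
    paths$voc <- write_voc(scenes,
                           image_files = vapply(scene_log, `[[`, character(1), "file"),
                           out_dir = file.path(out_dir, "voc"))
  }
  manifest <- list(
    n_scenes = n_scenes, seed = seed,
    config = unclass(config),
    scenes = scene_log,
    total_instances = sum(vapply(scenes, function(s) nrow(s$annotations),
                                 numeric(1)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scenes = scenes, manifest = manifest, paths = paths,
                 out_dir = out_dir))
}
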