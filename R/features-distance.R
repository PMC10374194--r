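#' Compute per-sprite phenotype descriptors
#'
#' Convenience wrapper producing the shape, color, and texture descriptors
#' for each sprite of a collection, used by [build_distance_matrix()] and
#' [select_optimal_sources()].
#'
#' @param sprites Named list of `phenosynth_sprite` objects.
#' @param n_points Contour resampling length, default 128.
#' @param n_terms Fourier terms retained, default 16.
#' @param mode Shape normalization mode, `"standard"` or `"paper"`.
#' @param bin_width CIELAB interval width, default 20.
#' @param n_patches,patch_size Texture sampling parameters (defaults 16, 32).
#' @param seed Integer seed (texture patch sampling).
#' @return A list of class `phenotype_descriptors` with elements `shape`,
#'   `color`, `texture` (parallel lists of descriptors), `labels`,
#'   `species`.
#' @export
phenotype_descriptors <- function(sprites, n_points = 128L, n_terms = 16L,
                                  mode = "standard", bin_width = 20,
                                  n_patches = 16L, patch_size = 32L,
                                  seed = 1L) {
  stopifnot(length(sprites) >= 1L)
  labels <- names(sprites) %||% sprintf("sprite_%03d", seq_along(sprites))
  shape <- vector("list", length(sprites))
  color <- vector("list", length(sprites))
  texture <- vector("list", length(sprites))
  for (i in seq_along(sprites)) {
    ct <- extract_contour(sprites[[i]], n_points)
    shape[[i]] <- shape_descriptor(ct, n_terms, mode)
    color[[i]] <- color_descriptor(sprites[[i]], bin_width)
    patches <- sample_texture_patches(sprites[[i]], n_patches, patch_size,
                                      seed = derive_seed(seed, 61L, i))
    texture[[i]] <- texture_descriptor(patches)
  }
  structure(list(shape = shape, color = color, texture = texture,
                 labels = labels, species = sprite_species(sprites)),
            class = "phenotype_descriptors")
}

feature_pair_distance <- function(feature, a, b) {
  switch(feature,
         shape = shape_distance(a, b),
         color = color_distance(a, b),
         texture = texture_distance(a, b))
}

new_distance_matrix <- function(values, labels, feature, level) {
  dimnames(values) <- list(labels, labels)
  structure(values, feature = feature, level = level,
            class = c("phenosynth_dist", "matrix", "array"))
}

#' Pairwise feature-distance matrix for a sprite collection
#'
#' At `level = "image"`, entry (i, j) is the feature dissimilarity between
#' the descriptors of sprites i and j.  At `level = "dataset"`, entities are
#' the species tags and entry (A, B) is the mean over all cross pairs of
#' image-level distances (one image from A, one from B); diagonals are 0 by
#' definition.  `aggregate = "descriptor-mean"` instead averages the
#' per-image descriptor vectors within each dataset before measuring
#' distances.
#'
#' @param sprites Named list of `phenosynth_sprite` objects (>= 2), or a
#'   precomputed [phenotype_descriptors()] object.
#' @param feature `"shape"`, `"color"`, or `"texture"`.
#' @param level `"image"` or `"dataset"`.
#' @param aggregate Dataset-level aggregation, `"cross-pairs"` (default) or
#'   `"descriptor-mean"`.
#' @inheritParams phenotype_descriptors
#' @return A `phenosynth_dist`: a symmetric nonnegative matrix with zero
#'   diagonal, labeled rows/columns, and `feature` / `level` attributes.
#' @export
build_distance_matrix <- function(sprites,
                                  feature = c("shape", "color", "texture"),
                                  level = c("image", "dataset"),
                                  aggregate = c("cross-pairs", "descriptor-mean"),
                                  n_points = 128L, n_terms = 16L,
                                  mode = "standard", bin_width = 20,
                                  n_patches = 16L, patch_size = 32L,
                                  seed = 1L) {
  feature <- match.arg(feature)
  level <- match.arg(level)
  aggregate <- match.arg(aggregate)

  desc <- if (inherits(sprites, "phenotype_descriptors")) {
    sprites
  } else {
    stopifnot(length(sprites) >= 2L)
    phenotype_descriptors(sprites, n_points, n_terms, mode, bin_width,
                          n_patches, patch_size, seed)
  }
  d_list <- desc[[feature]]
  n <- length(d_list)

  img <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- feature_pair_distance(feature, d_list[[i]], d_list[[j]])
      img[i, j] <- v
      img[j, i] <- v
    }
  }

  if (level == "image") {
    return(new_distance_matrix(img, desc$labels, feature, level))
  }

  species <- desc$species
  if (any(is.na(species)) || is.null(species)) {
    stop("Dataset-level matrix requires species tags on every sprite.",
         call. = FALSE)
  }
  sp <- unique(species)
  m <- length(sp)
  if (m < 2L) stop("Dataset level requires >= 2 species.", call. = FALSE)
  out <- matrix(0, m, m)
  if (aggregate == "cross-pairs") {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        v <- mean(img[species == sp[i], species == sp[j]])
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  } else {
    pooled <- lapply(sp, function(s) pool_descriptors(feature, d_list[species == s]))
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        v <- feature_pair_distance(feature, pooled[[i]], pooled[[j]])
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  new_distance_matrix(out, sp, feature, level)
}

# Average per-image descriptors of one dataset into a single descriptor.
pool_descriptors <- function(feature, ds) {
  if (feature == "shape") {
    d <- Reduce(`+`, lapply(ds, `[[`, "normalized")) / length(ds)
    structure(list(coefficients = NULL, normalized = d,
                   mode = ds[[1]]$mode, n_terms = ds[[1]]$n_terms),
              class = "shape_descriptor")
  } else if (feature == "color") {
    m <- Reduce(`+`, lapply(ds, `[[`, "lab_means")) / length(ds)
    structure(list(lab_means = m,
                   lab_vars = Reduce(`+`, lapply(ds, `[[`, "lab_vars")) / length(ds),
                   bin_width = ds[[1]]$bin_width, intervals = NULL),
              class = "color_descriptor")
  } else {
    agg <- Reduce(`+`, lapply(ds, `[[`, "aggregate")) / length(ds)
    structure(list(patch_histograms = NULL, aggregate = agg,
                   n_patches = ds[[1]]$n_patches,
                   patch_size = ds[[1]]$patch_size),
              class = "texture_descriptor")
  }
}

#' @export
print.phenosynth_dist <- function(x, ...) {
  cat(sprintf("<distance matrix> feature=%s level=%s, %d entities\n",
              attr(x, "feature"), attr(x, "level"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Tidy a distance matrix into a long tibble
#'
#' @param x A `phenosynth_dist`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `distance`, `feature`,
#'   `level` (upper triangle only).
#' @export
tidy.phenosynth_dist <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(from = labs[idx[, 1]], to = labs[idx[, 2]],
                 distance = x[idx],
                 feature = attr(x, "feature"), level = attr(x, "level"))
}
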