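#' Scale-normalize the three feature-distance matrices
#'
#' The shape, color, and texture dissimilarities live on different numeric
#' scales, so before fusing them each matrix is multiplied by
#' `scale_feature = max_range / own_range`, where a matrix's range is
#' `max - min` of its off-diagonal entries and `max_range` is the largest of
#' the three ranges.  After scaling, all three ranges are equal.
#'
#' @param d_shape,d_color,d_texture `phenosynth_dist` matrices over the same
#'   labels in the same order.
#' @return A list with `matrices` (named list of scaled matrices) and
#'   `scales` (named length-3 numeric).
#' @export
normalize_scales <- function(d_shape, d_color, d_texture) {
  mats <- list(shape = d_shape, color = d_color, texture = d_texture)
  labs <- rownames(d_shape)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    stopifnot(nrow(m) == ncol(m))
    if (!identical(rownames(m), labs)) {
      stop("Matrices must share labels in the same order.", call. = FALSE)
    }
  }
  ranges <- vapply(mats, function(m) {
    off <- m[row(m) != col(m)]
    max(off) - min(off)
  }, numeric(1))
  if (any(ranges == 0)) {
    stop(sprintf("Zero distance range in feature '%s'; cannot normalize.",
                 names(ranges)[which(ranges == 0)[1]]), call. = FALSE)
  }
  scales <- max(ranges) / ranges
  scaled <- mapply(function(m, s) {
    out <- m * s
    attributes(out) <- attributes(m)
    out
  }, mats, scales, SIMPLIFY = FALSE)
  list(matrices = scaled, scales = scales)
}

#' Classical multidimensional scaling embedding
#'
#' Torgerson MDS of a symmetric zero-diagonal distance matrix: the distance
#' matrix is double-centered into a Gram matrix whose top eigenpairs give
#' coordinates that preserve the pairwise distances (exactly, when the
#' distances are Euclidean-realizable in `dim` dimensions).  Axes are
#' deterministic up to sign; each axis is flipped so its largest-magnitude
#' coordinate is positive.
#'
#' @param d A symmetric matrix (e.g. `phenosynth_dist`) with zero diagonal.
#' @param dim Embedding dimension, default 2.
#' @return A numeric matrix (entities x dim) with label rownames.  If fewer
#'   than `dim` positive eigenvalues exist the missing axes are zero-padded
#'   with a warning.
#' @export
mds_embed <- function(d, dim = 2L) {
  stopifnot(nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12)) {
    stop("`d` must be symmetric with a zero diagonal.", call. = FALSE)
  }
  fit <- stats::cmdscale(as.matrix(d), k = min(dim, nrow(d) - 1L), eig = TRUE)
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  if (ncol(pts) < dim) {
    warning("Fewer than ", dim, " positive eigenvalues; padding with zeros.",
            call. = FALSE)
    pts <- cbind(pts, matrix(0, nrow(pts), dim - ncol(pts)))
  }
  pts <- fix_signs(pts)
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  pts
}

# Flip each column so its largest-magnitude entry is positive (deterministic
# tie-break: first index of the maximum magnitude).
fix_signs <- function(m) {
  for (j in seq_len(ncol(m))) {
    i <- which.max(abs(m[, j]))
    if (m[i, j] < 0) m[, j] <- -m[, j]
  }
  m
}

#' Fuse per-feature embeddings into one 2-D feature space
#'
#' The fused x coordinate is the first principal component score of the
#' shape embedding; the fused y coordinate is the first principal component
#' score of the concatenated color and texture embeddings (columns centered
#' before projection, component signs fixed as in [mds_embed()]).
#'
#' @param shape_xy,color_xy,texture_xy Two-column coordinate matrices over
#'   identical labels (from [mds_embed()]).
#' @return A tibble with columns `label`, `x`, `y`.
#' @export
fuse_features <- function(shape_xy, color_xy, texture_xy) {
  labs <- rownames(shape_xy)
  stopifnot(identical(labs, rownames(color_xy)),
            identical(labs, rownames(texture_xy)))
  x <- pc1_scores(shape_xy)
  y <- pc1_scores(cbind(color_xy, texture_xy))
  tibble::tibble(label = labs, x = x, y = y)
}

pc1_scores <- function(m) {
  mc <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(mc) < 1e-12)) {
    warning("Rank-0 block; axis set to zeros.", call. = FALSE)
    return(rep(0, nrow(m)))
  }
  p <- stats::prcomp(mc, center = FALSE, scale. = FALSE)
  fix_signs(p$x[, 1L, drop = FALSE])[, 1L]
}

#' Density-based clustering of the fused feature space with medoids
#'
#' Runs DBSCAN (Euclidean metric, radius `eps`, core threshold
#' `min_samples`, neighbor counts include the point itself) over the fused
#' 2-D coordinates, labels non-reachable points as noise (`-1`), and
#' selects each cluster's medoid: the member with the smallest mean distance
#' to its co-members (ties broken by label order).  `eps = "auto"` uses the
#' knee of the sorted `min_samples`-nearest-neighbor distance curve (the
#' point of maximum deviation from the chord joining the curve's endpoints).
#'
#' @param fused A tibble with `label`, `x`, `y` (from [fuse_features()]), or
#'   a 2-column coordinate matrix with rownames.
#' @param eps Neighborhood radius, or `"auto"`.
#' @param min_samples Core-point threshold, default 4.
#' @return An object of class `cluster_result`: list with `labels`,
#'   `cluster` (integer, `-1` = noise), `medoids` (tibble `cluster`,
#'   `label`), `eps`, `min_samples`, `coords`.
#' @export
cluster_embedding <- function(fused, eps = "auto", min_samples = 4L) {
  if (is.matrix(fused)) {
    coords <- fused
    labs <- rownames(fused) %||% as.character(seq_len(nrow(fused)))
  } else {
    labs <- fused$label
    coords <- cbind(fused$x, fused$y)
  }
  n <- nrow(coords)
  stopifnot(n >= min_samples)
  dm <- as.matrix(stats::dist(coords))

  if (identical(eps, "auto")) {
    eps <- knee_eps(dm, min_samples)
  }
  if (!is.numeric(eps) || eps <= 0) {
    stop("`eps` must be a positive number or \"auto\".", call. = FALSE)
  }

  cl <- dbscan_impl(dm, eps, min_samples)

  meds <- list()
  for (k in sort(unique(cl[cl > 0]))) {
    members <- which(cl == k)
    if (length(members) == 1L) {
      best <- members
    } else {
      avg <- vapply(members, function(i) mean(dm[i, setdiff(members, i)]),
                    numeric(1))
      best <- members[which.min(avg)]  # first minimum = label-order tie-break
    }
    meds[[length(meds) + 1L]] <- tibble::tibble(cluster = k, label = labs[best])
  }
  structure(list(labels = labs, cluster = cl,
                 medoids = if (length(meds)) dplyr::bind_rows(meds)
                           else tibble::tibble(cluster = integer(), label = character()),
                 eps = eps, min_samples = as.integer(min_samples),
                 coords = coords),
            class = "cluster_result")
}

# Automatic eps from the k-NN distance curve: 5% above the 90th percentile
# of the k-th nearest-neighbor distances.  The upper decile is excluded so
# that up to 10% genuine outliers stay noise, while cluster members of
# heterogeneously tight clusters (whose ascending k-dist curve has several
# plateaus but no noise tail) all remain density-reachable.
knee_eps <- function(dm, k) {
  n <- nrow(dm)
  stopifnot(n > k)
  dk <- vapply(seq_len(n), function(i) sort(dm[i, -i])[k], numeric(1))
  max(1.05 * stats::quantile(dk, 0.9, names = FALSE), 1e-12)
}

# Textbook DBSCAN over a precomputed distance matrix.
dbscan_impl <- function(dm, eps, min_samples) {
  n <- nrow(dm)
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  cl <- rep(0L, n)  # 0 = unassigned
  k <- 0L
  for (i in seq_len(n)) {
    if (cl[i] != 0L || !core[i]) next
    k <- k + 1L
    cl[i] <- k
    queue <- setdiff(nb[[i]], i)
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (cl[j] == -1L) cl[j] <- k        # noise becomes border
      if (cl[j] != 0L) next
      cl[j] <- k
      if (core[j]) queue <- c(queue, setdiff(nb[[j]], j))
    }
  }
  cl[cl == 0L] <- -1L
  cl
}

#' @export
print.cluster_result <- function(x, ...) {
  nk <- length(unique(x$cluster[x$cluster > 0]))
  cat(sprintf("<cluster_result> %d points, %d clusters, %d noise (eps=%.4g, min_samples=%d)\n",
              length(x$cluster), nk, sum(x$cluster == -1L), x$eps, x$min_samples))
  if (nrow(x$medoids)) {
    cat("medoids:", paste(sprintf("%d:%s", x$medoids$cluster, x$medoids$label),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  out <- list(label = x$labels, x = x$coords[, 1], y = x$coords[, 2],
              cluster = x$cluster,
              is_medoid = x$labels %in% x$medoids$label)
  tibble::as_tibble(out)
}

#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n = length(x$cluster),
                 n_clusters = length(unique(x$cluster[x$cluster > 0])),
                 n_noise = sum(x$cluster == -1L),
                 eps = x$eps, min_samples = x$min_samples)
}

#' Select optimal source-domain datasets
#'
#' End-to-end source selection: builds the three feature-distance matrices
#' for a sprite collection, scale-normalizes them, embeds each with
#' classical MDS, fuses the embeddings into a 2-D feature space (shape on
#' x, color + texture on y), clusters with DBSCAN, and recommends each
#' cluster's medoid — the dataset with the closest average phenotype
#' distance to the other members of its cluster — as that cluster's optimal
#' source domain.
#'
#' @param sprites Named list of species-tagged `phenosynth_sprite` objects,
#'   or a precomputed [phenotype_descriptors()] object.
#' @param level `"dataset"` (default) clusters species datasets;
#'   `"image"` clusters individual sprites.
#' @param eps,min_samples DBSCAN parameters (see [cluster_embedding()]).
#' @inheritParams build_distance_matrix
#' @param out Optional path: writes the embedding, clusters, and
#'   recommendations as JSON.
#' @param plot Optional path: writes a scatter plot of the fused space.
#' @return An object of class `source_selection`: list with `embedding`
#'   (tibble label/x/y), `per_feature` (list of MDS coordinate matrices),
#'   `scales`, `clusters` (a `cluster_result`), and `recommendations`
#'   (tibble `cluster`, `source`, `n_members`, `mean_distance`).
#' @export
select_optimal_sources <- function(sprites, level = "dataset",
                                   eps = "auto", min_samples = 4L,
                                   aggregate = "cross-pairs",
                                   n_points = 128L, n_terms = 16L,
                                   mode = "standard", bin_width = 20,
                                   n_patches = 16L, patch_size = 32L,
                                   seed = 1L, out = NULL, plot = NULL) {
  desc <- if (inherits(sprites, "phenotype_descriptors")) sprites
          else phenotype_descriptors(sprites, n_points, n_terms, mode,
                                     bin_width, n_patches, patch_size, seed)
  mats <- lapply(c(shape = "shape", color = "color", texture = "texture"),
                 function(f) build_distance_matrix(desc, f, level,
                                                   aggregate = aggregate))
  sc <- normalize_scales(mats$shape, mats$color, mats$texture)
  emb <- lapply(sc$matrices, mds_embed, dim = 2L)
  fused <- fuse_features(emb$shape, emb$color, emb$texture)
  cl <- cluster_embedding(fused, eps = eps, min_samples = min_samples)

  dm <- as.matrix(stats::dist(cl$coords))
  recs <- purrr::pmap_dfr(cl$medoids, function(cluster, label) {
    members <- which(cl$cluster == cluster)
    i <- which(cl$labels == label)
    tibble::tibble(cluster = cluster, source = label,
                   n_members = length(members),
                   mean_distance = if (length(members) > 1L)
                     mean(dm[i, setdiff(members, i)]) else 0)
  })

  res <- structure(list(embedding = fused, per_feature = emb,
                        scales = sc$scales, clusters = cl,
                        recommendations = recs, level = level),
                   class = "source_selection")
  if (!is.null(out)) write_selection_json(res, out)
  if (!is.null(plot)) {
    p <- autoplot.source_selection(res)
    ggplot2::ggsave(plot, p, width = 6, height = 5, dpi = 150)
  }
  res
}

write_selection_json <- function(res, path) {
  td <- tidy(res$clusters)
  jsonlite::write_json(
    list(labels = td$label,
         fused = list(x = td$x, y = td$y),
         cluster = td$cluster,
         medoids = res$clusters$medoids,
         recommendations = res$recommendations,
         parameters = list(eps = res$clusters$eps,
                           min_samples = res$clusters$min_samples,
                           scales = as.list(res$scales),
                           level = res$level)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.source_selection <- function(x, ...) {
  cat(sprintf("<source_selection> %d entities (%s level), %d clusters\n",
              nrow(x$embedding), x$level,
              nrow(x$recommendations)))
  print(x$recommendations)
  invisible(x)
}

#' @export
tidy.source_selection <- function(x, ...) tidy(x$clusters)

#' @export
glance.source_selection <- function(x, ...) glance(x$clusters)

#' Plot a fused feature space with clusters and medoids
#'
#' @param object A `source_selection`.
#' @param ... Unused.
#' @return A ggplot: fused 2-D coordinates colored by cluster, medoids
#'   highlighted.
#' @export
autoplot.source_selection <- function(object, ...) {
  td <- tidy(object$clusters)
  td$cluster <- factor(td$cluster)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = td[td$is_medoid, ], shape = 1, size = 5,
                        stroke = 1.2, color = "red") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 2.8, show.legend = FALSE) +
    ggplot2::labs(x = "shape (fused)", y = "color + texture (fused)",
                  title = "Fused phenotype feature space",
                  subtitle = "circled points are cluster medoids (optimal sources)") +
    ggplot2::theme_minimal()
}
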