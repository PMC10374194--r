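#' Sample interior texture patches from a sprite
#'
#' Randomly samples `n_patches` axis-aligned square patches among all
#' positions whose footprint is at least 95% inside the foreground mask,
#' then returns them as grayscale (Rec. 709 luma) matrices.  Sampling is
#' uniform over the valid positions and deterministic in `seed`.
#'
#' @param sprite A `phenosynth_sprite`.
#' @param n_patches Number of patches, default 16.
#' @param patch_size Patch side in pixels, default 32.
#' @param seed Integer seed.
#' @return A list of `patch_size` x `patch_size` numeric matrices with a
#'   `positions` attribute (tibble of 0-based top-left `x`, `y`).
#' @export
sample_texture_patches <- function(sprite, n_patches = 16L, patch_size = 32L,
                                   seed = 1L) {
  stopifnot(inherits(sprite, "phenosynth_sprite"),
            n_patches >= 1L, patch_size >= 3L)
  mask <- sprite_mask(sprite)
  h <- nrow(mask); w <- ncol(mask)
  ps <- as.integer(patch_size)
  if (h < ps || w < ps) {
    stop("Sprite smaller than `patch_size`; use a smaller patch_size.",
         call. = FALSE)
  }
  counts <- footprint_counts(mask, ps)
  valid <- which(counts >= 0.95 * ps * ps)
  if (length(valid) == 0L) {
    stop("No patch position is >= 95% inside the foreground; ",
         "use a smaller patch_size.", call. = FALSE)
  }
  nr <- h - ps + 1L
  pick <- with_seed(derive_seed(seed, 51L),
                    valid[sample.int(length(valid), n_patches, replace = TRUE)])
  r0 <- (pick - 1L) %% nr + 1L
  c0 <- (pick - 1L) %/% nr + 1L

  gray <- 0.2126 * sprite$pixels[, , 1] + 0.7152 * sprite$pixels[, , 2] +
    0.0722 * sprite$pixels[, , 3]
  patches <- lapply(seq_len(n_patches), function(i) {
    gray[r0[i]:(r0[i] + ps - 1L), c0[i]:(c0[i] + ps - 1L)]
  })
  attr(patches, "positions") <- tibble::tibble(x = c0 - 1L, y = r0 - 1L)
  patches
}

# Foreground pixel count of every patch_size footprint via an integral
# image; returns an (h-ps+1) x (w-ps+1) matrix.
footprint_counts <- function(mask, ps) {
  h <- nrow(mask); w <- ncol(mask)
  s <- matrix(0, h + 1L, w + 1L)
  s[-1, -1] <- apply(apply(mask, 2, cumsum), 1, cumsum) |> t()
  r <- seq_len(h - ps + 1L)
  c <- seq_len(w - ps + 1L)
  s[r + ps, c + ps, drop = FALSE] - s[r + ps, c, drop = FALSE] -
    s[r, c + ps, drop = FALSE] + s[r, c, drop = FALSE]
}

# Rotation-invariant uniform LBP codes (P = 8, R = 1) for the interior of a
# grayscale matrix; neighbors at exact circle positions with bilinear
# interpolation.  Codes: 0..8 = number of ones for uniform patterns
# (<= 2 circular transitions), 9 = non-uniform.
lbp_codes <- function(m, P = 8L, R = 1) {
  h <- nrow(m); w <- ncol(m)
  marg <- ceiling(R)
  ri <- (marg + 1L):(h - marg)
  ci <- (marg + 1L):(w - marg)
  center <- m[ri, ci, drop = FALSE]
  ones <- matrix(0L, length(ri), length(ci))
  bits <- vector("list", P)
  for (k in 0:(P - 1L)) {
    ang <- 2 * pi * k / P
    dx <- R * cos(ang)
    dy <- -R * sin(ang)
    # bilinear sample at (row + dy, col + dx)
    fr <- dy - floor(dy); fc <- dx - floor(dx)
    r0 <- ri + floor(dy); c0 <- ci + floor(dx)
    r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)  # zero-weight when f == 0
    nb <- m[r0, c0, drop = FALSE] * (1 - fr) * (1 - fc) +
      m[r0, c1, drop = FALSE] * (1 - fr) * fc +
      m[r1, c0, drop = FALSE] * fr * (1 - fc) +
      m[r1, c1, drop = FALSE] * fr * fc
    b <- (nb >= center - 1e-12) * 1L
    bits[[k + 1L]] <- b
    ones <- ones + b
  }
  trans <- matrix(0L, nrow(ones), ncol(ones))
  for (k in seq_len(P)) {
    nxt <- if (k == P) 1L else k + 1L
    trans <- trans + abs(bits[[k]] - bits[[nxt]])
  }
  code <- ifelse(trans <= 2L, ones, P + 1L)
  code
}

#' Texture descriptor from sampled patches
#'
#' Computes a rotation-invariant uniform local binary pattern histogram
#' (8 neighbors, radius 1, 10 bins) for each patch, L1-normalized, plus the
#' mean histogram across patches.
#'
#' @param patches A list of grayscale matrices, e.g. from
#'   [sample_texture_patches()].
#' @return A list of class `texture_descriptor` with `patch_histograms`
#'   (list of length-10 numeric vectors summing to 1), `aggregate` (their
#'   mean), `n_patches`, `patch_size`.
#' @export
texture_descriptor <- function(patches) {
  stopifnot(is.list(patches), length(patches) >= 1L)
  hists <- lapply(patches, function(p) {
    codes <- lbp_codes(p)
    hh <- tabulate(as.integer(codes) + 1L, nbins = 10L)
    hh / sum(hh)
  })
  agg <- Reduce(`+`, hists) / length(hists)
  structure(list(patch_histograms = hists, aggregate = agg,
                 n_patches = length(patches),
                 patch_size = nrow(patches[[1]])),
            class = "texture_descriptor")
}

#' @export
print.texture_descriptor <- function(x, ...) {
  cat(sprintf("<texture_descriptor> %d patches of %d px; aggregate: %s\n",
              x$n_patches, x$patch_size,
              paste(signif(x$aggregate, 2), collapse = " ")))
  invisible(x)
}

#' Texture dissimilarity between two descriptors
#'
#' `1 - rho`, the Pearson dissimilarity of the two aggregate LBP
#' histograms; range \[0, 2\], with the same zero-variance convention as
#' [shape_distance()].
#'
#' @param t1,t2 `texture_descriptor` objects with equal histogram length.
#' @return A single dissimilarity value in \[0, 2\].
#' @export
texture_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "texture_descriptor"),
            inherits(t2, "texture_descriptor"))
  if (length(t1$aggregate) != length(t2$aggregate)) {
    stop("Descriptors must share the LBP configuration.", call. = FALSE)
  }
  pearson_dissimilarity(t1$aggregate, t2$aggregate)
}
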