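# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

disc_spec <- function(seed = 1L) {
  species_spec("disc", exponent = 2, aspect = 1, wobble = 0,
               lab_center = c(70, 40, 50), lab_spread = c(0, 0, 0),
               octaves = 0L, contrast = 0, seed = seed)
}

disc_sprite <- function() memo("disc", generate_fruit_sprite(disc_spec(), 0))

# Uniform-color RGBA sprite from explicit sRGB values.
uniform_sprite <- function(rgb, size = 64L, radius = 24L) {
  px <- array(0, dim = c(size, size, 4))
  cx <- (size - 1) / 2
  xs <- matrix(rep(0:(size - 1), each = size), size, size) - cx
  ys <- matrix(rep(0:(size - 1), times = size), size, size) - cx
  inside <- xs^2 + ys^2 <= radius^2
  for (ch in 1:3) {
    plane <- matrix(0, size, size)
    plane[inside] <- rgb[ch]
    px[, , ch] <- plane
  }
  px[, , 4][inside] <- 1
  phenosynth:::new_sprite(px, "uniform")
}

demo_fruits <- function() memo("demo_fruits", {
  spec1 <- species_spec("orange", exponent = 2.2, aspect = 1, wobble = 0.03,
                        lab_center = c(65, 35, 50), lab_spread = c(2, 2, 2),
                        octaves = 4L, contrast = 0.2, seed = 21L)
  spec2 <- species_spec("apple", exponent = 2.6, aspect = 1.1, wobble = 0.04,
                        lab_center = c(55, 45, 35), lab_spread = c(2, 2, 2),
                        octaves = 4L, contrast = 0.1, seed = 22L)
  c(lapply(0:3, function(i) generate_fruit_sprite(spec1, i)),
    lapply(0:3, function(i) generate_fruit_sprite(spec2, i)))
})

demo_leaves <- function() memo("demo_leaves",
  lapply(0:9, function(i) generate_leaf_sprite(7L, i)))

demo_background <- function(seed = 101L) {
  memo(paste0("bg", seed), generate_background(480L, 360L, seed))
}

# Random ground-truth boxes spread over n_img images.
random_truth <- function(n_img, per_img, seed) {
  phenosynth:::with_seed(seed, {
    tibble::tibble(
      image = rep(sprintf("img%03d", seq_len(n_img)), each = per_img),
      x_min = stats::runif(n_img * per_img, 0, 400),
      y_min = stats::runif(n_img * per_img, 0, 300),
      w = stats::runif(n_img * per_img, 20, 60),
      h = stats::runif(n_img * per_img, 20, 60))
  })
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Independent occlusion oracle: rebuilds every placement's binary footprint
# from its raw RGBA raster and recounts covered pixels per fruit.
occlusion_oracle <- function(scene) {
  h <- dim(scene$image)[1]
  fps <- lapply(scene$raw_placements, function(p) {
    a <- p$pixels[p$sub_r, p$sub_c, 4, drop = TRUE]
    if (!is.matrix(a)) a <- matrix(a, length(p$sub_r), length(p$sub_c))
    as.integer(outer(p$rows, (p$cols - 1L) * h, `+`))[as.vector(a >= 0.5)]
  })
  z <- vapply(scene$raw_placements, `[[`, numeric(1), "z_order")
  vapply(seq_len(nrow(scene$annotations)), function(k) {
    id <- scene$annotations$instance_id[k]
    fp <- fps[[id]]
    later <- unlist(fps[z > z[id]])
    if (length(fp) == 0) return(1)
    if (length(later) == 0) return(0)
    mean(fp %in% later)
  }, numeric(1))
}
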