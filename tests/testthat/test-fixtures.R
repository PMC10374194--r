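test_that("disc-limit sprite has a single-harmonic boundary and planted color", {
  s <- disc_sprite()
  ct <- extract_contour(s, 128)
  d <- shape_descriptor(ct, 16, "standard")
  expect_lt(max(d$normalized), 1e-3)

  cd <- color_descriptor(s)
  expect_lt(sqrt(sum((cd$lab_means - c(70, 40, 50))^2)), 2.0)
  expect_true(all(cd$lab_vars < 1e-6))
})

test_that("sprite generation is deterministic and validated", {
  spec <- species_spec("x", seed = 42L)
  s1 <- generate_fruit_sprite(spec, 3L)
  s2 <- generate_fruit_sprite(spec, 3L)
  expect_identical(s1$pixels, s2$pixels)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  write_sprite(s1, f1); write_sprite(s2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  s3 <- generate_fruit_sprite(spec, 4L)
  expect_false(identical(s1$pixels, s3$pixels))

  expect_error(species_spec("bad", exponent = 0), "exponent")
  expect_error(species_spec("bad", lab_center = c(120, 0, 0)), "CIELAB")

  mask <- s1$pixels[, , 4] >= 0.5
  expect_gte(sum(mask), 500)
  # foreground bounding box strictly inside the canvas
  expect_true(all(rowSums(mask)[c(1, nrow(mask))] == 0))
  expect_true(all(colSums(mask)[c(1, ncol(mask))] == 0))
})

test_that("leaf sprites are deterministic, connected, and green-hued", {
  l1 <- generate_leaf_sprite(5L, 2L)
  l2 <- generate_leaf_sprite(5L, 2L)
  expect_identical(l1$pixels, l2$pixels)
  for (i in 0:9) {
    lf <- generate_leaf_sprite(5L, i)
    mask <- lf$pixels[, , 4] >= 0.5
    lab <- EBImage::bwlabel(phenosynth:::as_ebimage(mask * 1))
    expect_equal(max(EBImage::imageData(lab)), 1)
    expect_lt(color_descriptor(lf)$lab_means[["a"]], 0)
  }
})

test_that("backgrounds have a tree band fraction in [0.3, 0.7] and a partition mask", {
  for (seed in c(1L, 17L, 33L)) {
    bg <- generate_background(480L, 360L, seed)
    frac <- mean(bg$region_mask == 2L)
    expect_gte(frac, 0.3)
    expect_lte(frac, 0.7)
    expect_true(all(bg$region_mask %in% 1:3))
    expect_identical(dim(bg$region_mask), dim(bg$image)[1:2])
  }
  expect_error(generate_background(100, 360), ">= 128")
})

test_that("threshold segmentation recovers generated region masks", {
  agree <- vapply(1:10, function(seed) {
    bg <- generate_background(320L, 240L, seed)
    mean(segment_background(bg) == bg$region_mask)
  }, numeric(1))
  expect_true(all(agree >= 0.9))
})

test_that("species collections are tagged, counted, and statistically planted", {
  specs <- list(
    species_spec("a", exponent = 2, aspect = 1.3, lab_center = c(62, 45, 35),
                 lab_spread = c(1, 1, 1), octaves = 0L, contrast = 0, seed = 1L),
    species_spec("b", exponent = 4.5, lab_center = c(55, -38, 40),
                 lab_spread = c(1, 1, 1), contrast = 0.5, seed = 2L),
    species_spec("c", exponent = 1.2, aspect = 0.7, lab_center = c(75, 0, 30),
                 lab_spread = c(1, 1, 1), contrast = 0.2, seed = 3L))
  coll <- generate_species_collection(specs, 3L)
  expect_length(coll, 9L)
  expect_equal(unname(table(phenosynth::: sprite_species(coll))["a"]), 3L)

  # planted separation: within-species color distances below between-species
  cds <- lapply(coll, color_descriptor)
  species <- phenosynth:::sprite_species(coll)
  d <- outer(seq_along(cds), seq_along(cds),
             Vectorize(function(i, j) color_distance(cds[[i]], cds[[j]])))
  same <- outer(species, species, `==`) & upper.tri(d)
  diff <- outer(species, species, `!=`) & upper.tri(d)
  expect_lt(max(d[same]), min(d[diff]))

  # same spec, different seeds: distinct pixels, similar species statistics
  sa <- generate_fruit_sprite(specs[[1]], 0L)
  spec_b <- specs[[1]]; spec_b$seed <- 99L
  sb <- generate_fruit_sprite(spec_b, 0L)
  expect_false(identical(sa$pixels, sb$pixels))
  expect_lt(color_distance(color_descriptor(sa), color_descriptor(sb)), 8)
})

test_that("mock detector honors its identity, miss, and false-positive contracts", {
  truth <- random_truth(5, 4, 1L)
  ident <- mock_detector(truth, fp_rate = 0, miss_rate = 0, jitter_px = 0,
                         score_sd = 0, seed = 1L)
  expect_equal(nrow(ident), nrow(truth))
  expect_equal(ident$x_min, truth$x_min)
  expect_equal(ident$w, truth$w)
  expect_true(all(ident$matched_truth))

  none <- mock_detector(truth, miss_rate = 1, seed = 1L)
  expect_equal(nrow(none), 0L)

  # bimodal score sample: adaptive threshold falls between the modes
  det <- mock_detector(random_truth(25, 4, 2L), score_high = 0.9,
                       score_low = 0.2, fp_rate = 1, miss_rate = 0,
                       score_sd = 0.02, seed = 3L)
  th <- select_adaptive_threshold(det$score, 0.01)
  expect_gt(th$chosen, 0.2)
  expect_lt(th$chosen, 0.9)

  expect_error(mock_detector(truth, score_high = 0.2, score_low = 0.8))
})
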