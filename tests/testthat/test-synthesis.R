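test_that("segmentation handles degenerate and generated backgrounds", {
  blue <- array(0, dim = c(128, 128, 3))
  blue[, , 3] <- 0.9
  expect_error(segment_background(blue), "tree")

  bg <- demo_background()
  m <- segment_background(bg)
  expect_true(all(m %in% 1:3))
  expect_gte(mean(m == bg$region_mask), 0.9)
  tr <- attr(m, "tree_region")
  expect_true(is.logical(tr))
  expect_true(all(m[tr] == 2L))
})

test_that("sprite jitter honors identity, area, and photometric contracts", {
  s <- demo_fruits()[[1]]
  expect_identical(phenosynth:::apply_jitter(s, 1, 0, 1, 1), s)

  # 90 degree rotation of a square sprite conserves alpha area within 1%
  px <- array(0, dim = c(64, 64, 4))
  px[17:48, 17:48, ] <- 1
  sq <- phenosynth:::new_sprite(px, "square")
  rot <- phenosynth:::apply_jitter(sq, 1, 90, 1, 1)
  expect_lt(abs(sum(rot$pixels[, , 4]) - sum(px[, , 4])) / sum(px[, , 4]),
            0.01)

  # brightness multiplier scales the HSV value channel
  u <- uniform_sprite(c(0.5, 0.4, 0.3))
  br <- phenosynth:::apply_jitter(u, 1, 0, 1, 1.2)
  v0 <- pmax(u$pixels[, , 1], u$pixels[, , 2], u$pixels[, , 3])
  v1 <- pmax(br$pixels[, , 1], br$pixels[, , 2], br$pixels[, , 3])
  m0 <- u$pixels[, , 4] >= 0.5
  m1 <- br$pixels[, , 4] >= 0.5
  expect_equal(mean(v1[m1]) / mean(v0[m0]), 1.2, tolerance = 0.01)

  tiny <- uniform_sprite(c(0.5, 0.5, 0.5), size = 64, radius = 10)
  expect_error(phenosynth:::apply_jitter(tiny, 0.05, 0, 1, 1), "4 px")

  cfg <- scene_config()
  j <- jitter_sprite(s, cfg, seed = 5)
  expect_s3_class(j, "phenosynth_sprite")
  expect_named(attr(j, "photometric"),
               c("scale", "rotation", "saturation", "brightness"))
  expect_identical(jitter_sprite(s, cfg, seed = 5)$pixels, j$pixels)
})

test_that("fruit placement respects the tree region, counts, and determinism", {
  bg <- demo_background()
  cfg <- scene_config(n_fruits = c(5L, 5L), seed = 3L)
  st <- place_fruits(bg, demo_fruits(), cfg, seed = 3L)
  fruits <- Filter(function(p) p$category == "fruit", st$placements)
  expect_length(fruits, 5L)
  for (p in fruits) {
    expect_true(st$tree_region[p$center_y + 1L, p$center_x + 1L])
  }
  zs <- vapply(st$placements, `[[`, numeric(1), "z_order")
  expect_equal(zs, as.numeric(seq_along(zs)))

  st2 <- place_fruits(bg, demo_fruits(), cfg, seed = 3L)
  expect_identical(st$placements, st2$placements)

  st3 <- place_leaves(st, demo_leaves(), cfg, seed = 4L)
  leaves <- Filter(function(p) p$category == "leaf", st3$placements)
  expect_length(leaves, 5L)  # leaf_density 1
  cfg0 <- scene_config(n_fruits = c(5L, 5L), leaf_density = 0)
  expect_identical(place_leaves(st, demo_leaves(), cfg0), st)
})

test_that("occlusion ratios are exact pixel counts with the boundary accepted", {
  p1 <- list(footprint = 1:100)
  expect_equal(check_occlusion(p1, list()), 0)
  expect_equal(check_occlusion(p1, list(list(footprint = 51:150))), 0.5)
  expect_equal(check_occlusion(p1, list(list(footprint = 1:100))), 1)
  # union semantics: overlapping occluders are not double counted
  expect_equal(check_occlusion(p1, list(list(footprint = 1:30),
                                        list(footprint = 21:50))), 0.5)
  expect_equal(check_occlusion(list(footprint = integer(0)), list()), 1)
})

test_that("emitted annotations satisfy the occlusion bound and label fidelity", {
  bg <- demo_background()
  cfg <- scene_config(n_fruits = c(8L, 14L))
  for (seed in c(21L, 22L, 23L)) {
    sc <- synthesize_scene(bg, demo_fruits(), demo_leaves(), cfg, seed = seed)
    ann <- sc$annotations
    expect_gt(nrow(ann), 0)
    expect_true(all(ann$occlusion_ratio <= cfg$max_occlusion))
    # independent per-pixel recount
    expect_equal(occlusion_oracle(sc), ann$occlusion_ratio, tolerance = 1e-12)
    # bbox is exactly the tight box of the visible mask
    for (k in seq_len(nrow(ann))) {
      mk <- ann$mask[[k]]
      expect_true(any(mk$m[1, ]) && any(mk$m[nrow(mk$m), ]) &&
                    any(mk$m[, 1]) && any(mk$m[, ncol(mk$m)]))
      expect_equal(c(nrow(mk$m), ncol(mk$m)), c(ann$h[k], ann$w[k]),
                   ignore_attr = TRUE)
      expect_equal(c(mk$x_min, mk$y_min), c(ann$x_min[k], ann$y_min[k]),
                   ignore_attr = TRUE)
      expect_equal(sum(mk$m), ann$area[k])
    }
  }
})

test_that("composition is exact for a single unoccluded fruit", {
  bg <- demo_background()
  cfg <- scene_config(n_fruits = c(1L, 1L))
  sc <- synthesize_scene(bg, demo_fruits(), list(),
                         scene_config(n_fruits = c(1L, 1L), leaf_density = 0),
                         seed = 9L)
  ann <- sc$annotations
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$occlusion_ratio, 0)
  p <- sc$raw_placements[[ann$instance_id]]
  a <- p$pixels[p$sub_r, p$sub_c, 4]
  fg <- which(a >= 0.5, arr.ind = TRUE)
  expect_equal(ann$x_min, min(p$cols[fg[, 2]]) - 1)
  expect_equal(ann$y_min, min(p$rows[fg[, 1]]) - 1)
  expect_equal(ann$w, diff(range(p$cols[fg[, 2]])) + 1)
  expect_equal(ann$h, diff(range(p$rows[fg[, 1]])) + 1)
  expect_equal(ann$area, sum(a >= 0.5))

  # pixel accounting: visible areas + untouched background = image area
  h <- dim(sc$image)[1]; w <- dim(sc$image)[2]
  covered <- sum(vapply(sc$raw_placements, function(p) length(p$footprint),
                        numeric(1)))
  vis_total <- sum(ann$area)
  expect_equal(vis_total, covered)  # single sprite: all pixels visible
  expect_lte(vis_total, h * w)
})

test_that("dataset synthesis writes consistent scenes, labels, and manifest", {
  out1 <- file.path(tempdir(), "ds1")
  out2 <- file.path(tempdir(), "ds2")
  unlink(c(out1, out2), recursive = TRUE)
  cfg <- scene_config(n_fruits = c(3L, 6L))
  ds <- synthesize_dataset(demo_fruits(), demo_leaves(),
                           list(demo_background(), demo_background(102L)),
                           cfg, n_scenes = 4L, out_dir = out1,
                           format = c("coco", "voc"), seed = 31L)
  expect_length(list.files(out1, pattern = "^scene_.*png$"), 4L)
  coco <- read_coco(file.path(out1, "annotations_coco.json"))
  expect_equal(nrow(coco$images), 4L)
  expect_true(all(coco$annotations$image %in% coco$images$file_name))
  expect_equal(nrow(coco$annotations), ds$manifest$total_instances)
  # annotation boxes match the in-memory scenes exactly
  memo_ann <- dplyr::bind_rows(lapply(ds$scenes, `[[`, "annotations"))
  expect_equal(coco$annotations$x_min, memo_ann$x_min)
  expect_equal(coco$annotations$w, memo_ann$w)
  expect_equal(coco$annotations$area, memo_ann$area)
  expect_length(list.files(file.path(out1, "voc"), pattern = "xml$"), 4L)

  ds2 <- synthesize_dataset(demo_fruits(), demo_leaves(),
                            list(demo_background(), demo_background(102L)),
                            cfg, n_scenes = 4L, out_dir = out2,
                            format = c("coco", "voc"), seed = 31L)
  f1 <- list.files(out1, recursive = TRUE)
  expect_identical(f1, list.files(out2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = paste("hash of", f))
  }
})
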