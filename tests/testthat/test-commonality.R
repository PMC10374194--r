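sym_matrix <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("scale normalization equalizes the three distance ranges", {
  labs <- letters[1:4]
  # off-diagonal ranges 0.5, 2.0, 1.0 -> scales 4, 1, 2
  d_s <- sym_matrix(c(0.5, 0.7, 0.9, 1.0, 0.6, 0.8), labs)
  d_c <- sym_matrix(c(1.0, 2.0, 3.0, 1.5, 2.5, 2.8), labs)
  d_t <- sym_matrix(c(0.2, 0.7, 1.2, 0.5, 0.9, 1.1), labs)
  sc <- normalize_scales(d_s, d_c, d_t)
  expect_equal(unname(sc$scales), c(4, 1, 2))
  rng <- vapply(sc$matrices, function(m) {
    o <- m[row(m) != col(m)]; max(o) - min(o)
  }, numeric(1))
  expect_true(all(abs(rng - 2) < 1e-12))

  same <- normalize_scales(d_c, d_c, d_c)
  expect_equal(unname(same$scales), c(1, 1, 1))

  for (i in 1:5) {
    ms <- lapply(1:3, function(k) {
      sym_matrix(phenosynth:::with_seed(i * 10 + k, stats::runif(6, 0, k)), labs)
    })
    sc <- normalize_scales(ms[[1]], ms[[2]], ms[[3]])
    ranges0 <- vapply(ms, function(m) {
      o <- m[row(m) != col(m)]; max(o) - min(o)
    }, numeric(1))
    # direct arithmetic oracle for the scale factors
    expect_equal(unname(sc$scales), max(ranges0) / ranges0, tolerance = 1e-12)
    rng <- vapply(sc$matrices, function(m) {
      o <- m[row(m) != col(m)]; max(o) - min(o)
    }, numeric(1))
    expect_lt(max(rng) - min(rng), 1e-9)
  }

  dz <- sym_matrix(rep(0.3, 6), labs)
  expect_error(normalize_scales(dz, d_c, d_t), "shape")
  bad <- d_c; rownames(bad) <- colnames(bad) <- letters[5:8]
  expect_error(normalize_scales(d_s, bad, d_t), "labels")
})

test_that("classical MDS reproduces realizable planar configurations", {
  labs <- c("p", "q", "r")
  tri <- sym_matrix(rep(1, 3), labs)
  emb <- mds_embed(tri, 2)
  d <- as.matrix(stats::dist(emb))
  expect_true(all(abs(d[upper.tri(d)] - 1) < 1e-9))

  for (i in 1:3) {
    pts <- phenosynth:::with_seed(i, matrix(stats::rnorm(20, sd = 3), 10, 2))
    D <- as.matrix(stats::dist(pts))
    dimnames(D) <- list(paste0("n", 1:10), paste0("n", 1:10))
    emb <- mds_embed(D, 2)
    expect_lt(max(abs(as.matrix(stats::dist(emb)) - D)), 1e-6)
  }

  two <- sym_matrix(4, c("a", "b"))
  e2 <- suppressWarnings(mds_embed(two, 2))
  expect_equal(as.numeric(stats::dist(e2)), 4, tolerance = 1e-9)
  expect_equal(ncol(e2), 2L)

  asym <- sym_matrix(c(1, 2, 3), letters[1:3]); asym[1, 2] <- 9
  expect_error(mds_embed(asym, 2), "symmetric")
})

test_that("deterministic sign fixing makes embeddings reproducible", {
  pts <- phenosynth:::with_seed(9, matrix(stats::rnorm(16), 8, 2))
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(letters[1:8], letters[1:8])
  e1 <- mds_embed(D, 2)
  e2 <- mds_embed(D, 2)
  expect_identical(e1, e2)
  for (j in 1:2) expect_gt(e1[which.max(abs(e1[, j])), j], 0)
})

test_that("feature fusion projects onto first principal components", {
  labs <- paste0("d", 1:8)
  xy <- phenosynth:::with_seed(4, cbind(stats::rnorm(8, sd = 3), rep(0, 8)))
  rownames(xy) <- labs
  other <- phenosynth:::with_seed(5, matrix(stats::rnorm(16), 8, 2))
  rownames(other) <- labs
  fused <- fuse_features(xy, other, other)
  # rank-1 shape block: x equals its nonzero column up to centering and sign
  cc <- xy[, 1] - mean(xy[, 1])
  expect_lt(min(max(abs(fused$x - cc)), max(abs(fused$x + cc))), 1e-9)

  # rotation equivariance: rotating shape_xy leaves x unchanged up to sign
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy2 <- phenosynth:::with_seed(6, matrix(stats::rnorm(16), 8, 2))
  rownames(xy2) <- labs
  f1 <- fuse_features(xy2, other, other)
  xy2r <- xy2 %*% rot
  rownames(xy2r) <- labs
  f2 <- fuse_features(xy2r, other, other)
  expect_lt(min(max(abs(f1$x - f2$x)), max(abs(f1$x + f2$x))), 1e-9)

  # variance of x equals the top eigenvalue of the shape covariance
  ev <- eigen(stats::cov(xy2))$values[1]
  expect_equal(stats::var(f1$x), ev, tolerance = 1e-9)
})

test_that("density clustering finds planted blobs and exact medoids", {
  pts <- phenosynth:::with_seed(11, rbind(
    cbind(stats::rnorm(10, 0, 0.1), stats::rnorm(10, 0, 0.1)),
    cbind(stats::rnorm(10, 10, 0.1), stats::rnorm(10, 0, 0.1))))
  rownames(pts) <- paste0("p", 1:20)
  cl <- cluster_embedding(pts, eps = 1, min_samples = 3)
  expect_equal(length(unique(cl$cluster[cl$cluster > 0])), 2L)
  expect_equal(adjusted_rand(cl$cluster, rep(1:2, each = 10)), 1)

  # medoid optimality: exhaustive check over members in every cluster
  dm <- as.matrix(stats::dist(pts))
  for (k in unique(cl$cluster[cl$cluster > 0])) {
    members <- which(cl$cluster == k)
    avg <- vapply(members, function(i) mean(dm[i, setdiff(members, i)]),
                  numeric(1))
    best <- members[avg == min(avg)]
    med <- cl$medoids$label[cl$medoids$cluster == k]
    expect_true(which(cl$labels == med) %in% best)
  }

  # collinear triple: middle point is the medoid
  tri <- cbind(c(0, 1, 2), c(0, 0, 0))
  rownames(tri) <- c("lo", "mid", "hi")
  cl3 <- cluster_embedding(tri, eps = 1.5, min_samples = 2)
  expect_equal(cl3$medoids$label, "mid")

  # identical points: one cluster, tie broken by label order
  same <- matrix(1, 5, 2)
  rownames(same) <- paste0("s", 1:5)
  cls <- cluster_embedding(same, eps = 0.5, min_samples = 3)
  expect_equal(unique(cls$cluster), 1L)
  expect_equal(cls$medoids$label, "s1")

  expect_error(cluster_embedding(pts, eps = -1, min_samples = 3), "eps")
})

test_that("source selection is deterministic and recovers a planted center", {
  coll <- planted_collection(3, 5, 3, seed = 77L, size = 128L)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  sel1 <- select_optimal_sources(coll$sprites, seed = 77L, out = f1)
  sel2 <- select_optimal_sources(coll$sprites, seed = 77L, out = f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_s3_class(tidy(sel1), "tbl_df")
  expect_equal(nrow(tidy(sel1)), 15L)
  expect_s3_class(autoplot(sel1), "ggplot")
  g <- glance(sel1)
  expect_equal(g$n, 15L)

  # a single cohesive group yields exactly one recommendation
  one <- planted_collection(1, 5, 3, seed = 5L, size = 128L)
  sel_one <- select_optimal_sources(one$sprites, seed = 5L)
  expect_equal(nrow(sel_one$recommendations), 1L)
})
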