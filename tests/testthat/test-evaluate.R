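box <- function(image, x, y, w, h, score = NA_real_) {
  tibble::tibble(image = image, x_min = x, y_min = y, w = w, h = h,
                 score = score)
}

# Exhaustive matching oracle: tries every assignment of predictions to
# truth boxes (or none), keeps assignments feasible under the IoU
# threshold and one-truth-per-prediction, and maximizes TP count with
# score-priority tie-breaking (higher-scored predictions matched first).
match_oracle <- function(pred, truth, iou = 0.5) {
  n <- nrow(pred)
  iou_mat <- outer(seq_len(n), seq_len(nrow(truth)), Vectorize(function(i, j) {
    if (pred$image[i] != truth$image[j]) return(0)
    phenosynth:::box_iou(pred$x_min[i], pred$y_min[i], pred$w[i], pred$h[i],
                         truth$x_min[j], truth$y_min[j], truth$w[j],
                         truth$h[j])
  }))
  best <- NULL
  best_key <- c(-1, -Inf)
  assignments <- expand.grid(rep(list(0:nrow(truth)), n))
  for (r in seq_len(nrow(assignments))) {
    a <- as.integer(assignments[r, ])
    used <- a[a > 0]
    if (anyDuplicated(used)) next
    ok <- all(vapply(seq_len(n), function(i) {
      a[i] == 0 || iou_mat[i, a[i]] >= iou
    }, logical(1)))
    if (!ok) next
    key <- c(sum(a > 0), sum(pred$score[a > 0]))
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && key[2] > best_key[2])) {
      best <- a > 0
      best_key <- key
    }
  }
  best
}

test_that("greedy matching follows the single-match detection convention", {
  truth <- box("a", 10, 10, 20, 20)[, 1:5]
  exact <- box("a", 10, 10, 20, 20, 0.9)
  m <- match_detections(exact, truth)
  expect_true(m$tp)
  expect_equal(m$iou, 1)

  two <- dplyr::bind_rows(box("a", 10, 10, 20, 20, 0.9),
                          box("a", 11, 11, 20, 20, 0.7))
  m2 <- match_detections(two, truth)
  expect_identical(m2$tp, c(TRUE, FALSE))

  # hand-built 5-box scenario vs the exhaustive oracle
  truth5 <- dplyr::bind_rows(
    box("a", 0, 0, 20, 20), box("a", 50, 0, 20, 20),
    box("a", 100, 0, 20, 20), box("b", 0, 0, 30, 30))[, 1:5]
  pred5 <- dplyr::bind_rows(
    box("a", 2, 1, 20, 20, 0.95),   # matches truth 1
    box("a", 3, 2, 20, 20, 0.80),   # second claim on truth 1 -> FP
    box("a", 51, 0, 20, 22, 0.90),  # matches truth 2
    box("a", 200, 0, 20, 20, 0.85), # far from all -> FP
    box("b", 2, 2, 30, 30, 0.70))   # matches truth 4
  m5 <- match_detections(pred5, truth5)
  expect_identical(m5$tp, match_oracle(pred5, truth5))
})

test_that("AP matches a hand-computed precision envelope and its bounds", {
  truth <- dplyr::bind_rows(lapply(seq(0, 400, by = 100), function(x)
    box("a", x, 0, 20, 20)))[, 1:5]
  # six ranked predictions with TP pattern T F T T F T
  pred <- dplyr::bind_rows(
    box("a", 0, 0, 20, 20, 0.95),
    box("a", 0, 60, 20, 20, 0.90),
    box("a", 100, 0, 20, 20, 0.85),
    box("a", 200, 0, 20, 20, 0.80),
    box("a", 200, 60, 20, 20, 0.75),
    box("a", 300, 0, 20, 20, 0.70))
  pr <- pr_curve_and_ap(pred, truth)
  expect_equal(pr$curve$precision, c(1, 1/2, 2/3, 3/4, 3/5, 4/6))
  expect_equal(pr$curve$recall, c(0.2, 0.2, 0.4, 0.6, 0.6, 0.8))
  # hand-computed all-points envelope area:
  # env = (1, .75, .75, .75, 2/3, 2/3); AP = .2*1 + .2*.75 + .2*.75 + .2*2/3
  expect_equal(pr$ap, 0.2 * 1 + 0.2 * 0.75 + 0.2 * 0.75 + 0.2 * (2 / 3),
               tolerance = 1e-12)

  perfect <- dplyr::mutate(truth, score = seq(0.9, 0.5, length.out = 5))
  expect_equal(pr_curve_and_ap(perfect, truth)$ap, 1)

  allfp <- dplyr::bind_rows(box("a", 900, 900, 10, 10, 0.9),
                            box("a", 800, 800, 10, 10, 0.8))
  expect_equal(pr_curve_and_ap(allfp, truth)$ap, 0)
  expect_equal(pr_curve_and_ap(truth[0, ], truth)$ap, 0)
})

test_that("AP is non-increasing when false positives are added", {
  truth <- random_truth(6, 3, 8L)
  pred <- mock_detector(truth, score_high = 0.8, score_low = 0.3,
                        fp_rate = 0.2, miss_rate = 0.1, jitter_px = 2,
                        score_sd = 0.08, seed = 8L)
  ap0 <- pr_curve_and_ap(pred, truth)$ap
  expect_gte(ap0, 0); expect_lte(ap0, 1)
  for (s in c(0.1, 0.5, 0.95)) {
    extra <- dplyr::bind_rows(pred, box("img001", 900, 900, 15, 15, s))
    expect_lte(pr_curve_and_ap(extra, truth)$ap, ap0 + 1e-12)
  }
})

test_that("the balance point minimizes |P - R| with recall tie-breaking", {
  expect_equal(balance_point(c(0.95, 0.88, 0.70), c(0.5, 0.88, 0.99)),
               c(precision = 0.88, recall = 0.88))
  # no exact crossing: exhaustive scan oracle
  p <- c(1, 0.9, 0.8, 0.7, 0.6)
  r <- c(0.1, 0.3, 0.45, 0.68, 0.72)
  d <- abs(p - r)
  idx <- which(d == min(d))
  idx <- idx[which.max(r[idx])]
  expect_equal(balance_point(p, r),
               c(precision = p[idx], recall = r[idx]))
  # tie toward higher recall
  expect_equal(balance_point(c(0.8, 0.6), c(0.6, 0.8))[["recall"]], 0.8)
  expect_equal(balance_point(0.7, 0.4), c(precision = 0.7, recall = 0.4))
})
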