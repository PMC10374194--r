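#' Simulate detections from ground-truth boxes
#'
#' Test stand-in for a trained object detector: every ground-truth box not
#' dropped by `miss_rate` is re-emitted with jittered geometry and a
#' confidence score near `score_high`; additional false boxes (Poisson count
#' with mean `fp_rate` per truth box) are emitted with scores near
#' `score_low`.  Fully deterministic in `seed`.  The output keeps a
#' `matched_truth` bookkeeping column so tests can compute the precision of
#' any retained subset without re-matching.
#'
#' @param truth Tibble of ground-truth boxes with columns `image`, `x_min`,
#'   `y_min`, `w`, `h` (0-based pixel units).
#' @param score_high,score_low Mean confidence of true and false detections
#'   (`score_low < score_high`).
#' @param fp_rate Expected false boxes per truth box (>= 0).
#' @param miss_rate Probability that a truth box is not detected, in \[0, 1\].
#' @param jitter_px Standard deviation of the geometric jitter in pixels
#'   (0 reproduces truth geometry exactly).
#' @param score_sd Standard deviation of the confidence noise (scores are
#'   clipped to \[0.01, 0.99\]; 0 gives exact score levels).
#' @param seed Integer seed.
#' @return A tibble of scored boxes: `image`, `x_min`, `y_min`, `w`, `h`,
#'   `score`, `category`, `matched_truth`.
#' @export
mock_detector <- function(truth, score_high = 0.9, score_low = 0.2,
                          fp_rate = 0, miss_rate = 0, jitter_px = 0,
                          score_sd = 0.05, seed = 1L) {
  stopifnot(fp_rate >= 0, miss_rate >= 0, miss_rate <= 1,
            score_low < score_high)
  need <- c("image", "x_min", "y_min", "w", "h")
  stopifnot(all(need %in% names(truth)))
  n <- nrow(truth)

  with_seed(derive_seed(seed, 41L), {
    keep <- stats::runif(n) >= miss_rate
    tp <- truth[keep, need]
    m <- nrow(tp)
    if (m > 0 && jitter_px > 0) {
      tp$x_min <- tp$x_min + stats::rnorm(m, sd = jitter_px)
      tp$y_min <- tp$y_min + stats::rnorm(m, sd = jitter_px)
      tp$w <- pmax(2, tp$w * exp(stats::rnorm(m, sd = jitter_px / 20)))
      tp$h <- pmax(2, tp$h * exp(stats::rnorm(m, sd = jitter_px / 20)))
    }
    tp$score <- clamp(score_high + stats::rnorm(m, sd = score_sd), 0.01, 0.99)
    tp$matched_truth <- TRUE

    n_fp <- stats::rpois(1, fp_rate * n)
    if (n_fp > 0) {
      imgs <- unique(truth$image)
      fp <- tibble::tibble(
        image = sample(imgs, n_fp, replace = TRUE),
        x_min = stats::runif(n_fp, 0, 400),
        y_min = stats::runif(n_fp, 0, 300),
        w = stats::runif(n_fp, 10, 60),
        h = stats::runif(n_fp, 10, 60),
        score = clamp(score_low + stats::rnorm(n_fp, sd = score_sd), 0.01, 0.99),
        matched_truth = FALSE
      )
    } else {
      fp <- NULL
    }
    out <- dplyr::bind_rows(tp, fp)
    out$category <- "fruit"
    tibble::as_tibble(out)
  })
}

#' Build a pluggable mock detector contract
#'
#' Wraps [mock_detector()] in the detector contract consumed by
#' [self_learning_loop()]: a list with `infer(state, images, seed)`,
#' `train(state, images, labels)`, and an opaque `state`.  "Images" are
#' represented by their ground-truth annotation tables, which is what a
#' fixture-based detector can see.  Retraining on filtered pseudo-labels
#' emulates a detector sharpening under cleaner supervision: each
#' self-training round multiplies the false-positive rate by 0.3 and lowers
#' the false-positive score mean by 0.1 (floor 0.05).
#'
#' @param fp_rate,miss_rate,score_high,score_low,jitter_px,score_sd Initial
#'   detector characteristics, as in [mock_detector()].
#' @return A list of class `detector_contract`.
#' @export
make_mock_detector <- function(fp_rate = 0.3, miss_rate = 0,
                               score_high = 0.9, score_low = 0.2,
                               jitter_px = 0, score_sd = 0.05) {
  state0 <- list(fp_rate = fp_rate, miss_rate = miss_rate,
                 score_high = score_high, score_low = score_low,
                 jitter_px = jitter_px, score_sd = score_sd,
                 rounds_trained = 0L)
  structure(list(
    state = state0,
    infer = function(state, images, seed = 1L) {
      mock_detector(images,
                    score_high = state$score_high,
                    score_low = state$score_low,
                    fp_rate = state$fp_rate,
                    miss_rate = state$miss_rate,
                    jitter_px = state$jitter_px,
                    score_sd = state$score_sd,
                    seed = seed)
    },
    train = function(state, images, labels) {
      state$rounds_trained <- state$rounds_trained + 1L
      if (state$rounds_trained > 1L) {
        state$fp_rate <- state$fp_rate * 0.3
        state$score_low <- max(0.05, state$score_low - 0.1)
      }
      state
    }
  ), class = "detector_contract")
}
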