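#' Adaptive confidence-threshold selection (between-class variance)
#'
#' Scans a threshold grid `{step, 2*step, ..., 1 - step}` and, for each
#' candidate `t`, splits the scores into a low group (`score < t`) and a
#' high group (`score >= t`) and computes the Otsu between-class variance
#' `sigma^2(t) = w0 * w1 * (mu0 - mu1)^2`, with `w` the group weights and
#' `mu` the group means.  The chosen threshold maximizes the variance —
#' i.e. it best separates pseudo-labels into a low-quality and a
#' high-quality class; ties break toward the lower threshold.
#'
#' @param scores Numeric vector of confidence values in \[0, 1\] (>= 2).
#' @param grid_step Grid step in (0, 1), default 0.01.
#' @return A list of class `threshold_report`: `candidate_grid`,
#'   `variance_curve`, `count_curve` (high-group sizes, logged for
#'   inspection), `chosen`, `degenerate` flag.
#' @export
select_adaptive_threshold <- function(scores, grid_step = 0.01) {
  stopifnot(length(scores) >= 2L, grid_step > 0, grid_step < 1)
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)

  if (max(scores) == min(scores)) {
    return(structure(list(candidate_grid = grid,
                          variance_curve = rep(0, length(grid)),
                          count_curve = rep(NA_integer_, length(grid)),
                          chosen = grid[ceiling(length(grid) / 2)],
                          degenerate = TRUE),
                     class = "threshold_report"))
  }

  n <- length(scores)
  curve <- vapply(grid, function(t) {
    lo <- scores < t
    n0 <- sum(lo)
    if (n0 == 0L || n0 == n) return(0)
    w0 <- n0 / n
    w1 <- 1 - w0
    w0 * w1 * (mean(scores[lo]) - mean(scores[!lo]))^2
  }, numeric(1))
  counts <- vapply(grid, function(t) sum(scores >= t), integer(1))
  chosen <- grid[which.max(curve)]  # which.max returns the first (lowest) max

  structure(list(candidate_grid = grid, variance_curve = curve,
                 count_curve = counts, chosen = chosen, degenerate = FALSE),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> chosen = %.3g (sigma^2 = %.4g)%s\n",
              x$chosen, max(x$variance_curve),
              if (x$degenerate) " [degenerate: identical scores]" else ""))
  invisible(x)
}

#' @export
tidy.threshold_report <- function(x, ...) {
  tibble::tibble(threshold = x$candidate_grid,
                 between_class_variance = x$variance_curve,
                 n_high = x$count_curve,
                 chosen = x$candidate_grid == x$chosen)
}

#' @export
glance.threshold_report <- function(x, ...) {
  tibble::tibble(chosen = x$chosen,
                 max_variance = max(x$variance_curve),
                 degenerate = x$degenerate)
}

#' Plot a threshold-selection variance curve
#'
#' @param object A `threshold_report`.
#' @param ... Unused.
#' @return A ggplot of between-class variance vs candidate threshold.
#' @export
autoplot.threshold_report <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$threshold,
                                   y = .data$between_class_variance)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$chosen, linetype = 2,
                        color = "red") +
    ggplot2::labs(x = "confidence threshold",
                  y = "between-class variance",
                  title = "Adaptive pseudo-label threshold") +
    ggplot2::theme_minimal()
}

#' Filter pseudo-labels by confidence
#'
#' Keeps the boxes with `score >= threshold`, preserving order.
#'
#' @param boxes Tibble of scored boxes (needs a `score` column).
#' @param threshold Numeric threshold.
#' @return The high-quality subset of `boxes`.
#' @export
filter_pseudo_labels <- function(boxes, threshold) {
  stopifnot("score" %in% names(boxes))
  boxes[boxes$score >= threshold, , drop = FALSE]
}

#' Pseudo-label self-learning loop
#'
#' Round 0 trains the detector on the synthetic (auto-labeled) set.  Each
#' round then: infers on the unlabeled target images, selects the adaptive
#' confidence threshold from the pooled score distribution of that round's
#' detections, keeps the boxes above it as high-quality pseudo-labels, and
#' retrains the detector on them.  The threshold is re-selected every round
#' (dynamic adjustment), and per-round counts and thresholds are logged.
#'
#' @param detector A detector contract (e.g. [make_mock_detector()]): list
#'   with `infer(state, images, seed)`, `train(state, images, labels)`, and
#'   `state`.
#' @param synthetic Training annotations for round 0 (tibble of boxes).
#' @param target Unlabeled target images; for the mock detector, their
#'   ground-truth annotation table.
#' @param rounds Number of infer/filter/retrain rounds (>= 1), default 3.
#' @param grid_step Threshold grid step, default 0.01.
#' @param seed Integer seed.
#' @return A list of class `self_learning_result` with `labels` (last
#'   round's retained pseudo-labels), `report` (tibble: round, n_detections,
#'   threshold, n_retained), `thresholds` (list of `threshold_report`),
#'   `round_labels` (per-round retained label tibbles), `halted` flag.
#' @export
self_learning_loop <- function(detector, synthetic, target, rounds = 3L,
                               grid_step = 0.01, seed = 1L) {
  stopifnot(rounds >= 1L, is.list(detector),
            is.function(detector$infer), is.function(detector$train))
  state <- detector$train(detector$state, synthetic, synthetic)

  report <- list()
  thresholds <- list()
  round_labels <- list()
  labels <- NULL
  halted <- FALSE
  for (r in seq_len(rounds) - 1L) {
    preds <- detector$infer(state, target, seed = derive_seed(seed, 95L, r))
    if (nrow(preds) < 2L) {
      halted <- TRUE
      report[[length(report) + 1L]] <- tibble::tibble(
        round = r, n_detections = nrow(preds), threshold = NA_real_,
        n_retained = 0L)
      warning(sprintf("Round %d: too few detections; loop halted.", r),
              call. = FALSE)
      break
    }
    th <- select_adaptive_threshold(preds$score, grid_step)
    kept <- filter_pseudo_labels(preds, th$chosen)
    thresholds[[length(thresholds) + 1L]] <- th
    report[[length(report) + 1L]] <- tibble::tibble(
      round = r, n_detections = nrow(preds), threshold = th$chosen,
      n_retained = nrow(kept))
    if (nrow(kept) == 0L) {
      halted <- TRUE
      warning(sprintf("Round %d: empty filtered set; loop halted.", r),
              call. = FALSE)
      break
    }
    labels <- kept
    round_labels[[length(round_labels) + 1L]] <- kept
    state <- detector$train(state, target, kept)
  }
  structure(list(labels = labels, report = dplyr::bind_rows(report),
                 thresholds = thresholds, round_labels = round_labels,
                 halted = halted, final_state = state),
            class = "self_learning_result")
}

#' @export
print.self_learning_result <- function(x, ...) {
  cat("<self_learning_result>\n")
  print(x$report)
  invisible(x)
}

#' @export
tidy.self_learning_result <- function(x, ...) x$report

#' @export
glance.self_learning_result <- function(x, ...) {
  tibble::tibble(rounds = nrow(x$report),
                 final_threshold = utils::tail(x$report$threshold, 1),
                 final_retained = utils::tail(x$report$n_retained, 1),
                 halted = x$halted)
}
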