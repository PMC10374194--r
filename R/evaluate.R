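box_iou <- function(x1, y1, w1, h1, x2, y2, w2, h2) {
  ix <- pmax(0, pmin(x1 + w1, x2 + w2) - pmax(x1, x2))
  iy <- pmax(0, pmin(y1 + h1, y2 + h2) - pmax(y1, y2))
  inter <- ix * iy
  inter / (w1 * h1 + w2 * h2 - inter)
}

#' Match detections to ground truth (greedy, score-descending)
#'
#' Standard detection matching: predictions are visited in descending score
#' order; a prediction is a true positive if its IoU with a not-yet-matched
#' ground-truth box in the same image reaches `iou_threshold` (it consumes
#' the best such box), otherwise a false positive.  Each truth box is
#' matched at most once.
#'
#' @param predictions Tibble with `image`, `x_min`, `y_min`, `w`, `h`,
#'   `score`.
#' @param ground_truth Tibble with `image`, `x_min`, `y_min`, `w`, `h`.
#' @param iou_threshold IoU threshold, default 0.5.
#' @return `predictions` (original order) with logical column `tp` and
#'   numeric column `iou`.
#' @export
match_detections <- function(predictions, ground_truth, iou_threshold = 0.5) {
  need <- c("image", "x_min", "y_min", "w", "h")
  stopifnot(all(c(need, "score") %in% names(predictions)),
            all(need %in% names(ground_truth)))
  n <- nrow(predictions)
  tp <- logical(n)
  iou_out <- numeric(n)
  if (n == 0L) {
    return(dplyr::mutate(predictions, tp = logical(0), iou = numeric(0)))
  }
  ord <- order(-predictions$score)
  used <- logical(nrow(ground_truth))
  for (i in ord) {
    img <- predictions$image[i]
    cand <- which(ground_truth$image == img & !used)
    if (!length(cand)) next
    ious <- box_iou(predictions$x_min[i], predictions$y_min[i],
                    predictions$w[i], predictions$h[i],
                    ground_truth$x_min[cand], ground_truth$y_min[cand],
                    ground_truth$w[cand], ground_truth$h[cand])
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      iou_out[i] <- ious[j]
      used[cand[j]] <- TRUE
    }
  }
  dplyr::mutate(predictions, tp = tp, iou = iou_out)
}

#' Precision-recall curve and average precision
#'
#' Sweeps the score threshold over the ranked predictions, computes
#' precision and recall at each rank, and integrates the precision
#' envelope over recall (all-points interpolation) to obtain the average
#' precision for the single fruit class.
#'
#' @inheritParams match_detections
#' @return A list of class `pr_result` with `curve` (tibble: `score`,
#'   `precision`, `recall`) and `ap`.
#' @export
pr_curve_and_ap <- function(predictions, ground_truth, iou_threshold = 0.5) {
  stopifnot(nrow(ground_truth) >= 1L)
  if (nrow(predictions) == 0L) {
    return(structure(list(curve = tibble::tibble(score = numeric(),
                                                 precision = numeric(),
                                                 recall = numeric()),
                          ap = 0), class = "pr_result"))
  }
  m <- match_detections(predictions, ground_truth, iou_threshold)
  ord <- order(-m$score)
  tp <- cumsum(m$tp[ord])
  fp <- cumsum(!m$tp[ord])
  precision <- tp / (tp + fp)
  recall <- tp / nrow(ground_truth)

  env <- rev(cummax(rev(precision)))
  ap <- sum(diff(c(0, recall)) * env)

  structure(list(curve = tibble::tibble(score = m$score[ord],
                                        precision = precision,
                                        recall = recall),
                 ap = ap),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  bp <- if (nrow(x$curve)) balance_point(x$curve$precision, x$curve$recall)
        else c(precision = NA, recall = NA)
  cat(sprintf("<pr_result> AP = %.4f; balance point P = %.4f, R = %.4f\n",
              x$ap, bp[["precision"]], bp[["recall"]]))
  invisible(x)
}

#' @export
tidy.pr_result <- function(x, ...) x$curve

#' @export
glance.pr_result <- function(x, ...) {
  bp <- if (nrow(x$curve)) balance_point(x$curve$precision, x$curve$recall)
        else c(precision = NA_real_, recall = NA_real_)
  tibble::tibble(ap = x$ap, precision_balance = bp[["precision"]],
                 recall_balance = bp[["recall"]])
}

#' Plot a precision-recall curve
#'
#' @param object A `pr_result`.
#' @param ... Unused.
#' @return A ggplot of precision vs recall with the balance point marked.
#' @export
autoplot.pr_result <- function(object, ...) {
  bp <- balance_point(object$curve$precision, object$curve$recall)
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = bp[["recall"]], y = bp[["precision"]],
                      color = "red", size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("PR curve (AP = %.3f)", object$ap)) +
    ggplot2::theme_minimal()
}

#' Balance point of a precision-recall curve
#'
#' Returns the curve point where precision and recall are closest (the
#' balance point at which both metrics are customarily reported); ties
#' break toward higher recall.
#'
#' @param precision,recall Numeric vectors of equal positive length.
#' @return Named numeric `c(precision = , recall = )`.
#' @export
balance_point <- function(precision, recall) {
  stopifnot(length(precision) == length(recall), length(precision) >= 1L)
  d <- abs(precision - recall)
  best <- which(d == min(d))
  i <- best[which.max(recall[best])]
  c(precision = precision[i], recall = recall[i])
}
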