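#' CIELAB interval color descriptor of a sprite
#'
#' Converts the foreground pixels (alpha >= 0.5) from sRGB to CIELAB (D65,
#' 2 degree observer) and summarizes each channel by fixed-width intervals:
#' the fraction of pixels per interval `Rate_i = N_i / N_all`, the interval
#' means `Mean_i`, the weighted channel mean `sum_i Rate_i * Mean_i`, and
#' the matching weighted between-interval variance.  The default interval
#' width is 20 units per channel (L over \[0, 100\], a and b over
#' \[-128, 128\)).
#'
#' @param sprite A `phenosynth_sprite` with nonempty foreground.
#' @param bin_width Interval width in CIELAB units, default 20.
#' @return A list of class `color_descriptor` with `lab_means`, `lab_vars`
#'   (named length-3 numerics), `bin_width`, and `intervals`, a tibble with
#'   columns `channel`, `bin`, `rate`, `mean`.
#' @export
color_descriptor <- function(sprite, bin_width = 20) {
  stopifnot(inherits(sprite, "phenosynth_sprite"), bin_width > 0)
  mask <- sprite_mask(sprite)
  if (!any(mask)) stop("Sprite has an empty foreground.", call. = FALSE)

  rgb <- cbind(sprite$pixels[, , 1][mask],
               sprite$pixels[, , 2][mask],
               sprite$pixels[, , 3][mask])
  lab <- srgb_to_lab(rgb)
  colnames(lab) <- c("L", "a", "b")

  origin <- c(L = 0, a = -128, b = -128)
  rows <- list()
  means <- vars <- stats::setNames(numeric(3), c("L", "a", "b"))
  for (ch in c("L", "a", "b")) {
    v <- lab[, ch]
    bin <- floor((v - origin[[ch]]) / bin_width)
    agg <- tapply(v, bin, function(z) c(n = length(z), m = mean(z)))
    n_i <- vapply(agg, `[[`, numeric(1), "n")
    m_i <- vapply(agg, `[[`, numeric(1), "m")
    rate <- n_i / length(v)
    wmean <- sum(rate * m_i)
    means[[ch]] <- wmean
    vars[[ch]] <- sum(rate * (m_i - wmean)^2)
    rows[[ch]] <- tibble::tibble(channel = ch,
                                 bin = as.integer(names(agg)),
                                 rate = unname(rate), mean = unname(m_i))
  }
  structure(list(lab_means = means, lab_vars = vars,
                 bin_width = bin_width,
                 intervals = dplyr::bind_rows(rows)),
            class = "color_descriptor")
}

#' @export
print.color_descriptor <- function(x, ...) {
  cat(sprintf("<color_descriptor> Lab means (%.2f, %.2f, %.2f), bin width %g\n",
              x$lab_means[1], x$lab_means[2], x$lab_means[3], x$bin_width))
  invisible(x)
}

#' Color dissimilarity between two descriptors
#'
#' Euclidean (L2) distance between the interval-weighted CIELAB channel
#' means of the two descriptors.
#'
#' @param c1,c2 `color_descriptor` objects with identical `bin_width`.
#' @return A nonnegative distance (CIELAB Delta-E between the mean colors).
#' @export
color_distance <- function(c1, c2) {
  stopifnot(inherits(c1, "color_descriptor"), inherits(c2, "color_descriptor"))
  if (c1$bin_width != c2$bin_width) {
    stop("Descriptors must share `bin_width`.", call. = FALSE)
  }
  sqrt(sum((c1$lab_means - c2$lab_means)^2))
}
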