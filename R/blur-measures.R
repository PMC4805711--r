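#' No-reference blur measures
#'
#' All three measures are oriented so that a *larger* score means a *blurrier*
#' image, which is what the recursive equalization stop rule
#' (`B(I) >= theta`) requires.
#'
#' * `"ma"` — Marziliano-style edge-width measure: ratio of the average
#'   vertical-edge width (distance between the local intensity extrema
#'   bracketing each edge pixel) to the average edge magnitude (absolute
#'   gray-value difference between those extrema). Long, weak edges score
#'   high.
#' * `"cr"` — Crete-style perceptual blur: neighbouring-pixel intensity
#'   variations of the image are compared with those of a 3x3-average
#'   low-pass filtered copy; if low-pass filtering barely reduces the
#'   variation the image was already blurred. Score in \[0, 1\].
#' * `"co"` — negated neighbour contrast: mean squared difference of
#'   horizontal and vertical neighbour pairs, negated so that blur (which
#'   destroys contrast) increases the score.
#'
#' @param image Numeric image matrix (0--255 scale).
#' @param measure One of `"ma"`, `"cr"`, `"co"`.
#' @return A single numeric score (larger = blurrier).
#' @seealso [compute_thresholds()], [equalize_blur()]
#' @export
blur_score <- function(image, measure = c("co", "ma", "cr")) {
  measure <- match.arg(measure)
  switch(measure,
    ma = measure_marziliano(image),
    cr = measure_crete(image),
    co = measure_contrast(image)
  )
}

# Signal an image on which a measure is undefined (constant image, no edges).
degenerate_input <- function(msg) {
  stop(structure(class = c("blurtex_degenerate", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @rdname blur_score
#' @export
measure_marziliano <- function(image) {
  image <- as_gray_image(image, min_dim = 3L)
  h <- nrow(image); w <- ncol(image)
  # vertical edges: horizontal Sobel derivative
  gx <- conv2_mirror(image, sobel_x())
  mx <- abs(gx)
  mmax <- max(mx)
  if (mmax <= 0) degenerate_input("no vertical edges detected (constant image)")
  edge <- mx > 0.1 * mmax
  widths <- numeric(0)
  mags <- numeric(0)
  for (r in seq_len(h)) {
    ecols <- which(edge[r, ])
    if (length(ecols) == 0L) next
    v <- image[r, ]
    ex <- row_extrema(v)            # sorted extremum positions, incl. 1 and w
    res <- bracket_extrema(ecols, ex, v)
    widths <- c(widths, res$width)
    mags <- c(mags, res$mag)
  }
  keep <- mags > 0
  if (!any(keep)) degenerate_input("no measurable edges (zero-magnitude extrema)")
  mean(widths[keep]) / mean(mags[keep])
}

# Local intensity extrema of a row, with plateau runs collapsed: a pixel is an
# extremum when the nearest non-zero differences on its two sides have
# opposite (or one-sided zero) signs; row ends always count. Returns sorted
# unique positions.
row_extrema <- function(v) {
  n <- length(v)
  d <- sign(diff(v))
  # forward fill (sign of last non-zero diff at or before each gap)
  lastnz <- function(s) {
    idx <- seq_along(s)
    idx[s == 0] <- 0L
    idx <- cummax(idx)
    out <- numeric(length(s))
    out[idx > 0] <- s[idx[idx > 0]]
    out
  }
  bl <- lastnz(d)          # bl[i]: effective sign of the diff left of pixel i+1
  fr <- rev(lastnz(rev(d)))  # fr[i]: effective sign of the diff right of pixel i
  mid <- integer(0)
  if (n > 2L) {
    i <- 2:(n - 1L)
    left <- bl[i - 1L]
    right <- fr[i]
    turning <- (left * right < 0) | (xor(left == 0, right == 0))
    mid <- i[turning]
  }
  sort(unique(c(1L, mid, n)))
}

# For each edge column, the bracketing extrema pair; when the edge pixel is
# itself an extremum, the side with the larger intensity difference wins
# (ties go right).
bracket_extrema <- function(ecols, ex, v) {
  n <- length(v)
  li <- findInterval(ecols, ex)                 # last extremum index <= p
  left <- ex[pmax(li, 1L)]
  ri <- findInterval(ecols - 1L, ex) + 1L       # first extremum index >= p
  right <- ex[pmin(ri, length(ex))]
  width <- right - left
  mag <- abs(v[right] - v[left])
  onext <- width == 0L                          # p is an extremum itself
  if (any(onext)) {
    p <- ecols[onext]
    ip <- findInterval(p, ex)
    lprev <- ex[pmax(ip - 1L, 1L)]
    rnext <- ex[pmin(ip + 1L, length(ex))]
    dl <- abs(v[p] - v[lprev])
    dr <- abs(v[rnext] - v[p])
    useright <- dr >= dl
    width[onext] <- ifelse(useright, rnext - p, p - lprev)
    mag[onext] <- ifelse(useright, dr, dl)
  }
  list(width = width, mag = mag)
}

#' @rdname blur_score
#' @export
measure_crete <- function(image) {
  image <- as_gray_image(image, min_dim = 3L)
  blur <- convolve_image(image, matrix(1 / 9, 3L, 3L))
  dh_o <- abs(image[, -1, drop = FALSE] - image[, -ncol(image), drop = FALSE])
  dv_o <- abs(image[-1, , drop = FALSE] - image[-nrow(image), , drop = FALSE])
  dh_b <- abs(blur[, -1, drop = FALSE] - blur[, -ncol(blur), drop = FALSE])
  dv_b <- abs(blur[-1, , drop = FALSE] - blur[-nrow(blur), , drop = FALSE])
  s_h <- sum(dh_o); s_v <- sum(dv_o)
  if (s_h + s_v <= 0) degenerate_input("constant image: no intensity variation")
  per_dir <- function(s_o, d_o, d_b) {
    if (s_o <= 0) return(1)   # no variation in this direction: fully blurred
    v <- sum(pmax(0, d_o - d_b))
    (s_o - v) / s_o
  }
  max(per_dir(s_h, dh_o, dh_b), per_dir(s_v, dv_o, dv_b))
}

#' @rdname blur_score
#' @export
measure_contrast <- function(image) {
  image <- as_gray_image(image, min_dim = 2L)
  dh <- image[, -1, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  dv <- image[-1, , drop = FALSE] - image[-nrow(image), , drop = FALSE]
  n_pairs <- length(dh) + length(dv)
  -(sum(dh^2) + sum(dv^2)) / n_pairs
}

#' Decile blur thresholds from a set of scores
#'
#' The candidate equalization thresholds are the first to the tenth
#' ten-quantile of the blur scores of a reference image set (the undegraded
#' evaluation set in the reproduction protocol): at the k-th threshold,
#' 10k percent of the reference images are less blurry. Quantiles use the
#' inclusive linear-interpolation convention (R type 7), so the tenth
#' threshold is the maximum score.
#'
#' @param scores Numeric vector of blur scores (>= 10 values), all from the
#'   same measure.
#' @param measure The measure id the scores came from (`"ma"`, `"cr"`, `"co"`).
#' @return A `threshold_set`: list with `thetas` (10 non-decreasing values),
#'   `measure`, and `n` (number of source scores).
#' @export
compute_thresholds <- function(scores, measure = c("co", "ma", "cr")) {
  measure <- match.arg(measure)
  scores <- as.numeric(scores)
  if (length(scores) < 10L) stop("need at least 10 scores", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  thetas <- unname(stats::quantile(scores, probs = (1:10) / 10, type = 7))
  structure(list(thetas = thetas, measure = measure, n = length(scores)),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> measure=%s, n=%d\n", x$measure, x$n))
  print(stats::setNames(signif(x$thetas, 6), paste0("q", 1:10, "0")))
  invisible(x)
}

#' Tidy a threshold set into a tibble
#'
#' @param x A `threshold_set`.
#' @param ... Unused.
#' @return A tibble with columns `quantile` (0.1 ... 1.0), `theta`, `measure`.
#' @importFrom generics tidy
#' @method tidy threshold_set
#' @export
tidy.threshold_set <- function(x, ...) {
  tibble::tibble(quantile = (1:10) / 10, theta = x$thetas, measure = x$measure)
}

#' Blur scores for a dataset, as a tibble
#'
#' @param data A dataset tibble with a list-column `image` (see
#'   [generate_texture_dataset()]), or a bare list of image matrices.
#' @param measure Blur measure id.
#' @param on_degenerate What to do when the measure is undefined on an image:
#'   `"error"` (default) or `"na"`.
#' @return The input tibble with a numeric `score` column appended (bare
#'   lists are wrapped in a tibble first).
#' @export
score_dataset <- function(data, measure = c("co", "ma", "cr"),
                          on_degenerate = c("error", "na")) {
  measure <- match.arg(measure)
  on_degenerate <- match.arg(on_degenerate)
  if (!inherits(data, "data.frame")) data <- tibble::tibble(image = data)
  stopifnot(!is.null(data$image))
  one <- function(img) {
    if (on_degenerate == "na") {
      tryCatch(blur_score(img, measure),
               blurtex_degenerate = function(e) NA_real_)
    } else {
      blur_score(img, measure)
    }
  }
  dplyr::mutate(data, score = purrr::map_dbl(.data$image, one))
}
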