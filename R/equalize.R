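#' Equalize the blur level of an image
#'
#' Recursively convolves an image with a small Gaussian step kernel until the
#' chosen no-reference blur measure reaches the threshold `theta`:
#' the image is returned unchanged if it is already at least as blurry as the
#' target, otherwise one convolution step is applied and the test repeated.
#' Because a chain of Gaussian convolutions is itself a Gaussian convolution,
#' all images processed this way end up at (approximately) the same blur
#' level, which is what makes downstream texture descriptors blur-invariant.
#'
#' The returned iteration count is minimal: it is the smallest `n >= 0` such
#' that the measure of the `n`-step image reaches `theta`.
#'
#' @param image Numeric image matrix (0--255 scale, real-valued; no
#'   re-quantization happens between iterations).
#' @param theta Target score in the oriented space of `measure`
#'   (larger = blurrier).
#' @param measure Blur measure id (`"co"`, `"ma"`, `"cr"`), see [blur_score()].
#' @param step_sigma,step_size Standard deviation and side of the Gaussian
#'   step kernel; defaults 1 and 3. A larger step trades precision of the
#'   reached level for fewer iterations.
#' @param max_iter Iteration cap; images that cannot reach `theta` (e.g.
#'   near-constant ones) are returned after `max_iter` steps with
#'   `converged = FALSE` rather than looping forever.
#' @return A list of class `equalization_result`: `image`, `iterations`,
#'   `final_score`, `converged`, `measure`, `theta`.
#' @export
equalize_blur <- function(image, theta, measure = c("co", "ma", "cr"),
                          step_sigma = 1, step_size = 3L, max_iter = 64L) {
  measure <- match.arg(measure)
  image <- as_gray_image(image, min_dim = 16L)
  stopifnot(length(theta) == 1L, is.finite(theta), step_sigma > 0, max_iter >= 1)
  kern <- gaussian_kernel(step_sigma, step_size)
  cur <- image
  score <- blur_score(cur, measure)
  iter <- 0L
  while (score < theta && iter < max_iter) {
    cur <- conv2_mirror(cur, kern)
    score <- blur_score(cur, measure)
    iter <- iter + 1L
  }
  structure(list(image = cur, iterations = iter, final_score = score,
                 converged = score >= theta, measure = measure, theta = theta),
            class = "equalization_result")
}

#' @export
print.equalization_result <- function(x, ...) {
  cat(sprintf(
    "<equalization_result> %dx%d image, measure=%s, theta=%g\n  iterations=%d, final_score=%g, converged=%s\n",
    nrow(x$image), ncol(x$image), x$measure, x$theta,
    x$iterations, x$final_score, x$converged))
  invisible(x)
}

#' Glance at an equalization result
#'
#' @param x An `equalization_result`.
#' @param ... Unused.
#' @return One-row tibble with `iterations`, `final_score`, `converged`,
#'   `measure`, `theta`.
#' @method glance equalization_result
#' @export
glance.equalization_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, final_score = x$final_score,
                 converged = x$converged, measure = x$measure, theta = x$theta)
}

#' Equalize every image of a dataset to a common blur level
#'
#' Element-wise [equalize_blur()] with shared parameters. Images on which the
#' blur measure is undefined (degenerate, e.g. constant) are reported in the
#' result rather than aborting the batch.
#'
#' @inheritParams equalize_blur
#' @param data Dataset tibble with list-column `image`, or bare list of
#'   image matrices.
#' @return The dataset tibble with `image` replaced by its equalized version
#'   and columns `iterations`, `final_score`, `converged`, `degenerate`
#'   appended.
#' @export
equalize_dataset <- function(data, theta, measure = c("co", "ma", "cr"),
                             step_sigma = 1, step_size = 3L, max_iter = 64L) {
  measure <- match.arg(measure)
  if (!inherits(data, "data.frame")) data <- tibble::tibble(image = data)
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  res <- purrr::map(data$image, function(img) {
    tryCatch(
      equalize_blur(img, theta, measure, step_sigma, step_size, max_iter),
      blurtex_degenerate = function(e) e
    )
  })
  degen <- purrr::map_lgl(res, inherits, "blurtex_degenerate")
  out <- data
  out$image <- purrr::map2(res, data$image, function(r, orig) {
    if (inherits(r, "blurtex_degenerate")) orig else r$image
  })
  out$iterations <- purrr::map_int(res, function(r) {
    if (inherits(r, "blurtex_degenerate")) NA_integer_ else r$iterations
  })
  out$final_score <- purrr::map_dbl(res, function(r) {
    if (inherits(r, "blurtex_degenerate")) NA_real_ else r$final_score
  })
  out$converged <- purrr::map_lgl(res, function(r) {
    if (inherits(r, "blurtex_degenerate")) FALSE else r$converged
  })
  out$degenerate <- degen
  out
}

# Equalize one image against several thresholds in one forward pass: the
# score trajectory is non-decreasing in the vast majority of steps, but
# minimality is preserved exactly because each threshold records the *first*
# step at which it is reached. Returns a list (one element per theta) of
# equalization_result objects. Internal engine behind the experiment grid.
equalize_trajectory <- function(image, thetas, measure,
                                step_sigma = 1, step_size = 3L, max_iter = 64L) {
  kern <- gaussian_kernel(step_sigma, step_size)
  n_t <- length(thetas)
  out <- vector("list", n_t)
  cur <- image
  score <- blur_score(cur, measure)
  iter <- 0L
  pending <- seq_len(n_t)
  fill <- function(idx, converged) {
    structure(list(image = cur, iterations = iter, final_score = score,
                   converged = converged, measure = measure,
                   theta = thetas[idx]),
              class = "equalization_result")
  }
  repeat {
    done <- pending[thetas[pending] <= score]
    for (idx in done) out[[idx]] <- fill(idx, TRUE)
    pending <- setdiff(pending, done)
    if (length(pending) == 0L || iter >= max_iter) break
    cur <- conv2_mirror(cur, kern)
    score <- blur_score(cur, measure)
    iter <- iter + 1L
  }
  for (idx in pending) out[[idx]] <- fill(idx, FALSE)
  out
}
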