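#' Validate and coerce a grayscale image
#'
#' Images are plain numeric matrices on the 0--255 intensity scale, stored as
#' reals throughout the pipeline. Multi-channel arrays (as returned by the PNG
#' and TIFF readers for colour input) are collapsed to a single luminance
#' channel with the ITU-R 601 weights.
#'
#' @param x A numeric matrix, or a 3-d array whose third dimension holds
#'   colour channels (1, 3 for RGB, or 4 for RGBA; alpha is dropped).
#' @param min_dim Minimum height and width required (operations that fit local
#'   windows need at least 16 pixels per side).
#' @return A numeric matrix with all values finite.
#' @export
as_gray_image <- function(x, min_dim = 1L) {
  if (is.array(x) && length(dim(x)) == 3L) {
    nc <- dim(x)[3L]
    if (nc >= 3L) {
      x <- 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      x <- x[, , 1L]
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a grayscale image must be a numeric matrix", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("image contains non-finite values", call. = FALSE)
  if (nrow(x) < min_dim || ncol(x) < min_dim) {
    stop(sprintf("image must be at least %d x %d", min_dim, min_dim), call. = FALSE)
  }
  x
}

#' Read a grayscale image from PNG, TIFF or PGM
#'
#' Colour inputs are converted to luminance (ITU-R 601). Intensities are
#' rescaled to the 0--255 range when the file stores them on \[0, 1\].
#'
#' @param path File path; format is chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.pgm`).
#' @return A numeric image matrix on the 0--255 scale.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = read_pgm(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  img <- as_gray_image(x)
  if (ext %in% c("png", "tif", "tiff")) img <- img * 255
  img
}

#' Write a grayscale image as an 8-bit PNG
#'
#' Values are clipped to \[0, 255\] and quantized with round-half-even only at
#' this point; the in-memory pipeline keeps real-valued intensities.
#'
#' @param image Numeric image matrix on the 0--255 scale.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path) {
  image <- as_gray_image(image)
  q <- round(pmin(pmax(image, 0), 255)) # round() is round-half-even in R
  png::writePNG(q / 255, path)
  invisible(path)
}

# Minimal PGM (P2 ascii / P5 binary, maxval <= 255) reader; returns a matrix
# on the file's own intensity scale (0..maxval, conventionally 0..255).
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PGM header", call. = FALSE)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else {
        tok <- paste0(tok, ch)
      }
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) stop("bad PGM dimensions", call. = FALSE)
  if (magic == "P5") {
    if (maxval > 255L) stop("16-bit PGM not supported", call. = FALSE)
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Truncated, renormalized 2-D Gaussian kernel
#'
#' @param sigma Positive standard deviation in pixels. Values below `1e-6`
#'   give a discrete delta kernel.
#' @param size Odd positive side length; the kernel is truncated to
#'   `size x size` and renormalized to sum 1.
#' @return A `size x size` numeric matrix summing to 1, with the maximum at
#'   the centre, plus attribute `sigma`.
#' @export
gaussian_kernel <- function(sigma, size) {
  if (length(size) != 1L || is.na(size) || size < 1 || size %% 2 == 0) {
    stop("kernel size must be a positive odd integer", call. = FALSE)
  }
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("sigma must be a nonnegative real", call. = FALSE)
  }
  size <- as.integer(size)
  half <- (size - 1L) %/% 2L
  d <- seq(-half, half)
  if (sigma < 1e-6) {
    w1 <- as.numeric(d == 0L)
  } else {
    w1 <- exp(-d^2 / (2 * sigma^2))
    w1 <- w1 / sum(w1)
  }
  k <- outer(w1, w1) # separable product; normalization carries over
  k <- k / sum(k)
  attr(k, "sigma") <- sigma
  k
}

# Whole-sample symmetric padding (the border pixel is repeated, scipy's
# "symmetric"); preserves the mean of constant borders exactly. Index folding
# by repeated reflection also covers pads wider than the image.
mirror_pad <- function(x, top, bottom = top, left = top, right = top) {
  fold <- function(n, pad_lo, pad_hi) {
    idx <- seq.int(1L - pad_lo, n + pad_hi)
    period <- 2L * n
    idx <- ((idx - 1L) %% period + period) %% period + 1L
    over <- idx > n
    idx[over] <- period - idx[over] + 1L
    idx
  }
  x[fold(nrow(x), top, bottom), fold(ncol(x), left, right), drop = FALSE]
}

#' 2-D convolution with symmetric (mirror) boundary padding
#'
#' Same-size linear convolution of an image with an odd-sized kernel. The
#' image border is extended by whole-sample symmetric reflection before the
#' sum, so constant images stay constant and a delta kernel reproduces the
#' input exactly. Works for real and complex kernels.
#'
#' @param image Numeric image matrix.
#' @param kernel Odd-sized kernel matrix (rows and columns both odd).
#' @return Matrix of the same size as `image`.
#' @export
convolve_image <- function(image, kernel) {
  image <- as_gray_image(image)
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh %% 2 == 0 || kw %% 2 == 0) stop("kernel sides must be odd", call. = FALSE)
  if (kh > nrow(image) || kw > ncol(image)) {
    stop("kernel larger than image", call. = FALSE)
  }
  conv2_mirror(image, kernel)
}

# Separable same-size convolution with mirror padding: 1-D kernel `w` (odd
# length) applied along columns then rows. Algebraically identical to
# conv2_mirror with outer(w, w) but O(k) instead of O(k^2) per pixel.
conv_sep_mirror <- function(image, w) {
  k <- length(w)
  half <- (k - 1L) %/% 2L
  h <- nrow(image); wd <- ncol(image)
  p <- mirror_pad(image, top = half, bottom = half, left = 0L, right = 0L)
  tmp <- matrix(0, h, wd)
  for (i in seq_len(k)) tmp <- tmp + w[i] * p[(k - i + 1L):(k - i + h), , drop = FALSE]
  p <- mirror_pad(tmp, top = 0L, bottom = 0L, left = half, right = half)
  out <- matrix(0, h, wd)
  for (j in seq_len(k)) out <- out + w[j] * p[, (k - j + 1L):(k - j + wd), drop = FALSE]
  out
}

# Core shift-and-add convolution (flip kernel = true convolution); `image`
# real, `kernel` real or complex. No validation: internal hot path.
conv2_mirror <- function(image, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  hh <- (kh - 1L) %/% 2L; hw <- (kw - 1L) %/% 2L
  p <- mirror_pad(image, top = hh, bottom = hh, left = hw, right = hw)
  h <- nrow(image); w <- ncol(image)
  out <- matrix(if (is.complex(kernel)) 0 + 0i else 0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      wgt <- kernel[i, j]
      if (wgt == 0) next
      # output(y,x) = sum_k K(k) * I(y - dy, x - dx); with dy = i - hh - 1
      out <- out + wgt * p[(kh - i + 1L):(kh - i + h), (kw - j + 1L):(kw - j + w)]
    }
  }
  out
}

#' Specify an image degradation
#'
#' @param kind One of `"gaussian"`, `"average"`, `"median"`, `"none"`.
#' @param sigma Gaussian standard deviation (gaussian kind); `0` is identity.
#' @param size Odd window side (average/median kinds); `1` is identity.
#' @return A `degradation_spec` list.
#' @export
degradation_spec <- function(kind = c("gaussian", "average", "median", "none"),
                             sigma = 0, size = 1L) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (length(sigma) != 1L || is.na(sigma) || sigma < 0) {
      stop("sigma must be a nonnegative real", call. = FALSE)
    }
  }
  if (kind %in% c("average", "median")) {
    if (length(size) != 1L || is.na(size) || size < 1 || size %% 2 == 0) {
      stop("filter size must be a positive odd integer", call. = FALSE)
    }
    size <- as.integer(size)
  }
  structure(list(kind = kind, sigma = sigma, size = size),
            class = "degradation_spec")
}

#' @export
format.degradation_spec <- function(x, ...) {
  switch(x$kind,
    gaussian = sprintf("gaussian(sigma=%g)", x$sigma),
    average  = sprintf("average(%dx%d)", x$size, x$size),
    median   = sprintf("median(%dx%d)", x$size, x$size),
    none     = "none")
}

#' @export
print.degradation_spec <- function(x, ...) {
  cat("<degradation_spec> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Apply a simulated degradation to an image
#'
#' Gaussian blur uses a truncated kernel of side `2*ceiling(3*sigma) + 1`
#' (under 0.3 percent of mass truncated, then renormalized); averaging is a
#' normalized box filter; the median filter takes the per-pixel window median
#' over a mirror-padded image. Identity-sized specs (`sigma = 0`, `size = 1`,
#' or `kind = "none"`) return the input bit-identically.
#'
#' @param image Numeric image matrix.
#' @param spec A [degradation_spec()].
#' @return Degraded image, same size.
#' @export
degrade <- function(image, spec) {
  stopifnot(inherits(spec, "degradation_spec"))
  image <- as_gray_image(image)
  switch(spec$kind,
    none = image,
    gaussian = {
      if (spec$sigma < 1e-6) return(image)
      size <- 2L * as.integer(ceiling(3 * spec$sigma)) + 1L
      half <- (size - 1L) %/% 2L
      w1 <- exp(-(-half:half)^2 / (2 * spec$sigma^2))
      conv_sep_mirror(image, w1 / sum(w1)) # separable form of the 2-D kernel
    },
    average = {
      if (spec$size == 1L) return(image)
      conv_sep_mirror(image, rep(1 / spec$size, spec$size))
    },
    median = {
      if (spec$size == 1L) return(image)
      median_filter(image, spec$size)
    }
  )
}

# Per-pixel window median with mirror padding.
median_filter <- function(image, size) {
  h <- nrow(image); w <- ncol(image)
  half <- (size - 1L) %/% 2L
  p <- mirror_pad(image, top = half)
  n <- size * size
  stack <- matrix(0, h * w, n)
  k <- 0L
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      k <- k + 1L
      stack[, k] <- p[(i):(i + h - 1L), (j):(j + w - 1L)]
    }
  }
  med <- apply(stack, 1L, stats::median)
  matrix(med, h, w)
}
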