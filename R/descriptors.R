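#' Texture descriptors
#'
#' Five classical texture feature extractors, each mapping a grayscale image
#' to a fixed-length numeric vector:
#'
#' * `mrlbp()` (length 118) — multi-resolution uniform local binary
#'   patterns: the 59-bin uniform-LBP histograms at radii 1 and 2 pixels
#'   (8 neighbours each), concatenated.
#' * `elbp()` (length 59) — edge-based LBP: uniform LBP (radius 1) applied
#'   to the gradient-magnitude image.
#' * `mfs()` (length 78) — multi-fractal spectrum: per-pixel local fractal
#'   dimensions under three density measures (intensity, gradient magnitude,
#'   absolute Laplacian), histogrammed and concatenated.
#' * `ecm()` (length 64) — edge co-occurrence matrix: co-occurrence of
#'   quantized gradient orientations at displacement (1,1) after magnitude
#'   masking.
#' * `lpq()` (length 256) — local phase quantization: 8-bit codes from the
#'   signs of four low-frequency short-term Fourier coefficients over a
#'   15x15 window; phase is insensitive to centrally symmetric blur.
#'
#' All histogram-type outputs are L1-normalized to sum 1 (MRLBP, being two
#' concatenated unit histograms, sums to 2).
#'
#' @param image Numeric image matrix (0--255 scale).
#' @name descriptors
NULL

# ---- uniform LBP ------------------------------------------------------------

# 256 -> 59 uniform-pattern lookup (codes with <= 2 circular bit transitions
# get their own bin, in increasing code order; all others share bin 59).
lbp_uniform_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codes <- 0:255
      bits <- t(sapply(codes, function(cd) as.integer(intToBits(cd))[1:8]))
      trans <- rowSums(abs(bits - bits[, c(2:8, 1)]))
      uni <- which(trans <= 2)            # 58 uniform codes
      m <- rep(59L, 256L)
      m[uni] <- seq_along(uni)
      tab <<- m
    }
    tab
  }
})

# Interpolated neighbour image for the valid interior at offset (dr, dc) from
# each pixel; m is the interior margin. Coordinates snapped to the grid when
# within 1e-9 to keep exact-integer offsets exact.
sample_offset <- function(image, dr, dc, m) {
  h <- nrow(image); w <- ncol(image)
  rows <- (m + 1):(h - m); cols <- (m + 1):(w - m)
  r0 <- floor(dr + 1e-9); c0 <- floor(dc + 1e-9)
  fr <- dr - r0; fc <- dc - c0
  if (abs(fr) < 1e-9) fr <- 0
  if (abs(fc) < 1e-9) fc <- 0
  sub <- function(ro, co) image[rows + ro, cols + co, drop = FALSE]
  out <- (1 - fr) * (1 - fc) * sub(r0, c0)
  if (fc > 0) out <- out + (1 - fr) * fc * sub(r0, c0 + 1)
  if (fr > 0) out <- out + fr * (1 - fc) * sub(r0 + 1, c0)
  if (fr > 0 && fc > 0) out <- out + fr * fc * sub(r0 + 1, c0 + 1)
  out
}

#' Uniform LBP histogram
#'
#' Circular 8-neighbour local binary patterns with bilinear interpolation;
#' only "uniform" patterns (at most 2 bitwise transitions) keep individual
#' bins, the rest share one. A neighbour ties with the centre as `>=`, so a
#' constant image maps every pixel to the all-ones pattern.
#'
#' @inheritParams descriptors
#' @param radius Circle radius in pixels (1 or 2).
#' @param neighbors Number of sampling points (fixed at 8).
#' @return Numeric vector of length 59 summing to 1.
#' @export
lbp_uniform_hist <- function(image, radius = 1, neighbors = 8L) {
  stopifnot(radius %in% c(1, 2), neighbors == 8L)
  m <- as.integer(ceiling(radius))
  image <- as_gray_image(image, min_dim = 2L * m + 1L)
  codes <- lbp_codes(image, radius, m)
  bins <- lbp_uniform_table()[codes + 1L]
  h <- tabulate(bins, nbins = 59L)
  h / sum(h)
}

# Per-pixel LBP codes over the valid interior (margin m), returned as a
# matrix of integers 0..255.
lbp_codes <- function(image, radius, m) {
  angles <- 2 * pi * (0:7) / 8
  code <- NULL
  center <- image[(m + 1):(nrow(image) - m), (m + 1):(ncol(image) - m), drop = FALSE]
  for (k in 0:7) {
    a <- angles[k + 1]
    nb <- sample_offset(image, -radius * sin(a), radius * cos(a), m)
    bit <- (nb >= center) * 2^k
    code <- if (is.null(code)) bit else code + bit
  }
  code
}

#' @rdname descriptors
#' @return `mrlbp()`: numeric vector of length 118.
#' @export
mrlbp <- function(image) {
  c(lbp_uniform_hist(image, 1), lbp_uniform_hist(image, 2))
}

#' @rdname descriptors
#' @return `elbp()`: numeric vector of length 59.
#' @export
elbp <- function(image) {
  image <- as_gray_image(image, min_dim = 5L)
  lbp_uniform_hist(gradient_magnitude(image), 1)
}

# ---- multi-fractal spectrum -------------------------------------------------

disc_kernel <- function(r) {
  d <- -r:r
  mask <- outer(d^2, d^2, `+`) <= r^2
  mask * 1
}

#' @rdname descriptors
#' @param radii Disc radii (pixels) over which local densities are measured.
#' @param bins_per_measure Histogram bins per density measure, over the fixed
#'   local-dimension range \[0, 4\].
#' @return `mfs()`: numeric vector of length `3 * bins_per_measure` (78 by
#'   default); each block sums to 1.
#' @export
mfs <- function(image, radii = 1:4, bins_per_measure = 26L) {
  image <- as_gray_image(image, min_dim = 2L * max(radii) + 1L)
  stopifnot(length(radii) >= 2L)
  lap <- conv2_mirror(image, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L))
  measures <- list(
    intensity = image,
    gradient  = gradient_magnitude(image),
    laplacian = abs(lap)
  )
  lx <- log(radii)
  wslope <- (lx - mean(lx)) / sum((lx - mean(lx))^2) # least-squares slope weights
  out <- numeric(0)
  for (meas in measures) {
    mus <- lapply(radii, function(r) conv2_mirror(meas, disc_kernel(r)))
    ok <- Reduce(`&`, lapply(mus, function(mu) mu > 0))
    dim_map <- matrix(0, nrow(image), ncol(image))
    acc <- matrix(0, nrow(image), ncol(image))
    for (i in seq_along(radii)) acc <- acc + wslope[i] * log(pmax(mus[[i]], .Machine$double.xmin))
    dim_map[ok] <- acc[ok]                 # degenerate pixels keep dimension 0
    v <- pmin(pmax(dim_map, 0), 4)
    idx <- pmin(floor(v / (4 / bins_per_measure)) + 1L, bins_per_measure)
    h <- tabulate(idx, nbins = bins_per_measure)
    out <- c(out, h / sum(h))
  }
  out
}

# ---- edge co-occurrence matrix ----------------------------------------------

# Oriented first-derivative-of-Gaussian filter (sigma = 1, 7x7) at angle
# theta; zero-sum, so responses ignore the DC level.
oriented_dog_kernel <- function(theta, sigma = 1, size = 7L) {
  half <- (size - 1L) %/% 2L
  d <- -half:half
  xx <- outer(rep(1, size), d)   # column offsets
  yy <- outer(d, rep(1, size))   # row offsets
  u <- xx * cos(theta) + yy * sin(theta)
  k <- -u * exp(-(xx^2 + yy^2) / (2 * sigma^2))
  k - mean(k)  # analytically zero-sum; subtract numeric residual
}

#' @rdname descriptors
#' @param t_frac Magnitude mask: pixels whose maximal directional response is
#'   below `t_frac` times the global maximum response are excluded.
#' @param displacement Integer offset `(rows, cols)` between co-occurring
#'   pixels.
#' @return `ecm()`: numeric vector of length 64 (flattened 8x8 orientation
#'   co-occurrence matrix, column-major, rows = orientation at the first
#'   pixel) summing to 1.
#' @export
ecm <- function(image, t_frac = 0.25, displacement = c(1L, 1L)) {
  image <- as_gray_image(image, min_dim = 7L)
  thetas <- (0:7) * pi / 8
  resp <- vapply(thetas, function(th) {
    abs(conv2_mirror(image, oriented_dog_kernel(th)))
  }, matrix(0, nrow(image), ncol(image)))
  rmat <- matrix(resp, nrow(image) * ncol(image), 8L)
  ori <- max.col(rmat, ties.method = "first")
  mag <- rmat[cbind(seq_len(nrow(rmat)), ori)]
  gmax <- max(mag)
  # zero-sum kernels leave only round-off on constant images
  if (gmax <= 1e-9 * max(1, max(abs(image)))) {
    degenerate_input("no directional response (constant image)")
  }
  unmasked <- mag >= t_frac * gmax
  h <- nrow(image); w <- ncol(image)
  ori_m <- matrix(ori, h, w)
  ok_m <- matrix(unmasked, h, w)
  dy <- as.integer(displacement[1]); dx <- as.integer(displacement[2])
  r1 <- seq_len(h - abs(dy)); c1 <- seq_len(w - abs(dx))
  r2 <- r1 + abs(dy); c2 <- c1 + abs(dx)
  if (dy < 0) { tmp <- r1; r1 <- r2; r2 <- tmp }
  if (dx < 0) { tmp <- c1; c1 <- c2; c2 <- tmp }
  a <- ori_m[r1, c1]; b <- ori_m[r2, c2]
  keep <- ok_m[r1, c1] & ok_m[r2, c2]
  if (!any(keep)) degenerate_input("all pixel pairs masked out")
  idx <- (b[keep] - 1L) * 8L + a[keep]     # column-major: a = row index
  cm <- tabulate(idx, nbins = 64L)
  cm / sum(cm)
}

# ---- local phase quantization -----------------------------------------------

# Valid-region separable filtering: out[i, j] = sum_{dy, dx} wy[dy] wx[dx] *
# image[i + m + dy, j + m + dx]; complex weights allowed.
sep_filter_valid <- function(image, wy, wx) {
  n <- length(wy)
  h <- nrow(image); w <- ncol(image)
  Wy <- matrix(0 + 0i, h - n + 1L, h)
  for (i in seq_len(h - n + 1L)) Wy[i, i:(i + n - 1L)] <- wy
  Wx <- matrix(0 + 0i, w - n + 1L, w)
  for (j in seq_len(w - n + 1L)) Wx[j, j:(j + n - 1L)] <- wx
  Wy %*% image %*% t(Wx)
}

#' @rdname descriptors
#' @param window Odd side of the local short-term Fourier window (default 15).
#' @param whiten If `TRUE`, decorrelate the eight coefficient components with
#'   the standard first-order Markov image model before quantization
#'   (off by default).
#' @param rho Model pixel correlation used when `whiten = TRUE`.
#' @return `lpq()`: numeric vector of length 256 summing to 1.
#' @export
lpq <- function(image, window = 15L, whiten = FALSE, rho = 0.9) {
  window <- as.integer(window)
  stopifnot(window %% 2L == 1L, window >= 3L)
  image <- as_gray_image(image, min_dim = window)
  m <- (window - 1L) %/% 2L
  d <- -m:m
  e <- exp(-2i * pi * d / window)
  one <- rep(1 + 0i, window)
  c1 <- sep_filter_valid(image, one, e)        # frequency (a, 0): x-direction
  c2 <- sep_filter_valid(image, e, one)        # (0, a): y-direction
  c3 <- sep_filter_valid(image, e, e)          # (a, a)
  c4 <- sep_filter_valid(image, Conj(e), e)    # (a, -a)
  comp <- cbind(Re(c(c1)), Re(c(c2)), Re(c(c3)), Re(c(c4)),
                Im(c(c1)), Im(c(c2)), Im(c(c3)), Im(c(c4)))
  if (whiten) comp <- comp %*% lpq_whitening(window, rho)
  # snap numerically-zero coefficients (e.g. constant regions, where the
  # zero-sum windows leave only summation round-off) so the >= 0 sign rule
  # is deterministic
  tol <- 1e-9 * window^2 * max(1, max(abs(image)))
  comp[abs(comp) < tol] <- 0
  bits <- comp >= 0
  code <- as.vector(bits %*% 2^(0:7))
  h <- tabulate(code + 1L, nbins = 256L)
  h / sum(h)
}

# Decorrelation matrix for the 8 coefficient components under an isotropic
# first-order Markov model (corr rho^distance between pixels); returns the
# 8x8 orthonormal transform (right-multiplied onto the component matrix).
lpq_whitening <- function(window, rho) {
  m <- (window - 1L) %/% 2L
  d <- -m:m
  pos <- expand.grid(y = d, x = d)
  e <- function(freq_y, freq_x) exp(-2i * pi * (freq_y * pos$y + freq_x * pos$x) / window)
  W <- rbind(e(0, 1), e(1, 0), e(1, 1), e(-1, 1))
  Wri <- rbind(Re(W), Im(W))                       # 8 x 225 real basis
  dist <- as.matrix(stats::dist(pos))
  C <- Wri %*% (rho^dist) %*% t(Wri)
  sv <- svd(C)
  sv$u
}

# ---- dispatch & dataset-level extraction ------------------------------------

descriptor_ids <- function() c("mrlbp", "elbp", "mfs", "ecm", "lpq")

descriptor_length <- function(id) {
  c(mrlbp = 118L, elbp = 59L, mfs = 78L, ecm = 64L, lpq = 256L)[[id]]
}

#' Compute a texture descriptor by id
#'
#' @inheritParams descriptors
#' @param descriptor One of `"mrlbp"`, `"elbp"`, `"mfs"`, `"ecm"`, `"lpq"`.
#' @param ... Passed to the specific descriptor function.
#' @return Numeric feature vector of the descriptor's fixed length.
#' @export
texture_features <- function(image, descriptor = descriptor_ids(), ...) {
  descriptor <- match.arg(descriptor)
  switch(descriptor,
    mrlbp = mrlbp(image),
    elbp  = elbp(image),
    mfs   = mfs(image, ...),
    ecm   = ecm(image, ...),
    lpq   = lpq(image, ...)
  )
}

#' Extract descriptor features for a whole dataset
#'
#' @param data Dataset tibble with a list-column `image`, or bare list of
#'   image matrices.
#' @param descriptor Descriptor id, see [texture_features()].
#' @param ... Passed to the descriptor function.
#' @return The dataset tibble with columns `descriptor` and `features`
#'   (list-column of numeric vectors) appended.
#' @export
extract_features <- function(data, descriptor = descriptor_ids(), ...) {
  descriptor <- match.arg(descriptor)
  if (!inherits(data, "data.frame")) data <- tibble::tibble(image = data)
  feats <- purrr::map(data$image, texture_features, descriptor = descriptor, ...)
  dplyr::mutate(data, descriptor = .env$descriptor, features = feats)
}
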