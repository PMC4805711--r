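# Independent reference implementations used as oracles. Deliberately slow
# and literal (double loops, direct definitions) so they share no code with
# the package internals they check.

# Seeded random texture on the 0-255 scale.
random_texture <- function(n, seed, blur = 0) {
  set.seed(seed)
  img <- matrix(runif(n * n, 0, 255), n, n)
  if (blur > 0) img <- degrade(img, degradation_spec("gaussian", sigma = blur))
  img
}

# A small band-pass texture set (cheaper than the full frozen dataset).
small_texture_set <- function(n_classes = 4, n_per = 4, size = 64, seed = 11) {
  spec <- texture_dataset_spec(n_classes = n_classes, n_train = n_per,
                               n_eval = n_per, patch_size = size, seed = seed)
  generate_texture_dataset(spec)
}

# Reference symmetric-padded value lookup: image value at (possibly
# out-of-range) integer coordinates under whole-sample reflection.
ref_mirror_get <- function(img, r, c) {
  fold1 <- function(i, n) {
    period <- 2 * n
    i <- ((i - 1) %% period + period) %% period + 1
    if (i > n) i <- period - i + 1
    i
  }
  img[fold1(r, nrow(img)), fold1(c, ncol(img))]
}

# Literal same-size convolution: out(y,x) = sum_k K(i,j) I(y-di, x-dj).
ref_conv2 <- function(img, K) {
  kh <- nrow(K); kw <- ncol(K)
  hh <- (kh - 1) / 2; hw <- (kw - 1) / 2
  out <- matrix(0, nrow(img), ncol(img))
  for (y in seq_len(nrow(img))) {
    for (x in seq_len(ncol(img))) {
      acc <- 0
      for (i in seq_len(kh)) {
        for (j in seq_len(kw)) {
          di <- i - hh - 1; dj <- j - hw - 1
          acc <- acc + K[i, j] * ref_mirror_get(img, y - di, x - dj)
        }
      }
      out[y, x] <- acc
    }
  }
  out
}

# Per-pixel circular LBP code, one pixel at a time, with explicit bilinear
# interpolation.
ref_lbp_code <- function(img, y, x, radius) {
  bilin <- function(r, c) {
    r0 <- floor(r + 1e-9); c0 <- floor(c + 1e-9)
    fr <- r - r0; fc <- c - c0
    if (abs(fr) < 1e-9) fr <- 0
    if (abs(fc) < 1e-9) fc <- 0
    v <- (1 - fr) * (1 - fc) * img[r0, c0]
    if (fc > 0) v <- v + (1 - fr) * fc * img[r0, c0 + 1]
    if (fr > 0) v <- v + fr * (1 - fc) * img[r0 + 1, c0]
    if (fr > 0 && fc > 0) v <- v + fr * fc * img[r0 + 1, c0 + 1]
    v
  }
  code <- 0
  for (k in 0:7) {
    a <- 2 * pi * k / 8
    nb <- bilin(y - radius * sin(a), x + radius * cos(a))
    if (nb >= img[y, x]) code <- code + 2^k
  }
  code
}

# Direct windowed-DFT coefficient at the centre pixel of an image patch:
# c_u = sum_{dy,dx} f(y+dy, x+dx) * exp(-2i*pi*(fy*dy + fx*dx)/window).
ref_lpq_coeff <- function(img, y, x, window, fy, fx) {
  m <- (window - 1) / 2
  acc <- 0 + 0i
  for (dy in -m:m) {
    for (dx in -m:m) {
      acc <- acc + img[y + dy, x + dx] *
        exp(-2i * pi * (fy * dy + fx * dx) / window)
    }
  }
  acc
}

# Exhaustive forward search for the minimal equalization iteration count.
ref_min_iterations <- function(img, theta, measure, step_sigma = 1,
                               step_size = 3, max_iter = 64) {
  kern <- gaussian_kernel(step_sigma, step_size)
  cur <- img
  for (n in 0:max_iter) {
    if (blur_score(cur, measure) >= theta) return(n)
    cur <- convolve_image(cur, kern)
  }
  NA_integer_
}
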