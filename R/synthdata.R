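#' Specify a synthetic texture dataset
#'
#' The generator emulates a Kylberg-style benchmark layout: `n_classes`
#' texture classes, `n_train + n_eval` independent patches each, captured at
#' a single scale. Every class is oriented band-pass-filtered white noise —
#' a Gabor-like spectral envelope centred at a class-specific orientation and
#' spatial frequency — plus low-amplitude broadband noise, normalized to
#' mean 127 and standard deviation 40 on the 0--255 scale.
#'
#' Classes must be pairwise distinct by at least `pi / (2 * n_classes)` in
#' orientation or 20 percent in centre frequency, so that a linear classifier
#' on texture descriptors can separate clean patches reliably.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_train,n_eval Patches per class in the training ("A") and
#'   evaluation ("B") splits.
#' @param patch_size Square patch side in pixels (>= 64).
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bit-identically.
#' @param class_params Optional data frame with one row per class and
#'   columns `theta` (orientation, radians), `freq` (centre frequency,
#'   cycles/pixel), `bw_freq`, `bw_theta` (radial/angular bandwidths),
#'   `harmonic` (relative amplitude of a second band at `2 * freq`) and
#'   `noise_amp` (broadband noise amplitude relative to the unit-variance
#'   band-pass component). Defaults emulate a heterogeneous benchmark:
#'   orientations spread over half a turn, frequencies cycling over
#'   `{0.09, 0.12, 0.15}`, and per-class bandwidth/harmonic/noise variation.
#' @param jitter_theta,jitter_freq Per-patch standard deviations of the
#'   orientation (radians, additive) and frequency (relative, multiplicative)
#'   jitter that provide intra-class variability.
#' @return A `texture_dataset_spec` list.
#' @export
texture_dataset_spec <- function(n_classes = 8L, n_train = 20L, n_eval = 20L,
                                 patch_size = 128L, seed = 20L,
                                 class_params = NULL,
                                 jitter_theta = 0.015, jitter_freq = 0.05) {
  n_classes <- as.integer(n_classes)
  stopifnot(n_classes >= 2L, patch_size >= 64L, n_train >= 1L, n_eval >= 0L)
  if (is.null(class_params)) class_params <- default_class_params(n_classes)
  class_params <- as.data.frame(class_params)
  need <- c("theta", "freq", "bw_freq", "bw_theta", "harmonic", "noise_amp")
  stopifnot(nrow(class_params) == n_classes, all(need %in% names(class_params)))
  # pairwise distinctness margin
  ang_margin <- pi / (2 * n_classes)
  for (i in seq_len(n_classes - 1L)) {
    for (j in (i + 1L):n_classes) {
      da <- abs(class_params$theta[i] - class_params$theta[j]) %% pi
      da <- min(da, pi - da)
      df <- abs(class_params$freq[i] - class_params$freq[j]) /
        max(class_params$freq[i], class_params$freq[j])
      if (da < ang_margin && df < 0.2) {
        stop(sprintf("classes %d and %d are not distinct enough", i, j),
             call. = FALSE)
      }
    }
  }
  structure(list(n_classes = n_classes, n_train = n_train, n_eval = n_eval,
                 patch_size = as.integer(patch_size), seed = as.integer(seed),
                 class_params = class_params,
                 jitter_theta = jitter_theta, jitter_freq = jitter_freq),
            class = "texture_dataset_spec")
}

#' @rdname texture_dataset_spec
#' @export
default_class_params <- function(n_classes = 8L) {
  i <- seq_len(n_classes)
  data.frame(
    theta = (i - 1L) * pi / n_classes,
    freq = rep(c(0.09, 0.12, 0.15), length.out = n_classes),
    bw_freq = rep(c(0.02, 0.03, 0.02, 0.035), length.out = n_classes),
    bw_theta = rep(c(pi / 14, pi / 10, pi / 14, pi / 8), length.out = n_classes),
    harmonic = rep(c(0, 0, 0.5, 0.5), length.out = n_classes),
    noise_amp = rep(0.15, n_classes)
  )
}

# Spectral envelope of one class on the FFT frequency grid (cycles/pixel),
# symmetric in +/- orientation so the inverse transform is real. A second
# harmonic band at 2*f0 (relative amplitude `harm`) adds non-sinusoidal
# structure that density-based descriptors can pick up.
class_envelope <- function(n, theta, f0, bw_f, bw_t, harm = 0) {
  fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fx <- outer(rep(1, n), fr)
  fy <- outer(fr, rep(1, n))
  r <- sqrt(fx^2 + fy^2)
  phi <- atan2(fy, fx)
  dth <- (phi - theta) %% pi
  dth <- pmin(dth, pi - dth)
  radial <- exp(-(r - f0)^2 / (2 * bw_f^2)) +
    harm * exp(-(r - 2 * f0)^2 / (2 * bw_f^2))
  radial * exp(-dth^2 / (2 * bw_t^2))
}

synth_patch <- function(n, p, jitter_theta, jitter_freq) {
  theta <- p$theta + stats::rnorm(1L, sd = jitter_theta)
  f0 <- p$freq * (1 + stats::rnorm(1L, sd = jitter_freq))
  env <- class_envelope(n, theta, f0, p$bw_freq, p$bw_theta, p$harmonic)
  z <- matrix(stats::rnorm(n * n), n, n)
  bp <- Re(stats::fft(stats::fft(z) * env, inverse = TRUE)) / (n * n)
  bp <- bp / stats::sd(bp)
  img <- bp + p$noise_amp * matrix(stats::rnorm(n * n), n, n)
  img <- 127 + 40 * (img - mean(img)) / stats::sd(img)
  pmin(pmax(img, 0), 255)
}

#' Generate a seeded synthetic texture dataset
#'
#' @param spec A [texture_dataset_spec()].
#' @return A tibble with one row per patch: `id`, `class` (factor
#'   `"class1"` ...), `split` (`"train"`/`"eval"`), and the list-column
#'   `image` of `patch_size` x `patch_size` matrices.
#' @export
generate_texture_dataset <- function(spec = texture_dataset_spec()) {
  stopifnot(inherits(spec, "texture_dataset_spec"))
  with_seed(spec$seed, {
    rows <- list()
    id <- 0L
    for (cl in seq_len(spec$n_classes)) {
      for (split in c("train", "eval")) {
        n_p <- if (split == "train") spec$n_train else spec$n_eval
        for (p in seq_len(n_p)) {
          id <- id + 1L
          img <- synth_patch(spec$patch_size, spec$class_params[cl, ],
                             spec$jitter_theta, spec$jitter_freq)
          rows[[id]] <- tibble::tibble(
            id = id, class = paste0("class", cl), split = split,
            image = list(img))
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    out$class <- factor(out$class, levels = paste0("class", seq_len(spec$n_classes)))
    out
  })
}

#' Degraded copies of a dataset
#'
#' Applies each degradation to every image, preserving labels and the
#' pairing with the originals. The default grid is the nine Gaussian blur
#' levels `sigma = 0, 0.5, ..., 4` (`sigma = 0` copies are bit-identical to
#' the originals); averaging/median grids conventionally use window sizes
#' 1, 3, 5, 7, 9.
#'
#' @param data Dataset tibble with list-column `image`.
#' @param specs List of [degradation_spec()]s; default the nine Gaussian
#'   levels.
#' @return A tibble with one row per (patch, degradation): original columns
#'   plus `kind`, `param` (sigma or window size) and the degraded `image`.
#' @export
make_degraded_copies <- function(data, specs = gaussian_grid()) {
  stopifnot(inherits(data, "data.frame"), !is.null(data$image))
  purrr::map_dfr(specs, function(sp) {
    out <- data
    out$kind <- sp$kind
    out$param <- if (sp$kind == "gaussian") sp$sigma else as.numeric(sp$size)
    out$image <- purrr::map(data$image, degrade, spec = sp)
    out
  })
}

#' Standard degradation grids
#'
#' @param sigmas Gaussian blur levels.
#' @param sizes Window sizes for averaging/median filtering.
#' @return A list of [degradation_spec()]s.
#' @export
gaussian_grid <- function(sigmas = seq(0, 4, by = 0.5)) {
  lapply(sigmas, function(s) degradation_spec("gaussian", sigma = s))
}

#' @rdname gaussian_grid
#' @export
average_grid <- function(sizes = c(1, 3, 5, 7, 9)) {
  lapply(sizes, function(s) degradation_spec("average", size = s))
}

#' @rdname gaussian_grid
#' @export
median_grid <- function(sizes = c(1, 3, 5, 7, 9)) {
  lapply(sizes, function(s) degradation_spec("median", size = s))
}

#' Write a dataset as a directory-per-class PNG tree
#'
#' @param data Dataset tibble.
#' @param dir Output directory; a `manifest.csv` (path, class, split) is
#'   written alongside the class subdirectories.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "data.frame"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(data))
  for (i in seq_len(nrow(data))) {
    cls <- as.character(data$class[i])
    cdir <- file.path(dir, cls)
    dir.create(cdir, showWarnings = FALSE)
    paths[i] <- file.path(cdir, sprintf("%s-%04d.png", data$split[i], data$id[i]))
    write_gray(data$image[[i]], paths[i])
  }
  man <- tibble::tibble(path = paths, class = as.character(data$class),
                        split = data$split)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a Kylberg-style directory tree as a dataset tibble
#'
#' One subdirectory per class; images in PNG/TIFF/PGM. A `split` column is
#' set to `"all"` unless a `manifest.csv` with a split column is present.
#'
#' @param dir Root directory.
#' @return Dataset tibble with `id`, `class`, `split`, `path`, `image`.
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (file.exists(man_path)) {
    man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
    paths <- ifelse(file.exists(man$path), man$path, file.path(dir, man$path))
    cls <- man$class
    split <- if (!is.null(man$split)) man$split else rep("all", nrow(man))
  } else {
    cls_dirs <- list.dirs(dir, recursive = FALSE)
    if (length(cls_dirs) == 0L) stop("no class subdirectories in ", dir, call. = FALSE)
    paths <- character(0); cls <- character(0)
    for (cd in cls_dirs) {
      fs <- list.files(cd, pattern = "\\.(png|tif|tiff|pgm)$",
                       ignore.case = TRUE, full.names = TRUE)
      paths <- c(paths, fs)
      cls <- c(cls, rep(basename(cd), length(fs)))
    }
    split <- rep("all", length(paths))
  }
  tibble::tibble(
    id = seq_along(paths), class = factor(cls), split = split, path = paths,
    image = purrr::map(paths, read_gray))
}
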