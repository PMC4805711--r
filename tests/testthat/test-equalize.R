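test_that("an image already at the target is returned unchanged", {
  img <- random_texture(32, seed = 3, blur = 2)
  theta <- blur_score(img, "co") - 1  # strictly below current score
  r <- equalize_blur(img, theta, "co")
  expect_identical(r$image, img)
  expect_equal(r$iterations, 0L)
  expect_true(r$converged)
})

test_that("equalization is idempotent at a fixed threshold", {
  img <- random_texture(32, seed = 5)
  theta <- blur_score(degrade(img, degradation_spec("gaussian", 1.5)), "co")
  r1 <- equalize_blur(img, theta, "co")
  expect_true(r1$converged)
  r2 <- equalize_blur(r1$image, theta, "co")
  expect_equal(r2$iterations, 0L)
  expect_identical(r2$image, r1$image)
})

test_that("iteration count and image match brute-force forward iteration", {
  img <- small_texture_set(n_classes = 2, n_per = 1, size = 128)$image[[1]]
  kern <- gaussian_kernel(1, 3)
  ref <- img
  for (i in 1:3) ref <- convolve_image(ref, kern)
  theta <- blur_score(ref, "co")
  r <- equalize_blur(img, theta, "co")
  expect_equal(r$iterations, 3L)
  expect_identical(r$image, ref)
  expect_true(r$converged)
})

test_that("iteration counts equal exhaustive minimal search across measures", {
  ds <- small_texture_set(n_classes = 3, n_per = 2, size = 64)
  for (m in c("co", "cr")) {
    for (i in c(1, 4, 7)) {
      img <- ds$image[[i]]
      theta <- blur_score(degrade(img, degradation_spec("gaussian", 1)), m)
      r <- equalize_blur(img, theta, m)
      expect_equal(r$iterations, ref_min_iterations(img, theta, m))
    }
  }
})

test_that("non-convergence is reported, not fatal", {
  img <- random_texture(32, seed = 6)
  r <- equalize_blur(img, theta = 1e9, "co", max_iter = 5)
  expect_false(r$converged)
  expect_equal(r$iterations, 5L)
})

test_that("degenerate images propagate a contextual error from equalize_blur", {
  expect_error(equalize_blur(matrix(4, 32, 32), 0.5, "cr"),
               class = "blurtex_degenerate")
})

test_that("equalize_dataset applies shared parameters element-wise", {
  ds <- small_texture_set(n_classes = 2, n_per = 2, size = 64)
  theta <- stats::median(score_dataset(ds, "co")$score)
  out <- equalize_dataset(ds, theta, "co")
  expect_equal(nrow(out), nrow(ds))
  expect_true(all(out$final_score >= theta | !out$converged))
  # images already above theta keep iteration count 0
  blurry <- equalize_dataset(
    lapply(ds$image, degrade, spec = degradation_spec("gaussian", 3)),
    theta, "co")
  expect_true(all(blurry$iterations == 0L))
})

test_that("equalize_dataset rejects empty input and survives degenerates", {
  expect_error(equalize_dataset(list(), 0, "co"), "empty")
  mixed <- list(random_texture(32, 1), matrix(2, 32, 32))
  out <- equalize_dataset(mixed, 0.5, "cr")
  expect_equal(out$degenerate, c(FALSE, TRUE))
  expect_identical(out$image[[2]], matrix(2, 32, 32))
})

test_that("dataset members end within one step increment of each other", {
  img <- small_texture_set(n_classes = 2, n_per = 1, size = 128)$image[[1]]
  pair <- list(img, degrade(img, degradation_spec("gaussian", 1)))
  theta <- blur_score(degrade(img, degradation_spec("gaussian", 2.5)), "co")
  out <- equalize_dataset(pair, theta, "co")
  expect_true(all(out$converged))
  # score increment of one extra step on either equalized image
  step <- gaussian_kernel(1, 3)
  incs <- sapply(out$image, function(im) {
    abs(blur_score(convolve_image(im, step), "co") - blur_score(im, "co"))
  })
  expect_lte(abs(out$final_score[1] - out$final_score[2]), max(incs))
})

test_that("blur score trajectory is predominantly non-decreasing", {
  ds <- small_texture_set(n_classes = 3, n_per = 1, size = 64)
  for (m in c("co", "ma", "cr")) {
    steps_ok <- 0; steps_all <- 0
    for (img in ds$image[1:3]) {
      kern <- gaussian_kernel(1, 3)
      cur <- img
      sc <- blur_score(cur, m)
      for (i in 1:10) {
        cur <- convolve_image(cur, kern)
        s2 <- blur_score(cur, m)
        steps_all <- steps_all + 1
        if (s2 >= sc) steps_ok <- steps_ok + 1
        sc <- s2
      }
    }
    expect_gte(steps_ok / steps_all, 0.95)
  }
})

test_that("equalization at least halves descriptor distances between blur levels", {
  # the core invariance claim: after equalizing I and its blurred copy to a
  # common level, their descriptors are far closer than before
  # a half-pixel equalization step keeps the residual blur-level
  # quantization well below the smallest tested offset (sigma = 0.5)
  ds <- small_texture_set(n_classes = 8, n_per = 1, size = 64, seed = 31)
  imgs <- ds$image[ds$split == "train"]
  descs <- c("mrlbp", "elbp", "mfs", "ecm", "lpq")
  sigmas <- c(0.5, 1, 2)
  pass <- matrix(TRUE, length(imgs), length(descs),
                 dimnames = list(NULL, descs))
  for (i in seq_along(imgs)) {
    img <- imgs[[i]]
    theta <- blur_score(degrade(img, degradation_spec("gaussian", 2.5)), "co")
    ei <- equalize_blur(img, theta, "co", step_sigma = 0.5, step_size = 5)$image
    for (s in sigmas) {
      j <- degrade(img, degradation_spec("gaussian", s))
      ej <- equalize_blur(j, theta, "co", step_sigma = 0.5, step_size = 5)$image
      for (d in descs) {
        d_raw <- sum(abs(texture_features(img, d) - texture_features(j, d)))
        d_eq <- sum(abs(texture_features(ei, d) - texture_features(ej, d)))
        if (d_eq > 0.5 * d_raw) pass[i, d] <- FALSE
      }
    }
  }
  for (d in descs) expect_gte(mean(pass[, d]), 0.8)
})

test_that("glance() summarizes an equalization result", {
  img <- random_texture(32, seed = 8)
  g <- glance(equalize_blur(img, blur_score(img, "co") + 100, "co"))
  expect_s3_class(g, "tbl_df")
  expect_named(g, c("iterations", "final_score", "converged", "measure", "theta"))
})
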