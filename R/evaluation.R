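#' Intra-/inter-class blur prediction error
#'
#' How well does a blur measure order two textures by their true Gaussian
#' blur? For each base level `sigma`, pairs are formed from one image at
#' `sigma` and a different image at `sigma + sigma_step`; the prediction is
#' correct when the oriented score of the more-blurred image is larger (ties
#' split evenly, so comparing an image with itself at equal blur scores error
#' 0.5, the guessing anchor). `"intra"` pairs images of the same class,
#' `"inter"` images of different classes; inter-class prediction is the
#' harder task.
#'
#' @param data Dataset tibble of undegraded images (list-column `image`,
#'   column `class`) with at least 2 classes.
#' @param measure Blur measure id.
#' @param mode `"intra"`, `"inter"`, or both; the blur-score matrix is
#'   computed once and shared.
#' @param base_sigmas Base blur levels compared against
#'   `base_sigmas + sigma_step`.
#' @param sigma_step Blur step between the two members of a pair.
#' @param max_pairs Above this count, pairs are subsampled (seeded).
#' @param seed Seed for the subsample.
#' @return Tibble with columns `mode`, `measure`, `base_sigma`,
#'   `error_rate`, `n_pairs`, `n_skipped` (pairs dropped because the measure
#'   was degenerate on a member).
#' @export
blur_prediction_error <- function(data, measure = c("co", "ma", "cr"),
                                  mode = c("intra", "inter"),
                                  base_sigmas = seq(0, 3.5, by = 0.5),
                                  sigma_step = 0.5, max_pairs = 1e4,
                                  seed = 1L) {
  measure <- match.arg(measure)
  mode <- match.arg(mode, several.ok = TRUE)
  stopifnot(inherits(data, "data.frame"), !is.null(data$image),
            nlevels(factor(data$class)) >= 2L)
  sigmas <- sort(unique(c(base_sigmas, base_sigmas + sigma_step)))
  n <- nrow(data)
  scores <- matrix(NA_real_, n, length(sigmas),
                   dimnames = list(NULL, as.character(sigmas)))
  for (j in seq_along(sigmas)) {
    sp <- degradation_spec("gaussian", sigma = sigmas[j])
    for (i in seq_len(n)) {
      scores[i, j] <- tryCatch(
        blur_score(degrade(data$image[[i]], sp), measure),
        blurtex_degenerate = function(e) NA_real_)
    }
  }
  cls <- as.character(data$class)
  same <- outer(cls, cls, `==`)
  purrr::map_dfr(mode, function(md) {
    eligible <- if (md == "intra") same else !same
    diag(eligible) <- FALSE
    purrr::map_dfr(base_sigmas, function(bs) {
      lo <- scores[, as.character(bs)]
      hi <- scores[, as.character(bs + sigma_step)]
      ok <- outer(!is.na(lo), !is.na(hi), `&`) & eligible
      skipped <- sum(eligible) - sum(ok)
      idx <- which(ok, arr.ind = TRUE)
      if (nrow(idx) > max_pairs) {
        idx <- idx[with_seed(seed, sample.int(nrow(idx), max_pairs)), , drop = FALSE]
      }
      a <- lo[idx[, 1]]; b <- hi[idx[, 2]]
      correct <- (b > a) + 0.5 * (b == a)
      tibble::tibble(mode = md, measure = measure, base_sigma = bs,
                     error_rate = 1 - mean(correct), n_pairs = nrow(idx),
                     n_skipped = skipped)
    })
  })
}

# Standardize by train-set mean/scale, fit the linear SVM (unit
# regularization), return evaluation accuracy.
linear_svm_accuracy <- function(train_x, train_y, eval_x, eval_y) {
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  tx <- sweep(sweep(train_x, 2, mu), 2, sdv, "/")
  ex <- sweep(sweep(eval_x, 2, mu), 2, sdv, "/")
  train_y <- factor(train_y)
  fit <- e1071::svm(tx, train_y, kernel = "linear", cost = 1, scale = FALSE)
  pred <- stats::predict(fit, ex)
  mean(as.character(pred) == as.character(eval_y))
}

# Feature matrices for the equalized variants of a set of images: returns
# list[[theta_key]][[descriptor]] = n x p matrix, plus "baseline" theta_key
# for the unequalized images, and a non-convergence count per theta_key.
variant_features <- function(images, measure, thetas, theta_keys, descriptors,
                             step_sigma, step_size, max_iter,
                             include_baseline = TRUE) {
  n <- length(images)
  keys <- c(if (include_baseline) "baseline", theta_keys)
  feats <- lapply(stats::setNames(keys, keys), function(k)
    lapply(stats::setNames(descriptors, descriptors), function(d)
      matrix(NA_real_, n, descriptor_length(d))))
  nonconv <- stats::setNames(integer(length(keys)), keys)
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (include_baseline) {
      for (d in descriptors) feats[["baseline"]][[d]][i, ] <- texture_features(img, d)
    }
    if (length(thetas)) {
      eqs <- tryCatch(
        equalize_trajectory(img, thetas, measure, step_sigma, step_size, max_iter),
        blurtex_degenerate = function(e) NULL)
      for (t in seq_along(thetas)) {
        key <- theta_keys[t]
        if (is.null(eqs)) { # degenerate: kept unequalized, tallied
          eq_img <- img
          nonconv[key] <- nonconv[key] + 1L
        } else {
          eq_img <- eqs[[t]]$image
          if (!eqs[[t]]$converged) nonconv[key] <- nonconv[key] + 1L
        }
        for (d in descriptors) feats[[key]][[d]][i, ] <- texture_features(eq_img, d)
      }
    }
  }
  list(features = feats, nonconverged = nonconv)
}

#' Train-clean / evaluate-degraded experiment grid
#'
#' The full experimental harness: blur-measure thresholds are taken as
#' deciles of the scores of the undegraded evaluation set (reproduction
#' protocol; set `threshold_source = "train"` for the deployment variant);
#' for every combination of descriptor, blur measure, threshold index and
#' degradation level, both the clean training set and the degraded
#' evaluation set are blur-equalized at the threshold, descriptor features
#' are extracted, a linear SVM (unit cost, train-set standardization) is
#' fitted on the training set, and evaluation accuracy is reported. Baseline
#' rows (`theta_index = NA`) skip equalization.
#'
#' @param train,eval_data Dataset tibbles (list-column `image`, column
#'   `class`) with matching class sets, or directory paths readable by
#'   [read_dataset()].
#' @param descriptors Descriptor ids to evaluate.
#' @param measures Blur measure ids to evaluate.
#' @param degradations List of [degradation_spec()]s applied to the
#'   evaluation set (the identity level gives the clean reference).
#' @param theta_quantiles Decile indices 1..10 to evaluate.
#' @param include_baseline Include unequalized rows.
#' @param threshold_source `"eval"` (deciles of the undegraded evaluation
#'   set, the reproduction protocol) or `"train"`.
#' @param step_sigma,step_size,max_iter Equalization parameters, see
#'   [equalize_blur()].
#' @return A tibble of class `blur_experiment_grid`: one row per cell with
#'   `descriptor`, `measure`, `theta_index` (NA = baseline), `theta`,
#'   `kind`, `param`, `accuracy`, `n_eval`, `n_nonconverged`.
#' @export
run_experiment <- function(train, eval_data,
                           descriptors = "mrlbp", measures = "co",
                           degradations = gaussian_grid(),
                           theta_quantiles = 1:10,
                           include_baseline = TRUE,
                           threshold_source = c("eval", "train"),
                           step_sigma = 1, step_size = 3L, max_iter = 64L) {
  threshold_source <- match.arg(threshold_source)
  if (is.character(train)) train <- read_dataset(train)
  if (is.character(eval_data)) eval_data <- read_dataset(eval_data)
  if (!setequal(unique(as.character(train$class)),
                unique(as.character(eval_data$class)))) {
    stop("training and evaluation class sets differ", call. = FALSE)
  }
  descriptors <- match.arg(descriptors, descriptor_ids(), several.ok = TRUE)
  measures <- match.arg(measures, c("co", "ma", "cr"), several.ok = TRUE)
  theta_quantiles <- sort(unique(as.integer(theta_quantiles)))
  stopifnot(all(theta_quantiles %in% 1:10))
  ref <- if (threshold_source == "eval") eval_data else train
  thr <- if (length(theta_quantiles) == 0L) NULL else
    lapply(stats::setNames(measures, measures), function(m) {
      compute_thresholds(score_dataset(ref, m, on_degenerate = "na")$score |>
                           stats::na.omit(), m)
    })
  rows <- list()
  for (m in measures) {
    thetas <- if (is.null(thr)) numeric(0) else thr[[m]]$thetas[theta_quantiles]
    keys <- if (length(theta_quantiles)) paste0("q", theta_quantiles) else character(0)
    tr_feat <- variant_features(train$image, m, thetas, keys, descriptors,
                                step_sigma, step_size, max_iter,
                                include_baseline = include_baseline)
    for (dg in degradations) {
      ev_imgs <- lapply(eval_data$image, degrade, spec = dg)
      ev_feat <- variant_features(ev_imgs, m, thetas, keys, descriptors,
                                  step_sigma, step_size, max_iter,
                                  include_baseline = include_baseline)
      all_keys <- names(ev_feat$features)
      for (key in all_keys) {
        ti <- if (key == "baseline") NA_integer_ else theta_quantiles[match(key, keys)]
        for (d in descriptors) {
          acc <- linear_svm_accuracy(tr_feat$features[[key]][[d]], train$class,
                                     ev_feat$features[[key]][[d]], eval_data$class)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            descriptor = d, measure = m, theta_index = ti,
            theta = if (is.na(ti)) NA_real_ else thr[[m]]$thetas[ti],
            kind = dg$kind,
            param = if (dg$kind == "gaussian") dg$sigma else as.numeric(dg$size),
            accuracy = acc, n_eval = nrow(eval_data),
            n_nonconverged = unname(ev_feat$nonconverged[key] +
                                      tr_feat$nonconverged[key]))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("blur_experiment_grid", class(out))
  out
}

#' Best-threshold accuracy curve
#'
#' For each descriptor, measure and degradation level, the accuracy of the
#' best threshold (the upper envelope of the per-theta curves), next to the
#' unequalized baseline.
#'
#' @param grid A grid from [run_experiment()] that includes baseline rows.
#' @return Tibble with `descriptor`, `measure`, `kind`, `param`,
#'   `best_accuracy`, `best_theta_index`, `baseline_accuracy`.
#' @export
best_theta_curve <- function(grid) {
  stopifnot(inherits(grid, "data.frame"))
  eq <- dplyr::filter(grid, !is.na(.data$theta_index))
  bl <- dplyr::filter(grid, is.na(.data$theta_index)) |>
    dplyr::select("descriptor", "measure", "kind", "param",
                  baseline_accuracy = "accuracy")
  best <- eq |>
    dplyr::group_by(.data$descriptor, .data$measure, .data$kind, .data$param) |>
    dplyr::summarise(
      best_accuracy = max(.data$accuracy),
      best_theta_index = .data$theta_index[which.max(.data$accuracy)],
      .groups = "drop")
  dplyr::left_join(best, bl, by = c("descriptor", "measure", "kind", "param"))
}

#' Ideal equalization curve from known Gaussian blur
#'
#' On synthetic data the true Gaussian `sigma` of each evaluation image is
#' known by construction, so equalization can be driven by it directly: an
#' image at blur `sigma` is brought to a target level `sigma_star` by a
#' single convolution with a Gaussian of `sqrt(sigma_star^2 - sigma^2)` (the
#' semigroup rule); images already at or past the target pass through
#' unchanged (blur is only ever added). This upper-bounds what any
#' measure-driven equalization could achieve.
#'
#' @param train Clean training dataset tibble (true `sigma` 0).
#' @param eval_degraded Evaluation tibble from [make_degraded_copies()] with
#'   `kind == "gaussian"` and `param` holding the true sigma; anything else
#'   is refused.
#' @param descriptors Descriptor ids.
#' @param sigma_star Target blur levels.
#' @return Tibble with `descriptor`, `sigma_star`, `param` (true eval
#'   sigma), `accuracy`, `n_eval`.
#' @export
ideal_sigma_curve <- function(train, eval_degraded, descriptors = "mrlbp",
                              sigma_star = c(1, 2, 3)) {
  stopifnot(inherits(eval_degraded, "data.frame"))
  if (!all(c("kind", "param") %in% names(eval_degraded)) ||
      !all(eval_degraded$kind == "gaussian")) {
    stop("ideal equalization needs Gaussian-degraded data with known sigma",
         call. = FALSE)
  }
  descriptors <- match.arg(descriptors, descriptor_ids(), several.ok = TRUE)
  to_level <- function(img, sig, target) {
    add <- sqrt(max(0, target^2 - sig^2))
    degrade(img, degradation_spec("gaussian", sigma = add))
  }
  levels <- sort(unique(eval_degraded$param))
  rows <- list()
  for (ss in sigma_star) {
    tr_imgs <- lapply(train$image, to_level, sig = 0, target = ss)
    tr_x <- lapply(stats::setNames(descriptors, descriptors), function(d)
      do.call(rbind, lapply(tr_imgs, texture_features, descriptor = d)))
    for (lv in levels) {
      sub <- eval_degraded[eval_degraded$param == lv, ]
      ev_imgs <- lapply(sub$image, to_level, sig = lv, target = ss)
      for (d in descriptors) {
        ev_x <- do.call(rbind, lapply(ev_imgs, texture_features, descriptor = d))
        acc <- linear_svm_accuracy(tr_x[[d]], train$class, ev_x, sub$class)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          descriptor = d, sigma_star = ss, param = lv, accuracy = acc,
          n_eval = nrow(sub))
      }
    }
  }
  dplyr::bind_rows(rows)
}
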