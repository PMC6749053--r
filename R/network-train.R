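#' Training configuration for the ConvNet
#'
#' The reference regime is stochastic gradient descent with a learning rate
#' held constant across epochs (default `1e-4`), mini-batches of approximately
#' 5% of the dataset (rounded up) reshuffled every epoch, and a random
#' 80/20 train/validation split repeated `n_repeats` times with averaged
#' statistics.  At desk scale (hundreds of images, tens of epochs) a larger
#' constant learning rate converges in far fewer iterations and can be set
#' here; the rate is never decayed.
#'
#' @param learning_rate Constant SGD learning rate.
#' @param minibatch_fraction Mini-batch size as a fraction of the training
#'   set; the size used is `ceiling(fraction * n)`.
#' @param val_fraction Fraction of images held out for validation.
#' @param n_repeats Number of independent random splits to train.
#' @param max_epochs Maximum number of epochs per fit.
#' @param shuffle_each_epoch Reshuffle mini-batch composition every epoch.
#' @param bn_momentum Momentum of the batch-norm running statistics.
#' @param target_val_accuracy Optional early-stopping target: training stops
#'   once validation accuracy reaches this value.
#' @param seed Integer seed controlling splits, weight initialization and
#'   shuffling.
#' @return A list of class `slc_training_config`.
#' @export
training_config <- function(learning_rate = 1e-4,
                            minibatch_fraction = 0.05,
                            val_fraction = 0.2,
                            n_repeats = 10L,
                            max_epochs = 30L,
                            shuffle_each_epoch = TRUE,
                            bn_momentum = 0.1,
                            target_val_accuracy = NULL,
                            seed = 1L) {
  if (minibatch_fraction <= 0 || minibatch_fraction >= 1) {
    stop_bad_arg("`minibatch_fraction` must lie in (0, 1)")
  }
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop_bad_arg("`val_fraction` must lie in (0, 1)")
  }
  if (learning_rate <= 0) stop_bad_arg("`learning_rate` must be positive")
  structure(
    list(
      learning_rate = learning_rate,
      minibatch_fraction = minibatch_fraction,
      val_fraction = val_fraction,
      n_repeats = check_positive_int(n_repeats, "n_repeats"),
      max_epochs = check_positive_int(max_epochs, "max_epochs"),
      shuffle_each_epoch = isTRUE(shuffle_each_epoch),
      bn_momentum = bn_momentum,
      target_val_accuracy = target_val_accuracy,
      seed = as.integer(seed)
    ),
    class = "slc_training_config"
  )
}

#' Binomial confidence interval on the classification error
#'
#' Computes `epsilon +/- c * sqrt(epsilon * (1 - epsilon) / n)` with the
#' endpoints clipped to `[0, 1]`; `c = 1.96` gives the 95% interval.
#'
#' @param epsilon Classification error in `[0, 1]`.
#' @param n Validation-set size (positive integer).
#' @param c Normal quantile multiplier (default 1.96).
#' @return Named numeric vector with `lo` and `hi`.
#' @examples
#' error_confidence_interval(0.5, 100) # 0.402 .. 0.598
#' @export
error_confidence_interval <- function(epsilon, n, c = 1.96) {
  n <- check_positive_int(n, "n")
  if (!is.finite(epsilon) || epsilon < 0 || epsilon > 1) {
    stop_bad_arg("`epsilon` must lie in [0, 1]")
  }
  half <- c * sqrt(epsilon * (1 - epsilon) / n)
  c(lo = max(0, epsilon - half), hi = min(1, epsilon + half))
}

# Fit one network on explicit train/validation index sets.  `images` is a
# (side^2) x N matrix, `labels` integer classes 1..K.  Consumes the caller's
# RNG stream (shuffling, initialization).
fit_network <- function(images, labels, spec, config,
                        train_idx, val_idx, verbose = FALSE) {
  side <- spec$input_shape[1]
  params <- init_network_params(spec)
  run_stats <- init_run_stats(spec)
  n_train <- length(train_idx)
  batch_size <- ceiling(config$minibatch_fraction * n_train)

  history <- vector("list", config$max_epochs)
  target <- config$target_val_accuracy
  train_imgs <- images[, train_idx, drop = FALSE]
  train_lab <- labels[train_idx]
  val_imgs <- if (length(val_idx)) images[, val_idx, drop = FALSE]
  val_lab <- labels[val_idx]

  for (epoch in seq_len(config$max_epochs)) {
    ord <- if (config$shuffle_each_epoch) sample.int(n_train) else seq_len(n_train)
    res <- cnn_train_epoch(train_imgs, train_lab, params, run_stats,
                           config$learning_rate, ord, batch_size,
                           config$bn_momentum, side)
    params <- res$params
    # re-estimate batch-norm statistics under the current weights; the
    # exponential running averages lag at short-schedule learning rates
    bn_n <- min(128L, n_train)
    run_stats <- cnn_update_bn(train_imgs[, seq_len(bn_n), drop = FALSE],
                               params, res$run_stats, side,
                               chunk = max(8L, batch_size))

    val_acc <- val_loss <- NA_real_
    if (length(val_idx)) {
      fwd <- cnn_forward(val_imgs, params, run_stats, side)
      pred <- max.col(fwd$probs, ties.method = "first")
      val_acc <- mean(pred == val_lab)
      p_true <- fwd$probs[cbind(seq_along(val_lab), val_lab)]
      val_loss <- -mean(log(pmax(p_true, 1e-12)))
    }
    history[[epoch]] <- tibble(
      epoch = epoch, train_loss = res$loss, train_accuracy = res$accuracy,
      val_loss = val_loss, val_accuracy = val_acc
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.3f/%.3f  val %.3f/%.3f",
                      epoch, res$loss, res$accuracy, val_loss, val_acc))
    }
    if (!is.null(target) && is.finite(val_acc) && val_acc >= target) break
  }

  structure(
    list(
      spec = spec,
      params = params,
      run_stats = run_stats,
      history = dplyr::bind_rows(history[!vapply(history, is.null, logical(1))]),
      input_side = side,
      config = config
    ),
    class = "slc_model"
  )
}

#' Train the cell-type classification ConvNet
#'
#' Runs `n_repeats` independent fits, each on a fresh stratified random
#' train/validation split (default 80/20), and reports per-repeat training
#' histories plus a summary with the binomial confidence interval on the
#' validation error.
#'
#' @param data A tibble with a list-column of square grayscale image matrices
#'   and a label column.
#' @param label_col,image_col Column names for labels and images.
#' @param config A [training_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `slc_model_set`: `models` (list of fitted
#'   `slc_model`), `summary` (one row per repeat with final accuracies and the
#'   95% CI on validation error), `classes`, and `config`.  [tidy()] returns
#'   the stacked per-epoch histories, [glance()] the across-repeat means.
#' @export
train_classifier <- function(data, label_col = "cell_type",
                             config = training_config(),
                             image_col = "image", verbose = FALSE) {
  labels_raw <- data[[label_col]]
  if (is.null(labels_raw)) stop_bad_arg("column `", label_col, "` not found")
  labels_f <- factor(labels_raw)
  if (nlevels(labels_f) < 2) {
    stop_bad_arg("training requires at least 2 classes, got ", nlevels(labels_f))
  }
  side <- nrow(data[[image_col]][[1]])
  images <- images_to_matrix(data[[image_col]], side)
  labels <- as.integer(labels_f)
  spec <- build_network_spec(nlevels(labels_f), input_side = side)
  n <- length(labels)

  reps <- purrr::map(seq_len(config$n_repeats), function(rep) {
    withr::with_seed(config$seed + rep - 1L, {
      val_idx <- unlist(lapply(split(seq_len(n), labels), function(ix) {
        sample(ix, max(1L, round(config$val_fraction * length(ix))))
      }), use.names = FALSE)
      train_idx <- setdiff(seq_len(n), val_idx)
      model <- fit_network(images, labels, spec, config, train_idx, val_idx,
                           verbose = verbose)
      model$classes <- levels(labels_f)
      last <- model$history[nrow(model$history), ]
      ci <- error_confidence_interval(1 - last$val_accuracy, length(val_idx))
      list(model = model,
           summary = tibble(
             repeat_id = rep,
             epochs = last$epoch,
             train_accuracy = last$train_accuracy,
             val_accuracy = last$val_accuracy,
             val_n = length(val_idx),
             error_ci_lo = ci[["lo"]],
             error_ci_hi = ci[["hi"]]
           ))
    })
  })

  structure(
    list(
      models = purrr::map(reps, "model"),
      summary = dplyr::bind_rows(purrr::map(reps, "summary")),
      classes = levels(labels_f),
      config = config
    ),
    class = "slc_model_set"
  )
}

#' @export
print.slc_model_set <- function(x, ...) {
  cat("<slc_model_set> ", length(x$models), " repeat(s), classes: ",
      paste(x$classes, collapse = ", "), "\n", sep = "")
  cat(sprintf("  mean validation accuracy %.3f (train %.3f)\n",
              mean(x$summary$val_accuracy), mean(x$summary$train_accuracy)))
  invisible(x)
}

#' @export
print.slc_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<slc_model> ", x$spec$n_classes, "-class ConvNet, input side ",
      x$input_side, "\n", sep = "")
  cat(sprintf("  %d epoch(s); final train acc %.3f, val acc %.3f\n",
              last$epoch, last$train_accuracy, last$val_accuracy))
  invisible(x)
}

#' @rdname train_classifier
#' @param x An `slc_model_set` or `slc_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.slc_model_set <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$models, function(m, i) {
    dplyr::mutate(m$history, repeat_id = i, .before = 1)
  }))
}

#' @rdname train_classifier
#' @exportS3Method generics::glance
glance.slc_model_set <- function(x, ...) {
  tibble(
    n_repeats = length(x$models),
    mean_train_accuracy = mean(x$summary$train_accuracy),
    mean_val_accuracy = mean(x$summary$val_accuracy),
    mean_error_ci_lo = mean(x$summary$error_ci_lo),
    mean_error_ci_hi = mean(x$summary$error_ci_hi)
  )
}

#' @exportS3Method generics::tidy
tidy.slc_model <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.slc_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(epochs = last$epoch, train_accuracy = last$train_accuracy,
         val_accuracy = last$val_accuracy)
}

#' Predict classes, probabilities or LCA features for new images
#'
#' @param object A fitted `slc_model`.
#' @param newdata A tibble with an image list-column, or a plain list of image
#'   matrices.
#' @param type `"class"`, `"prob"` or `"lca"`.
#' @param image_col Image column name when `newdata` is a tibble.
#' @param ... Unused.
#' @return A character vector of class labels, an N x K probability matrix,
#'   or an N x 288 LCA matrix.
#' @export
predict.slc_model <- function(object, newdata, type = c("class", "prob", "lca"),
                              image_col = "image", ...) {
  type <- match.arg(type)
  images <- if (is.data.frame(newdata)) newdata[[image_col]] else newdata
  if (length(images) == 0) stop_bad_arg("no images to predict on")
  mat <- images_to_matrix(images, object$input_side)
  fwd <- cnn_forward(mat, object$params, object$run_stats, object$input_side)
  switch(type,
    prob = fwd$probs,
    lca = fwd$lca,
    class = {
      idx <- max.col(fwd$probs, ties.method = "first")
      if (!is.null(object$classes)) object$classes[idx] else idx
    }
  )
}

#' Evaluate a fitted model on a labelled dataset
#'
#' @param model A fitted `slc_model`.
#' @param data A tibble with image and label columns.
#' @param label_col,image_col Column names.
#' @return A list of class `slc_evaluation`: `accuracy`, `n`, the 95%
#'   confidence interval on the error, and a `counts` tibble of
#'   truth x prediction.
#' @export
evaluate <- function(model, data, label_col = "cell_type", image_col = "image") {
  if (nrow(data) == 0) stop_bad_arg("dataset is empty")
  truth <- data[[label_col]]
  if (is.null(truth) || anyNA(truth)) stop_bad_arg("dataset labels are missing")
  pred <- predict(model, data, type = "class", image_col = image_col)
  acc <- mean(as.character(pred) == as.character(truth))
  ci <- error_confidence_interval(1 - acc, nrow(data))
  counts <- dplyr::count(tibble(truth = as.character(truth),
                                prediction = as.character(pred)),
                         .data$truth, .data$prediction)
  structure(
    list(accuracy = acc, n = nrow(data),
         error = 1 - acc, error_ci = ci, counts = counts),
    class = "slc_evaluation"
  )
}

#' @export
print.slc_evaluation <- function(x, ...) {
  cat(sprintf("<slc_evaluation> accuracy %.3f on %d cells; error %.3f (95%% CI %.3f-%.3f)\n",
              x$accuracy, x$n, x$error, x$error_ci[["lo"]], x$error_ci[["hi"]]))
  invisible(x)
}

#' Score mixed-population frames cell by cell
#'
#' Crops each annotated cell center from the frame, quantile-normalizes the
#' crop to the model's reference distribution, classifies it, and reports the
#' per-frame accuracy (fraction of correctly typed crops) together with the
#' mean over frames.  Frames without any crop center are skipped with a
#' message.
#'
#' @param model A fitted `slc_model` (2-class cell-type network).
#' @param frames A list of [render_mixed_frame()] objects (or a single one).
#' @param ref A [reference_distribution()] used to normalize each crop; when
#'   `NULL` the model's stored reference is used.
#' @return A list of class `slc_mixed_eval` with `per_frame` (tibble: frame,
#'   n_cells, accuracy) and `overall` (mean per-frame accuracy).
#' @export
classify_mixed_frames <- function(model, frames, ref = NULL) {
  if (inherits(frames, "slc_mixed_frame")) frames <- list(frames)
  ref <- ref %||% model$reference
  if (is.null(ref)) stop_bad_arg("a reference distribution is required")
  rows <- purrr::imap(frames, function(fr, i) {
    centers <- fr$centers
    if (is.null(centers) || nrow(centers) == 0) {
      message("frame ", i, " has no crop centers; skipped")
      return(NULL)
    }
    crops <- purrr::map2(centers$row, centers$col, function(r, c) {
      quantile_normalize(crop_cell(fr$pixels, c(r, c)), ref)
    })
    pred <- predict(model, crops, type = "class")
    tibble(frame = i, n_cells = nrow(centers),
           accuracy = mean(as.character(pred) == as.character(centers$true_type)))
  })
  per_frame <- dplyr::bind_rows(rows)
  structure(
    list(per_frame = per_frame,
         overall = mean(per_frame$accuracy)),
    class = "slc_mixed_eval"
  )
}

#' @export
print.slc_mixed_eval <- function(x, ...) {
  cat(sprintf("<slc_mixed_eval> %d frame(s); overall per-frame accuracy %.3f\n",
              nrow(x$per_frame), x$overall))
  invisible(x)
}
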