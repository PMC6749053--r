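#' Build a self-label dataset: one class per cell
#'
#' Each cell is augmented into `policy$m` copies that together form that
#' cell's own class (labels `1 .. N` for `N` cells).  The copies are split
#' 80/20 into training and validation within every class; the original
#' (unaugmented) images are excluded from both splits and kept separately —
#' they are the inputs whose LCA features are later extracted.
#'
#' @param cells A tibble of cells (`cell_id` unique, `image` list-column);
#'   any `condition` column is carried along.
#' @param policy An [augmentation_policy()] with `m >= 2`.
#' @param ref A [reference_distribution()]; defaults to the first cell.  The
#'   originals are normalized to it as well.
#' @param val_fraction Fraction of each class held out for validation.
#' @param seed Seed for augmentation and splitting.
#' @return An object of class `slc_self_label_dataset`: `images` (tibble
#'   with `class`, `copy`, `split`, `image`), `originals` (normalized input
#'   cells), `n_cells`, `m`, `ref`.
#' @export
build_self_label_dataset <- function(cells, policy, ref = NULL,
                                     val_fraction = 0.2, seed = 1L) {
  if (anyDuplicated(cells$cell_id)) stop_bad_arg("`cell_id` values must be unique")
  if (nrow(cells) < 2) stop_bad_arg("self-label classification needs at least 2 cells")
  if (policy$m < 2) stop_bad_arg("`policy$m` must be >= 2 to split train/validation")
  ref <- ref %||% reference_distribution(cells$image[[1]])

  withr::with_seed(as.integer(seed), {
    aug <- augment_cells(cells, policy, ref = ref, seed = NULL)
    aug$class <- match(aug$cell_id, cells$cell_id)
    n_val <- max(1L, round(val_fraction * policy$m))
    aug <- dplyr::group_by(aug, .data$class)
    aug <- dplyr::mutate(aug,
      split = ifelse(.data$copy %in% sample(unique(.data$copy), n_val),
                     "validation", "train"))
    aug <- dplyr::ungroup(aug)

    originals <- cells
    originals$image <- purrr::map(cells$image, quantile_normalize, ref = ref)

    structure(
      list(images = aug, originals = originals, n_cells = nrow(cells),
           m = policy$m, ref = ref),
      class = "slc_self_label_dataset"
    )
  })
}

#' @export
print.slc_self_label_dataset <- function(x, ...) {
  cat("<slc_self_label_dataset> N = ", x$n_cells, " classes x m = ", x$m,
      " copies (", sum(x$images$split == "train"), " train / ",
      sum(x$images$split == "validation"), " validation; originals held out)\n",
      sep = "")
  invisible(x)
}

#' Train the Self-Label ConvNet
#'
#' Fits the N-class network (same six-block architecture, head widened to
#' one class per cell) on the augmented copies, using the dataset's built-in
#' stratified split.  Training stops when validation accuracy reaches
#' `config$target_val_accuracy` (default 0.98, standing in for "nearly
#' 100%") or after `max_epochs`; if the final accuracy does not exceed
#' twice chance level a diagnostic warning is emitted but the model is still
#' returned.
#'
#' @param dataset A [build_self_label_dataset()] result.
#' @param config A [training_config()]; `n_repeats` is ignored (the split is
#'   fixed by the dataset).
#' @param verbose Print per-epoch progress.
#' @return An `slc_model` whose `reference` is the dataset's reference
#'   distribution.
#' @export
train_self_label <- function(dataset, config = training_config(),
                             verbose = FALSE) {
  if (!inherits(dataset, "slc_self_label_dataset")) {
    stop_bad_arg("`dataset` must come from build_self_label_dataset()")
  }
  side <- nrow(dataset$images$image[[1]])
  spec <- build_network_spec(dataset$n_cells, input_side = side)
  images <- images_to_matrix(dataset$images$image, side)
  labels <- dataset$images$class
  train_idx <- which(dataset$images$split == "train")
  val_idx <- which(dataset$images$split == "validation")
  config$target_val_accuracy <- config$target_val_accuracy %||% 0.98

  model <- withr::with_seed(config$seed, {
    fit_network(images, labels, spec, config, train_idx, val_idx,
                verbose = verbose)
  })
  final_acc <- model$history$val_accuracy[nrow(model$history)]
  if (is.finite(final_acc) && final_acc <= 2 / dataset$n_cells) {
    warn(sprintf("self-label validation accuracy %.3f is not above chance (1/%d)",
                 final_acc, dataset$n_cells))
  }
  model$classes <- as.character(seq_len(dataset$n_cells))
  model$reference <- dataset$ref
  model
}

#' Extract the LCA feature vector of one image
#'
#' Forwards the image through the trained network and returns the pooled
#' activations of the last convolutional block flattened channel-major
#' (channel 1 map in column-major order, then channel 2, ...): a length-288
#' vector for the 224-pixel architecture.
#'
#' @param model A fitted `slc_model`.
#' @param image A square image matrix matching the model's input side.
#' @return A numeric vector of length `model$spec$lca_length`.
#' @export
extract_lca <- function(model, image) {
  check_image(image, model$input_side)
  as.vector(predict(model, list(image), type = "lca"))
}

#' LCA feature matrix for a set of cells
#'
#' Row i is [extract_lca()] of cell i; metadata (`cell_id`, `condition` if
#' present) is carried in leading columns, features in `f001 ... f288`.
#'
#' @param model A fitted `slc_model`.
#' @param cells A tibble with an `image` list-column (typically the held-out
#'   originals of the self-label dataset).
#' @return A tibble of class `slc_lca`.
#' @export
lca_matrix <- function(model, cells) {
  if (nrow(cells) == 0) stop_bad_arg("`cells` is empty")
  lca <- predict(model, cells, type = "lca")
  colnames(lca) <- sprintf("f%03d", seq_len(ncol(lca)))
  meta <- cells[, intersect(c("cell_id", "flask_id", "condition", "mode",
                              "mode_id", "cell_type"), names(cells))]
  out <- dplyr::bind_cols(meta, as_tibble(lca))
  class(out) <- c("slc_lca", class(out))
  out
}

# Extract the numeric feature matrix from an slc_lca tibble (or pass a
# plain matrix / data frame through).
lca_values <- function(x) {
  if (is.matrix(x)) return(x)
  fcols <- grep("^f[0-9]+$", names(x), value = TRUE)
  if (length(fcols) == 0) {
    fcols <- names(x)[vapply(x, is.numeric, logical(1))]
  }
  as.matrix(x[, fcols])
}
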