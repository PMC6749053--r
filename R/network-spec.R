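#' Declarative specification of the cell-type classification ConvNet
#'
#' Builds the six-block architecture used throughout the package: each block
#' is convolution (stride 1, "same" zero padding), batch normalization, ReLU,
#' and 2x2 average pooling with stride 2 (floor on odd sizes, so 7 pools to
#' 3).  Block 1 has 32 kernels of 11x11x1; blocks 2-6 have 32 kernels of
#' 5x5x32.  The head is a fully connected layer of shape
#' `n_classes` x 288 on the flattened pooled activations of block 6 (the LCA
#' feature vector, 32 maps of 3x3), followed by softmax.
#'
#' @param n_classes Number of output classes (>= 2).  2 for two-type
#'   classification; equal to the number of cells for the self-label network.
#' @param input_side Input image side length in pixels.  The reference
#'   architecture uses 224; smaller powers-of-two-friendly sizes (>= 64) are
#'   accepted for quick experiments and scale the LCA length accordingly.
#'
#' @return An object of class `slc_network_spec`: a list with `n_classes`,
#'   `input_shape`, a `blocks` tibble (kernel geometry and the conv/pool
#'   output shape of every block) and `lca_length` (288 for 224-pixel input).
#' @examples
#' spec <- build_network_spec(2)
#' spec$lca_length # 288
#' @export
build_network_spec <- function(n_classes, input_side = 224L) {
  n_classes <- check_positive_int(n_classes, "n_classes")
  if (n_classes < 2) stop_bad_arg("`n_classes` must be >= 2")
  input_side <- check_positive_int(input_side, "input_side")
  if (input_side < 64) stop_bad_arg("`input_side` must be >= 64 so that six pooling stages survive")

  kernel <- c(11L, rep(5L, 5L))
  in_ch <- c(1L, rep(32L, 5L))
  out_ch <- rep(32L, 6L)
  side <- input_side
  conv_side <- pool_side <- integer(6)
  for (b in 1:6) {
    conv_side[b] <- side          # stride-1 same-padded convolution
    side <- side %/% 2L           # 2x2 average pool, stride 2, floor
    pool_side[b] <- side
  }
  blocks <- tibble(
    block = 1:6,
    kernel = kernel,
    in_channels = in_ch,
    out_channels = out_ch,
    conv_side = conv_side,
    pool_side = pool_side
  )
  lca_length <- side^2 * 32L

  spec <- structure(
    list(
      n_classes = n_classes,
      input_shape = c(input_side, input_side, 1L),
      blocks = blocks,
      head_shape = c(n_classes, lca_length),
      lca_length = lca_length
    ),
    class = "slc_network_spec"
  )
  if (input_side == 224L) {
    stopifnot(identical(pool_side, c(112L, 56L, 28L, 14L, 7L, 3L)),
              lca_length == 288L)
  }
  spec
}

#' @export
print.slc_network_spec <- function(x, ...) {
  cat("<slc_network_spec> ", x$n_classes, "-class ConvNet, input ",
      paste(x$input_shape, collapse = "x"), "\n", sep = "")
  cat("  6 blocks of conv/batch-norm/ReLU/2x2 average pool\n")
  for (b in seq_len(nrow(x$blocks))) {
    r <- x$blocks[b, ]
    cat(sprintf("  block %d: conv %dx%dx%dx%d -> %dx%dx%d, pool -> %dx%dx%d\n",
                r$block, r$kernel, r$kernel, r$in_channels, r$out_channels,
                r$conv_side, r$conv_side, r$out_channels,
                r$pool_side, r$pool_side, r$out_channels))
  }
  cat(sprintf("  head: fully connected %d x %d + softmax (LCA length %d)\n",
              x$head_shape[1], x$head_shape[2], x$lca_length))
  invisible(x)
}

# He-style fan-in-scaled random initialization; batch-norm scale 1, offset 0.
init_network_params <- function(spec, seed = NULL) {
  with_seed_if(seed, {
    conv <- purrr::pmap(spec$blocks, function(block, kernel, in_channels,
                                              out_channels, ...) {
      fan_in <- kernel^2 * in_channels
      list(
        W = array(rnorm(fan_in * out_channels, sd = sqrt(2 / fan_in)),
                  dim = c(kernel, kernel, in_channels, out_channels)),
        b = numeric(out_channels),
        gamma = rep(1, out_channels),
        beta = numeric(out_channels)
      )
    })
    fc <- list(
      W = matrix(rnorm(spec$n_classes * spec$lca_length,
                       sd = sqrt(1 / spec$lca_length)),
                 nrow = spec$n_classes),
      b = numeric(spec$n_classes)
    )
    list(conv = conv, fc = fc)
  })
}

init_run_stats <- function(spec) {
  purrr::map(seq_len(nrow(spec$blocks)), function(b) {
    list(mean = numeric(spec$blocks$out_channels[b]),
         var = rep(1, spec$blocks$out_channels[b]))
  })
}

#' Forward a probe image and report every layer's output shape
#'
#' Propagates a probe input through a freshly initialized (or supplied)
#' network and records the actual dimensions of each convolution and pooling
#' output, plus the flattened LCA length.  Construction fails if any computed
#' shape disagrees with the declared architecture.
#'
#' @param spec A [build_network_spec()] object, or a fitted `slc_model` (its
#'   own weights are then probed).
#' @param probe Optional probe image (matrix of the spec's input side); by
#'   default a deterministic intensity ramp.
#' @return A tibble with one row per layer (`block`, `layer`, `height`,
#'   `width`, `channels`) carrying the LCA length as attribute `lca_length`.
#' @examples
#' shapes <- activation_shapes(build_network_spec(2))
#' subset(shapes, layer == "pool")$height # 112 56 28 14 7 3
#' @export
activation_shapes <- function(spec, probe = NULL) {
  if (inherits(spec, "slc_model")) {
    params <- spec$params
    run_stats <- spec$run_stats
    side <- spec$input_side
    spec <- spec$spec
  } else if (inherits(spec, "slc_network_spec")) {
    params <- init_network_params(spec, seed = 1L)
    run_stats <- init_run_stats(spec)
    side <- spec$input_shape[1]
  } else {
    stop_bad_arg("`spec` must be an slc_network_spec or slc_model")
  }
  if (is.null(probe)) {
    probe <- matrix(seq(0, 1, length.out = side^2), nrow = side)
  }
  check_image(probe, side, "probe")
  tr <- cnn_activation_trace(probe, params, run_stats, side)

  rows <- purrr::imap(tr$stages, function(st, b) {
    tibble(
      block = as.integer(b),
      layer = c("conv", "pool"),
      height = c(st$conv[1], st$pool[1]),
      width = c(st$conv[2], st$pool[2]),
      channels = c(st$conv[3], st$pool[3])
    )
  })
  out <- dplyr::bind_rows(rows)

  expected <- spec$blocks
  got_conv <- out[out$layer == "conv", ]
  got_pool <- out[out$layer == "pool", ]
  if (!all(got_conv$height == expected$conv_side) ||
      !all(got_pool$height == expected$pool_side) ||
      tr$lca_length != spec$lca_length) {
    abort("forward-propagated activation shapes disagree with the declared architecture",
          class = "cellslc_construction_error")
  }
  attr(out, "lca_length") <- tr$lca_length
  out
}
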