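test_that("the network spec matches the declared six-block architecture", {
  spec <- build_network_spec(2)
  expect_equal(spec$head_shape, c(2L, 288L))
  expect_equal(spec$lca_length, 288L)
  expect_equal(spec$blocks$kernel, c(11L, rep(5L, 5)))
  expect_equal(spec$blocks$in_channels, c(1L, rep(32L, 5)))
  expect_equal(spec$blocks$pool_side, c(112L, 56L, 28L, 14L, 7L, 3L))

  wide <- build_network_spec(2208)
  expect_equal(wide$head_shape, c(2208L, 288L))

  expect_error(build_network_spec(1), class = "cellslc_argument_error")
})

test_that("forward-propagated activation shapes reproduce the ladder", {
  shapes <- activation_shapes(build_network_spec(2))
  conv <- shapes[shapes$layer == "conv", ]
  pool <- shapes[shapes$layer == "pool", ]
  expect_equal(conv$height, c(224L, 112L, 56L, 28L, 14L, 7L))
  expect_equal(pool$height, c(112L, 56L, 28L, 14L, 7L, 3L))
  expect_true(all(shapes$channels == 32L))
  # pooling an odd 7-pixel grid floors to 3
  expect_equal(pool$height[6], 3L)
  expect_equal(attr(shapes, "lca_length"), 288L)
})

test_that("the error confidence interval matches the closed form", {
  expect_equal(error_confidence_interval(0, 100), c(lo = 0, hi = 0))
  expect_equal(error_confidence_interval(1, 50), c(lo = 1, hi = 1))

  ci <- error_confidence_interval(0.5, 100)
  expect_equal(unname(ci), c(0.402, 0.598), tolerance = 1e-3)

  # 3 errors in 100: half-width 0.0334; the lower end clips at 0
  ci3 <- error_confidence_interval(0.03, 100)
  expect_equal(ci3[["hi"]] - 0.03, 1.96 * sqrt(0.03 * 0.97 / 100),
               tolerance = 1e-12)
  expect_equal(1.96 * sqrt(0.03 * 0.97 / 100), 0.0334, tolerance = 2e-3)
  expect_equal(ci3[["lo"]], 0)

  # width shrinks with n, maximal at epsilon = 0.5
  w <- function(e, n) diff(error_confidence_interval(e, n))
  expect_true(all(diff(vapply(c(10, 40, 160, 640), function(n) w(0.5, n),
                              numeric(1))) < 0))
  expect_true(all(w(0.5, 100) >= vapply(c(0.1, 0.3, 0.7, 0.95),
                                        function(e) w(e, 100), numeric(1))))

  expect_error(error_confidence_interval(0.5, 0), class = "cellslc_argument_error")
  expect_error(error_confidence_interval(1.2, 10), class = "cellslc_argument_error")
})

test_that("backpropagated gradients agree with finite differences", {
  side <- 64
  spec <- build_network_spec(3, input_side = side)
  params <- cellslc:::init_network_params(spec, seed = 7)
  run <- cellslc:::init_run_stats(spec)
  withr::with_seed(42, {
    imgs <- matrix(runif(side^2 * 4), nrow = side^2)
  })
  labs <- c(1L, 2L, 3L, 1L)
  lr <- 1e-3
  res <- cellslc:::cnn_train_epoch(imgs, labs, params, run, lr, 1:4, 4L, 0.1, side)

  check <- function(path, idx, eps = 5e-3) {
    leaf <- function(p) { for (k in path) p <- p[[k]]; p[idx] }
    poke <- function(p, v) {
      if (length(path) == 3) p[[path[[1]]]][[path[[2]]]][[path[[3]]]][idx] <- v
      else p[[path[[1]]]][[path[[2]]]][idx] <- v
      p
    }
    g_an <- (leaf(params) - leaf(res$params)) / lr
    lp <- cellslc:::cnn_batch_loss(imgs, labs, poke(params, leaf(params) + eps), run, side)
    lm <- cellslc:::cnn_batch_loss(imgs, labs, poke(params, leaf(params) - eps), run, side)
    g_num <- (lp - lm) / (2 * eps)
    # single-precision finite differences are noisy; allow 12% + floor
    expect_lt(abs(g_an - g_num), 0.12 * max(abs(g_an), abs(g_num)) + 2e-3)
    expect_gt(abs(g_an), 0)
  }
  check(list("fc", "W"), 10)
  check(list("fc", "b"), 2)
  check(list("conv", 2L, "W"), 100)
  check(list("conv", 3L, "beta"), 10)
  check(list("conv", 6L, "gamma"), 20)
})

test_that("training memorizes separable toy data and validation follows", {
  fit <- fx_toy_model_set()
  expect_gte(max(fit$summary$train_accuracy), 0.9)
  expect_gte(fit$summary$val_accuracy[1], 0.9)
  expect_equal(fit$summary$val_n[1], 8)

  h <- tidy(fit)
  expect_true(all(c("repeat_id", "epoch", "train_loss", "val_accuracy") %in% names(h)))
  g <- glance(fit)
  expect_equal(g$n_repeats, 1)
})

test_that("single-class training data is rejected", {
  cells <- toy_cells(3)
  cells$cell_type <- "A"
  expect_error(train_classifier(cells), class = "cellslc_argument_error")
})

test_that("evaluation reports accuracy, counts and the error CI", {
  # a degenerate model that always predicts the first class
  model <- untrained_model(2, side = 64)
  model$params$fc$W[] <- 0
  model$params$fc$b <- c(10, 0)
  model$classes <- c("A", "B")
  cells <- toy_cells(5)
  ev <- evaluate(model, cells)
  expect_equal(ev$accuracy, 0.5)
  expect_equal(ev$n, 10)
  expect_equal(unname(ev$error_ci),
               unname(error_confidence_interval(0.5, 10)))
  expect_true(all(ev$counts$prediction == "A"))

  expect_error(evaluate(model, cells[0, ]), class = "cellslc_argument_error")
})

test_that("mixed-frame scoring is per-crop and skips empty frames", {
  lib <- fx_library()
  fr <- render_mixed_frame(lib, n_per_type = c(3, 2), seed = 8,
                           frame_dim = c(700L, 700L))
  ref <- reference_distribution(matrix(runif(224^2), 224))
  # oracle model: always predicts type 1
  model <- untrained_model(2, side = 224)
  model$params$fc$W[] <- 0
  model$params$fc$b <- c(10, 0)
  model$classes <- c("1", "2")
  empty <- structure(list(pixels = matrix(0.5, 700, 700),
                          truth_channel = matrix(0L, 700, 700),
                          centers = tibble::tibble(row = integer(),
                                                   col = integer(),
                                                   true_type = integer())),
                     class = "slc_mixed_frame")
  expect_message(res <- classify_mixed_frames(model, list(fr, empty), ref),
                 "no crop centers")
  expect_equal(nrow(res$per_frame), 1)
  expect_equal(res$per_frame$n_cells, 5)
  expect_equal(res$per_frame$accuracy, 3 / 5)  # the three type-1 cells
  expect_equal(res$overall, 3 / 5)
})
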