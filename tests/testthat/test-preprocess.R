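test_that("grayscale conversion is the unweighted channel mean", {
  z <- array(0, dim = c(4, 5, 3))
  expect_equal(to_grayscale(z), matrix(0, 4, 5))

  eq <- array(0.3, dim = c(4, 5, 3))
  expect_equal(to_grayscale(eq), matrix(0.3, 4, 5))

  px <- array(0, dim = c(2, 2, 3))
  px[1, 1, 1] <- 1
  expect_equal(to_grayscale(px)[1, 1], 1 / 3)
  expect_equal(to_grayscale(px)[2, 2], 0)

  expect_error(to_grayscale(array(0, dim = c(4, 5, 2))),
               class = "cellslc_argument_error")
})

test_that("cropping follows the half-open 224-window convention", {
  frame <- matrix(seq_len(1216 * 1616) / (1216 * 1616), 1216, 1616)
  crop <- crop_cell(frame, c(609, 809))   # 1-based center
  expect_equal(dim(crop), c(224, 224))
  expect_equal(crop, frame[497:720, 697:920])

  expect_error(crop_cell(frame, c(10, 10)), class = "cellslc_crop_rejection")
  expect_error(crop_cell(frame, c(1216, 808)), class = "cellslc_crop_rejection")

  small <- matrix(runif(224^2), 224, 224)
  expect_identical(crop_cell(small, c(113, 113)), small)
})

test_that("quantile normalization maps ranks onto the reference exactly", {
  # toy case: scan-order values 4,1,3,2 onto reference 10,20,30,40
  img <- matrix(c(4, 1, 3, 2), 2, 2)
  ref <- reference_distribution(c(10, 20, 30, 40))
  expect_equal(quantile_normalize(img, ref), matrix(c(40, 10, 30, 20), 2, 2))

  # constant image: ties broken by scan order
  const <- matrix(5, 2, 2)
  expect_equal(quantile_normalize(const, ref), matrix(c(10, 20, 30, 40), 2, 2))

  # image already matching the reference is unchanged; idempotence is exact
  x <- matrix(runif(64), 8, 8)
  refx <- reference_distribution(x)
  expect_identical(quantile_normalize(x, refx), x)
  y <- matrix(runif(64), 8, 8)
  once <- quantile_normalize(y, refx)
  expect_identical(quantile_normalize(once, refx), once)
  expect_identical(sort(as.vector(once)), refx$sorted_values)

  # rank order preserved (no ties)
  expect_equal(cor(as.vector(y), as.vector(once), method = "spearman"), 1)

  expect_error(quantile_normalize(matrix(0, 3, 3), ref),
               class = "cellslc_argument_error")
})

test_that("synthesized background is zero-mean, smooth, at the target SD", {
  z <- synthesize_background(c(50, 60), 0)
  expect_equal(z, matrix(0, 50, 60))

  sds <- vapply(1:10, function(s) {
    sd(synthesize_background(c(224, 224), 0.05, seed = s))
  }, numeric(1))
  expect_true(all(sds >= 0.03 & sds <= 0.07))
  f <- synthesize_background(c(100, 100), 0.05, seed = 1)
  expect_lt(abs(mean(f)), 1e-10)
  expect_identical(f, synthesize_background(c(100, 100), 0.05, seed = 1))

  # smoothness: neighboring pixels are strongly correlated
  expect_gt(cor(as.vector(f[-1, ]), as.vector(f[-100, ])), 0.9)

  expect_error(synthesize_background(c(10, 10), -0.1),
               class = "cellslc_argument_error")
})

test_that("rotation by 180 degrees twice returns the image", {
  img <- matrix(runif(64^2), 64, 64)
  r1 <- cellslc:::rotate_image(img, 180)
  r2 <- cellslc:::rotate_image(r1, 180)
  expect_lt(max(abs(r2 - img)), 0.02)
})

test_that("augmentation yields m renormalized copies; identity policy is exact", {
  lib <- fx_library()
  cell <- render_cell(lib[1, ], seed = 2)
  ref <- reference_distribution(cell$image)
  norm_img <- quantile_normalize(cell$image, ref)

  id_policy <- augmentation_policy(m = 1, rotation_range = c(0, 0),
                                   max_translation_px = 0,
                                   background_amplitude = 0)
  out <- augment(norm_img, id_policy, ref, seed = 1)
  expect_length(out, 1)
  expect_identical(out[[1]], norm_img)

  pol <- augmentation_policy(m = 7, max_translation_px = 5,
                             background_amplitude = 0.03)
  copies <- augment(norm_img, pol, ref, seed = 3)
  expect_length(copies, 7)
  # every copy carries the reference intensity multiset exactly
  for (cp in copies) {
    expect_identical(sort(as.vector(cp)), ref$sorted_values)
  }
  # and none equals the original (the original is excluded)
  expect_false(any(vapply(copies, identical, logical(1), norm_img)))

  expect_error(augmentation_policy(m = 0), class = "cellslc_argument_error")
  expect_error(augmentation_policy(max_translation_px = 150),
               class = "cellslc_argument_error")
})

test_that("augment_cells returns one labelled row per copy", {
  lib <- fx_library()
  cells <- generate_flask(flask_design("A", 1, "low", 3, c(1, 0, 0), seed = 1), lib)
  pol <- augmentation_policy(m = 4)
  aug <- augment_cells(cells, pol, seed = 2)
  expect_equal(nrow(aug), 12)
  expect_equal(as.integer(table(aug$cell_id)), rep(4L, 3))
  expect_true(all(aug$copy %in% 1:4))
  aug2 <- augment_cells(cells, pol, seed = 2)
  expect_identical(aug$image[[5]], aug2$image[[5]])
})
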