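test_that("k-means matches the exhaustive-partition oracle on small instances", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(6, 0, 0.3), 3, 2),
               matrix(rnorm(6, 4, 0.3), 3, 2))
  })
  fit <- slc_kmeans(X, 2, seed = 1)
  oracle <- brute_force_kmeans(X, 2)
  expect_equal(fit$tot_withinss, oracle$ss, tolerance = 1e-8)

  # random small instances: restarts + k-means++ reach the global optimum
  for (s in 1:4) {
    withr::with_seed(100 + s, {
      Y <- matrix(rnorm(14), 7, 2)
    })
    f <- slc_kmeans(Y, 3, seed = s, restarts = 20)
    o <- brute_force_kmeans(Y, 3)
    expect_lt(f$tot_withinss, o$ss + 1e-6)
  }
})

test_that("degenerate k values behave as documented", {
  withr::with_seed(2, X <- matrix(rnorm(20), 10, 2))
  one <- slc_kmeans(X, 1)
  expect_equal(as.vector(one$centers), colMeans(X))
  expect_true(is.na(one$mean_silhouette))

  all_k <- slc_kmeans(X, 10, seed = 3, restarts = 3)
  expect_equal(all_k$within_distance_sum, 0, tolerance = 1e-9)

  expect_error(slc_kmeans(X, 11), class = "cellslc_argument_error")
  expect_error(slc_kmeans(X[1, , drop = FALSE], 1),
               class = "cellslc_argument_error")

  # determinism
  f1 <- slc_kmeans(X, 3, seed = 9)
  f2 <- slc_kmeans(X, 3, seed = 9)
  expect_identical(f1$labels, f2$labels)
})

test_that("scan_k selects the planted blob count and survives duplicates", {
  withr::with_seed(7, {
    X <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
               matrix(rnorm(40, 6, 0.5), 20, 2),
               cbind(rnorm(20, 3, 0.5), rnorm(20, 6, 0.5)))
  })
  ks <- scan_k(X, 2, 8, seed = 1, restarts = 5)
  expect_equal(ks$selected_k, 3)
  expect_equal(ks$scan$k, 2:8)
  # elbow curve decreases overall
  expect_lt(ks$scan$within_distance_sum[7], ks$scan$within_distance_sum[1])

  # duplicated single point: no crash, degenerate silhouettes
  dup <- matrix(1, 6, 2)
  expect_no_error(ks_dup <- scan_k(dup, 2, 3, seed = 1, restarts = 2))
  expect_true(all(is.na(ks_dup$scan$silhouette)))

  single <- scan_k(X, 2, 2, seed = 1)
  expect_equal(single$selected_k, 2)

  expect_error(scan_k(X, 5, 2), class = "cellslc_argument_error")
})

test_that("ordered distance matrices expose block structure", {
  same <- matrix(1, 4, 3)
  D0 <- ordered_distance_matrix(same, c(1, 2, 1, 2))
  expect_true(all(D0 == 0))

  withr::with_seed(3, {
    X <- rbind(matrix(rnorm(20, 0, 0.4), 10, 2),
               matrix(rnorm(20, 5, 0.4), 10, 2))
  })
  labels <- rep(c(2, 1), each = 10)
  D <- ordered_distance_matrix(X, labels)
  expect_equal(dim(unclass(D)), c(20, 20))
  expect_true(isSymmetric(unclass(D)[1:20, 1:20]))
  expect_true(all(diag(unclass(D)) == 0))
  grp <- attr(D, "labels")
  within <- outer(grp, grp, "==") & upper.tri(D)
  between <- outer(grp, grp, "!=") & upper.tri(D)
  expect_lt(mean(D[within]), mean(D[between]))
})

test_that("the PCA baseline clusters rotated copies by orientation", {
  lib <- fx_library()
  base <- render_cell(lib[lib$mode_id == "T1.M2", ], seed = 6)$image
  rot <- cellslc:::rotate_image(base, 90)
  rot[is.na(rot)] <- median(base)
  jitter <- function(img, s) {
    withr::with_seed(s, pmax(pmin(img + matrix(rnorm(length(img), 0, 0.01),
                                               nrow(img)), 1), 0))
  }
  images <- list(jitter(base, 1), jitter(base, 2),
                 jitter(rot, 3), jitter(rot, 4))
  pb <- pca_baseline(images, n_components = 3, k = 2, seed = 2)
  expect_equal(pb$labels[1], pb$labels[2])
  expect_equal(pb$labels[3], pb$labels[4])
  expect_false(pb$labels[1] == pb$labels[3])

  # component scores are mean-centered
  expect_lt(max(abs(colMeans(pb$scores))), 1e-8)

  expect_error(pca_baseline(images, 0, 2), class = "cellslc_argument_error")
  expect_error(pca_baseline(images[1], 2, 2), class = "cellslc_argument_error")
})
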