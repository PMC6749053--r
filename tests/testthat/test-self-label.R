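test_that("self-label datasets have one class per cell with originals held out", {
  lib <- fx_library()
  cells <- generate_flask(flask_design("S", 1, "low", 10, c(1, 1, 1) / 3, seed = 1),
                          lib)
  pol <- augmentation_policy(m = 5)
  ds <- build_self_label_dataset(cells, pol, seed = 2)

  expect_equal(nrow(ds$images), 50)           # N x m
  expect_equal(ds$n_cells, 10)
  expect_equal(sort(unique(ds$images$class)), 1:10)
  per_class <- table(ds$images$class, ds$images$split)
  expect_true(all(per_class[, "train"] == 4))
  expect_true(all(per_class[, "validation"] == 1))

  # originals appear in neither split
  orig <- ds$originals$image[[1]]
  expect_false(any(vapply(ds$images$image, identical, logical(1), orig)))
  expect_equal(nrow(ds$originals), 10)

  dup <- cells
  dup$cell_id[2] <- dup$cell_id[1]
  expect_error(build_self_label_dataset(dup, pol), class = "cellslc_argument_error")
  expect_error(build_self_label_dataset(cells[1, ], pol),
               class = "cellslc_argument_error")
  expect_error(build_self_label_dataset(cells, augmentation_policy(m = 1)),
               class = "cellslc_argument_error")
})

test_that("LCA extraction returns deterministic finite length-288 vectors", {
  model <- untrained_model(3, side = 224)
  img <- matrix(runif(224^2), 224)
  v <- extract_lca(model, img)
  expect_length(v, 288)
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_lca(model, img))

  zero <- extract_lca(model, matrix(0, 224, 224))
  expect_true(all(is.finite(zero)))

  expect_error(extract_lca(model, matrix(0, 64, 64)),
               class = "cellslc_argument_error")
})

test_that("lca_matrix stacks per-cell rows in input order with metadata", {
  lib <- fx_library()
  cells <- generate_flask(flask_design("L", 1, "high", 3, c(1, 0, 0), seed = 4),
                          lib)
  model <- untrained_model(3, side = 224)
  lca <- lca_matrix(model, cells)
  expect_equal(dim(cellslc:::lca_values(lca)), c(3, 288))
  expect_equal(lca$cell_id, cells$cell_id)
  expect_equal(lca$condition, rep("high", 3))
  expect_equal(unname(cellslc:::lca_values(lca)[2, ]),
               extract_lca(model, cells$image[[2]]))
})
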