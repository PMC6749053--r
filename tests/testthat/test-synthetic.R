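test_that("phenotype library is deterministic, grouped, and type-separated", {
  lib1 <- make_phenotype_library(2, 3, seed = 7)
  lib2 <- make_phenotype_library(2, 3, seed = 7)
  expect_identical(lib1, lib2)
  expect_equal(nrow(lib1), 6)
  expect_equal(as.integer(table(lib1$type)), c(3L, 3L))

  expect_error(make_phenotype_library(0, 1, seed = 1), class = "cellslc_argument_error")
  expect_error(make_phenotype_library(2, -1, seed = 1), class = "cellslc_argument_error")

  # mean between-type parameter distance exceeds the within-type mode spread
  lib <- make_phenotype_library(2, 2, seed = 11)
  P <- as.matrix(lib[, c("body_radius_px", "eccentricity", "boundary_roughness",
                         "n_protrusions", "interior_texture_sd",
                         "intensity_contrast")])
  D <- as.matrix(dist(P))
  same <- outer(lib$type, lib$type, "==") & upper.tri(D)
  diff <- outer(lib$type, lib$type, "!=") & upper.tri(D)
  expect_gt(mean(D[diff]), mean(D[same]))
})

test_that("rendering is seed-reproducible and geometrically sound", {
  lib <- make_phenotype_library(1, 1, seed = 0)
  a <- render_cell(lib[1, ], seed = 42)
  b <- render_cell(lib[1, ], seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_equal(dim(a$image), c(224, 224))
  expect_true(all(a$image >= 0 & a$image <= 1))

  # smooth disk: mask area close to pi R^2, skeleton collapses (<= 2 endpoints)
  disk <- list(body_radius_px = 20, eccentricity = 0, boundary_roughness = 0,
               n_protrusions = 0L, interior_texture_sd = 0.02,
               intensity_contrast = 0.3)
  cell <- render_cell(disk, seed = 1)
  expect_lt(abs(sum(cell$mask) - pi * 20^2) / (pi * 20^2), 0.05)
  expect_lte(skeleton_endpoints(cell$mask), 2)

  # flat interior when texture and noise are off
  flat_opts <- render_options(background_amplitude = 0, sensor_noise_sd = 0,
                              granule_contrast_sd = 0)
  flat <- render_cell(modifyList(disk, list(interior_texture_sd = 0)),
                      opts = flat_opts, seed = 1)
  # strictly interior region (inside the edge roll-off)
  cc <- (224 + 1) / 2
  d2 <- outer(seq_len(224) - cc, seq_len(224) - cc,
              function(r, c) r^2 + c^2)
  interior <- d2 <= (20 - 4)^2
  expect_equal(sd(flat$image[interior]), 0)
  expect_equal(texture_sum_variance(flat$image, interior), 0)

  # an oversized phenotype is rejected
  expect_error(render_cell(modifyList(disk, list(body_radius_px = 120)), seed = 1),
               class = "cellslc_render_error")
})

test_that("protrusion count is recovered by the skeleton-endpoint oracle", {
  ph <- list(body_radius_px = 25, eccentricity = 0.1, boundary_roughness = 0.02,
             n_protrusions = 4L, interior_texture_sd = 0.03,
             intensity_contrast = 0.3)
  eps <- vapply(1:20, function(s) skeleton_endpoints(render_cell(ph, seed = s)$mask),
                integer(1))
  expect_true(all(abs(eps - 4) <= 1))
})

test_that("flask generation follows the mode mixture and batch structure", {
  lib <- fx_library()

  pure <- generate_flask(
    flask_design("F1", 1, "low", 50, c(1, 0, 0), seed = 3), lib,
    render = FALSE)
  expect_true(all(pure$mode == 1))

  big <- generate_flask(
    flask_design("F2", 1, "low", 1000, c(0.2, 0.8, 0), seed = 9), lib,
    render = FALSE)
  # binomial 3-sigma bound around 0.2 at n = 1000
  expect_lt(abs(mean(big$mode == 1) - 0.2), 0.04)

  # differing seeds: same schema, different images
  d1 <- generate_flask(flask_design("F3", 2, "high", 3, c(1, 0, 0) / 1, seed = 1), lib)
  d2 <- generate_flask(flask_design("F3", 2, "high", 3, c(1, 0, 0) / 1, seed = 2), lib)
  expect_identical(names(d1), names(d2))
  expect_false(identical(d1$image[[1]], d2$image[[1]]))

  expect_error(
    generate_flask(flask_design("F4", 1, "low", 5, c(0.5, 0.5), seed = 1), lib),
    class = "cellslc_argument_error")
})

test_that("mixed frames place non-overlapping cells with consistent truth", {
  lib <- fx_library()
  fr <- render_mixed_frame(lib, n_per_type = c(5, 5), seed = 21,
                           frame_dim = c(800L, 900L))
  expect_equal(dim(fr$pixels), c(800, 900))
  expect_equal(nrow(fr$centers), 10)
  expect_equal(sum(fr$centers$true_type == 1), 5)
  expect_true(all(fr$centers$row >= 113 & fr$centers$row <= 800 - 111))
  expect_true(all(fr$centers$col >= 113 & fr$centers$col <= 900 - 111))
  expect_setequal(unique(as.vector(fr$truth_channel)), c(0L, 1L, 2L))
  # every crop center sits on its own cell's truth pixels
  for (i in seq_len(nrow(fr$centers))) {
    patch <- fr$truth_channel[fr$centers$row[i] + (-3:3),
                              fr$centers$col[i] + (-3:3)]
    expect_true(any(patch == fr$centers$true_type[i]))
  }

  # majority-type and empty frames
  rich <- render_mixed_frame(lib, n_per_type = c(9, 1), seed = 5,
                             frame_dim = c(800L, 900L))
  expect_equal(sum(rich$centers$true_type == 1), 9)
  empty <- render_mixed_frame(lib, n_per_type = c(0, 0), seed = 1,
                              frame_dim = c(400L, 400L))
  expect_equal(nrow(empty$centers), 0)
  expect_true(all(empty$truth_channel == 0))
})

test_that("cells and frames round-trip through 16-bit TIFF and CSV", {
  lib <- fx_library()
  cells <- generate_flask(flask_design("IO", 1, "low", 2, c(1, 0, 0), seed = 1), lib)
  dir <- withr::local_tempdir()
  write_cells(cells, dir)
  back <- read_cells(dir)
  expect_equal(back$cell_id, cells$cell_id)
  expect_lt(max(abs(back$image[[1]] - cells$image[[1]])), 1 / 65535 + 1e-9)
  expect_identical(back$mask[[1]], cells$mask[[1]])

  fr <- render_mixed_frame(lib, n_per_type = c(1, 1), seed = 3,
                           frame_dim = c(400L, 400L))
  path <- file.path(dir, "frame.tif")
  write_mixed_frame(fr, path)
  back_fr <- read_mixed_frame(path)
  expect_equal(back_fr$truth_channel, fr$truth_channel)
  expect_equal(back_fr$centers$true_type, fr$centers$true_type)
})
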