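# Core geometry: evaluate the star-convex body of a phenotype on a pixel
# grid.  The boundary is r(theta) = R * (1 + roughness harmonics + protrusion
# bumps), drawn in an ellipse frame with random orientation.  Returns the
# intensity increment over the background ("delta") and the binary mask;
# consumes the caller's RNG stream.
render_cell_body <- function(phenotype, opts = render_options()) {
  ph <- check_phenotype(phenotype)
  side <- opts$side
  R <- ph$body_radius_px
  q <- sqrt(1 - ph$eccentricity^2)
  a <- R / sqrt(q)                       # semi-axes, area ~ pi R^2
  b <- R * sqrt(q)

  # roughness harmonics (orders 3-6)
  nh <- 4L
  amp_c <- rnorm(nh, 0, ph$boundary_roughness / 2)
  amp_s <- rnorm(nh, 0, ph$boundary_roughness / 2)
  orders <- 3:6

  # protrusions at roughly equispaced angles with jitter
  np <- ph$n_protrusions
  if (np > 0) {
    ang <- (seq_len(np) - 1) * 2 * pi / np + runif(1, 0, 2 * pi) +
      runif(np, -0.25, 0.25) * 2 * pi / np
  } else {
    ang <- numeric(0)
  }
  phi <- runif(1, 0, 2 * pi)             # body orientation

  # reject phenotypes that cannot fit with a 10 px margin
  max_r <- max(a, b) * (1 + 2 * ph$boundary_roughness +
                          ifelse(np > 0, opts$protrusion_length, 0))
  if (max_r > side / 2 - 10) {
    abort(sprintf("cell of maximal radius %.1f px cannot fit a %d px window with 10 px margin",
                  max_r, side),
          class = "cellslc_render_error")
  }

  cc <- (side + 1) / 2
  ro <- rep(seq_len(side) - cc, times = side)
  co <- rep(seq_len(side) - cc, each = side)
  u <- (ro * cos(phi) + co * sin(phi)) / a
  v <- (-ro * sin(phi) + co * cos(phi)) / b
  rho <- sqrt(u^2 + v^2)                 # radius in units of R
  theta <- atan2(v, u)

  rfun <- rep(1, length(theta))
  for (h in seq_len(nh)) {
    rfun <- rfun + amp_c[h] * cos(orders[h] * theta) +
      amp_s[h] * sin(orders[h] * theta)
  }
  for (ak in ang) {
    d <- abs(((theta - ak + pi) %% (2 * pi)) - pi)
    rfun <- rfun + opts$protrusion_length * exp(-0.5 * (d / opts$protrusion_width)^2)
  }

  # signed distance from the boundary in pixels (positive inside)
  sdist <- (rfun - rho) * sqrt(a * b)
  mask <- matrix(sdist > 0, side, side)
  edge <- clip01(matrix(sdist / opts$edge_softness, side, side))

  delta <- ph$intensity_contrast * edge
  if (ph$interior_texture_sd > 0) {
    tex <- smooth_random_field(side, side, opts$texture_correlation)
    tex <- (tex - mean(tex)) / sd(tex) * ph$interior_texture_sd
    delta <- delta + tex * edge
  }

  # organelle-like granules: their number, sizes and contrasts form a
  # rotation-independent per-cell signature
  ng <- opts$granule_count_range
  n_gran <- if (ng[2] > ng[1]) sample(ng[1]:ng[2], 1) else ng[1]
  if (n_gran > 0 && opts$granule_contrast_sd > 0) {
    for (g in seq_len(n_gran)) {
      grho <- sqrt(runif(1)) * 0.55
      gth <- runif(1, 0, 2 * pi)
      gr <- runif(1, opts$granule_radius_range[1], opts$granule_radius_range[2])
      gamp <- rnorm(1, 0, opts$granule_contrast_sd)
      # granule center in image coordinates (invert the ellipse transform)
      gu <- grho * cos(gth) * a
      gv <- grho * sin(gth) * b
      gro <- gu * cos(phi) - gv * sin(phi)
      gco <- gu * sin(phi) + gv * cos(phi)
      gd2 <- (ro - gro)^2 + (co - gco)^2
      delta <- delta + gamp * exp(-gd2 / (2 * gr^2)) * edge
    }
  }
  list(delta = delta, mask = mask)
}

#' Render one synthetic single-cell image
#'
#' Draws the phenotype's star-convex body on a noisy substrate background:
#' flat level + smooth correlated field + i.i.d. sensor noise, with the cell
#' added as a contrast offset plus interior texture, and intensities clipped
#' to `[0, 1]`.  The mask marks the cell body (a single connected component
#' for the library's parameter ranges).
#'
#' @param phenotype One row of a [make_phenotype_library()] (or an equivalent
#'   named list).
#' @param opts [render_options()].
#' @param seed Optional seed; with a fixed seed the rendering is
#'   bit-reproducible.
#' @return A list with `image` (side x side matrix in `[0, 1]`), `mask`
#'   (logical matrix), and `phenotype`.
#' @examples
#' lib <- make_phenotype_library(1, 1, seed = 1)
#' cell <- render_cell(lib[1, ], seed = 5)
#' range(cell$image)
#' @export
render_cell <- function(phenotype, opts = render_options(), seed = NULL) {
  with_seed_if(seed, {
    body <- render_cell_body(phenotype, opts)
    side <- opts$side
    bg <- matrix(opts$background_level, side, side)
    if (opts$background_amplitude > 0) {
      bg <- bg + synthesize_background(c(side, side), opts$background_amplitude,
                                       opts$correlation_length)
    }
    if (opts$sensor_noise_sd > 0) {
      bg <- bg + matrix(rnorm(side^2, 0, opts$sensor_noise_sd), side, side)
    }
    list(image = clip01(bg + body$delta), mask = body$mask,
         phenotype = check_phenotype(phenotype))
  })
}
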