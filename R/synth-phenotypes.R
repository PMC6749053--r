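# Base morphology templates.  Types cycle through these four archetypes
# (rounded epithelial-like, stellate, elongated, large ruffled), which keeps
# between-type parameter separation much larger than the within-type mode
# spread regardless of seed.
slc_type_templates <- function() {
  tibble(
    body_radius_px = c(22, 27, 18, 30),
    eccentricity = c(0.15, 0.20, 0.45, 0.10),
    boundary_roughness = c(0.03, 0.08, 0.05, 0.12),
    n_protrusions = c(0L, 4L, 2L, 6L),
    interior_texture_sd = c(0.025, 0.06, 0.04, 0.08),
    intensity_contrast = c(0.22, 0.30, 0.26, 0.34)
  )
}

#' Generate a library of synthetic cell phenotypes
#'
#' Creates `n_types * modes_per_type` phenotype parameter sets describing
#' star-convex cell bodies: radius, eccentricity, boundary roughness
#' (radial-harmonic amplitude), protrusion count (rendered as radial bumps
#' that become skeleton branches), interior texture level, and
#' cell-vs-background intensity contrast.  Types are anchored to distinct
#' morphological archetypes so the mean between-type parameter distance
#' exceeds the within-type spread; modes within a type emulate the distinct
#' morphological phenotypes a single cell type exhibits (radius, protrusion
#' and texture offsets scaled by `mode_spread`).
#'
#' @param n_types Number of cell types (>= 1).
#' @param modes_per_type Number of phenotype modes per type (>= 1).
#' @param seed Integer seed; the library is deterministic given the seed.
#' @param mode_spread Scale of the within-type mode offsets (1 = default
#'   separation, chosen so modes are recoverable from simple morphometrics).
#' @return A tibble of class `slc_phenotype_library` with one row per
#'   phenotype (`type`, `mode`, `mode_id` plus the six parameters).
#' @examples
#' lib <- make_phenotype_library(2, 3, seed = 7)
#' nrow(lib) # 6
#' @export
make_phenotype_library <- function(n_types, modes_per_type, seed,
                                   mode_spread = 1) {
  n_types <- check_positive_int(n_types, "n_types")
  modes_per_type <- check_positive_int(modes_per_type, "modes_per_type")
  templates <- slc_type_templates()
  prot_offsets <- c(0L, 2L, 4L, 6L, 1L, 3L)   # distinct per mode within a type

  withr::with_seed(as.integer(seed), {
    rows <- purrr::map(seq_len(n_types), function(t) {
      base <- templates[(t - 1L) %% nrow(templates) + 1L, ]
      base$body_radius_px <- base$body_radius_px +
        1.5 * ((t - 1L) %/% nrow(templates)) + rnorm(1, 0, 0.5)
      base$eccentricity <- min(0.9, max(0, base$eccentricity + rnorm(1, 0, 0.02)))
      base$intensity_contrast <- base$intensity_contrast + rnorm(1, 0, 0.01)
      purrr::map(seq_len(modes_per_type), function(j) {
        u <- j - (modes_per_type + 1) / 2
        off <- prot_offsets[(j - 1L) %% length(prot_offsets) + 1L]
        tibble(
          type = t,
          mode = j,
          mode_id = sprintf("T%d.M%d", t, j),
          body_radius_px = min(34, max(12,
            base$body_radius_px * (1 + 0.12 * mode_spread * u))),
          eccentricity = min(0.9, max(0, base$eccentricity +
            0.04 * mode_spread * u)),
          boundary_roughness = max(0, base$boundary_roughness +
            0.01 * mode_spread * u),
          n_protrusions = max(0L, base$n_protrusions +
            as.integer(round(off * mode_spread))),
          interior_texture_sd = max(0.005, base$interior_texture_sd +
            0.012 * mode_spread * u),
          intensity_contrast = min(0.45, max(0.12, base$intensity_contrast +
            0.02 * mode_spread * u))
        )
      })
    })
    lib <- dplyr::bind_rows(purrr::flatten(rows))
    class(lib) <- c("slc_phenotype_library", class(lib))
    lib
  })
}

#' Rendering options for synthetic cells and frames
#'
#' The background is a flat substrate level plus a smooth correlated random
#' field (amplitude roughly 10% of the typical cell contrast) plus i.i.d.
#' sensor noise.  Cell bodies are star-convex radial functions with
#' roughness harmonics; protrusions are narrow Gaussian radial bumps long
#' enough to register as skeleton branches.
#'
#' @param side Crop side length in pixels.
#' @param background_level Mean substrate intensity.
#' @param background_amplitude SD of the smooth background field.
#' @param correlation_length Correlation scale of the background field (px).
#' @param sensor_noise_sd SD of per-pixel sensor noise.
#' @param protrusion_length Bump amplitude relative to the body radius.
#' @param protrusion_width Angular bump width (radians).
#' @param texture_correlation Correlation scale of interior texture (px).
#' @param edge_softness Width of the intensity roll-off at the cell edge (px).
#' @param granule_count_range Integer range of organelle-like interior
#'   granules per cell.  Granules (nucleoli, vacuoles, vesicles) give each
#'   individual cell a rotation-independent signature — their number, sizes
#'   and contrasts do not change when the cell is rotated or translated.
#' @param granule_radius_range Granule radius range in pixels.
#' @param granule_contrast_sd SD of the (signed) granule intensity offsets.
#' @return A list of class `slc_render_options`.
#' @export
render_options <- function(side = 224L,
                           background_level = 0.45,
                           background_amplitude = 0.025,
                           correlation_length = 40,
                           sensor_noise_sd = 0.01,
                           protrusion_length = 0.8,
                           protrusion_width = 0.14,
                           texture_correlation = 4,
                           edge_softness = 1.5,
                           granule_count_range = c(2L, 6L),
                           granule_radius_range = c(2.5, 5),
                           granule_contrast_sd = 0.08) {
  structure(
    list(side = check_positive_int(side, "side"),
         background_level = background_level,
         background_amplitude = background_amplitude,
         correlation_length = correlation_length,
         sensor_noise_sd = sensor_noise_sd,
         protrusion_length = protrusion_length,
         protrusion_width = protrusion_width,
         texture_correlation = texture_correlation,
         edge_softness = edge_softness,
         granule_count_range = granule_count_range,
         granule_radius_range = granule_radius_range,
         granule_contrast_sd = granule_contrast_sd),
    class = "slc_render_options"
  )
}

check_phenotype <- function(phenotype) {
  need <- c("body_radius_px", "eccentricity", "boundary_roughness",
            "n_protrusions", "interior_texture_sd", "intensity_contrast")
  if (is.data.frame(phenotype)) phenotype <- as.list(phenotype[1, ])
  missing <- setdiff(need, names(phenotype))
  if (length(missing)) {
    stop_bad_arg("phenotype lacks fields: ", paste(missing, collapse = ", "))
  }
  vals <- unlist(phenotype[need])
  if (!all(is.finite(vals))) stop_bad_arg("phenotype parameters must be finite")
  if (phenotype$eccentricity < 0 || phenotype$eccentricity >= 1) {
    stop_bad_arg("eccentricity must lie in [0, 1)")
  }
  phenotype
}
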