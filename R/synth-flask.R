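#' Flask design
#'
#' Describes one synthetic culture flask: a cell type, a density condition
#' ("low"/"high" seeding, represented purely as a label that drives the
#' phenotype-mode mixture, never as cells per crop), the number of cells, the
#' per-mode mixing probabilities, and a flask-level batch shift applied to
#' every cell's phenotype parameters (flask-to-flask morphological
#' heterogeneity).
#'
#' @param flask_id Identifier.
#' @param cell_type Type index into the phenotype library.
#' @param condition `"low"` or `"high"`.
#' @param n_cells Number of cells to render (>= 1).
#' @param mode_mixing Probability vector over the type's modes (sums to 1).
#' @param batch_shift Named numeric offsets added to phenotype parameters
#'   (any of `body_radius_px`, `intensity_contrast`, `interior_texture_sd`,
#'   `boundary_roughness`); `NULL` draws one from `batch_sd`.
#' @param batch_sd Standard deviations used to draw a random batch shift
#'   (radius px, contrast, texture).  The magnitude of real flask-to-flask
#'   variability is not pinned down by data, so it is an explicit knob.
#' @param cell_jitter Scale of per-cell parameter variability around the
#'   drawn mode (1 = default).  Individual cells of one phenotype mode are
#'   not clones: radius, eccentricity, protrusion count and texture level
#'   vary from cell to cell, which is what makes single cells identifiable
#'   to the self-label network.  The jitter is kept well below the
#'   between-mode offsets so modes remain recoverable.
#' @param seed Seed for the flask's rendering stream.
#' @return A list of class `slc_flask_design`.
#' @export
flask_design <- function(flask_id, cell_type, condition = c("low", "high"),
                         n_cells, mode_mixing, batch_shift = NULL,
                         batch_sd = c(body_radius_px = 1.2,
                                      intensity_contrast = 0.02,
                                      interior_texture_sd = 0.008),
                         cell_jitter = 1,
                         seed = 1L) {
  condition <- match.arg(condition)
  n_cells <- check_positive_int(n_cells, "n_cells")
  if (abs(sum(mode_mixing) - 1) > 1e-8 || any(mode_mixing < 0)) {
    stop_bad_arg("`mode_mixing` must be a probability vector summing to 1")
  }
  structure(
    list(flask_id = as.character(flask_id), cell_type = cell_type,
         condition = condition, n_cells = n_cells,
         mode_mixing = as.numeric(mode_mixing), batch_shift = batch_shift,
         batch_sd = batch_sd, cell_jitter = cell_jitter,
         seed = as.integer(seed)),
    class = "slc_flask_design"
  )
}

apply_param_shift <- function(phenotype, shift) {
  for (nm in names(shift)) {
    if (nm %in% names(phenotype)) {
      phenotype[[nm]] <- phenotype[[nm]] + shift[[nm]]
    }
  }
  phenotype$body_radius_px <- min(34, max(10, phenotype$body_radius_px))
  phenotype$interior_texture_sd <- max(0, phenotype$interior_texture_sd)
  phenotype$boundary_roughness <- max(0, phenotype$boundary_roughness)
  phenotype$intensity_contrast <- min(0.45, max(0.08, phenotype$intensity_contrast))
  phenotype
}

# Per-cell biological variability within a mode (order ~1/3 of the
# between-mode offsets).
jitter_cell_params <- function(ph, scale) {
  if (scale <= 0) return(ph)
  ph$body_radius_px <- ph$body_radius_px * (1 + rnorm(1, 0, 0.04 * scale))
  ph$eccentricity <- ph$eccentricity + rnorm(1, 0, 0.03 * scale)
  ph$n_protrusions <- ph$n_protrusions +
    sample(-1:1, 1, prob = c(0.15, 0.7, 0.15))
  ph$interior_texture_sd <- ph$interior_texture_sd + rnorm(1, 0, 0.004 * scale)
  ph$intensity_contrast <- ph$intensity_contrast + rnorm(1, 0, 0.01 * scale)
  ph$eccentricity <- min(0.9, max(0, ph$eccentricity))
  ph$n_protrusions <- max(0L, as.integer(ph$n_protrusions))
  apply_param_shift(ph, list())   # re-clip ranges
}

#' Generate all cells of one flask
#'
#' Draws each cell's phenotype mode from the design's `mode_mixing`, applies
#' the flask-level batch shift to the phenotype parameters, and renders the
#' cell on its own background.  Deterministic given the design's seed.
#'
#' @param design A [flask_design()].
#' @param library A [make_phenotype_library()] containing the design's cell
#'   type.
#' @param opts [render_options()].
#' @param render Render pixel data (`TRUE`); `FALSE` returns the metadata
#'   (drawn modes, batch shift) only, for cheap composition checks.
#' @return A tibble with `cell_id`, `flask_id`, `cell_type`, `condition`,
#'   `mode`, `mode_id`, and (when rendered) list-columns `image`, `mask`.
#' @export
generate_flask <- function(design, library, opts = render_options(),
                           render = TRUE) {
  if (!inherits(design, "slc_flask_design")) {
    stop_bad_arg("`design` must be a flask_design()")
  }
  modes <- library[library$type == design$cell_type, , drop = FALSE]
  if (nrow(modes) == 0) {
    stop_bad_arg("library has no phenotypes for type ", design$cell_type)
  }
  if (length(design$mode_mixing) != nrow(modes)) {
    stop_bad_arg("`mode_mixing` has length ", length(design$mode_mixing),
                 " but type ", design$cell_type, " has ", nrow(modes), " modes")
  }
  withr::with_seed(design$seed, {
    shift <- design$batch_shift %||% {
      s <- rnorm(length(design$batch_sd), 0, design$batch_sd)
      stats::setNames(as.list(s), names(design$batch_sd))
    }
    mode_draw <- sample.int(nrow(modes), design$n_cells, replace = TRUE,
                            prob = design$mode_mixing)
    rows <- purrr::map(seq_len(design$n_cells), function(i) {
      meta <- tibble(
        cell_id = sprintf("%s_c%04d", design$flask_id, i),
        flask_id = design$flask_id,
        cell_type = design$cell_type,
        condition = design$condition,
        mode = modes$mode[mode_draw[i]],
        mode_id = modes$mode_id[mode_draw[i]]
      )
      if (render) {
        ph <- apply_param_shift(as.list(modes[mode_draw[i], ]), shift)
        ph <- jitter_cell_params(ph, design$cell_jitter)
        cell <- render_cell(ph, opts)
        meta$image <- list(cell$image)
        meta$mask <- list(cell$mask)
      }
      meta
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate a cohort of cells mixing several phenotype groups
#'
#' Draws each cell's phenotype group (library `type`) from `type_mixing`,
#' then a uniform sub-mode within the group, applies per-cell jitter and
#' renders.  This is the natural cohort for self-label clustering fixtures:
#' the planted groups are morphological phenotypes whose prevalence depends
#' on the condition, while the individual cells inside a group remain
#' morphologically distinct from one another.
#'
#' @param library A [make_phenotype_library()].
#' @param n_cells Number of cells.
#' @param type_mixing Probability vector over the library's types.
#' @param condition Condition label carried in the metadata.
#' @param cohort_id Identifier prefix for cell ids.
#' @param seed Integer seed.
#' @param opts [render_options()].
#' @param cell_jitter Per-cell parameter jitter scale (see [flask_design()]).
#' @return A tibble like [generate_flask()]'s, with `group` = the drawn type.
#' @export
generate_cohort <- function(library, n_cells, type_mixing,
                            condition = "low", cohort_id = "C",
                            seed = 1L, opts = render_options(),
                            cell_jitter = 1) {
  types <- sort(unique(library$type))
  if (length(type_mixing) != length(types)) {
    stop_bad_arg("`type_mixing` has length ", length(type_mixing),
                 " but the library has ", length(types), " types")
  }
  n_cells <- check_positive_int(n_cells, "n_cells")
  withr::with_seed(as.integer(seed), {
    draw <- sample(types, n_cells, replace = TRUE, prob = type_mixing)
    rows <- purrr::map(seq_len(n_cells), function(i) {
      modes <- library[library$type == draw[i], , drop = FALSE]
      ph <- as.list(modes[sample.int(nrow(modes), 1), ])
      mode_id <- ph$mode_id
      ph <- jitter_cell_params(ph, cell_jitter)
      cell <- render_cell(ph, opts)
      tibble(
        cell_id = sprintf("%s_c%04d", cohort_id, i),
        flask_id = cohort_id,
        cell_type = 1L,
        group = draw[i],
        condition = condition,
        mode = draw[i],
        mode_id = mode_id,
        image = list(cell$image),
        mask = list(cell$mask)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Render a mixed-population frame with ground truth
#'
#' Places cells of two types on one full microscope frame without mask
#' overlap, together with a per-pixel truth channel (0 = background,
#' otherwise the type id) standing in for a fluorescent nuclear-label ground
#' truth, and the list of crop centers with their true types.  Uneven
#' `n_per_type` emulates frames rich in one type.
#'
#' @param library A phenotype library with (at least) two types.
#' @param types Length-2 vector of type ids to mix.
#' @param n_per_type Integer vector `c(n1, n2)`; `c(0, 0)` gives a pure
#'   background frame.
#' @param seed Integer seed.
#' @param frame_dim Frame size in pixels (rows, cols).
#' @param opts [render_options()].
#' @param max_tries Placement retries per cell before giving up.
#' @return A list of class `slc_mixed_frame`: `pixels`, `truth_channel`,
#'   `centers` (tibble `row`, `col`, `true_type`).
#' @export
render_mixed_frame <- function(library, types = c(1, 2), n_per_type = c(5, 5),
                               seed = 1L, frame_dim = c(1216L, 1616L),
                               opts = render_options(), max_tries = 200L) {
  if (length(n_per_type) != 2 || any(n_per_type < 0)) {
    stop_bad_arg("`n_per_type` must be two nonnegative counts")
  }
  H <- frame_dim[1]; W <- frame_dim[2]
  half <- opts$side %/% 2L
  withr::with_seed(as.integer(seed), {
    bg <- matrix(opts$background_level, H, W) +
      synthesize_background(frame_dim, opts$background_amplitude,
                            opts$correlation_length) +
      matrix(rnorm(H * W, 0, opts$sensor_noise_sd), H, W)
    truth <- matrix(0L, H, W)
    pixels <- bg
    centers <- list()

    type_seq <- rep(types, n_per_type)
    for (ci in seq_along(type_seq)) {
      ty <- type_seq[ci]
      modes <- library[library$type == ty, , drop = FALSE]
      if (nrow(modes) == 0) stop_bad_arg("library has no phenotypes for type ", ty)
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r <- sample((half + 1):(H - half), 1)
        c <- sample((half + 1):(W - half), 1)
        ph <- as.list(modes[sample.int(nrow(modes), 1), ])
        body <- render_cell_body(ph, opts)
        rows <- (r - half):(r + half - 1L)
        cols <- (c - half):(c + half - 1L)
        if (any(truth[rows, cols][body$mask] != 0L)) next
        pixels[rows, cols] <- pixels[rows, cols] + body$delta
        truth[rows, cols][body$mask] <- as.integer(ty)
        centers[[length(centers) + 1L]] <-
          tibble(row = r, col = c, true_type = ty)
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf("failed to place cell %d of type %s after %d tries",
                      ci, ty, max_tries),
              class = "cellslc_generation_error")
      }
    }
    structure(
      list(pixels = clip01(pixels), truth_channel = truth,
           centers = if (length(centers)) dplyr::bind_rows(centers)
                     else tibble(row = integer(), col = integer(),
                                 true_type = integer())),
      class = "slc_mixed_frame"
    )
  })
}

#' @export
print.slc_mixed_frame <- function(x, ...) {
  cat("<slc_mixed_frame> ", nrow(x$pixels), "x", ncol(x$pixels), " px, ",
      nrow(x$centers), " cells\n", sep = "")
  invisible(x)
}
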