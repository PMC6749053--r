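#' Convert an RGB frame to grayscale
#'
#' Uses the unweighted channel mean: brightfield images carry no color
#' semantics, so no luminance weighting is applied.  Passing three equal
#' channels returns the common channel unchanged.
#'
#' @param frame An H x W x 3 numeric array.
#' @return An H x W matrix.
#' @export
to_grayscale <- function(frame) {
  if (!is.array(frame) || length(dim(frame)) != 3 || dim(frame)[3] != 3) {
    stop_bad_arg("`frame` must be an H x W x 3 array")
  }
  if (!all(is.finite(frame))) stop_bad_arg("`frame` contains non-finite values")
  (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
}

#' Crop a 224-pixel single-cell window from a frame
#'
#' Returns the half-open window `rows [r - 112, r + 112)`, `cols [c - 112,
#' c + 112)` around the 1-based center `(r, c)`, which is exactly 224 x 224
#' for integer centers.  Centers whose window would leave the frame are
#' rejected with an error of class `cellslc_crop_rejection` so callers can
#' skip and log them.
#'
#' @param frame A numeric matrix at least 224 x 224.
#' @param center Integer vector `c(row, col)`, 1-based.
#' @param size Window side length (default 224).
#' @return A `size` x `size` matrix.
#' @export
crop_cell <- function(frame, center, size = 224L) {
  if (!is.matrix(frame)) stop_bad_arg("`frame` must be a matrix")
  size <- check_positive_int(size, "size")
  half <- size %/% 2L
  r <- as.integer(center[1]); c <- as.integer(center[2])
  r0 <- r - half; r1 <- r + half - 1L
  c0 <- c - half; c1 <- c + half - 1L
  if (r0 < 1 || c0 < 1 || r1 > nrow(frame) || c1 > ncol(frame)) {
    abort(sprintf("crop window [%d,%d]x[%d,%d] exceeds frame %dx%d",
                  r0, r1, c0, c1, nrow(frame), ncol(frame)),
          class = "cellslc_crop_rejection")
  }
  frame[r0:r1, c0:c1]
}

#' Reference intensity distribution for quantile normalization
#'
#' Records the sorted pixel intensities of one arbitrarily chosen single-cell
#' image; every other cell is normalized so that its sorted intensity
#' multiset equals this reference exactly.
#'
#' @param image A cell image (matrix) or a numeric vector of intensities.
#' @return An object of class `slc_reference` holding `sorted_values`.
#' @export
reference_distribution <- function(image) {
  v <- as.vector(image)
  if (!all(is.finite(v))) stop_bad_arg("reference image has non-finite values")
  structure(list(sorted_values = sort(v)), class = "slc_reference")
}

#' @export
print.slc_reference <- function(x, ...) {
  cat("<slc_reference> ", length(x$sorted_values), " sorted intensities in [",
      sprintf("%.3f, %.3f", min(x$sorted_values), max(x$sorted_values)),
      "]\n", sep = "")
  invisible(x)
}

#' Quantile-normalize a cell image to a reference distribution
#'
#' Replaces the image's intensities rank-for-rank by the reference's sorted
#' values: the output's sorted pixel multiset equals the reference exactly
#' while the spatial rank order of the input is preserved.  Ties are broken
#' by scan order (column-major), making the map deterministic and the
#' operation idempotent.
#'
#' @param image A numeric matrix.
#' @param ref A [reference_distribution()] with as many values as `image`
#'   has pixels.
#' @return A matrix of the same shape.
#' @export
quantile_normalize <- function(image, ref) {
  if (!inherits(ref, "slc_reference")) {
    stop_bad_arg("`ref` must be a reference_distribution()")
  }
  v <- as.vector(image)
  if (length(v) != length(ref$sorted_values)) {
    stop_bad_arg("image has ", length(v), " pixels but reference has ",
                 length(ref$sorted_values))
  }
  out <- numeric(length(v))
  out[order(v, method = "radix")] <- ref$sorted_values
  matrix(out, nrow = nrow(image))
}

#' Synthesize a smooth artificial background field
#'
#' Produces a zero-mean, spatially correlated random field (Gaussian-smoothed
#' white noise, rescaled so its standard deviation equals `amplitude`)
#' imitating substrate irregularities.  Used both when rendering synthetic
#' cells and as the background-addition augmentation.
#'
#' @param shape Integer vector `c(h, w)`.
#' @param amplitude Target standard deviation of the field (0 gives a zero
#'   field).
#' @param correlation_length Smoothing scale in pixels.
#' @param seed Optional seed for reproducibility.
#' @return An h x w matrix.
#' @export
synthesize_background <- function(shape, amplitude,
                                  correlation_length = 40,
                                  seed = NULL) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 || !is.finite(amplitude) ||
      amplitude < 0) {
    stop_bad_arg("`amplitude` must be a nonnegative number")
  }
  h <- check_positive_int(shape[1], "shape[1]")
  w <- check_positive_int(shape[2], "shape[2]")
  if (amplitude == 0) return(matrix(0, h, w))
  with_seed_if(seed, {
    f <- smooth_random_field(h, w, correlation_length)
    (f - mean(f)) / sd(f) * amplitude
  })
}

# Rotate counterclockwise by `theta_deg` about the image center with bilinear
# interpolation; pixels sampled outside the support are NA.
rotate_image <- function(image, theta_deg) {
  n <- nrow(image)
  stopifnot(ncol(image) == n)
  if (theta_deg %% 360 == 0) return(image)
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cc <- (n + 1) / 2
  ro <- rep(seq_len(n) - cc, times = n)   # row offsets, column-major order
  co <- rep(seq_len(n) - cc, each = n)
  sr <- ro * ct - co * st + cc            # source coordinates
  sc <- ro * st + co * ct + cc
  tol <- 1e-9
  ok <- sr >= 1 - tol & sr <= n + tol & sc >= 1 - tol & sc <= n + tol
  sr <- pmin(pmax(sr, 1), n); sc <- pmin(pmax(sc, 1), n)
  r0 <- pmin(floor(sr), n - 1); c0 <- pmin(floor(sc), n - 1)
  fr <- sr - r0; fc <- sc - c0
  out <- rep(NA_real_, n * n)
  i <- which(ok)
  i00 <- (c0[i] - 1) * n + r0[i]
  out[i] <- (1 - fr[i]) * (1 - fc[i]) * image[i00] +
    fr[i] * (1 - fc[i]) * image[i00 + 1] +
    (1 - fr[i]) * fc[i] * image[i00 + n] +
    fr[i] * fc[i] * image[i00 + n + 1]
  matrix(out, n, n)
}

# Rigid integer translation; vacated pixels are NA.
translate_image <- function(image, dr, dc) {
  n <- nrow(image); m <- ncol(image)
  out <- matrix(NA_real_, n, m)
  src_r <- seq_len(n) - dr
  src_c <- seq_len(m) - dc
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= m
  out[ok_r, ok_c] <- image[src_r[ok_r], src_c[ok_c]]
  out
}

#' Augmentation policy
#'
#' Each augmented copy is produced by rotating the cell by a uniform random
#' angle, translating it rigidly by uniform integer offsets, adding a
#' synthesized background field, and re-quantile-normalizing.  `m = 50`
#' copies per cell is the reference setting for self-label training.
#'
#' @param m Copies per cell (>= 1).
#' @param rotation_range Interval of rotation angles in degrees.
#' @param max_translation_px Maximum absolute translation per axis (< 112).
#' @param background_amplitude Standard deviation of the added background
#'   field.
#' @param correlation_length Smoothing scale of the background field.
#' @param seed Optional seed consumed by [augment_cells()].
#' @return A list of class `slc_augmentation_policy`.
#' @export
augmentation_policy <- function(m = 50L,
                                rotation_range = c(0, 360),
                                max_translation_px = 10L,
                                background_amplitude = 0.03,
                                correlation_length = 40,
                                seed = NULL) {
  m <- check_positive_int(m, "m")
  if (max_translation_px < 0 || max_translation_px >= 112) {
    stop_bad_arg("`max_translation_px` must lie in [0, 112)")
  }
  if (background_amplitude < 0) stop_bad_arg("`background_amplitude` must be >= 0")
  structure(
    list(m = m, rotation_range = as.numeric(rotation_range),
         max_translation_px = as.integer(max_translation_px),
         background_amplitude = background_amplitude,
         correlation_length = correlation_length, seed = seed),
    class = "slc_augmentation_policy"
  )
}

#' Augment a single cell image
#'
#' Produces `policy$m` copies: rotation by a uniform angle from
#' `rotation_range` (bilinear interpolation), integer translation uniform in
#' `[-t, t]^2`, addition of a synthesized background field, then quantile
#' normalization back to `ref`.  Pixels vacated by rotation or translation
#' are filled with the image's border level plus the background field rather
#' than zeros, so the network cannot key on corner artifacts.  The original
#' image is not part of the returned list.
#'
#' @param image A square cell image (matrix in `[0, 1]`).
#' @param policy An [augmentation_policy()].
#' @param ref A [reference_distribution()]; each copy is re-normalized to it.
#' @param seed Optional seed.
#' @return A list of `policy$m` image matrices.
#' @export
augment <- function(image, policy, ref, seed = NULL) {
  if (!inherits(policy, "slc_augmentation_policy")) {
    stop_bad_arg("`policy` must be an augmentation_policy()")
  }
  check_image(image)
  n <- nrow(image)
  border_level <- median(c(image[1, ], image[n, ], image[, 1], image[, n]))
  with_seed_if(seed, {
    purrr::map(seq_len(policy$m), function(i) {
      theta <- runif(1, policy$rotation_range[1], policy$rotation_range[2])
      out <- rotate_image(image, theta)
      t <- policy$max_translation_px
      if (t > 0) {
        out <- translate_image(out, sample(-t:t, 1), sample(-t:t, 1))
      }
      out[is.na(out)] <- border_level
      if (policy$background_amplitude > 0) {
        out <- out + synthesize_background(dim(out), policy$background_amplitude,
                                           policy$correlation_length)
      }
      quantile_normalize(clip01(out), ref)
    })
  })
}

#' Augment every cell of a manifest
#'
#' Applies [augment()] to each row of a cell tibble, returning one row per
#' augmented copy with the originating cell's metadata, a `copy` index and a
#' class label equal to the cell's position in the input (the self-label
#' convention).
#'
#' @param cells A tibble with an `image` list-column and a `cell_id` column.
#' @param policy An [augmentation_policy()]; its `seed` (or the `seed`
#'   argument) makes the output reproducible.
#' @param ref A [reference_distribution()]; defaults to the first cell's
#'   distribution.
#' @param seed Optional seed overriding `policy$seed`.
#' @return A tibble with columns of `cells` (minus `image`), plus `copy` and
#'   `image`.
#' @export
augment_cells <- function(cells, policy, ref = NULL, seed = NULL) {
  if (nrow(cells) == 0) stop_bad_arg("`cells` is empty")
  ref <- ref %||% reference_distribution(cells$image[[1]])
  seed <- seed %||% policy$seed
  with_seed_if(seed, {
    rows <- purrr::map(seq_len(nrow(cells)), function(i) {
      copies <- augment(cells$image[[i]], policy, ref)
      meta <- cells[rep(i, policy$m), setdiff(names(cells), "image")]
      meta$copy <- seq_len(policy$m)
      meta$image <- copies
      meta
    })
    dplyr::bind_rows(rows)
  })
}
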