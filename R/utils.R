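# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; a NULL seed
# uses (and advances) the caller's RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

stop_bad_arg <- function(...) abort(paste0(...), class = "cellslc_argument_error")

check_positive_int <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != as.integer(x)) {
    stop_bad_arg("`", name, "` must be a positive integer, got ", deparse(x))
  }
  as.integer(x)
}

check_image <- function(image, side = NULL, name = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_bad_arg("`", name, "` must be a numeric matrix")
  }
  if (!is.null(side) && !all(dim(image) == side)) {
    stop_bad_arg("`", name, "` must be ", side, "x", side,
                 ", got ", nrow(image), "x", ncol(image))
  }
  if (!all(is.finite(image))) stop_bad_arg("`", name, "` contains non-finite values")
  invisible(image)
}

# Stack a list of square images into a (side^2) x N matrix of columns.
images_to_matrix <- function(images, side) {
  vapply(images, function(im) {
    check_image(im, side)
    as.vector(im)
  }, numeric(side * side))
}

# Separable Gaussian smoothing with edge-padded sampling: the input is
# generated `pad` pixels larger on each side and cropped after filtering, so
# the interior variance is free of boundary attenuation.
smooth_random_field <- function(h, w, correlation_length) {
  sigma <- correlation_length / 2
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  noise <- matrix(rnorm((h + 2 * half) * (w + 2 * half)),
                  nrow = h + 2 * half)
  sm <- apply(noise, 2, function(col) as.numeric(stats::filter(col, kern, sides = 2)))
  sm <- t(apply(sm, 1, function(row) as.numeric(stats::filter(row, kern, sides = 2))))
  sm[(half + 1):(half + h), (half + 1):(half + w)]
}

# pmin/pmax take attributes from their first argument, so keep x first to
# preserve matrix dimensions.
clip01 <- function(x) pmax(pmin(x, 1), 0)
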