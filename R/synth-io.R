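# Disk round-tripping: 16-bit grayscale TIFFs plus a CSV manifest, matching
# how cropped single-cell datasets are exchanged.

#' Write a flask (or any cell tibble) to disk
#'
#' Each cell image goes to `<cell_id>.tif` (16-bit grayscale), each mask to
#' `<cell_id>_mask.tif`, and the metadata to `manifest.csv`.
#'
#' @param cells A tibble with `cell_id` and list-columns `image` (and
#'   optionally `mask`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cells <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cells))) {
    tiff::writeTIFF(cells$image[[i]],
                    file.path(dir, paste0(cells$cell_id[i], ".tif")),
                    bits.per.sample = 16L)
    if ("mask" %in% names(cells)) {
      tiff::writeTIFF(cells$mask[[i]] * 1,
                      file.path(dir, paste0(cells$cell_id[i], "_mask.tif")),
                      bits.per.sample = 8L)
    }
  }
  meta <- cells[, setdiff(names(cells), c("image", "mask"))]
  readr::write_csv(meta, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a cell directory written by [write_cells()]
#'
#' @param dir Directory containing `manifest.csv` and per-cell TIFFs.
#' @param masks Also read `*_mask.tif` files when present.
#' @return A tibble with the manifest columns plus `image` (and `mask`)
#'   list-columns.
#' @export
read_cells <- function(dir, masks = TRUE) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  manifest$image <- purrr::map(manifest$cell_id, function(id) {
    tiff::readTIFF(file.path(dir, paste0(id, ".tif")))
  })
  if (masks && file.exists(file.path(dir, paste0(manifest$cell_id[1], "_mask.tif")))) {
    manifest$mask <- purrr::map(manifest$cell_id, function(id) {
      tiff::readTIFF(file.path(dir, paste0(id, "_mask.tif"))) > 0.5
    })
  }
  manifest
}

#' Write a mixed-population frame as a two-page TIFF
#'
#' Page 1 is the brightfield frame (16-bit); page 2 the truth channel with
#' type ids scaled by 1/255 (8-bit).  Crop centers go to a sidecar CSV.
#'
#' @param frame An [render_mixed_frame()] object.
#' @param path Output TIFF path; centers are written to `<path>_centers.csv`.
#' @return `path`, invisibly.
#' @export
write_mixed_frame <- function(frame, path) {
  tiff::writeTIFF(list(frame$pixels, frame$truth_channel / 255),
                  path, bits.per.sample = 16L)
  readr::write_csv(frame$centers, paste0(path, "_centers.csv"))
  invisible(path)
}

#' Read a mixed-population frame written by [write_mixed_frame()]
#'
#' @param path TIFF path.
#' @return An `slc_mixed_frame`.
#' @export
read_mixed_frame <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  centers <- readr::read_csv(paste0(path, "_centers.csv"),
                             show_col_types = FALSE)
  structure(
    list(pixels = pages[[1]],
         truth_channel = matrix(as.integer(round(pages[[2]] * 255)),
                                nrow(pages[[2]])),
         centers = centers),
    class = "slc_mixed_frame"
  )
}
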