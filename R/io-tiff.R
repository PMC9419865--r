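#' Read a grey-scale image from TIFF (+ optional JSON sidecar)
#'
#' @param path TIFF path; a sidecar `<path minus ext>.json` with
#'   `pixel_size` and other metadata is read when present.
#' @return List: `image` (matrix), `pixel_size` (NA when no sidecar),
#'   `meta`.
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) stop("input missing: ", path)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  json_path <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(json_path))
    jsonlite::read_json(json_path, simplifyVector = TRUE) else list()
  list(image = img, pixel_size = meta$pixel_size %||% NA_real_, meta = meta)
}

#' Write a grey-scale image as TIFF with a JSON metadata sidecar
#'
#' Intensities are clipped to [0, 1] and stored as 16-bit. Pixel size and
#' any extra metadata go into the sidecar.
#'
#' @param image Numeric matrix.
#' @param path Output TIFF path.
#' @param pixel_size Physical pixel size (units defined by the caller).
#' @param meta Extra named metadata stored in the sidecar.
#' @return Invisibly, the TIFF path.
#' @export
write_image_tiff <- function(image, path, pixel_size = NA_real_,
                             meta = list()) {
  img <- pmin(pmax(image, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  meta$pixel_size <- pixel_size
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
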