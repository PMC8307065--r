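#' Vessel map: the computational domain
#'
#' A `vessel_map` couples a binary raster of vessel lumina to a physical
#' grid. Vessel pixels (`TRUE`) are flux sources, not simulated tissue: the
#' oxygen and ligand fields live on the complementary tissue pixels, and
#' Neumann flux conditions are applied across tissue-pixel faces adjacent to
#' vessel pixels.
#'
#' @param mask Logical matrix, `TRUE` on vessel lumen pixels.
#' @param pixel_size_um Edge length of one pixel in micrometers.
#' @param voxel_depth_um Assumed third-dimension thickness used for
#'   volume/activity/dose conversions. Defaults to `pixel_size_um` (cubic
#'   voxels).
#' @return An object of class `vessel_map` with fields `mask`,
#'   `pixel_size_um`, `voxel_depth_um`, and `extent_mm` (physical
#'   width/height).
#' @examples
#' m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE
#' vm <- vessel_map(m, pixel_size_um = 4)
#' vascular_fraction(vm)
#' @export
vessel_map <- function(mask, pixel_size_um, voxel_depth_um = pixel_size_um) {
  if (is.numeric(mask)) mask <- mask > 0.5
  stopifnot(is.matrix(mask), is.logical(mask))
  if (anyNA(mask)) stop("vessel mask must not contain NA")
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            pixel_size_um > 0, voxel_depth_um > 0)
  structure(
    list(
      mask = mask,
      pixel_size_um = as.numeric(pixel_size_um),
      voxel_depth_um = as.numeric(voxel_depth_um),
      extent_mm = dim(mask) * pixel_size_um / 1000
    ),
    class = "vessel_map"
  )
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf(
    "vessel_map: %d x %d pixels at %.3g um/pixel (%.3g x %.3g mm), VF = %.3f%%\n",
    nrow(x$mask), ncol(x$mask), x$pixel_size_um,
    x$extent_mm[1], x$extent_mm[2], 100 * vascular_fraction(x)
  ))
  invisible(x)
}

#' Vascular fraction of a vessel map
#'
#' Fraction of domain pixels occupied by vessel lumina.
#'
#' @param map A [vessel_map()].
#' @return Dimensionless fraction in `[0, 1)`.
#' @export
vascular_fraction <- function(map) {
  stopifnot(inherits(map, "vessel_map"))
  mean(map$mask)
}

#' Euclidean distance to the nearest vessel
#'
#' Per-pixel Euclidean distance (in micrometers) to the nearest vessel
#' pixel; zero on vessel pixels. Uses the exact Euclidean distance transform
#' (EBImage) scaled by the pixel size.
#'
#' @param map A [vessel_map()] with at least one vessel pixel.
#' @return Numeric matrix of distances, um.
#' @export
distance_to_vessel <- function(map) {
  stopifnot(inherits(map, "vessel_map"))
  if (!any(map$mask)) stop("vessel-free map: distance to vessel is undefined")
  d <- EBImage::distmap(matrix(as.numeric(!map$mask), nrow(map$mask)),
                        metric = "euclidean")
  as.matrix(d) * map$pixel_size_um
}

#' Read a binary vessel mask from a PNG or TIFF file
#'
#' Pixels with intensity above 0.5 (on the 0-1 scale of [png::readPNG()] /
#' [tiff::readTIFF()]) are vessel lumina. Multi-channel images are collapsed
#' to their first channel.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @inheritParams vessel_map
#' @return A [vessel_map()].
#' @export
read_vessel_mask <- function(path, pixel_size_um, voxel_depth_um = pixel_size_um) {
  img <- read_gray_image(path)
  vessel_map(img > 0.5, pixel_size_um, voxel_depth_um)
}

#' Write a binary vessel mask as an 8-bit PNG or TIFF (0/255)
#'
#' @param map A [vessel_map()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_vessel_mask <- function(map, path) {
  stopifnot(inherits(map, "vessel_map"))
  img <- matrix(as.numeric(map$mask), nrow(map$mask))
  write_gray_image(img, path)
  invisible(path)
}

# Read a grayscale image (PNG/TIFF) as a numeric matrix on [0, 1].
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

write_gray_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(img, 0), 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}
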