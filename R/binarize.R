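#' Huang fuzzy-entropy threshold
#'
#' Automated threshold selection by minimizing Huang and Wang's measure of
#' fuzziness. For each candidate split of the gray-level histogram the two
#' class means are computed, every level is assigned a fuzzy membership
#' `u(g) = 1 / (1 + |g - mu_class| / C)` (with `C` the gray-level range),
#' and the Shannon fuzzy entropy `-u log u - (1-u) log(1-u)` is accumulated
#' over the histogram. The returned threshold is the midpoint between the
#' optimal split level and the next observed level, so that thresholding
#' with `image > threshold` reproduces the optimal class assignment.
#'
#' Images with more than 512 distinct values are binned to 256 equal-width
#' levels first (the classical 8-bit formulation).
#'
#' @param image Numeric matrix (or vector) of gray intensities with at
#'   least two distinct values.
#' @return The scalar threshold; vessels/foreground are `image > threshold`.
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' huang_threshold(img)
#' @export
huang_threshold <- function(image) {
  g <- as.numeric(image)
  g <- g[!is.na(g)]
  lev <- sort(unique(g))
  if (length(lev) < 2L) {
    stop("constant image: no threshold exists")
  }
  if (length(lev) > 512L) {
    # bin to 256 levels on the observed range
    brk <- seq(min(g), max(g), length.out = 257L)
    mid <- (brk[-1L] + brk[-257L]) / 2
    cnt <- tabulate(findInterval(g, brk, rightmost.closed = TRUE), 256L)
    keep <- cnt > 0L
    lev <- mid[keep]
    cnt <- cnt[keep]
  } else {
    cnt <- as.numeric(table(match(g, lev)))
  }
  C <- max(lev) - min(lev)
  w <- cnt / sum(cnt)
  csum_w <- cumsum(w)
  csum_wg <- cumsum(w * lev)
  tot_w <- csum_w[length(w)]
  tot_wg <- csum_wg[length(w)]

  nlev <- length(lev)
  fuzz <- rep(NA_real_, nlev - 1L)
  for (k in seq_len(nlev - 1L)) {
    mu0 <- csum_wg[k] / csum_w[k]
    mu1 <- (tot_wg - csum_wg[k]) / (tot_w - csum_w[k])
    mu <- c(rep(mu0, k), rep(mu1, nlev - k))
    u <- 1 / (1 + abs(lev - mu) / C)
    h <- ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
    fuzz[k] <- sum(w * h)
  }
  k_opt <- which.min(fuzz)
  (lev[k_opt] + lev[k_opt + 1L]) / 2
}

#' Clean a raw binary vessel mask
#'
#' Removes connected components smaller than `min_object_px` and fills
#' holes enclosed in the surviving vessel lumina, mirroring the
#' noise-removal step applied to binarized anti-CD31 histology.
#'
#' @param raw_mask Logical matrix (raw binarization output).
#' @param min_object_px Minimum component size, in pixels, to keep.
#' @return Logical matrix of the same shape.
#' @export
clean_mask <- function(raw_mask, min_object_px = 10) {
  if (is.numeric(raw_mask)) raw_mask <- raw_mask > 0.5
  stopifnot(is.matrix(raw_mask), is.logical(raw_mask))
  if (!any(raw_mask)) return(raw_mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(raw_mask), nrow(raw_mask)))
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= min_object_px)
  m <- matrix(as.integer(lab) %in% keep, nrow(raw_mask))
  if (!any(m)) return(m)
  filled <- EBImage::fillHull(matrix(as.numeric(m), nrow(m)))
  as.matrix(filled) > 0.5
}

#' Binarize a grayscale histology ROI into a vessel mask
#'
#' Applies the Huang threshold and mask cleaning in one step. Vessels are
#' assumed to be the high-intensity class; set `invert = TRUE` when they are
#' dark on a bright background (as in DAB-stained brightfield images).
#'
#' @param image Numeric matrix of gray intensities.
#' @param min_object_px Passed to [clean_mask()].
#' @param invert If `TRUE`, the low-intensity class is taken as vessels.
#' @inheritParams vessel_map
#' @return A [vessel_map()].
#' @export
binarize_histology <- function(image, pixel_size_um, min_object_px = 10,
                               invert = FALSE,
                               voxel_depth_um = pixel_size_um) {
  thr <- huang_threshold(image)
  raw <- if (invert) image < thr else image > thr
  vessel_map(clean_mask(raw, min_object_px), pixel_size_um, voxel_depth_um)
}
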