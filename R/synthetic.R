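#' Specification for a synthetic vessel map
#'
#' Describes a randomly generated vessel configuration: disc-shaped lumina
#' with lognormal radii placed either uniformly (Poisson) or in clusters
#' (Thomas process: cluster parents placed uniformly, vessels scattered
#' around them with an isotropic Gaussian). Clustered maps leave large
#' avascular regions, the geometric driver of diffusion-limited chronic
#' hypoxia seen in xenograft histology.
#'
#' @param target_vascular_fraction Target area fraction of vessel lumina,
#'   in `(0, 0.2)`; the generator achieves it within 10% relative.
#' @param radius_mean_um Median vessel radius, um (lognormal `meanlog =
#'   log(radius_mean_um)`).
#' @param radius_sdlog Lognormal sd of the radius, in log-units.
#' @param clustering Spatial clumping intensity, `>= 0`. `0` places vessels
#'   uniformly; larger values put on average `1 + 15 * clustering` vessels
#'   in each cluster. The default (0.4) emulates the clustered vasculature
#'   of xenograft ROIs (see the package vignette).
#' @param cluster_sigma_um Gaussian scatter of vessels around their cluster
#'   center, um.
#' @param seed Integer seed; the same seed and spec give a bitwise
#'   identical map.
#' @return An object of class `synthetic_vessel_spec`.
#' @export
synthetic_vessel_spec <- function(target_vascular_fraction,
                                  radius_mean_um = 8,
                                  radius_sdlog = 0.4,
                                  clustering = 0.4,
                                  cluster_sigma_um = 50,
                                  seed = 1L) {
  stopifnot(target_vascular_fraction > 0, target_vascular_fraction < 0.2,
            radius_mean_um > 0, radius_sdlog >= 0,
            clustering >= 0, cluster_sigma_um > 0)
  structure(
    list(
      target_vascular_fraction = target_vascular_fraction,
      radius_mean_um = radius_mean_um,
      radius_sdlog = radius_sdlog,
      clustering = clustering,
      cluster_sigma_um = cluster_sigma_um,
      seed = as.integer(seed)
    ),
    class = "synthetic_vessel_spec"
  )
}

#' Generate a synthetic vessel map
#'
#' Places disc vessels according to a [synthetic_vessel_spec()] until the
#' achieved vascular fraction reaches the target (within 10% relative).
#' Discs drawn near the target are radius-capped so the target is not
#' overshot. Placement is rejection-sampled to keep overlap between discs
#' minimal; discs may be clipped by the domain edge.
#'
#' @param spec A [synthetic_vessel_spec()].
#' @param shape Grid dimensions `c(nrow, ncol)`, each `>= 64`.
#' @param pixel_size_um Pixel edge length, um.
#' @param voxel_depth_um Slab thickness for volume conversions; defaults to
#'   `pixel_size_um`.
#' @return A [vessel_map()].
#' @examples
#' vm <- generate_synthetic_map(synthetic_vessel_spec(0.01, seed = 7),
#'                              shape = c(128, 128), pixel_size_um = 12.5)
#' vascular_fraction(vm)
#' @export
generate_synthetic_map <- function(spec, shape = c(400, 400),
                                   pixel_size_um = 4,
                                   voxel_depth_um = pixel_size_um) {
  stopifnot(inherits(spec, "synthetic_vessel_spec"),
            length(shape) == 2L, all(shape >= 64))
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  n_px <- nr * nc
  target_px <- spec$target_vascular_fraction * n_px

  mask <- with_local_seed(spec$seed, {
    r_mean_px <- spec$radius_mean_um / pixel_size_um
    # expected disc area in px (lognormal second moment)
    e_area <- pi * exp(2 * log(r_mean_px) + 2 * spec$radius_sdlog^2)
    n_est <- max(1, ceiling(target_px / e_area))
    mean_per_cluster <- 1 + 15 * spec$clustering
    n_clusters <- max(1L, round(n_est / mean_per_cluster))
    parents <- cbind(stats::runif(n_clusters, 0.5, nr + 0.5),
                     stats::runif(n_clusters, 0.5, nc + 0.5))
    sig_px <- spec$cluster_sigma_um / pixel_size_um

    m <- matrix(FALSE, nr, nc)
    placed_px <- 0
    attempts <- 0L
    max_attempts <- 400L * n_est + 2000L
    while (placed_px < target_px) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not reach target vascular fraction ",
             spec$target_vascular_fraction, " after ", max_attempts,
             " attempts (infeasible for this grid/radius)")
      }
      r_px <- stats::rlnorm(1, log(r_mean_px), spec$radius_sdlog)
      remaining <- target_px - placed_px
      # never overshoot the target by more than a fraction of a small disc
      r_px <- min(r_px, sqrt(max(remaining, 1) / pi))
      r_px <- max(r_px, 0.6)
      if (spec$clustering > 0) {
        p <- parents[sample.int(n_clusters, 1L), ]
        ci <- p[1] + stats::rnorm(1, 0, sig_px)
        cj <- p[2] + stats::rnorm(1, 0, sig_px)
      } else {
        ci <- stats::runif(1, 0.5, nr + 0.5)
        cj <- stats::runif(1, 0.5, nc + 0.5)
      }
      if (ci < 0.5 || ci > nr + 0.5 || cj < 0.5 || cj > nc + 0.5) next
      ii <- max(1L, floor(ci - r_px)):min(nr, ceiling(ci + r_px))
      jj <- max(1L, floor(cj - r_px)):min(nc, ceiling(cj + r_px))
      if (!length(ii) || !length(jj)) next
      disc <- outer((ii - ci)^2, (jj - cj)^2, "+") <= r_px^2
      if (!any(disc)) next
      new_px <- sum(disc & !m[ii, jj, drop = FALSE])
      # keep overlap between discs minimal
      if (new_px < 0.6 * sum(disc) && attempts %% 50L != 0L) next
      m[ii, jj] <- m[ii, jj] | disc
      placed_px <- sum(m)
    }
    m
  })

  map <- vessel_map(mask, pixel_size_um, voxel_depth_um)
  achieved <- vascular_fraction(map)
  rel_err <- abs(achieved - spec$target_vascular_fraction) /
    spec$target_vascular_fraction
  if (rel_err > 0.10) {
    stop(sprintf(
      "generated vascular fraction %.4f misses target %.4f by %.1f%%",
      achieved, spec$target_vascular_fraction, 100 * rel_err))
  }
  map
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
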