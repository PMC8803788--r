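#' Projection count data container
#'
#' Integer Poisson counts on the projector grid (angles x radial bins x
#' slices) with duration-fraction provenance and the expected-counts scale
#' used to simulate them.
#'
#' @param counts non-negative integer array (angles x radial bins x slices).
#' @param duration_fraction scan-duration fraction in (0, 1].
#' @param scale expected-counts multiplier (counts per SUV-voxel line
#'   integral at full duration).
#' @param seed integer seed the counts were generated with.
#' @param voxel_size voxel size (mm) of the originating volume.
#' @return an object of class `pet_sinogram`.
#' @export
pet_sinogram <- function(counts, duration_fraction = 1, scale = 1,
                         seed = NA_integer_, voxel_size = c(4, 4, 4)) {
  if (length(dim(counts)) != 3L) stopf("counts must be a 3-D array")
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (duration_fraction <= 0 || duration_fraction > 1)
    stopf("duration_fraction must lie in (0, 1]")
  structure(list(counts = counts,
                 duration_fraction = as.numeric(duration_fraction),
                 scale = as.numeric(scale), seed = as.integer(seed),
                 voxel_size = as.numeric(voxel_size)),
            class = "pet_sinogram")
}

#' @export
#' @method print pet_sinogram
print.pet_sinogram <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<pet_sinogram> %d angles x %d bins x %d slices, duration %.2g, total counts %.0f\n",
              d[1], d[2], d[3], x$duration_fraction, sum(x$counts)))
  invisible(x)
}

#' Simulate Poisson projection counts from an activity volume
#'
#' Counts are drawn independently per bin from
#' `Poisson(scale * forward_project(volume))`, the full-duration acquisition
#' model (expectation linear in scan time through `scale`).
#'
#' @param volume a [pet_volume()].
#' @param config a [projector_config()].
#' @param scale positive expected-counts multiplier.
#' @param seed integer seed; identical seeds give identical counts.
#' @return a [pet_sinogram()] with `duration_fraction = 1`.
#' @export
simulate_counts <- function(volume, config, scale = 1, seed = 1L) {
  if (scale <= 0) stopf("scale must be > 0")
  proj <- forward_project(volume, config)
  if (!all(is.finite(proj))) stopf("non-finite forward projections")
  lam <- scale * proj
  counts <- with_seed(seed, rpois(length(lam), lam))
  counts <- array(as.double(counts), dim = dim(proj))
  pet_sinogram(counts, duration_fraction = 1, scale = scale, seed = seed,
               voxel_size = volume$voxel_size)
}

#' Thin projection counts to emulate a reduced scan duration
#'
#' Each count is thinned independently as `Binomial(n = count, p = fraction)`,
#' the exact statistical surrogate for retaining a fraction of a Poisson
#' acquisition: thinned Poisson counts remain Poisson with rate scaled by
#' `fraction`.
#'
#' @param sino a [pet_sinogram()].
#' @param fraction retained fraction in (0, 1].
#' @param seed integer seed.
#' @return a [pet_sinogram()] with `duration_fraction` multiplied by
#'   `fraction`; counts never exceed the input counts.
#' @export
thin_counts <- function(sino, fraction, seed = 1L) {
  stopifnot(inherits(sino, "pet_sinogram"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction > 1)
    stopf("fraction must lie in (0, 1]")
  counts <- if (fraction == 1) sino$counts else {
    thinned <- with_seed(seed, rbinom(length(sino$counts),
                                      size = as.integer(sino$counts),
                                      prob = fraction))
    array(as.double(thinned), dim = dim(sino$counts))
  }
  pet_sinogram(counts, duration_fraction = sino$duration_fraction * fraction,
               scale = sino$scale, seed = seed, voxel_size = sino$voxel_size)
}
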