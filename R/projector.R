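#' Slice-wise parallel-beam projector configuration
#'
#' The projector models line integrals at `n_angles` view angles evenly
#' spaced over 180 degrees, with `radial_bins` detector bins of one-voxel
#' pitch, applied independently to each axial slice. Resolution (PSF) is
#' modelled as an in-plane Gaussian blur of FWHM `psf_fwhm` mm applied in
#' image space before projection; the back-projector applies the same
#' (self-adjoint) blur after back-projection so the pair remains an exact
#' adjoint pair.
#'
#' @param n_angles number of projection angles over 180 degrees (>= 8).
#' @param radial_bins number of radial bins; defaults to the smallest odd
#'   integer covering the transverse diagonal of `grid_xy` plus a margin.
#' @param psf_fwhm image-space Gaussian FWHM in mm (0 disables the PSF).
#' @param grid_xy transverse grid size (2 integers) the projector is built
#'   for; used to derive `radial_bins` and validate inputs.
#' @return an object of class `projector_config`.
#' @export
projector_config <- function(n_angles = 48L, radial_bins = NULL,
                             psf_fwhm = 5, grid_xy = c(64L, 64L)) {
  n_angles <- as.integer(n_angles)
  grid_xy <- as.integer(grid_xy)
  if (n_angles < 8L) stopf("n_angles must be >= 8")
  diag_vox <- ceiling(sqrt(sum(grid_xy^2)))
  if (is.null(radial_bins)) radial_bins <- as.integer(diag_vox + 4L + (diag_vox %% 2L))
  radial_bins <- as.integer(radial_bins)
  if (radial_bins < diag_vox)
    stopf("radial_bins (%d) must cover the image diagonal (%d voxels)",
          radial_bins, diag_vox)
  if (psf_fwhm < 0) stopf("psf_fwhm must be >= 0 mm")
  structure(list(n_angles = n_angles, radial_bins = radial_bins,
                 psf_fwhm = as.numeric(psf_fwhm), grid_xy = grid_xy),
            class = "projector_config")
}

# cache of sparse system matrices keyed by geometry
.petdle_cache <- new.env(parent = emptyenv())

# Pixel-driven sparse projection matrix: rows indexed by (angle, radial bin),
# columns by transverse pixel. Each pixel deposits unit weight per angle,
# linearly interpolated between the two nearest radial bins, so mass is
# preserved exactly at every angle.
system_matrix <- function(config) {
  key <- sprintf("A_%d_%d_%d_%d", config$grid_xy[1], config$grid_xy[2],
                 config$n_angles, config$radial_bins)
  if (!is.null(.petdle_cache[[key]])) return(.petdle_cache[[key]])
  nx <- config$grid_xy[1]; ny <- config$grid_xy[2]
  na <- config$n_angles; nb <- config$radial_bins
  px <- rep(seq_len(nx), times = ny) - (nx + 1) / 2
  py <- rep(seq_len(ny), each = nx) - (ny + 1) / 2
  theta <- (seq_len(na) - 1L) * pi / na
  ii <- jj <- integer(0); xx <- numeric(0)
  for (a in seq_len(na)) {
    t <- px * cos(theta[a]) + py * sin(theta[a]) + (nb + 1) / 2
    b0 <- floor(t); w1 <- t - b0
    ok0 <- b0 >= 1 & b0 <= nb
    ok1 <- (b0 + 1) >= 1 & (b0 + 1) <= nb
    # row index a + na*(bin-1): angle varies fastest in the sinogram array
    ii <- c(ii, a + na * (as.integer(b0[ok0]) - 1L),
            a + na * as.integer(b0[ok1]))
    jj <- c(jj, which(ok0), which(ok1))
    xx <- c(xx, (1 - w1)[ok0], w1[ok1])
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(na * nb, nx * ny))
  .petdle_cache[[key]] <- A
  A
}

# 1-D symmetric Gaussian convolution matrix (zero padding) for one axis;
# symmetric Toeplitz, hence self-adjoint.
gauss_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(Matrix::Diagonal(n))
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  i <- j <- integer(0); x <- numeric(0)
  for (d in seq(-half, half)) {
    idx <- seq_len(n)
    keep <- idx + d >= 1 & idx + d <= n
    i <- c(i, idx[keep]); j <- c(j, idx[keep] + d)
    x <- c(x, rep(k[d + half + 1L], sum(keep)))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

psf_blur_slices <- function(vmat, config, voxel_size) {
  if (config$psf_fwhm <= 0) return(vmat)
  nx <- config$grid_xy[1]; ny <- config$grid_xy[2]
  sig <- config$psf_fwhm / 2.3548
  key <- sprintf("B_%d_%d_%.4f_%.4f_%.4f", nx, ny, sig,
                 voxel_size[1], voxel_size[2])
  if (is.null(.petdle_cache[[key]])) {
    .petdle_cache[[key]] <- list(Bx = gauss_matrix(nx, sig / voxel_size[1]),
                                 By = gauss_matrix(ny, sig / voxel_size[2]))
  }
  B <- .petdle_cache[[key]]
  nz <- ncol(vmat)
  out <- matrix(0, nrow(vmat), nz)
  for (z in seq_len(nz)) {
    s <- matrix(vmat[, z], nx, ny)
    out[, z] <- as.vector(as.matrix(B$Bx %*% s %*% B$By))
  }
  out
}

as_volume_values <- function(volume) {
  if (inherits(volume, "pet_volume")) volume$values else volume
}

#' Forward-project a volume into a real-valued sinogram
#'
#' Applies the in-plane Gaussian PSF (if configured) and then the
#' parallel-beam line-integral operator slice by slice.
#'
#' @param volume a [pet_volume()] or 3-D array (finite, non-negative).
#' @param config a [projector_config()] matching the transverse grid.
#' @param voxel_size voxel size in mm (taken from `volume` when it is a
#'   `pet_volume`).
#' @return numeric array (`n_angles` x `radial_bins` x `n_slices`).
#' @export
forward_project <- function(volume, config, voxel_size = c(4, 4, 4)) {
  vals <- as_volume_values(volume)
  if (inherits(volume, "pet_volume")) voxel_size <- volume$voxel_size
  d <- dim(vals)
  if (length(d) != 3L || d[1] != config$grid_xy[1] || d[2] != config$grid_xy[2])
    stopf("volume grid %s does not match projector grid %s",
          paste(d[1:2], collapse = "x"),
          paste(config$grid_xy, collapse = "x"))
  if (!all(is.finite(vals))) stopf("volume must be finite")
  vmat <- matrix(vals, d[1] * d[2], d[3])
  vmat <- psf_blur_slices(vmat, config, voxel_size)
  A <- system_matrix(config)
  smat <- as.matrix(A %*% vmat)
  array(smat, dim = c(config$n_angles, config$radial_bins, d[3]))
}

#' Back-project a sinogram (exact adjoint of [forward_project()])
#'
#' @param sino numeric array (`n_angles` x `radial_bins` x `n_slices`) or a
#'   matrix of stacked slices.
#' @param config a [projector_config()].
#' @param voxel_size voxel size in mm.
#' @return 3-D numeric array on the projector's transverse grid.
#' @export
back_project <- function(sino, config, voxel_size = c(4, 4, 4)) {
  d <- check_sino_dims(sino, config)
  smat <- matrix(sino, d[1] * d[2], d[3])
  A <- system_matrix(config)
  vmat <- as.matrix(Matrix::crossprod(A, smat))
  vmat <- psf_blur_slices(vmat, config, voxel_size)
  array(vmat, dim = c(config$grid_xy, d[3]))
}

check_sino_dims <- function(sino, config) {
  d <- dim(sino)
  if (length(d) != 3L || d[1] != config$n_angles || d[2] != config$radial_bins)
    stopf("sinogram dims %s do not match projector (%d angles x %d bins)",
          paste(d, collapse = "x"), config$n_angles, config$radial_bins)
  d
}

#' Axial z-filter
#'
#' Light axial smoothing with the 3-point kernel (1, 4, 1)/6; edge slices
#' use the truncated, renormalised kernel. Transverse planes are untouched.
#' Volumes with fewer than 3 slices are returned unchanged with a warning.
#'
#' @param volume a [pet_volume()] or 3-D array.
#' @return same type as the input.
#' @export
z_filter <- function(volume) {
  vals <- as_volume_values(volume)
  d <- dim(vals)
  if (d[3] < 3L) {
    warnf("z_filter needs >= 3 slices; returning input unchanged")
    return(volume)
  }
  out <- vals
  out[, , 2:(d[3] - 1)] <- (vals[, , 1:(d[3] - 2)] +
                              4 * vals[, , 2:(d[3] - 1)] +
                              vals[, , 3:d[3]]) / 6
  out[, , 1] <- (4 * vals[, , 1] + vals[, , 2]) / 5
  out[, , d[3]] <- (4 * vals[, , d[3]] + vals[, , d[3] - 1]) / 5
  if (inherits(volume, "pet_volume")) { volume$values <- out; volume }
  else out
}
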