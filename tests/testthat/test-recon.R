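test_that("MLEM fits a noiseless disc sinogram", {
  proj <- projector_config(16, psf_fwhm = 0, grid_xy = c(32, 32))
  disc <- disc_phantom(32, 10)
  lam <- forward_project(disc, proj) * 1000
  sino <- pet_sinogram(round(lam), scale = 1000, voxel_size = c(4, 4, 4))
  rec <- osem_reconstruct(sino, proj,
                          recon_params("OSEM", iterations = 200, subsets = 1,
                                       z_filter = FALSE))
  fitted <- forward_project(rec, proj)
  ybar <- sino$counts / 1000
  nrmse <- sqrt(mean((fitted - ybar)^2)) / mean(ybar)
  expect_lt(nrmse, 0.01)
  # count conservation after convergence
  expect_lt(abs(sum(fitted) - sum(ybar)) / sum(ybar), 0.005)
  # SUV calibration: uniform disc reconstructs to ~1 in the interior
  expect_lt(abs(mean(rec$values[13:20, 13:20, 1]) - 1), 0.02)
})

test_that("the EM update has the truth as a fixed point on noiseless data", {
  proj <- projector_config(16, psf_fwhm = 0, grid_xy = c(32, 32))
  disc <- disc_phantom(32, 10)
  lam <- forward_project(disc, proj)
  # one full manual EM update initialised at the truth
  A <- petdle:::system_matrix(proj)
  sens <- as.vector(Matrix::colSums(A))
  x <- as.vector(disc$values[, , 1])
  bp <- as.vector(Matrix::crossprod(A, as.vector(lam) /
                                      (as.vector(A %*% x) + 1e-8)))
  x1 <- x * bp / (sens + 1e-8)
  fit0 <- as.vector(A %*% x)
  fit1 <- as.vector(A %*% x1)
  expect_lt(max(abs(fit1 - fit0)), 1e-6 * max(fit0))
})

test_that("OSEM liver noise increases as scan duration decreases", {
  nc <- noisy_case()
  par <- recon_params("OSEM", 2, 8)
  o_full <- osem_reconstruct(nc$sim$sinos$f100, nc$proj, par)
  o_half <- osem_reconstruct(nc$sim$sinos$f050, nc$proj, par)
  n_full <- voi_stats(o_full, nc$rois$vois)$liver_noise_sd
  n_half <- voi_stats(o_half, nc$rois$vois)$liver_noise_sd
  expect_gt(n_half, n_full)
  # provenance is carried through reconstruction
  expect_equal(o_half$duration_fraction, 0.5)
  expect_equal(o_half$method, "OSEM")
})

test_that("BSREM with beta = 0 degenerates to OSEM", {
  nc <- noisy_case()
  osem <- osem_reconstruct(nc$sim$sinos$f100, nc$proj,
                           recon_params("OSEM", 2, 8, z_filter = FALSE))
  bs0 <- bsrem_reconstruct(nc$sim$sinos$f100, nc$proj,
                           recon_params("BSREM", 2, 8, beta = 0,
                                        relaxation_decay = 0,
                                        z_filter = FALSE))
  denom <- pmax(osem$values, 1e-6)
  expect_lt(max(abs(bs0$values - osem$values) / denom), 1e-6)
})

test_that("beta trades noise against lesion contrast monotonically", {
  nc <- noisy_case()
  grid <- c(0, 0.5, 1, 2)
  noise <- numeric(0); suvmax <- numeric(0)
  for (b in grid) {
    par <- recon_params("BSREM", 20, 8, beta = b, relaxation_decay = 0.1)
    rec <- bsrem_reconstruct(nc$sim$sinos$f100, nc$proj, par)
    noise <- c(noise, voi_stats(rec, nc$rois$vois)$liver_noise_sd)
    suvmax <- c(suvmax, mean(vapply(nc$rois$lesion_centers, function(ctr)
      segment_lesion(rec, ctr)$suv_max, numeric(1))))
  }
  expect_true(all(diff(noise) < 0))
  expect_true(all(diff(suvmax) <= 0))
})

test_that("the relative difference prior matches its closed form", {
  # two-voxel image (a, b) = (2, 1), gamma = 2: each ordered pair
  # contributes (a-b)^2 / (a + b + gamma*|a-b| + eps) = 1/5, so R = 2/5
  x <- array(c(2, 1), c(2, 1, 1))
  expect_equal(rdp_value(x, gamma = 2, eps = 0), 2 / 5, tolerance = 1e-12)
  # gradient agrees with central finite differences on a random 3-D field
  set.seed(9)
  y <- array(runif(4 * 3 * 3, 0.5, 3), c(4, 3, 3))
  g <- rdp_grad(y, gamma = 2)
  for (i in c(1L, 7L, 20L, 36L)) {
    h <- 1e-6
    y1 <- y; y1[i] <- y1[i] + h
    y2 <- y; y2[i] <- y2[i] - h
    num <- (rdp_value(y1, 2) - rdp_value(y2, 2)) / (2 * h)
    expect_lt(abs(num - g[i]) / max(abs(num), 1e-8), 1e-4)
  }
})

test_that("reconstruction parameter validation and divergence guard work", {
  expect_error(recon_params("OSEM", iterations = 0), "positive integers")
  expect_error(recon_params("BSREM", beta = -1), "beta")
  nc <- noisy_case()
  expect_error(bsrem_reconstruct(nc$sim$sinos$f100, nc$proj,
                                 recon_params("OSEM", 2, 8)), "BSREM")
  # subsets must divide the angle count
  expect_error(osem_reconstruct(nc$sim$sinos$f100, nc$proj,
                                recon_params("OSEM", 2, 7)), "divide")
  # an aggressively regularised run trips the divergence detector
  expect_error(bsrem_reconstruct(nc$sim$sinos$f100, nc$proj,
                                 recon_params("BSREM", 20, 8, beta = 50,
                                              relaxation_decay = 0.05)),
               "diverged")
})
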