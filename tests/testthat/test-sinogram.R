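test_that("simulated counts are reproducible and Poisson-mean-correct", {
  vol <- build_phantom(simple_spec())
  proj <- projector_config(16, psf_fwhm = 0, grid_xy = c(32, 32))
  s1 <- simulate_counts(vol, proj, scale = 2, seed = 42L)
  s2 <- simulate_counts(vol, proj, scale = 2, seed = 42L)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts >= 0 & s1$counts == round(s1$counts)))
  expect_equal(s1$duration_fraction, 1)

  # Monte-Carlo mean against the analytic expectation (aggregate over bins)
  lam_tot <- 2 * sum(forward_project(vol, proj))
  tots <- vapply(1:200, function(s)
    sum(simulate_counts(vol, proj, scale = 2, seed = s)$counts), numeric(1))
  se <- sqrt(lam_tot / 200)   # SE of the mean of 200 Poisson totals
  expect_lt(abs(mean(tots) - lam_tot), 3 * se)
})

test_that("a vanishing scale gives vanishing counts", {
  vol <- build_phantom(simple_spec())
  proj <- projector_config(16, psf_fwhm = 0, grid_xy = c(32, 32))
  s <- simulate_counts(vol, proj, scale = 1e-12, seed = 1L)
  expect_true(all(s$counts == 0))
  expect_error(simulate_counts(vol, proj, scale = 0), "scale")
})

test_that("thinning honours the binomial contract", {
  vol <- build_phantom(simple_spec())
  proj <- projector_config(16, psf_fwhm = 0, grid_xy = c(32, 32))
  sino <- simulate_counts(vol, proj, scale = 1, seed = 3L)
  # fraction 1 is the identity
  expect_identical(thin_counts(sino, 1, seed = 9L)$counts, sino$counts)
  # all-zero input stays zero
  z <- pet_sinogram(array(0, c(4, 4, 2)))
  expect_true(all(thin_counts(z, 0.5, seed = 1L)$counts == 0))
  # thinned counts never exceed the input and the fraction is recorded
  th <- thin_counts(sino, 0.5, seed = 4L)
  expect_true(all(th$counts <= sino$counts))
  expect_equal(th$duration_fraction, 0.5)
  expect_error(thin_counts(sino, 0), "fraction")
  expect_error(thin_counts(sino, 1.2), "fraction")
})

test_that("thinned Poisson counts remain Poisson with the scaled rate", {
  # thinning-of-Poisson property: Poisson(lambda) thinned at p ~ Poisson(p*lambda),
  # checked by a 5-bin chi-square at alpha = 0.01 over 2000 replicates
  lambda <- 12; p <- 0.5
  reps <- 2000L
  vals <- petdle:::with_seed(77L, {
    n <- rpois(reps, lambda)
    rbinom(reps, n, p)
  })
  brks <- c(-0.5, 3.5, 4.5, 5.5, 7.5, Inf)
  obs <- table(cut(vals, brks))
  pr <- diff(ppois(c(-1, 3, 4, 5, 7, Inf), p * lambda))
  chi2 <- sum((as.numeric(obs) - reps * pr)^2 / (reps * pr))
  expect_lt(chi2, qchisq(0.99, df = 4))
})

test_that("expected counts scale linearly with the retained fraction", {
  vol <- build_phantom(simple_spec())
  proj <- projector_config(16, psf_fwhm = 0, grid_xy = c(32, 32))
  sino <- simulate_counts(vol, proj, scale = 1, seed = 6L)
  tot <- sum(sino$counts)
  for (f in c(0.75, 0.5, 0.25)) {
    tots <- vapply(1:50, function(s)
      sum(thin_counts(sino, f, seed = s)$counts), numeric(1))
    se <- sqrt(tot * f * (1 - f) / 50)
    expect_lt(abs(mean(tots) - f * tot), 3 * se)
  }
})

test_that("double thinning matches single thinning distributionally", {
  # Binomial thinning composes: f1 then f2 equals f1*f2 in distribution;
  # compare the first two empirical moments over 2000 replicates
  n0 <- 40L; f1 <- 0.8; f2 <- 0.5
  reps <- 2000L
  two <- petdle:::with_seed(11L, rbinom(reps, rbinom(reps, n0, f1), f2))
  one <- petdle:::with_seed(12L, rbinom(reps, n0, f1 * f2))
  se_mean <- sqrt(2 * n0 * f1 * f2 / reps)
  expect_lt(abs(mean(two) - mean(one)), 3 * se_mean)
  expect_lt(abs(var(two) - var(one)) / var(one), 0.2)
})

test_that("sinograms round-trip through the compressed container", {
  vol <- build_phantom(simple_spec())
  proj <- projector_config(16, psf_fwhm = 0, grid_xy = c(32, 32))
  sino <- thin_counts(simulate_counts(vol, proj, scale = 1, seed = 2L),
                      0.75, seed = 3L)
  path <- withr::local_tempfile(fileext = ".sino.gz")
  write_sinogram(sino, path)
  back <- read_sinogram(path)
  expect_identical(back$counts, sino$counts)
  expect_equal(back$duration_fraction, 0.75)
  expect_equal(back$scale, sino$scale)
})
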