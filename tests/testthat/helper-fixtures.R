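# Shared fixtures: built in code at test time, deterministic under fixed
# seeds. Heavier objects are memoised per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# a small but fully featured phantom spec (deterministic lesions)
tiny_spec <- function(seed = 1L) default_phantom_spec(seed)

# simple hand-built spec: body + liver + one lesion
simple_spec <- function() {
  phantom_spec(
    grid_shape = c(32, 32, 16), voxel_size = c(4, 4, 4),
    body = list(center = c(16.5, 16.5, 8.5), semi_axes = c(14, 12, 20),
                suv = 1.0),
    organs = list(list(label = "liver", center = c(20, 18, 8),
                       semi_axes = c(7, 6, 5), suv = 2.5)),
    lesions = list(list(center = c(20, 18, 8), radius = 2.5, suv = 8.0)))
}

# small projector + noiseless disc sinogram for reconstruction tests
disc_phantom <- function(n = 32, radius = 10) {
  vals <- array(0, c(n, n, 1))
  ctr <- (n + 1) / 2
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= radius^2) vals[i, j, 1] <- 1
  pet_volume(vals, c(4, 4, 4))
}

# one reconstructed noisy case at two durations (memoised; used by several
# recon and eval tests)
noisy_case <- function() {
  fixture("noisy_case", function() {
    spec <- tiny_spec(5L)
    proj <- projector_config(48, psf_fwhm = 5)
    sim <- simulate_case(spec, proj, scale = 1,
                         fractions = c(1, 0.5), seed = 5L)
    list(spec = spec, proj = proj, sim = sim, rois = phantom_rois(spec))
  })
}
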