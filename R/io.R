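# File I/O conventions: volumes are NIfTI-1 float32 with voxel sizes in the
# header and a JSON sidecar carrying method/duration provenance; sinograms
# are a gzip-compressed flat text array with a JSON sidecar; configs are
# YAML with a schema_version key. Voxel indices in all on-disk JSON/YAML are
# 0-based (axial = last axis); they are converted to R's 1-based indexing at
# the I/O boundary.

io_error <- function(msg) {
  stop(structure(class = c("petdle_io_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image volume as NIfTI-1 with a JSON sidecar
#'
#' Values are stored as 32-bit float with voxel sizes (mm) in the header;
#' method and duration-fraction provenance go to `<path>.json`.
#'
#' @param volume a [pet_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  vals <- volume$values
  attr(vals, "pixdim") <- volume$voxel_size   # honoured by asNifti
  img <- RNifti::asNifti(vals, datatype = "float")
  RNifti::writeNifti(img, path)
  meta <- list(method = volume$method,
               duration_fraction = volume$duration_fraction,
               voxel_size_mm = volume$voxel_size)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image volume written by [write_volume()]
#'
#' A missing sidecar is tolerated: the read succeeds with provenance marked
#' unknown and a warning. A corrupt file raises a typed
#' `petdle_io_error`.
#'
#' @param path NIfTI file path.
#' @return a [pet_volume()].
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    io_error(sprintf("failed to read NIfTI '%s': %s", path,
                                     conditionMessage(e))))
  vals <- array(as.numeric(img), dim = dim(img))
  vx <- RNifti::pixdim(img)[seq_len(min(3L, length(RNifti::pixdim(img))))]
  if (length(vx) < 3L) vx <- rep(vx, length.out = 3L)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    pet_volume(vals, meta$voxel_size_mm %||% vx, method = meta$method,
               duration_fraction = meta$duration_fraction)
  } else {
    warnf("no sidecar for '%s'; provenance marked unknown", path)
    pet_volume(vals, vx, method = "unknown", duration_fraction = 1)
  }
}

#' Write a sinogram as a gzip-compressed text array with a JSON sidecar
#'
#' @param sino a [pet_sinogram()].
#' @param path output path (conventionally `.sino.gz`).
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "pet_sinogram"))
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(format(as.integer(sino$counts), scientific = FALSE), con)
  meta <- list(dims = dim(sino$counts),
               duration_fraction = sino$duration_fraction,
               scale = sino$scale, seed = sino$seed,
               voxel_size_mm = sino$voxel_size)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path sinogram file path.
#' @return a [pet_sinogram()].
#' @export
read_sinogram <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) io_error(sprintf("missing sinogram sidecar '%s'", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  con <- gzfile(path, "r")
  on.exit(close(con))
  counts <- as.numeric(readLines(con))
  pet_sinogram(array(counts, dim = meta$dims),
               duration_fraction = meta$duration_fraction,
               scale = meta$scale, seed = meta$seed,
               voxel_size = meta$voxel_size_mm)
}

# --- phantom spec and ROI files ---------------------------------------------

#' Read/write a phantom specification as YAML
#'
#' The on-disk schema (versioned with `schema_version: 1`) stores voxel
#' coordinates 0-based; they are shifted to R's 1-based indexing on read.
#'
#' @param path YAML file path.
#' @return a [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version) || y$schema_version != 1L)
    io_error(sprintf("unsupported phantom spec schema_version in '%s'", path))
  shift <- function(p) as.numeric(p) + 1
  body <- if (!is.null(y$body))
    list(center = shift(y$body$center),
         semi_axes = as.numeric(y$body$semi_axes), suv = y$body$suv)
  organs <- lapply(y$organs %||% list(), function(o)
    list(label = o$label, center = shift(o$center),
         semi_axes = as.numeric(o$semi_axes), suv = o$suv))
  lesions <- lapply(y$lesions %||% list(), function(l)
    list(center = shift(l$center), radius = l$radius, suv = l$suv))
  phantom_spec(unlist(y$grid_shape), unlist(y$voxel_size), body, organs,
               lesions, seed = y$seed %||% 1L)
}

#' @rdname read_phantom_spec
#' @param spec a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  unshift <- function(p) as.numeric(p) - 1
  y <- list(schema_version = 1L,
            grid_shape = as.integer(spec$grid_shape),
            voxel_size = as.numeric(spec$voxel_size),
            seed = spec$seed)
  if (!is.null(spec$body))
    y$body <- list(center = unshift(spec$body$center),
                   semi_axes = spec$body$semi_axes, suv = spec$body$suv)
  y$organs <- lapply(spec$organs, function(o)
    list(label = o$label, center = unshift(o$center),
         semi_axes = o$semi_axes, suv = o$suv))
  y$lesions <- lapply(spec$lesions, function(l)
    list(center = unshift(l$center), radius = l$radius, suv = l$suv))
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}

#' Read/write per-case ROI definitions (JSON sidecar)
#'
#' VOI centres and lesion bounding-box centres are stored 0-based on disk.
#'
#' @param path JSON file path.
#' @return list with `vois` and `lesion_centers` (1-based).
#' @export
read_rois <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vois <- lapply(seq_len(nrow(j$vois)), function(i)
    voi(unlist(j$vois[i, c("x", "y", "z")]) + 1L, organ = j$vois$organ[i]))
  lesion_centers <- lapply(seq_len(nrow(j$lesions)), function(i)
    as.integer(unlist(j$lesions[i, c("x", "y", "z")])) + 1L)
  list(vois = vois, lesion_centers = lesion_centers)
}

#' @rdname read_rois
#' @param rois list with `vois` (list of [voi()]) and `lesion_centers`.
#' @export
write_rois <- function(rois, path) {
  vdf <- do.call(rbind, lapply(rois$vois, function(v)
    data.frame(organ = v$organ, x = v$center[1] - 1L, y = v$center[2] - 1L,
               z = v$center[3] - 1L)))
  ldf <- do.call(rbind, lapply(rois$lesion_centers, function(ctr)
    data.frame(x = ctr[1] - 1L, y = ctr[2] - 1L, z = ctr[3] - 1L)))
  jsonlite::write_json(list(vois = vdf, lesions = ldf), path, digits = NA)
  invisible(path)
}

# --- experiment configuration ------------------------------------------------

#' Experiment configuration for the end-to-end pipeline
#'
#' Bundles the phantom/corpus layout, projector, reconstruction,
#' network and training settings, the evaluated duration fractions and the
#' master seed. All sub-configurations are validated up front; the object
#' round-trips losslessly through YAML.
#'
#' @param n_train,n_val,n_test corpus split sizes.
#' @param fractions scan-duration fractions to simulate and evaluate.
#' @param scale expected-counts multiplier at full duration.
#' @param n_angles,psf_fwhm projector settings (see [projector_config()]).
#' @param osem_iterations,osem_subsets OSEM input settings (partial
#'   convergence regime).
#' @param bsrem_iterations,bsrem_subsets,beta,rdp_gamma,relaxation_decay
#'   BSREM target settings; `beta = NULL` requests per-corpus calibration
#'   against `target_noise_sd`.
#' @param target_noise_sd liver-noise target (SUV) for beta calibration.
#' @param variant network variant(s) to train (`"smooth"`, `"standard"`,
#'   `"sharp"`).
#' @param levels,base_channels network size (see [network_config()]).
#' @param max_epochs,learning_rate,batch_size training settings.
#' @param seed master seed; all stage seeds are derived from it.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_train = 20L, n_val = 4L, n_test = 4L,
                              fractions = c(1, 0.75, 0.5, 0.25),
                              scale = 1, n_angles = 48L, psf_fwhm = 5,
                              osem_iterations = 2L, osem_subsets = 8L,
                              bsrem_iterations = 20L, bsrem_subsets = 8L,
                              beta = 1, rdp_gamma = 2,
                              relaxation_decay = 0.1,
                              target_noise_sd = 0.15,
                              variant = "standard", levels = 3L,
                              base_channels = 8L, max_epochs = 6L,
                              learning_rate = 1e-3, batch_size = 4L,
                              seed = 1L) {
  cfg <- structure(as.list(environment()), class = "experiment_config")
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(cfg) {
  stopifnot(cfg$n_train >= 1, cfg$n_val >= 1, cfg$n_test >= 1,
            all(cfg$fractions > 0 & cfg$fractions <= 1), cfg$scale > 0)
  projector_config(cfg$n_angles, psf_fwhm = cfg$psf_fwhm)
  if (cfg$n_angles %% cfg$osem_subsets != 0L ||
      cfg$n_angles %% cfg$bsrem_subsets != 0L)
    stopf("subsets must divide n_angles (%d)", cfg$n_angles)
  recon_params("OSEM", cfg$osem_iterations, cfg$osem_subsets)
  recon_params("BSREM", cfg$bsrem_iterations, cfg$bsrem_subsets,
               beta = cfg$beta %||% 1, rdp_gamma = cfg$rdp_gamma,
               relaxation_decay = cfg$relaxation_decay)
  for (v in cfg$variant)
    model_variant(v, levels = cfg$levels, base_channels = cfg$base_channels)
  training_config(cfg$max_epochs, cfg$learning_rate, cfg$batch_size)
  invisible(cfg)
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$schema_version) || y$schema_version != 1L)
    io_error(sprintf("unsupported experiment config schema_version in '%s'",
                     path))
  y$schema_version <- NULL
  if (!is.null(y$beta) && is.character(y$beta) && y$beta == "calibrate")
    y["beta"] <- list(NULL)   # keep the element so the default is not used
  do.call(experiment_config, y)
}

#' @rdname experiment_config
#' @param config an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  y <- unclass(config)
  if (is.null(y$beta)) y$beta <- "calibrate"
  yaml::write_yaml(c(list(schema_version = 1L), y), path, precision = 15L)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
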