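#' Torso-like activity phantom specification
#'
#' Defines a voxelised activity distribution in SUV units: an ellipsoidal
#' body compartment, labelled organ ellipsoids (liver, left/right lung) and
#' spherical lesions. Coordinates are voxel-centre positions on the 1-based
#' R grid; the axial direction is the last axis.
#'
#' @param grid_shape integer vector of 3 voxel counts (x, y, z), each >= 16.
#' @param voxel_size numeric vector of 3 voxel edge lengths in mm.
#' @param body list with `center`, `semi_axes` (voxels) and `suv`, or `NULL`
#'   for an empty (all-zero) phantom.
#' @param organs list of lists with `label` (one of `"liver"`,
#'   `"lung_left"`, `"lung_right"`), `center`, `semi_axes`, `suv`.
#' @param lesions list of lists with `center`, `radius` (voxels) and `suv`.
#' @param seed integer seed recorded with the spec (texture generation only;
#'   the phantom itself is deterministic).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size = c(4, 4, 4), body = NULL,
                         organs = list(), lesions = list(), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stopf("grid_shape must be 3 integers, each >= 16")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("voxel_size must be 3 positive lengths (mm)")
  spec <- structure(list(grid_shape = grid_shape,
                         voxel_size = as.numeric(voxel_size),
                         body = body, organs = organs, lesions = lesions,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

ellipsoid_contains <- function(center, semi, x, y, z) {
  ((x - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 +
    ((z - center[3]) / semi[3])^2 <= 1
}

# sample points on an ellipsoid surface (for containment checks)
ellipsoid_surface <- function(center, semi, n = 14L) {
  th <- seq(0, pi, length.out = n)
  ph <- seq(0, 2 * pi, length.out = 2L * n)
  g <- expand.grid(th = th, ph = ph)
  cbind(center[1] + semi[1] * sin(g$th) * cos(g$ph),
        center[2] + semi[2] * sin(g$th) * sin(g$ph),
        center[3] + semi[3] * cos(g$th))
}

validate_phantom_spec <- function(spec) {
  b <- spec$body
  structures <- c(spec$organs, spec$lesions)
  if (is.null(b)) {
    if (length(structures) > 0L)
      stopf("phantom has organs/lesions but no body compartment")
    return(invisible(spec))
  }
  if (b$suv < 0) stopf("body SUV must be >= 0")
  for (o in spec$organs) {
    if (!(o$label %in% c("liver", "lung_left", "lung_right")))
      stopf("unknown organ label '%s'", o$label)
    if (o$suv < 0) stopf("organ '%s' SUV must be >= 0", o$label)
    s <- ellipsoid_surface(o$center, o$semi_axes)
    if (!all(ellipsoid_contains(b$center, b$semi_axes, s[, 1], s[, 2], s[, 3])))
      stopf("organ '%s' lies outside the body ellipsoid", o$label)
  }
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    s <- ellipsoid_surface(l$center, rep(l$radius, 3))
    if (!all(ellipsoid_contains(b$center, b$semi_axes, s[, 1], s[, 2], s[, 3])))
      stopf("lesion %d lies outside the body ellipsoid", i)
    encl <- enclosing_suv(spec, l$center)
    if (l$suv <= encl)
      stopf("lesion %d SUV (%.2f) must exceed its compartment SUV (%.2f)",
            i, l$suv, encl)
  }
  nl <- length(spec$lesions)
  if (nl > 1L) for (i in seq_len(nl - 1L)) for (j in (i + 1L):nl) {
    li <- spec$lesions[[i]]; lj <- spec$lesions[[j]]
    if (sqrt(sum((li$center - lj$center)^2)) < li$radius + lj$radius)
      stopf("lesions %d and %d overlap", i, j)
  }
  invisible(spec)
}

# SUV of the innermost organ/body compartment containing a point
enclosing_suv <- function(spec, p) {
  suv <- 0
  b <- spec$body
  if (!is.null(b) && ellipsoid_contains(b$center, b$semi_axes, p[1], p[2], p[3]))
    suv <- b$suv
  for (o in spec$organs)
    if (ellipsoid_contains(o$center, o$semi_axes, p[1], p[2], p[3]))
      suv <- o$suv
  suv
}

#' Rasterise a phantom specification into an activity volume
#'
#' Each voxel takes the SUV of the innermost structure containing its
#' centre (lesion over organ over body over zero outside the body).
#'
#' @param spec a [phantom_spec()].
#' @return a [pet_volume()] with `method = "ground_truth"`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  vals <- array(0, dim = d)
  if (!is.null(spec$body)) {
    x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
    X <- array(rep(x, times = d[2] * d[3]), dim = d)
    Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
    Z <- array(rep(z, each = d[1] * d[2]), dim = d)
    b <- spec$body
    vals[ellipsoid_contains(b$center, b$semi_axes, X, Y, Z)] <- b$suv
    for (o in spec$organs)
      vals[ellipsoid_contains(o$center, o$semi_axes, X, Y, Z)] <- o$suv
    for (l in spec$lesions)
      vals[ellipsoid_contains(l$center, rep(l$radius, 3), X, Y, Z)] <- l$suv
  }
  pet_volume(vals, spec$voxel_size, method = "ground_truth",
             duration_fraction = 1)
}

#' Reconstructed or simulated PET image volume
#'
#' The common container for every image series in the pipeline: ground
#' truth, OSEM, BSREM and DLE volumes. Values are SUV, non-negative and
#' finite; method and duration-fraction provenance are always carried.
#'
#' @param values 3-D numeric array of SUVs.
#' @param voxel_size numeric vector of 3 voxel edge lengths in mm.
#' @param method one of `"ground_truth"`, `"OSEM"`, `"BSREM"`, `"DLE"`,
#'   or `"unknown"`.
#' @param duration_fraction scan-duration fraction in (0, 1].
#' @param params reconstruction parameters or model reference used to
#'   produce the volume (kept as provenance).
#' @return an object of class `pet_volume`.
#' @export
pet_volume <- function(values, voxel_size = c(4, 4, 4), method = "unknown",
                       duration_fraction = 1, params = NULL) {
  if (length(dim(values)) != 3L) stopf("values must be a 3-D array")
  if (!all(is.finite(values))) stopf("volume values must be finite")
  if (any(values < 0)) stopf("volume values must be >= 0")
  if (!is.numeric(duration_fraction) || duration_fraction <= 0 ||
      duration_fraction > 1)
    stopf("duration_fraction must lie in (0, 1]")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 method = method,
                 duration_fraction = as.numeric(duration_fraction),
                 params = params),
            class = "pet_volume")
}

#' @export
#' @method print pet_volume
print.pet_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_volume> %dx%dx%d voxels (%.1fx%.1fx%.1f mm), %s, duration %.2g\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$method, x$duration_fraction))
  cat(sprintf("  SUV range [%.3f, %.3f], mean %.3f\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' Default desk-scale torso phantom
#'
#' A 64 x 64 x 24 voxel (4 mm isotropic) torso: body background SUV 1.0,
#' liver ellipsoid SUV 2.2, two lung ellipsoids SUV 0.5, and 3-5 spherical
#' lesions of radius 2-4 voxels and SUV 5-10 placed at seed-dependent
#' positions (one in the liver, the rest in the body background).
#'
#' @param seed integer; controls lesion number, size and placement.
#' @return a [phantom_spec()].
#' @export
default_phantom_spec <- function(seed = 1L) {
  grid <- c(64L, 64L, 24L)
  body <- list(center = c(32.5, 32.5, 12.5), semi_axes = c(27, 21, 40),
               suv = 1.0)
  organs <- list(
    list(label = "liver", center = c(41, 38, 9), semi_axes = c(13, 10, 6.5),
         suv = 2.2),
    list(label = "lung_left", center = c(21, 27, 17),
         semi_axes = c(9, 8, 7), suv = 0.5),
    list(label = "lung_right", center = c(44, 27, 17),
         semi_axes = c(9, 8, 7), suv = 0.5))
  lesions <- with_seed(seed, {
    n <- sample(3:5, 1L)
    out <- list()
    # one liver lesion, kept clear of the five liver VOI sites
    out[[1]] <- list(center = c(41 + runif(1, 6, 8), 38 + runif(1, -3, 3),
                                9 + runif(1, -1, 1)),
                     radius = runif(1, 2, 3), suv = runif(1, 5, 10))
    # remaining lesions in the body background, left/anterior of the liver
    k <- 1L; tries <- 0L
    while (k < n) {
      if ((tries <- tries + 1L) > 10000L)
        stopf("could not place %d non-overlapping lesions", n)
      cand <- list(center = c(runif(1, 14, 30), runif(1, 36, 50),
                              runif(1, 5, 20)),
                   radius = runif(1, 2, 4), suv = runif(1, 5, 10))
      ok <- all(vapply(out, function(l)
        sqrt(sum((l$center - cand$center)^2)) >= l$radius + cand$radius + 1,
        logical(1)))
      s <- ellipsoid_surface(cand$center, rep(cand$radius, 3))
      ok <- ok && all(ellipsoid_contains(body$center, body$semi_axes,
                                         s[, 1], s[, 2], s[, 3]))
      for (o in organs)  # keep background lesions out of organs
        ok <- ok && !any(ellipsoid_contains(o$center, o$semi_axes + cand$radius,
                                            cand$center[1], cand$center[2],
                                            cand$center[3]))
      if (ok) { k <- k + 1L; out[[k]] <- cand }
    }
    out
  })
  phantom_spec(grid, c(4, 4, 4), body, organs, lesions, seed = seed)
}

#' Organ VOI and lesion ROI definitions for a phantom
#'
#' Places five 7x7x7-voxel VOIs in the liver and five across the two lungs
#' (fixed offsets from the organ centres, checked to lie inside the organ
#' and clear of any lesion), and records one 7x7x7 lesion bounding-box
#' centre per lesion at the voxel nearest the lesion centre.
#'
#' @param spec a [phantom_spec()] containing liver and lung organs.
#' @return a list with elements `vois` (list of [voi()]) and
#'   `lesion_centers` (list of integer voxel triples).
#' @export
phantom_rois <- function(spec) {
  organ_of <- function(lbl) {
    for (o in spec$organs) if (o$label == lbl) return(o)
    stopf("phantom has no organ labelled '%s'", lbl)
  }
  clear_of_lesions <- function(ctr) {
    half <- 3
    for (l in spec$lesions) {
      near <- pmin(pmax(l$center, ctr - half), ctr + half)
      if (sqrt(sum((near - l$center)^2)) <= l$radius + 1) return(FALSE)
    }
    TRUE
  }
  vol <- build_phantom(spec)$values
  voi_ok <- function(o, ctr) {
    corners <- as.matrix(expand.grid(ctr[1] + c(-3, 3), ctr[2] + c(-3, 3),
                                     ctr[3] + c(-3, 3)))
    if (any(ctr - 3 < 1) || any(ctr + 3 > spec$grid_shape)) return(FALSE)
    box <- vol[(ctr[1] - 3):(ctr[1] + 3), (ctr[2] - 3):(ctr[2] + 3),
               (ctr[3] - 3):(ctr[3] + 3)]
    all(ellipsoid_contains(o$center, o$semi_axes,
                           corners[, 1], corners[, 2], corners[, 3])) &&
      all(box == o$suv) &&         # uniform: no other organ/lesion intrudes
      clear_of_lesions(ctr)
  }
  # greedy centre-out search over a candidate offset grid, keeping VOI
  # centres at least `min_sep` voxels apart
  place <- function(o, n_want, min_sep = 3) {
    grid <- expand.grid(dx = -6:6, dy = -5:5, dz = -3:3)
    grid <- grid[order(grid$dx^2 + grid$dy^2 + 2 * grid$dz^2), ]
    ctrs <- list()
    for (i in seq_len(nrow(grid))) {
      ctr <- round(o$center) + as.integer(grid[i, ])
      if (!voi_ok(o, ctr)) next
      far <- all(vapply(ctrs, function(c0)
        sqrt(sum((c0 - ctr)^2)) >= min_sep, logical(1)))
      if (far) ctrs[[length(ctrs) + 1L]] <- ctr
      if (length(ctrs) == n_want) break
    }
    ctrs
  }
  liver <- place(organ_of("liver"), 5L)
  if (length(liver) < 5L) stopf("could not place 5 liver VOIs")
  lungL <- place(organ_of("lung_left"), 3L)
  lungR <- place(organ_of("lung_right"), 2L)
  if (length(lungL) + length(lungR) < 5L) stopf("could not place 5 lung VOIs")
  vois <- c(lapply(liver, voi, organ = "liver"),
            lapply(c(lungL, lungR), voi, organ = "lung"))
  lesion_centers <- lapply(spec$lesions, function(l) {
    ctr <- as.integer(round(l$center))
    pmin(pmax(ctr, 4L), spec$grid_shape - 3L)
  })
  list(vois = vois, lesion_centers = lesion_centers)
}
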