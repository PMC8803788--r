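#' Training configuration for the enhancement network
#'
#' @param max_epochs maximum number of epochs (default 100; desk-scale runs
#'   use far fewer).
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size (>= 1).
#' @param patch_size 3 integers, or `NULL` for full-transverse, full-axial
#'   patches of the (cropped, padded) volumes.
#' @param axial_stride maximum axial spacing between patch offsets; `NULL`
#'   uses the patch depth (minimal-count coverage).
#' @param crop_fraction_max cap on the transverse fraction removed by body
#'   cropping, in `[0, 0.4]`.
#' @param seed integer seed controlling shuffling (and any stochastic step).
#' @param momentum_bn batch-normalisation running-statistics momentum.
#' @return an object of class `training_config`.
#' @export
training_config <- function(max_epochs = 100L, learning_rate = 1e-3,
                            batch_size = 4L, patch_size = NULL,
                            axial_stride = NULL, crop_fraction_max = 0.4,
                            seed = 1L, momentum_bn = 0.1) {
  if (!is_count(max_epochs)) stopf("max_epochs must be a positive integer")
  if (max_epochs > 100L)
    message("training_config: max_epochs ", max_epochs,
            " exceeds the default cap of 100")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (!is_count(batch_size)) stopf("batch_size must be >= 1")
  if (crop_fraction_max < 0 || crop_fraction_max > 0.4)
    stopf("crop_fraction_max must lie in [0, 0.4]")
  structure(list(max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patch_size = patch_size, axial_stride = axial_stride,
                 crop_fraction_max = crop_fraction_max,
                 seed = as.integer(seed), momentum_bn = momentum_bn),
            class = "training_config")
}

# --- body cropping -----------------------------------------------------------

dilate6 <- function(m) {
  d <- dim(m); out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

largest_component <- function(mask) {
  best <- NULL; bestn <- 0L
  remaining <- mask
  while (any(remaining)) {
    comp <- array(FALSE, dim(mask))
    comp[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate6(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    n <- sum(comp)
    if (n > bestn) { best <- comp; bestn <- n }
    remaining <- remaining & !comp
  }
  best
}

#' Crop a volume transversely to its body bounding box
#'
#' The body mask is the largest 6-connected component of voxels above 5% of
#' the volume maximum. The crop is limited so that no more than
#' `crop_fraction_max` of each transverse dimension is removed; the axial
#' extent is never cropped. Crop offsets are recorded in the `"crop"`
#' attribute for exact inversion with [uncrop_volume()]; the same crop can
#' be applied to a voxel-aligned series with [apply_crop()].
#'
#' @param volume a [pet_volume()].
#' @param crop_fraction_max maximum removed fraction per transverse axis.
#' @return the cropped [pet_volume()] with a `"crop"` attribute.
#' @export
crop_to_body <- function(volume, crop_fraction_max = 0.4) {
  stopifnot(inherits(volume, "pet_volume"))
  vals <- volume$values
  d <- dim(vals)
  mask <- if (max(vals) > 0) vals >= 0.05 * max(vals)
  else array(FALSE, d)
  if (!any(mask)) {
    warnf("crop_to_body: empty body mask; volume left uncropped")
    crop <- list(x = c(1L, d[1]), y = c(1L, d[2]), orig_dim = d)
    attr(volume, "crop") <- crop
    return(volume)
  }
  mask <- largest_component(mask)
  box <- lapply(1:2, function(ax) {
    pres <- apply(mask, ax, any)
    range(which(pres))
  })
  for (ax in 1:2) {
    lo <- box[[ax]][1]; hi <- box[[ax]][2]
    max_remove <- floor(crop_fraction_max * d[ax])
    removed <- d[ax] - (hi - lo + 1L)
    while (removed > max_remove) {     # relax the box symmetrically
      if (lo > 1L && (d[ax] - hi) <= (lo - 1L)) lo <- lo - 1L
      else hi <- hi + 1L
      removed <- d[ax] - (hi - lo + 1L)
    }
    box[[ax]] <- c(lo, hi)
  }
  crop <- list(x = as.integer(box[[1]]), y = as.integer(box[[2]]),
               orig_dim = d)
  out <- apply_crop(volume, crop)
  attr(out, "crop") <- crop
  out
}

#' @rdname crop_to_body
#' @param crop a crop record from [crop_to_body()].
#' @export
apply_crop <- function(volume, crop) {
  vals <- as_volume_values(volume)
  out <- vals[crop$x[1]:crop$x[2], crop$y[1]:crop$y[2], , drop = FALSE]
  if (inherits(volume, "pet_volume")) {
    volume$values <- out
    attr(volume, "crop") <- crop
    volume
  } else out
}

#' @rdname crop_to_body
#' @export
uncrop_volume <- function(volume, crop = attr(volume, "crop")) {
  if (is.null(crop)) stopf("no crop record available")
  vals <- as_volume_values(volume)
  out <- array(0, dim = crop$orig_dim)
  out[crop$x[1]:crop$x[2], crop$y[1]:crop$y[2], ] <- vals
  if (inherits(volume, "pet_volume")) { volume$values <- out; attr(volume, "crop") <- NULL; volume }
  else out
}

# --- patch extraction --------------------------------------------------------

axis_offsets <- function(L, P, stride = P) {
  if (!is.numeric(stride) || stride <= 0) stopf("stride must be > 0")
  if (P > L) stopf("patch extent (%d) exceeds volume extent (%d)", P, L)
  if (L == P) return(0L)
  k <- max(2L, as.integer(ceiling((L - P) / stride)) + 1L)
  unique(as.integer(round(seq(0, L - P, length.out = k))))
}

#' Split a volume into equally spaced 3-D patches
#'
#' Patch offsets along each axis are equally spaced with the minimal count
#' needed to cover every voxel at least once (the last patch always ends at
#' the final voxel). The returned placement map is sufficient for exact
#' reassembly, and applying it to a paired volume yields identical
#' placements.
#'
#' @param volume 3-D array or [pet_volume()].
#' @param patch_size 3 positive integers.
#' @param axial_stride maximum spacing of axial offsets (defaults to the
#'   axial patch extent).
#' @return list with `patches` (list of arrays), `offsets` (0-based integer
#'   matrix, one row per patch) and `dim` (the source volume dimensions).
#' @export
extract_patches <- function(volume, patch_size, axial_stride = NULL) {
  vals <- as_volume_values(volume)
  d <- dim(vals)
  patch_size <- as.integer(patch_size)
  offs <- list(axis_offsets(d[1], patch_size[1]),
               axis_offsets(d[2], patch_size[2]),
               axis_offsets(d[3], patch_size[3],
                            stride = axial_stride %||% patch_size[3]))
  grid <- as.matrix(expand.grid(x = offs[[1]], y = offs[[2]], z = offs[[3]]))
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    o <- grid[i, ]
    vals[o[1] + seq_len(patch_size[1]), o[2] + seq_len(patch_size[2]),
         o[3] + seq_len(patch_size[3]), drop = FALSE]
  })
  list(patches = patches, offsets = grid, dim = d)
}

#' Reassemble patches into a volume by overlap-averaging
#'
#' @param patches list of 3-D arrays.
#' @param offsets 0-based offsets matrix from [extract_patches()].
#' @param dim target volume dimensions.
#' @return 3-D numeric array.
#' @export
reassemble_patches <- function(patches, offsets, dim) {
  acc <- array(0, dim); cnt <- array(0, dim)
  for (i in seq_along(patches)) {
    p <- patches[[i]]; o <- offsets[i, ]; ps <- dim(p)
    ix <- o[1] + seq_len(ps[1]); iy <- o[2] + seq_len(ps[2])
    iz <- o[3] + seq_len(ps[3])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + p
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  acc / pmax(cnt, 1)
}

pad_to_multiple <- function(vals, mult) {
  d <- dim(vals)
  target <- as.integer(ceiling(d / mult) * mult)
  pad_lo <- (target - d) %/% 2L
  out <- array(0, target)
  out[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
      pad_lo[3] + seq_len(d[3])] <- vals
  list(values = out, pad = list(lo = pad_lo, dim = d))
}

crop_padding <- function(vals, pad) {
  vals[pad$lo[1] + seq_len(pad$dim[1]), pad$lo[2] + seq_len(pad$dim[2]),
       pad$lo[3] + seq_len(pad$dim[3]), drop = FALSE]
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(tensors) {
  st <- lapply(tensors, function(t) list(m = array(0, dim = t$dims),
                                         v = array(0, dim = t$dims)))
  names(st) <- vapply(tensors, `[[`, character(1), "name")
  st
}

adam_step <- function(params, grads, state, t, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  ptens <- flatten_params(params)
  gtens <- flatten_params(grads)
  for (i in seq_along(ptens)) {
    nm <- ptens[[i]]$name
    g <- as.numeric(gtens[[i]]$value)
    s <- state[[nm]]
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    upd <- as.numeric(ptens[[i]]$value) - lr * mhat / (sqrt(vhat) + eps)
    params <- assign_tensor(params, nm, array(upd, dim = ptens[[i]]$dims))
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# --- training ----------------------------------------------------------------

prepare_pair <- function(pair, crop_fraction_max, mult, patch_size,
                         axial_stride) {
  inp <- crop_to_body(pair$input, crop_fraction_max)
  tgt <- apply_crop(pair$target, attr(inp, "crop"))
  pi_ <- pad_to_multiple(inp$values, mult)
  pt_ <- pad_to_multiple(tgt$values, mult)
  ps <- patch_size %||% dim(pi_$values)
  ps <- pmin(as.integer(ps), dim(pi_$values))
  ps <- as.integer(ceiling(ps / mult) * mult)
  ppi <- extract_patches(pi_$values, ps, axial_stride)
  ppt <- extract_patches(pt_$values, ps, axial_stride)
  Map(function(a, b) list(input = a, target = b), ppi$patches, ppt$patches)
}

batch_stack <- function(patches) {
  ps <- dim(patches[[1]])
  stopifnot(all(vapply(patches, function(p) identical(dim(p), ps),
                       logical(1))))
  array(unlist(patches, use.names = FALSE), dim = c(ps, 1L, length(patches)))
}

# Pad every (input, target) patch pair with zeros to a common shape so that
# shuffled mini-batches can mix cases whose cropped extents differ slightly.
pad_patches_common <- function(patches, mult) {
  dims <- vapply(patches, function(p) dim(p$input), integer(3))
  target <- as.integer(ceiling(apply(dims, 1, max) / mult) * mult)
  lapply(patches, function(p) {
    if (identical(dim(p$input), target)) return(p)
    list(input = pad_to_multiple_shape(p$input, target),
         target = pad_to_multiple_shape(p$target, target))
  })
}

pad_to_multiple_shape <- function(vals, target) {
  d <- dim(vals)
  lo <- (target - d) %/% 2L
  out <- array(0, target)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <-
    vals
  out
}

val_metrics <- function(network, val_pairs, val_rois) {
  mapd <- numeric(0); noise_pd <- numeric(0); mse <- numeric(0)
  for (i in seq_along(val_pairs)) {
    pair <- val_pairs[[i]]
    enh <- enhance_volume(network, pair$input)
    mse <- c(mse, mean((enh$values - pair$target$values)^2))
    roi <- val_rois[[i]]
    for (ctr in roi$lesion_centers) {
      s_e <- segment_lesion(enh, ctr)$suv_max
      s_t <- segment_lesion(pair$target, ctr)$suv_max
      mapd <- c(mapd, abs(percent_difference(s_e, s_t)))
    }
    n_e <- voi_stats(enh, roi$vois)$liver_noise_sd
    n_t <- voi_stats(pair$target, roi$vois)$liver_noise_sd
    noise_pd <- c(noise_pd, percent_difference(n_e, n_t))
  }
  list(val_mse = mean(mse), val_suvmax_mapd = mean(mapd),
       val_liver_noise_pd = mean(noise_pd))
}

#' Train an enhancement model on paired reconstructions
#'
#' Supervised training of the residual encoder-decoder on (noisy OSEM
#' input, full-duration BSREM target) pairs: body cropping, axial patching
#' with identical placements for input and target, shuffled mini-batch MSE
#' optimisation with Adam, and per-epoch validation. Epoch 0 (the untrained
#' network) is recorded and checkpointed too. The returned model carries
#' the weights of the epoch chosen by [select_best_epoch()], which combines
#' the lowest validation loss with the lowest validation lesion-SUVmax
#' quantification difference by rank sum.
#'
#' @param train_pairs list of `list(input =, target =)` [pet_volume()]
#'   pairs.
#' @param val_pairs validation pairs in the same format (>= 1).
#' @param val_rois per-validation-case ROI definitions
#'   (`list(vois =, lesion_centers =)`, as from [phantom_rois()]).
#' @param net_config a [network_config()] or [model_variant()].
#' @param train_config a [training_config()].
#' @param net_seed seed for weight initialisation.
#' @param verbose print per-epoch progress.
#' @return an object of class `dle_model`: the trained network, the
#'   per-epoch `record` data frame, `chosen_epoch` and the logged shuffling
#'   permutations.
#' @export
dle_train <- function(train_pairs, val_pairs, val_rois,
                      net_config = model_variant("standard"),
                      train_config = training_config(),
                      net_seed = 1L, verbose = FALSE) {
  stopifnot(length(train_pairs) >= 1L, length(val_pairs) >= 1L,
            length(val_rois) == length(val_pairs))
  mult <- 2L^(net_config$levels - 1L)
  patches <- list()
  for (pair in train_pairs)
    patches <- c(patches, prepare_pair(pair, train_config$crop_fraction_max,
                                       mult, train_config$patch_size,
                                       train_config$axial_stride))
  patches <- pad_patches_common(patches, mult)
  network <- build_network(net_config, seed = net_seed)
  tensors <- flatten_params(network$params)
  state <- adam_init(tensors)
  record <- data.frame()
  checkpoints <- list()
  permutations <- list()
  np <- length(patches)
  t_adam <- 0L
  with_seed(train_config$seed, {
    vm0 <- val_metrics(network, val_pairs, val_rois)
    record <- rbind(record, data.frame(epoch = 0L, train_mse = NA_real_,
                                       val_mse = vm0$val_mse,
                                       val_suvmax_mapd = vm0$val_suvmax_mapd,
                                       val_liver_noise_pd = vm0$val_liver_noise_pd,
                                       seconds = 0))
    checkpoints[[1]] <- network$params
    for (epoch in seq_len(train_config$max_epochs)) {
      t0 <- Sys.time()
      perm <- sample.int(np)
      permutations[[epoch]] <- perm
      losses <- numeric(0)
      b0 <- 1L
      while (b0 <= np) {
        idx <- perm[b0:min(np, b0 + train_config$batch_size - 1L)]
        b0 <- b0 + train_config$batch_size
        xin <- batch_stack(lapply(patches[idx], `[[`, "input"))
        tgt <- batch_stack(lapply(patches[idx], `[[`, "target"))
        fw <- net_forward(network, xin, training = TRUE)
        network <- fw$model
        diffv <- xin + fw$residue - tgt
        loss <- mean(diffv^2)
        if (!is.finite(loss))
          stopf("non-finite training loss at epoch %d (batch starting %d)",
                epoch, b0 - train_config$batch_size)
        losses <- c(losses, loss)
        dres <- 2 * diffv / length(diffv)
        grads <- net_backward(network, fw$cache, dres)
        t_adam <- t_adam + 1L
        st <- adam_step(network$params, grads, state, t_adam,
                        train_config$learning_rate)
        network$params <- st$params
        state <- st$state
      }
      vm <- val_metrics(network, val_pairs, val_rois)
      record <- rbind(record, data.frame(epoch = epoch,
                                         train_mse = mean(losses),
                                         val_mse = vm$val_mse,
                                         val_suvmax_mapd = vm$val_suvmax_mapd,
                                         val_liver_noise_pd = vm$val_liver_noise_pd,
                                         seconds = as.numeric(Sys.time() - t0,
                                                              units = "secs")))
      checkpoints[[epoch + 1L]] <- network$params
      if (verbose)
        message(sprintf("epoch %d: train MSE %.5g, val MSE %.5g, val SUVmax MAPD %.2f%%",
                        epoch, mean(losses), vm$val_mse, vm$val_suvmax_mapd))
    }
  })
  chosen <- select_best_epoch(record)
  network$params <- checkpoints[[chosen + 1L]]
  structure(list(network = network, record = record, chosen_epoch = chosen,
                 permutations = permutations,
                 net_config = net_config, train_config = train_config,
                 n_train_patches = np),
            class = "dle_model")
}

#' Choose the stopping epoch from a training record
#'
#' Epochs are ranked by validation MSE and by validation lesion-SUVmax mean
#' absolute percentage difference; the chosen epoch minimises the sum of
#' the two ranks, with ties broken towards the earlier epoch.
#'
#' @param record data frame with columns `epoch`, `val_mse`,
#'   `val_suvmax_mapd` (one row per recorded epoch).
#' @return the chosen epoch number.
#' @export
select_best_epoch <- function(record) {
  stopifnot(nrow(record) >= 1L)
  rs <- rank(record$val_mse, ties.method = "min") +
    rank(record$val_suvmax_mapd, ties.method = "min")
  record$epoch[which.min(rs)]   # which.min takes the first (earliest) minimum
}

#' @export
#' @method print dle_model
print.dle_model <- function(x, ...) {
  cat(sprintf("<dle_model> %s, %d epochs trained, chosen epoch %d\n",
              x$net_config$variant %||% "custom",
              max(x$record$epoch), x$chosen_epoch))
  r <- x$record[x$record$epoch == x$chosen_epoch, ]
  cat(sprintf("  val MSE %.5g, val lesion SUVmax MAPD %.2f%%, val liver-noise diff %.2f%%\n",
              r$val_mse, r$val_suvmax_mapd, r$val_liver_noise_pd))
  invisible(x)
}

#' @export
#' @method summary dle_model
summary.dle_model <- function(object, ...) {
  print(object)
  cat(sprintf("  network: %d trainable parameters, %d training patches\n",
              count_params(object$network), object$n_train_patches))
  print(object$record, row.names = FALSE)
  invisible(object$record)
}

#' @export
predict.dle_model <- function(object, newdata, ...) {
  enhance_volume(object$network, newdata)
}

#' @export
plot.dle_model <- function(x, ...) {
  r <- x$record[x$record$epoch > 0, ]
  graphics::matplot(r$epoch, cbind(r$train_mse, r$val_mse), type = "b",
                    pch = c(1, 2), lty = 1, xlab = "epoch", ylab = "MSE",
                    main = "training and validation loss", ...)
  graphics::abline(v = x$chosen_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 2),
                   col = 1:2, bty = "n")
  invisible(x)
}

#' Write a training record as JSON lines
#'
#' @param model a [dle_model] (or its `record` data frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_training_record <- function(model, path) {
  record <- if (inherits(model, "dle_model")) model$record else model
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(record)))
    writeLines(jsonlite::toJSON(as.list(record[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  invisible(path)
}
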