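#' Enhancement network configuration
#'
#' A residual 3-D convolutional encoder-decoder (U-Net): per resolution
#' level two 3x3x3 convolution + batch-normalisation + ReLU blocks, 2x2x2
#' max-pooling between encoder levels, tri-linear up-sampling with skip
#' concatenation in the decoder, and a final 3x3x3 convolution predicting a
#' signed residue image that is added to the input. Channel widths at level
#' `l` are `round(base_channels * channel_multiplier * 2^(l-1))`, so the
#' trainable-parameter count grows with `channel_multiplier` — the knob that
#' realises the smooth/standard/sharp model family.
#'
#' @param levels encoder depth (>= 2).
#' @param base_channels channel width of the first level before the
#'   multiplier (>= 4).
#' @param channel_multiplier positive width multiplier.
#' @param final_layer_zero_init logical; zero-initialise the final
#'   convolution so the untrained network is the identity map.
#' @return an object of class `network_config`.
#' @export
network_config <- function(levels = 3L, base_channels = 8L,
                           channel_multiplier = 1,
                           final_layer_zero_init = TRUE) {
  levels <- as.integer(levels)
  if (levels < 2L) stopf("levels must be >= 2")
  if (base_channels < 4L) stopf("base_channels must be >= 4")
  if (channel_multiplier <= 0) stopf("channel_multiplier must be > 0")
  structure(list(levels = levels, base_channels = as.integer(base_channels),
                 channel_multiplier = as.numeric(channel_multiplier),
                 final_layer_zero_init = isTRUE(final_layer_zero_init)),
            class = "network_config")
}

#' Named model variants of the enhancement network
#'
#' The smooth/standard/sharp family differs only in channel multiplier
#' (0.5, 1.0, 1.5), hence in trainable-parameter count
#' (smooth < standard < sharp): larger models preserve more detail and
#' noise, smaller ones smooth more aggressively.
#'
#' @param name `"smooth"`, `"standard"` or `"sharp"`.
#' @param ... further arguments passed to [network_config()].
#' @return a [network_config()].
#' @export
model_variant <- function(name = c("standard", "smooth", "sharp"), ...) {
  name <- match.arg(name)
  mult <- c(smooth = 0.5, standard = 1.0, sharp = 1.5)[[name]]
  cfg <- network_config(channel_multiplier = mult, ...)
  cfg$variant <- name
  cfg
}

net_widths <- function(config) {
  vapply(seq_len(config$levels), function(l)
    max(2L, as.integer(round(config$base_channels *
                               config$channel_multiplier * 2^(l - 1)))),
    integer(1))
}

#' Build (initialise) an enhancement network
#'
#' Weights use He initialisation; batch-normalisation scales start at 1 and
#' running statistics at (0, 1). With `final_layer_zero_init` the final
#' layer's weights and bias are zero, so the untrained model returns its
#' input unchanged.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `dle_network`; its exact trainable-parameter
#'   count is available via [count_params()].
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  w <- net_widths(config)
  L <- config$levels
  params <- with_seed(seed, {
    enc <- vector("list", L)
    cin <- 1L
    for (l in seq_len(L)) {
      enc[[l]] <- list(convA = conv_init(cin, w[l]), bnA = bn_init(w[l]),
                       convB = conv_init(w[l], w[l]), bnB = bn_init(w[l]))
      cin <- w[l]
    }
    dec <- vector("list", L)
    for (l in seq_len(L - 1L)) {
      cin_d <- w[l] + w[l + 1L]
      dec[[l]] <- list(convA = conv_init(cin_d, w[l]), bnA = bn_init(w[l]),
                       convB = conv_init(w[l], w[l]), bnB = bn_init(w[l]))
    }
    final <- conv_init(w[1], 1L, zero = config$final_layer_zero_init)
    list(enc = enc, dec = dec, final = final)
  })
  structure(list(config = config, widths = w, params = params,
                 seed = as.integer(seed)),
            class = "dle_network")
}

#' Exact trainable-parameter count of a network
#'
#' Counts convolution weights and biases plus batch-normalisation scale and
#' shift parameters (running statistics are not trainable).
#'
#' @param model a [dle_network] or a [network_config()].
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  if (inherits(model, "network_config")) model <- build_network(model)
  n <- 0L
  count_block <- function(bp) {
    length(bp$convA$W) + length(bp$convA$b) + 2L * length(bp$bnA$gamma) +
      length(bp$convB$W) + length(bp$convB$b) + 2L * length(bp$bnB$gamma)
  }
  for (bp in model$params$enc) n <- n + count_block(bp)
  for (bp in model$params$dec) if (!is.null(bp)) n <- n + count_block(bp)
  n + length(model$params$final$W) + length(model$params$final$b)
}

#' @export
#' @method print dle_network
print.dle_network <- function(x, ...) {
  cat(sprintf("<dle_network> %s%d levels, widths %s, %d trainable parameters\n",
              if (!is.null(x$config$variant))
                paste0(x$config$variant, ", ") else "",
              x$config$levels, paste(x$widths, collapse = "/"),
              count_params(x)))
  invisible(x)
}

check_divisible <- function(d, levels) {
  need <- 2L^(levels - 1L)
  ax <- c("x", "y", "z")
  for (i in 1:3) if (d[i] %% need != 0L)
    stopf("spatial dim %s (%d) is not divisible by %d", ax[i], d[i], need)
}

# double conv + BN + ReLU block; returns output, cache, updated params
block_fw <- function(x, bp, training) {
  aA <- conv_fw(x, bp$convA)
  nA <- bn_fw(aA, bp$bnA, training)
  bp$bnA <- nA$par
  rA <- relu_fw(nA$y)
  aB <- conv_fw(rA, bp$convB)
  nB <- bn_fw(aB, bp$bnB, training)
  bp$bnB <- nB$par
  out <- relu_fw(nB$y)
  list(out = out, par = bp,
       cache = list(x_in = x, bnA = nA$cache, yA = nA$y,
                    bnB = nB$cache, yB = nB$y))
}

block_bw <- function(cache, bp, dout) {
  d1 <- relu_bw(cache$yB, dout)
  bb <- bn_bw(cache$bnB, bp$bnB$gamma, d1)
  cB <- conv_bw(relu_fw(cache$yA), bp$convB, bb$dx)
  d2 <- relu_bw(cache$yA, cB$dx)
  ba <- bn_bw(cache$bnA, bp$bnA$gamma, d2)
  cA <- conv_bw(cache$x_in, bp$convA, ba$dx)
  list(dx = cA$dx,
       grads = list(convA = list(W = cA$dW, b = cA$db),
                    bnA = list(gamma = ba$dgamma, beta = ba$dbeta),
                    convB = list(W = cB$dW, b = cB$db),
                    bnB = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

# Full forward pass; x is (X,Y,Z,1,N). Returns residue, layer caches and the
# model with updated batch-norm running statistics.
net_forward <- function(model, x, training = FALSE) {
  L <- model$config$levels
  check_divisible(dim(x)[1:3], L)
  p <- model$params
  cache <- list(enc = vector("list", L), dec = vector("list", L))
  skips <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    eb <- block_fw(h, p$enc[[l]], training)
    p$enc[[l]] <- eb$par
    cache$enc[[l]] <- list(block = eb$cache)
    skips[[l]] <- eb$out
    if (l < L) {
      mp <- maxpool3d_fw(eb$out, dim(eb$out))
      cache$enc[[l]]$pool_argmax <- mp$argmax
      cache$enc[[l]]$pool_indim <- dim(eb$out)
      h <- mp$out
    } else h <- eb$out
  }
  for (l in rev(seq_len(L - 1L))) {
    up <- upsample3d_fw(h, dim(h))
    cache$dec[[l]] <- list(up_indim = dim(h), cat_c1 = dim(skips[[l]])[4])
    db <- block_fw(concat_chan(skips[[l]], up), p$dec[[l]], training)
    p$dec[[l]] <- db$par
    cache$dec[[l]]$block <- db$cache
    h <- db$out
  }
  res <- conv_fw(h, p$final)
  cache$final_in <- h
  model$params <- p
  list(residue = res, cache = cache, model = model)
}

# Backward pass: gradient of the loss w.r.t. every trainable tensor, given
# the gradient w.r.t. the residue.
net_backward <- function(model, cache, dres) {
  p <- model$params
  L <- model$config$levels
  g <- list(enc = vector("list", L), dec = vector("list", L))
  cf <- conv_bw(cache$final_in, p$final, dres)
  g$final <- list(W = cf$dW, b = cf$db)
  dh <- cf$dx
  dskips <- vector("list", L)
  for (l in seq_len(L - 1L)) {   # decoder blocks in reverse application order
    db <- block_bw(cache$dec[[l]]$block, p$dec[[l]], dh)
    g$dec[[l]] <- db$grads
    c1 <- cache$dec[[l]]$cat_c1
    ctot <- dim(db$dx)[4]
    dskips[[l]] <- db$dx[, , , seq_len(c1), , drop = FALSE]
    dup <- db$dx[, , , (c1 + 1L):ctot, , drop = FALSE]
    dh <- upsample3d_bw(dup, cache$dec[[l]]$up_indim)
  }
  for (l in rev(seq_len(L))) {
    dblock <- if (l < L) {
      maxpool3d_bw(dh, cache$enc[[l]]$pool_argmax,
                   cache$enc[[l]]$pool_indim) + dskips[[l]]
    } else dh
    eb <- block_bw(cache$enc[[l]]$block, p$enc[[l]], dblock)
    g$enc[[l]] <- eb$grads
    dh <- eb$dx
  }
  g
}

#' Predict the residue image for a patch
#'
#' Runs the network in evaluation mode (batch-normalisation running
#' statistics) and returns only the signed residue; the enhanced patch is
#' `patch + residue`, clipped at zero before any SUV quantification.
#'
#' @param model a [dle_network].
#' @param patch 3-D numeric array (or [pet_volume()]) whose spatial dims are
#'   divisible by `2^(levels - 1)`.
#' @return 3-D numeric array of the same shape as the input.
#' @export
predict_residue <- function(model, patch) {
  vals <- as_volume_values(patch)
  if (anyNA(vals)) stopf("patch contains NaN/NA values")
  d <- dim(vals)
  x <- array(vals, dim = c(d, 1L, 1L))
  fw <- net_forward(model, x, training = FALSE)
  array(fw$residue, dim = d)
}

#' Enhance a full volume with a trained network
#'
#' Pads the volume symmetrically with zeros so each spatial dimension is
#' divisible by `2^(levels - 1)`, splits it into equally spaced axial
#' patches, predicts and adds the residue per patch, reassembles the patches
#' by overlap-averaging, crops the padding back and clips the result at
#' zero (quantification requires non-negative SUVs).
#'
#' @param model a [dle_network] (or [dle_model]).
#' @param volume a [pet_volume()].
#' @param patch_depth axial patch extent; defaults to the full (padded)
#'   axial extent, i.e. a single patch.
#' @return a [pet_volume()] with `method = "DLE"`.
#' @export
enhance_volume <- function(model, volume, patch_depth = NULL) {
  if (inherits(model, "dle_model")) model <- model$network
  stopifnot(inherits(volume, "pet_volume"))
  mult <- 2L^(model$config$levels - 1L)
  pv <- pad_to_multiple(volume$values, mult)
  dz <- dim(pv$values)[3]
  pd <- patch_depth %||% dz
  pd <- min(dz, max(mult, as.integer(ceiling(pd / mult) * mult)))
  pp <- extract_patches(pv$values, patch_size = c(dim(pv$values)[1:2], pd))
  enhanced <- lapply(pp$patches, function(pt) pt + predict_residue(model, pt))
  out <- reassemble_patches(enhanced, pp$offsets, dim(pv$values))
  out <- crop_padding(out, pv$pad)
  pet_volume(pmax(out, 0), volume$voxel_size, method = "DLE",
             duration_fraction = volume$duration_fraction,
             params = list(variant = model$config$variant %||% "custom",
                           levels = model$config$levels))
}

#' Serialise a network to a single file with an embedded JSON header
#'
#' The file holds one JSON header line (format tag, configuration, widths,
#' seed, tensor inventory) followed by the raw little-endian doubles of all
#' tensors in inventory order.
#'
#' @param model a [dle_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  tensors <- flatten_params(model$params, running = TRUE)
  header <- list(format = "petdle_model", version = 1L,
                 config = unclass(model$config), widths = model$widths,
                 seed = model$seed,
                 tensors = lapply(tensors, function(t)
                   list(name = t$name, dims = t$dims)))
  con <- file(path, "wb")
  on.exit(close(con))
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  writeBin(charToRaw(paste0(hjson, "\n")), con)
  for (t in tensors) writeBin(as.numeric(t$value), con, size = 8,
                              endian = "little")
  invisible(path)
}

#' Read a serialised network
#'
#' @param path file written by [write_model()].
#' @return a [dle_network].
#' @export
read_model <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hchars <- raw(0)
  repeat {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L || ch == charToRaw("\n")) break
    hchars <- c(hchars, ch)
  }
  header <- jsonlite::fromJSON(rawToChar(hchars), simplifyVector = TRUE)
  if (!identical(header$format, "petdle_model"))
    stopf("'%s' is not a petdle model file", path)
  cfg <- network_config(header$config$levels, header$config$base_channels,
                        header$config$channel_multiplier,
                        header$config$final_layer_zero_init)
  cfg$variant <- header$config$variant
  model <- build_network(cfg, seed = header$seed)
  tensors <- flatten_params(model$params, running = TRUE)
  for (i in seq_along(tensors)) {
    t <- tensors[[i]]
    v <- readBin(con, "numeric", prod(t$dims), size = 8, endian = "little")
    model$params <- assign_tensor(model$params, t$name, array(v, dim = t$dims))
  }
  model
}

# Flatten the nested parameter list into named tensors (stable order).
flatten_params <- function(p, running = FALSE) {
  out <- list()
  add <- function(name, value) {
    out[[length(out) + 1L]] <<- list(name = name, value = value,
                                     dims = dim(value) %||% length(value))
  }
  add_block <- function(prefix, bp) {
    add(paste0(prefix, ".convA.W"), bp$convA$W)
    add(paste0(prefix, ".convA.b"), bp$convA$b)
    add(paste0(prefix, ".bnA.gamma"), bp$bnA$gamma)
    add(paste0(prefix, ".bnA.beta"), bp$bnA$beta)
    add(paste0(prefix, ".convB.W"), bp$convB$W)
    add(paste0(prefix, ".convB.b"), bp$convB$b)
    add(paste0(prefix, ".bnB.gamma"), bp$bnB$gamma)
    add(paste0(prefix, ".bnB.beta"), bp$bnB$beta)
    if (running) {
      add(paste0(prefix, ".bnA.run_mean"), bp$bnA$run_mean)
      add(paste0(prefix, ".bnA.run_var"), bp$bnA$run_var)
      add(paste0(prefix, ".bnB.run_mean"), bp$bnB$run_mean)
      add(paste0(prefix, ".bnB.run_var"), bp$bnB$run_var)
    }
  }
  for (l in seq_along(p$enc)) add_block(sprintf("enc%d", l), p$enc[[l]])
  for (l in seq_along(p$dec)) if (!is.null(p$dec[[l]]))
    add_block(sprintf("dec%d", l), p$dec[[l]])
  add("final.W", p$final$W)
  add("final.b", p$final$b)
  out
}

assign_tensor <- function(p, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  grp <- parts[1]; layer <- parts[2]; field <- parts[3]
  if (grp == "final") {
    v <- if (layer == "W") matrix(value, nrow = dim(p$final$W)[1]) else as.numeric(value)
    p$final[[layer]] <- v
    return(p)
  }
  l <- as.integer(sub("^(enc|dec)", "", grp))
  side <- sub("[0-9]+$", "", grp)
  cur <- p[[side]][[l]][[layer]][[field]]
  p[[side]][[l]][[layer]][[field]] <-
    if (is.matrix(cur)) matrix(value, nrow = nrow(cur)) else as.numeric(value)
  p
}
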