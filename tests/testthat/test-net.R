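# naive R reference for the 3x3x3 convolution (zero padding, stride 1)
naive_conv3d <- function(x, W, b) {
  d <- dim(x); X <- d[1]; Y <- d[2]; Z <- d[3]; Cin <- d[4]; N <- d[5]
  Cout <- ncol(W)
  out <- array(0, c(X, Y, Z, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (iz in 1:Z) for (iy in 1:Y)
    for (ix in 1:X) {
      acc <- b[co]
      for (ci in 1:Cin) for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
        sx <- ix + dx - 1L; sy <- iy + dy - 1L; sz <- iz + dz - 1L
        if (sx >= 1 && sx <= X && sy >= 1 && sy <= Y && sz >= 1 && sz <= Z) {
          row <- dx + 3L * (dy + 3L * dz) + 27L * (ci - 1L) + 1L
          acc <- acc + x[sx, sy, sz, ci, n] * W[row, co]
        }
      }
      out[ix, iy, iz, co, n] <- acc
    }
  out
}

test_that("the compiled convolution matches a naive R reference", {
  set.seed(21)
  x <- array(rnorm(5 * 4 * 3 * 2 * 2), c(5, 4, 3, 2, 2))
  W <- matrix(rnorm(27 * 2 * 3), 27 * 2, 3)
  b <- rnorm(3)
  out <- petdle:::conv3d_fw(x, dim(x), W, b)
  expect_equal(out, naive_conv3d(x, W, b), tolerance = 1e-12)
})

test_that("network gradients agree with finite differences", {
  set.seed(22)
  cfg <- network_config(levels = 2, base_channels = 4,
                        final_layer_zero_init = FALSE)
  net <- build_network(cfg, seed = 3)
  xin <- array(abs(rnorm(8 * 8 * 4 * 2)), c(8, 8, 4, 1, 2))
  tgt <- array(abs(rnorm(length(xin))), dim(xin))
  loss_fn <- function(net) {
    fw <- petdle:::net_forward(net, xin, training = TRUE)
    mean((xin + fw$residue - tgt)^2)
  }
  fw <- petdle:::net_forward(net, xin, training = TRUE)
  dres <- 2 * (xin + fw$residue - tgt) / length(xin)
  grads <- petdle:::net_backward(fw$model, fw$cache, dres)
  tens <- petdle:::flatten_params(net$params)
  gten <- petdle:::flatten_params(grads)
  for (ti in seq_along(tens)) {
    t <- tens[[ti]]
    i <- sample(length(t$value), 1L)
    h <- 1e-5
    v1 <- t$value; v1[i] <- v1[i] + h
    v2 <- t$value; v2[i] <- v2[i] - h
    n1 <- net; n2 <- net
    n1$params <- petdle:::assign_tensor(n1$params, t$name, array(v1, dim = t$dims))
    n2$params <- petdle:::assign_tensor(n2$params, t$name, array(v2, dim = t$dims))
    num <- (loss_fn(n1) - loss_fn(n2)) / (2 * h)
    ana <- as.numeric(gten[[ti]]$value)[i]
    expect_lt(abs(num - ana), 1e-6 + 1e-4 * max(abs(num), abs(ana)))
  }
})

test_that("zero-initialised final layer makes the untrained net an identity", {
  net <- build_network(network_config(levels = 3, base_channels = 8), seed = 1)
  vals <- array(runif(16 * 16 * 8, 0, 10), c(16, 16, 8))
  res <- predict_residue(net, vals)
  expect_lt(max(abs(res)), 1e-5)
  enh <- enhance_volume(net, pet_volume(vals, method = "OSEM"))
  expect_lt(max(abs(enh$values - vals)), 1e-5)
  expect_equal(enh$method, "DLE")
})

test_that("residue is definitional and inference is deterministic", {
  net <- build_network(network_config(levels = 2, base_channels = 4,
                                      final_layer_zero_init = FALSE),
                       seed = 7)
  patch <- array(runif(8 * 8 * 4, 0, 5), c(8, 8, 4))
  r1 <- predict_residue(net, patch)
  r2 <- predict_residue(net, patch)
  expect_identical(r1, r2)                      # eval-mode determinism
  expect_equal(dim(r1), dim(patch))             # shape preservation
  expect_gt(max(abs(r1)), 0)                    # non-trivial residue
  bad <- patch; bad[1] <- NaN
  expect_error(predict_residue(net, bad), "NaN")
  # indivisible spatial dims are rejected with the axis named
  expect_error(predict_residue(net, array(1, c(9, 8, 4))), "dim x")
  expect_error(predict_residue(net, array(1, c(8, 8, 5))), "dim z")
})

test_that("parameter counts order the smooth/standard/sharp family", {
  counts <- vapply(c("smooth", "standard", "sharp"), function(v)
    count_params(model_variant(v)), numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("parameter count matches a layer-by-layer analytic oracle", {
  count_cfg <- function(w, levels) {
    conv <- function(cin, cout) 27 * cin * cout + cout
    bn <- function(c) 2 * c
    n <- 0; cin <- 1
    for (l in 1:levels) {
      n <- n + conv(cin, w[l]) + bn(w[l]) + conv(w[l], w[l]) + bn(w[l])
      cin <- w[l]
    }
    for (l in 1:(levels - 1))
      n <- n + conv(w[l] + w[l + 1], w[l]) + bn(w[l]) +
        conv(w[l], w[l]) + bn(w[l])
    n + conv(w[1], 1)
  }
  for (base in c(4L, 8L)) {
    cfg <- network_config(levels = 3, base_channels = base)
    expect_identical(count_params(cfg),
                     as.integer(count_cfg(petdle:::net_widths(cfg), 3)))
  }
  # doubling base_channels roughly quadruples a conv-dominated net
  r <- count_params(network_config(3, 16)) / count_params(network_config(3, 8))
  expect_lt(abs(r - 4), 0.2)
})

test_that("models round-trip through the serialised container", {
  net <- build_network(model_variant("smooth", base_channels = 4), seed = 5)
  # give the running stats non-trivial values
  x <- array(abs(rnorm(8 * 8 * 4)), c(8, 8, 4, 1, 1))
  fw <- petdle:::net_forward(net, x, training = TRUE)
  net <- fw$model
  path <- withr::local_tempfile(fileext = ".bin")
  write_model(net, path)
  back <- read_model(path)
  expect_equal(back$config$channel_multiplier, 0.5)
  p1 <- petdle:::flatten_params(net$params, running = TRUE)
  p2 <- petdle:::flatten_params(back$params, running = TRUE)
  for (i in seq_along(p1))
    expect_equal(as.numeric(p2[[i]]$value), as.numeric(p1[[i]]$value),
                 tolerance = 1e-15, label = p1[[i]]$name)
  # the reloaded model predicts identically
  patch <- array(runif(8 * 8 * 4), c(8, 8, 4))
  expect_equal(predict_residue(back, patch), predict_residue(net, patch))
})
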