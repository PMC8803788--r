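# Layer primitives for the enhancement network. Activations are 5-D arrays
# (X, Y, Z, C, N). Convolutions run through the compiled im2col kernels;
# batch normalisation and ReLU are vectorised R.

conv_init <- function(cin, cout, zero = FALSE, gain = 2) {
  W <- if (zero) matrix(0, 27 * cin, cout)
  else matrix(rnorm(27 * cin * cout, sd = sqrt(gain / (27 * cin))),
              27 * cin, cout)
  list(W = W, b = numeric(cout))
}

conv_fw <- function(x, par) {
  conv3d_fw(x, dim(x), par$W, par$b)
}

conv_bw <- function(x, par, dout) {
  conv3d_bw(x, dim(x), par$W, dout)
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

.bn_eps <- 1e-5

# per-channel sums of a 5-D activation
chan_stat <- function(x, S, C, N, square = FALSE) {
  m <- matrix(if (square) x * x else x, S, C * N)
  rowSums(matrix(colSums(m), C, N))
}

bcast <- function(v, S, C, N) rep(rep(v, each = S), times = N)

bn_fw <- function(x, par, training, momentum = 0.1) {
  d <- dim(x); S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  if (training) {
    m <- S * N
    mu <- chan_stat(x, S, C, N) / m
    var <- chan_stat(x, S, C, N, square = TRUE) / m - mu^2
    var <- pmax(var, 0)
    par$run_mean <- (1 - momentum) * par$run_mean + momentum * mu
    par$run_var <- (1 - momentum) * par$run_var + momentum * var
  } else {
    mu <- par$run_mean; var <- par$run_var
  }
  invstd <- 1 / sqrt(var + .bn_eps)
  xhat <- (x - bcast(mu, S, C, N)) * bcast(invstd, S, C, N)
  y <- xhat * bcast(par$gamma, S, C, N) + bcast(par$beta, S, C, N)
  dim(y) <- d; dim(xhat) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d),
       par = par)
}

bn_bw <- function(cache, gamma, dout) {
  d <- cache$dims; S <- prod(d[1:3]); C <- d[4]; N <- d[5]
  m <- S * N
  xhat <- cache$xhat
  dgamma <- chan_stat(dout * xhat, S, C, N)
  dbeta <- chan_stat(dout, S, C, N)
  dxhat <- dout * bcast(gamma, S, C, N)
  dx <- (bcast(cache$invstd, S, C, N) / m) *
    (m * dxhat - bcast(dbeta * gamma, S, C, N) -
       xhat * bcast(dgamma * gamma, S, C, N))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) {
  y <- pmax(x, 0); dim(y) <- dim(x); y
}

relu_bw <- function(x, dout) {
  dx <- dout * (x > 0); dim(dx) <- dim(x); dx
}

concat_chan <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}
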