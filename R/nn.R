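# Neural-network primitives: SELU, linear, 1-d convolution, GRU, softmax
# cross-entropy, and Adam. Everything is batch-major base-R matrix code with
# hand-written backward passes; analytic gradients are verified against
# finite differences in the test suite. Shapes: batches of sequences are 3-d
# arrays [batch, time, features]; dense activations are [batch, features].

SELU_ALPHA <- 1.6732632423543772
SELU_LAMBDA <- 1.0507009873554805

selu <- function(x) {
  neg <- pmin(x, 0)
  SELU_LAMBDA * (pmax(x, 0) + SELU_ALPHA * (exp(neg) - 1))
}

# derivative wrt pre-activation, given the pre-activation
selu_grad <- function(x) {
  pos <- x > 0
  SELU_LAMBDA * (pos + (!pos) * SELU_ALPHA * exp(pmin(x, 0)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# add a bias row-vector to every row (column-major recycling; faster than sweep)
add_bias <- function(y, b) y + rep(b, each = nrow(y))

# row maxima via max.col (C speed)
row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

# --- parameter initialization ----------------------------------------------

# LeCun-normal init, the standard pairing for SELU self-normalization.
init_linear <- function(fan_in, fan_out) {
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = 1 / sqrt(fan_in)),
                  fan_in, fan_out),
       b = numeric(fan_out))
}

init_gru <- function(input_dim, hidden_dim) {
  s <- 1 / sqrt(hidden_dim)
  list(
    Wx = matrix(stats::runif(input_dim * 3 * hidden_dim, -s, s), input_dim, 3 * hidden_dim),
    Wh = matrix(stats::runif(hidden_dim * 3 * hidden_dim, -s, s), hidden_dim, 3 * hidden_dim),
    bx = numeric(3 * hidden_dim),
    bh = numeric(3 * hidden_dim)
  )
}

# --- dense layer ------------------------------------------------------------

linear_fwd <- function(x, p) {
  list(y = add_bias(x %*% p$W, p$b), x = x)
}

linear_bwd <- function(dy, cache, p) {
  list(dx = dy %*% t(p$W),
       grad = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

# --- 1-d convolution over the time axis (valid padding) ---------------------
# x: [B, L, Cin]; weight W: [k*Cin, Cout]; output: [B, L-k+1, Cout].
# im2col layout: row (b, t) at index b + (t-1)*B, column block j for kernel
# offset j holds x[, t+j-1, ].

conv1d_fwd <- function(x, p, k) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  Lo <- L - k + 1
  stopifnot(Lo >= 1)
  xc <- matrix(0, B * Lo, k * Cin)
  for (j in seq_len(k)) {
    slice <- x[, j:(j + Lo - 1), , drop = FALSE]
    dim(slice) <- c(B * Lo, Cin)
    xc[, ((j - 1) * Cin + 1):(j * Cin)] <- slice
  }
  y <- add_bias(xc %*% p$W, p$b)
  dim(y) <- c(B, Lo, ncol(p$W))
  list(y = y, xc = xc, dims = c(B = B, L = L, Cin = Cin, k = k, Lo = Lo))
}

conv1d_bwd <- function(dy, cache, p) {
  dm <- cache$dims
  B <- dm[["B"]]; L <- dm[["L"]]; Cin <- dm[["Cin"]]; k <- dm[["k"]]; Lo <- dm[["Lo"]]
  Cout <- ncol(p$W)
  dy_m <- dy
  dim(dy_m) <- c(B * Lo, Cout)
  dW <- crossprod(cache$xc, dy_m)
  db <- colSums(dy_m)
  dxc <- dy_m %*% t(p$W)
  dx <- array(0, c(B, L, Cin))
  for (j in seq_len(k)) {
    blk <- dxc[, ((j - 1) * Cin + 1):(j * Cin), drop = FALSE]
    dim(blk) <- c(B, Lo, Cin)
    dx[, j:(j + Lo - 1), ] <- dx[, j:(j + Lo - 1), , drop = FALSE] + blk
  }
  list(dx = dx, grad = list(W = dW, b = db))
}

# --- GRU --------------------------------------------------------------------
# Gate layout in the 3H columns: [reset | update | candidate].
# r = sigmoid(x Wx_r + bx_r + h Wh_r + bh_r)
# u = sigmoid(x Wx_u + bx_u + h Wh_u + bh_u)
# n = tanh(x Wx_n + bx_n + r * (h Wh_n + bh_n))
# h' = (1 - u) * n + u * h

gru_cell_fwd <- function(gx, h, p, H) {
  gh <- add_bias(h %*% p$Wh, p$bh)
  ir <- 1:H; iu <- (H + 1):(2 * H); ic <- (2 * H + 1):(3 * H)
  r <- sigmoid(gx[, ir, drop = FALSE] + gh[, ir, drop = FALSE])
  u <- sigmoid(gx[, iu, drop = FALSE] + gh[, iu, drop = FALSE])
  ghn <- gh[, ic, drop = FALSE]
  n <- tanh(gx[, ic, drop = FALSE] + r * ghn)
  h_new <- (1 - u) * n + u * h
  list(h = h_new, r = r, u = u, n = n, ghn = ghn, h_prev = h)
}

# Full-sequence forward. x: [B, L, D]; h0: [B, H].
gru_seq_fwd <- function(x, h0, p) {
  d <- dim(x); B <- d[1]; L <- d[2]; D <- d[3]
  H <- ncol(p$Wh)/3
  xm <- x
  dim(xm) <- c(B * L, D)
  gx_all <- add_bias(xm %*% p$Wx, p$bx)
  h <- h0
  hs <- array(0, c(B, L, H))
  caches <- vector("list", L)
  for (t in seq_len(L)) {
    gx <- gx_all[(t - 1) * B + seq_len(B), , drop = FALSE]
    st <- gru_cell_fwd(gx, h, p, H)
    h <- st$h
    hs[, t, ] <- h
    caches[[t]] <- st
  }
  list(y = hs, caches = caches, x = x, h0 = h0)
}

# dy: [B, L, H] gradient on outputs. Returns dx [B,L,D], dh0, parameter grads.
gru_seq_bwd <- function(dy, fwd, p) {
  x <- fwd$x
  d <- dim(x); B <- d[1]; L <- d[2]; D <- d[3]
  H <- ncol(p$Wh)/3
  ir <- 1:H; iu <- (H + 1):(2 * H); ic <- (2 * H + 1):(3 * H)
  dWx <- matrix(0, D, 3 * H); dWh <- matrix(0, H, 3 * H)
  dbx <- numeric(3 * H); dbh <- numeric(3 * H)
  dgx_all <- matrix(0, B * L, 3 * H)
  dh <- matrix(0, B, H)
  for (t in rev(seq_len(L))) {
    st <- fwd$caches[[t]]
    dh_t <- dh + dy[, t, ]
    dn <- dh_t * (1 - st$u)
    du <- dh_t * (st$h_prev - st$n)
    dh <- dh_t * st$u
    dgn <- dn * (1 - st$n^2)       # pre-tanh
    dr <- dgn * st$ghn
    dghn <- dgn * st$r
    dgu <- du * st$u * (1 - st$u)  # pre-sigmoid
    dgr <- dr * st$r * (1 - st$r)
    dgx <- cbind(dgr, dgu, dgn)
    dgh <- cbind(dgr, dgu, dghn)
    dgx_all[(t - 1) * B + seq_len(B), ] <- dgx
    dWh <- dWh + crossprod(st$h_prev, dgh)
    dbh <- dbh + colSums(dgh)
    dh <- dh + dgh %*% t(p$Wh)
  }
  xm <- x
  dim(xm) <- c(B * L, D)
  dWx <- crossprod(xm, dgx_all)
  dbx <- colSums(dgx_all)
  dx <- dgx_all %*% t(p$Wx)
  dim(dx) <- c(B, L, D)
  list(dx = dx, dh0 = dh,
       grad = list(Wx = dWx, Wh = dWh, bx = dbx, bh = dbh))
}

# Single-step forward for generation mode; x: [B, D], h: [B, H].
gru_step <- function(x, h, p) {
  H <- ncol(p$Wh)/3
  gru_cell_fwd(add_bias(x %*% p$Wx, p$bx), h, p, H)$h
}

# --- GRU with an input that is constant over time (the latent point) --------
# Avoids materializing the [B, L, D] input tensor; gx is computed once.

gru_seq_fwd_const <- function(z, L, h0, p) {
  B <- nrow(z)
  H <- ncol(p$Wh)/3
  gx <- add_bias(z %*% p$Wx, p$bx)
  h <- h0
  hs <- array(0, c(B, L, H))
  caches <- vector("list", L)
  for (t in seq_len(L)) {
    st <- gru_cell_fwd(gx, h, p, H)
    h <- st$h
    hs[, t, ] <- h
    caches[[t]] <- st
  }
  list(y = hs, caches = caches, z = z, h0 = h0)
}

gru_seq_bwd_const <- function(dy, fwd, p) {
  z <- fwd$z
  B <- nrow(z); L <- dim(dy)[2]
  H <- ncol(p$Wh)/3
  dWh <- matrix(0, H, 3 * H)
  dbh <- numeric(3 * H)
  dgx_sum <- matrix(0, B, 3 * H)
  dh <- matrix(0, B, H)
  for (t in rev(seq_len(L))) {
    st <- fwd$caches[[t]]
    dh_t <- dh + dy[, t, ]
    dn <- dh_t * (1 - st$u)
    du <- dh_t * (st$h_prev - st$n)
    dh <- dh_t * st$u
    dgn <- dn * (1 - st$n^2)
    dr <- dgn * st$ghn
    dghn <- dgn * st$r
    dgu <- du * st$u * (1 - st$u)
    dgr <- dr * st$r * (1 - st$r)
    dgx <- cbind(dgr, dgu, dgn)
    dgh <- cbind(dgr, dgu, dghn)
    dgx_sum <- dgx_sum + dgx
    dWh <- dWh + crossprod(st$h_prev, dgh)
    dbh <- dbh + colSums(dgh)
    dh <- dh + dgh %*% t(p$Wh)
  }
  list(dz = dgx_sum %*% t(p$Wx), dh0 = dh,
       grad = list(Wx = crossprod(z, dgx_sum), Wh = dWh,
                   bx = colSums(dgx_sum), bh = dbh))
}

# --- softmax cross-entropy over sequences -----------------------------------
# logits: [B, L, V]; target_idx: [B, L] 1-based token indices.
# Loss = mean over batch of sum over positions of -log p(target).
# Returns per-position log-probabilities as well (for DecoderOutput).

softmax_xent_fwd <- function(logits, target_idx) {
  d <- dim(logits); B <- d[1]; L <- d[2]; V <- d[3]
  lm <- logits
  dim(lm) <- c(B * L, V)
  mx <- row_max(lm)
  sh <- lm - mx
  lse <- log(rowSums(exp(sh)))
  logp <- sh - lse
  tgt <- as.vector(target_idx)  # column-major: (b, t) -> b + (t-1)B, matches
  picked <- logp[cbind(seq_len(B * L), tgt)]
  loss <- -sum(picked) / B
  probs <- exp(logp)
  list(loss = loss, logp = logp, probs = probs, dims = d, target = tgt)
}

softmax_xent_bwd <- function(cache) {
  d <- cache$dims; B <- d[1]
  dlogits <- cache$probs
  dlogits[cbind(seq_len(nrow(dlogits)), cache$target)] <-
    dlogits[cbind(seq_len(nrow(dlogits)), cache$target)] - 1
  dlogits <- dlogits / B
  dim(dlogits) <- d
  dlogits
}

# --- Adam -------------------------------------------------------------------
# Parameters and gradients are nested named lists of matrices/vectors with
# identical structure.

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 3.1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# elementwise sum of two gradient lists with identical structure
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(Map(grad_add, a, b))
  a + b
}

grad_scale <- function(a, s) {
  if (is.list(a)) return(lapply(a, grad_scale, s = s))
  a * s
}
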