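# The autoencoder networks. Encoder: three 1-d convolutions over the one-hot
# token sequence, SELU activations, then two dense layers; the final layer is
# read as the mean and log-variance of a diagonal Gaussian posterior (VAE) or
# as the latent point itself (deterministic encoder, used by the adversarial
# variants). Decoder: one dense layer maps the latent point to the initial
# hidden states of three stacked GRU layers; the latent point is additionally
# concatenated as input to the first GRU layer at every step; with teacher
# forcing the last GRU layer also receives the previous target token (training
# mode) or the previously sampled token (generation mode). A final dense
# layer produces per-position token log-probabilities.

#' Autoencoder architecture configuration
#'
#' Layer counts are fixed (three convolutions + two dense layers in the
#' encoder; one dense layer + three GRU layers in the decoder; SELU
#' activations throughout); all widths are configurable. Defaults are sized
#' for desk-scale experiments; `latent_dim` defaults to the 56 dimensions
#' used for full-corpus training.
#'
#' @param latent_dim Latent-space dimensionality (default 56).
#' @param max_length Tokens per sequence (default 120).
#' @param conv_channels Integer vector of length 3: feature maps per
#'   convolution layer.
#' @param conv_kernels Integer vector of length 3: kernel sizes.
#' @param fc_dim Width of the encoder's intermediate dense layer.
#' @param gru_hidden Hidden units per GRU layer.
#' @param teacher_forcing Feed the previous token to the last GRU layer.
#' @param variational Encoder returns a Gaussian posterior (`TRUE`, VAE) or a
#'   deterministic latent point (`FALSE`, adversarial variants).
#' @param kl_max Final KL weight of the annealing schedule (1 reproduces the
#'   plain variational objective).
#' @param kl_anneal_epochs Epochs over which the KL weight ramps linearly
#'   from 0 to `kl_max`.
#' @param disc_hidden Integer vector of length 2: hidden widths of the
#'   adversarial discriminator (used by the adversarial variants only).
#' @return A `model_config` list.
#' @export
model_config <- function(latent_dim = 56L, max_length = 120L,
                         conv_channels = c(9L, 9L, 10L),
                         conv_kernels = c(9L, 9L, 11L),
                         fc_dim = 196L, gru_hidden = 100L,
                         teacher_forcing = TRUE, variational = TRUE,
                         kl_max = 1, kl_anneal_epochs = 100L,
                         disc_hidden = c(256L, 256L)) {
  stopifnot(latent_dim > 0, length(conv_channels) == 3L,
            length(conv_kernels) == 3L, fc_dim > 0, gru_hidden > 0,
            kl_max >= 0)
  structure(
    list(latent_dim = as.integer(latent_dim),
         max_length = as.integer(max_length),
         conv_channels = as.integer(conv_channels),
         conv_kernels = as.integer(conv_kernels),
         fc_dim = as.integer(fc_dim),
         gru_hidden = as.integer(gru_hidden),
         teacher_forcing = isTRUE(teacher_forcing),
         variational = isTRUE(variational),
         kl_max = kl_max,
         kl_anneal_epochs = as.integer(kl_anneal_epochs),
         disc_hidden = as.integer(disc_hidden)),
    class = "model_config"
  )
}

# Initialize all parameters for a given vocabulary size.
init_autoencoder_params <- function(config, vocab_size) {
  L <- config$max_length
  ck <- config$conv_kernels; cc <- config$conv_channels
  L1 <- L - ck[1] + 1; L2 <- L1 - ck[2] + 1; L3 <- L2 - ck[3] + 1
  stopifnot(L3 >= 1)
  H <- config$gru_hidden; Z <- config$latent_dim
  enc_out <- if (config$variational) 2L * Z else Z
  list(
    enc = list(
      conv1 = init_linear(ck[1] * vocab_size, cc[1]),
      conv2 = init_linear(ck[2] * cc[1], cc[2]),
      conv3 = init_linear(ck[3] * cc[2], cc[3]),
      fc1 = init_linear(L3 * cc[3], config$fc_dim),
      fc2 = init_linear(config$fc_dim, enc_out)
    ),
    dec = list(
      fc = init_linear(Z, 3L * H),
      gru1 = init_gru(Z, H),
      gru2 = init_gru(H, H),
      gru3 = init_gru(H + if (config$teacher_forcing) vocab_size else 0L, H),
      out = init_linear(H, vocab_size)
    )
  )
}

# one-hot tensor [B, L, V] from an index matrix [B, L]
onehot_tensor <- function(idx, vocab_size) {
  B <- nrow(idx); L <- ncol(idx)
  x <- array(0, c(B, L, vocab_size))
  x[cbind(rep(seq_len(B), L), rep(seq_len(L), each = B), as.vector(idx))] <- 1
  x
}

# --- encoder ----------------------------------------------------------------

encoder_fwd <- function(x, params, config) {
  ck <- config$conv_kernels
  c1 <- conv1d_fwd(x, params$conv1, ck[1]); a1 <- selu(c1$y)
  c2 <- conv1d_fwd(a1, params$conv2, ck[2]); a2 <- selu(c2$y)
  c3 <- conv1d_fwd(a2, params$conv3, ck[3]); a3 <- selu(c3$y)
  B <- dim(x)[1]
  flat <- a3
  dim(flat) <- c(B, prod(dim(a3)[2:3]))
  f1 <- linear_fwd(flat, params$fc1); a4 <- selu(f1$y)
  f2 <- linear_fwd(a4, params$fc2)
  list(out = f2$y,
       cache = list(c1 = c1, c2 = c2, c3 = c3, f1 = f1, f2 = f2,
                    a3dim = dim(a3)))
}

encoder_bwd <- function(dout, fwd, params) {
  cc <- fwd$cache
  b2 <- linear_bwd(dout, cc$f2, params$fc2)
  da4 <- b2$dx * selu_grad(cc$f1$y)
  b1 <- linear_bwd(da4, cc$f1, params$fc1)
  dflat <- b1$dx
  dim(dflat) <- cc$a3dim
  da3 <- dflat * selu_grad(cc$c3$y)
  bc3 <- conv1d_bwd(da3, cc$c3, params$conv3)
  da2 <- bc3$dx * selu_grad(cc$c2$y)
  bc2 <- conv1d_bwd(da2, cc$c2, params$conv2)
  da1 <- bc2$dx * selu_grad(cc$c1$y)
  bc1 <- conv1d_bwd(da1, cc$c1, params$conv1)
  list(grad = list(conv1 = bc1$grad, conv2 = bc2$grad, conv3 = bc3$grad,
                   fc1 = b1$grad, fc2 = b2$grad))
}

# --- decoder (training mode, full sequences) --------------------------------
# z: [B, Z]; target_idx: [B, L] used both for teacher forcing (shifted right
# one step) and as the reconstruction target.

decoder_fwd <- function(z, target_idx, params, config, vocab_size) {
  B <- nrow(z); L <- config$max_length; H <- config$gru_hidden
  fc <- linear_fwd(z, params$fc)
  h0_all <- selu(fc$y)
  h01 <- h0_all[, 1:H, drop = FALSE]
  h02 <- h0_all[, (H + 1):(2 * H), drop = FALSE]
  h03 <- h0_all[, (2 * H + 1):(3 * H), drop = FALSE]

  g1 <- gru_seq_fwd_const(z, L, h01, params$gru1)
  g2 <- gru_seq_fwd(g1$y, h02, params$gru2)

  if (config$teacher_forcing) {
    prev <- cbind(0L, target_idx[, -L, drop = FALSE])  # 0 marks "no token"
    yprev <- array(0, c(B, L, vocab_size))
    nz <- which(prev > 0L, arr.ind = TRUE)
    if (nrow(nz) > 0L) {
      yprev[cbind(nz[, 1], nz[, 2], prev[nz])] <- 1
    }
    x3 <- array(0, c(B, L, H + vocab_size))
    x3[, , 1:H] <- g2$y
    x3[, , (H + 1):(H + vocab_size)] <- yprev
  } else {
    x3 <- g2$y
  }
  g3 <- gru_seq_fwd(x3, h03, params$gru3)

  h3m <- g3$y
  dim(h3m) <- c(B * L, H)
  out <- linear_fwd(h3m, params$out)
  logits <- out$y
  dim(logits) <- c(B, L, vocab_size)
  list(logits = logits,
       cache = list(fc = fc, g1 = g1, g2 = g2, g3 = g3, out = out,
                    h0_all = h0_all, B = B, L = L, H = H))
}

decoder_bwd <- function(dlogits, fwd, params, config) {
  cc <- fwd$cache
  B <- cc$B; L <- cc$L; H <- cc$H
  dlm <- dlogits
  dim(dlm) <- c(B * L, dim(dlogits)[3])
  bo <- linear_bwd(dlm, cc$out, params$out)
  dh3 <- bo$dx
  dim(dh3) <- c(B, L, H)
  b3 <- gru_seq_bwd(dh3, cc$g3, params$gru3)
  dx3 <- b3$dx
  dh2_seq <- if (config$teacher_forcing) dx3[, , 1:H, drop = FALSE] else dx3
  dim(dh2_seq) <- c(B, L, H)
  b2 <- gru_seq_bwd(dh2_seq, cc$g2, params$gru2)
  b1 <- gru_seq_bwd_const(b2$dx, cc$g1, params$gru1)
  dz_steps <- b1$dz  # latent fed at every step

  dh0_all <- cbind(b1$dh0, b2$dh0, b3$dh0)
  dfc_pre <- dh0_all * selu_grad(cc$fc$y)
  bfc <- linear_bwd(dfc_pre, cc$fc, params$fc)
  dz <- dz_steps + bfc$dx
  list(dz = dz,
       grad = list(fc = bfc$grad, gru1 = b1$grad, gru2 = b2$grad,
                   gru3 = b3$grad, out = bo$grad))
}

# --- spec-level operations --------------------------------------------------

#' Encode sequences to the Gaussian posterior
#'
#' Runs the encoder on one-hot sequences and returns the mean and
#' log-variance of the diagonal Gaussian posterior q(z|X). Deterministic
#' given the parameters and input. For deterministic-encoder models
#' (adversarial variants) the log-variance is `-Inf` conceptually; here the
#' mean alone is returned in `$mean` and `$log_variance` is `NULL`.
#'
#' @param model A trained `molecular_autoencoder` (or a params/config/vocab
#'   list of the same shape).
#' @param smiles Character vector of SMILES, or a data frame with a `smiles`
#'   column, or an index matrix from `encode_corpus()`.
#' @return List with `mean` (n x latent_dim matrix) and `log_variance`
#'   (matrix or `NULL`).
#' @export
encode_posterior <- function(model, smiles) {
  idx <- if (is.matrix(smiles)) smiles else encode_corpus(smiles, model$vocab)
  V <- length(model$vocab$tokens)
  x <- onehot_tensor(idx, V)
  out <- encoder_fwd(x, model$params$enc, model$config)$out
  Z <- model$config$latent_dim
  if (model$config$variational) {
    list(mean = out[, 1:Z, drop = FALSE],
         log_variance = out[, (Z + 1):(2 * Z), drop = FALSE])
  } else {
    list(mean = out, log_variance = NULL)
  }
}

#' Sample latent points by the reparameterization trick
#'
#' Draws z = mu + sigma * eps with eps ~ N(0, I), using R's RNG stream so a
#' fixed seed reproduces the draw.
#'
#' @param posterior List with `mean` and `log_variance` matrices (rows =
#'   samples), as returned by [encode_posterior()].
#' @return Matrix of latent points, same shape as `posterior$mean`.
#' @export
reparameterized_sample <- function(posterior) {
  mu <- posterior$mean
  if (is.null(posterior$log_variance)) return(mu)
  sigma <- exp(0.5 * posterior$log_variance)
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + sigma * eps
}

#' KL divergence of a diagonal Gaussian posterior from N(0, I)
#'
#' Closed form: -1/2 sum_i (1 + log sigma_i^2 - mu_i^2 - sigma_i^2),
#' computed per row and always nonnegative.
#'
#' @param mean Matrix (n x d) of posterior means.
#' @param log_variance Matrix (n x d) of posterior log-variances.
#' @return Numeric vector of n KL divergences.
#' @export
kl_to_standard_normal <- function(mean, log_variance) {
  stopifnot(all(dim(mean) == dim(log_variance)))
  -0.5 * rowSums(1 + log_variance - mean^2 - exp(log_variance))
}

#' Variational loss
#'
#' Reconstruction negative log-likelihood (summed over all sequence
#' positions, pad included, averaged over the batch) plus `kl_weight` times
#' the KL divergence of the posterior from N(0, I). With `kl_weight = 1` this
#' is the negative of the usual variational objective.
#'
#' @param logits Decoder output array `[n, max_length, vocab]` of
#'   (unnormalized) scores; log-probabilities are formed internally.
#' @param target_idx Integer matrix `[n, max_length]` of target token
#'   indices.
#' @param posterior List with `mean` and `log_variance` (may be `NULL` for a
#'   deterministic encoder, in which case the KL term is 0).
#' @param kl_weight Scalar weight on the KL term.
#' @return Scalar loss (batch mean).
#' @export
vae_loss <- function(logits, target_idx, posterior, kl_weight = 1) {
  sm <- softmax_xent_fwd(logits, target_idx)
  kl <- if (!is.null(posterior$log_variance)) {
    mean(kl_to_standard_normal(posterior$mean, posterior$log_variance))
  } else 0
  sm$loss + kl_weight * kl
}

#' Teacher-forced decoding of latent points against a target
#'
#' Runs the decoder in training mode and returns per-position token
#' log-probabilities. With teacher forcing the prediction at position t is
#' conditioned on the true target token at t-1; without, the decoder sees
#' only the previous GRU layer's output, so the logits are independent of the
#' target content.
#'
#' @param model A `molecular_autoencoder`.
#' @param z Matrix of latent points (rows).
#' @param target_idx Integer matrix of target token indices.
#' @return Array `[n, max_length, vocab]` of log-probabilities (each
#'   position's row exponentiates and sums to 1).
#' @export
decode_train <- function(model, z, target_idx) {
  V <- length(model$vocab$tokens)
  fwd <- decoder_fwd(z, target_idx, model$params$dec, model$config, V)
  d <- dim(fwd$logits)
  lm <- fwd$logits
  dim(lm) <- c(d[1] * d[2], d[3])
  mx <- row_max(lm)
  logp <- lm - mx - log(rowSums(exp(lm - mx)))
  dim(logp) <- d
  logp
}
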