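# Adversarial autoencoder machinery: the discriminator network, the
# discriminator/generator losses, prior sampling, and the three-step
# per-batch training loop (reconstruction; discriminator; encoder-as-
# generator). The encoder is deterministic here — no reparameterized noise —
# and the decoder always uses teacher forcing.

#' Latent prior specification
#'
#' @param family `"standard_gaussian"` (zero mean, unit variance per
#'   coordinate) or `"uniform"` (independent per-coordinate uniform).
#' @param lower,upper Bounds for the uniform family (defaults -1, 1).
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(family = c("standard_gaussian", "uniform"),
                       lower = -1, upper = 1) {
  family <- match.arg(family)
  if (family == "uniform") stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  structure(list(family = family, lower = lower, upper = upper),
            class = "prior_spec")
}

#' Sample i.i.d. latent points from a prior
#'
#' @param prior A [prior_spec()].
#' @param n Number of points.
#' @param dim Latent dimensionality.
#' @return `n` x `dim` matrix of draws from R's RNG stream (seed-reproducible).
#' @export
sample_prior <- function(prior, n, dim) {
  stopifnot(n > 0, dim > 0)
  if (prior$family == "standard_gaussian") {
    matrix(stats::rnorm(n * dim), n, dim)
  } else {
    matrix(stats::runif(n * dim, prior$lower, prior$upper), n, dim)
  }
}

# discriminator: affine -> affine + SELU -> affine + sigmoid
init_discriminator_params <- function(latent_dim, hidden = c(256L, 256L)) {
  list(fc1 = init_linear(latent_dim, hidden[1]),
       fc2 = init_linear(hidden[1], hidden[2]),
       fc3 = init_linear(hidden[2], 1L))
}

disc_fwd <- function(z, p) {
  f1 <- linear_fwd(z, p$fc1)               # affine only
  f2 <- linear_fwd(f1$y, p$fc2)
  a2 <- selu(f2$y)
  f3 <- linear_fwd(a2, p$fc3)
  prob <- sigmoid(f3$y)
  list(prob = as.vector(prob), logit = as.vector(f3$y),
       cache = list(f1 = f1, f2 = f2, f3 = f3))
}

# dlogit: vector of gradients wrt the pre-sigmoid output
disc_bwd <- function(dlogit, fwd, p) {
  cc <- fwd$cache
  b3 <- linear_bwd(matrix(dlogit, ncol = 1), cc$f3, p$fc3)
  da2 <- b3$dx * selu_grad(cc$f2$y)
  b2 <- linear_bwd(da2, cc$f2, p$fc2)
  b1 <- linear_bwd(b2$dx, cc$f1, p$fc1)
  list(dz = b1$dx,
       grad = list(fc1 = b1$grad, fc2 = b2$grad, fc3 = b3$grad))
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Discriminator loss
#'
#' `-(log D(z') + log(1 - D(z)))`, averaged over the batch, where `d_real`
#' are discriminator outputs on prior samples z' and `d_fake` on encoder
#' outputs z. Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the
#' logarithms.
#'
#' @param d_real,d_fake Vectors of discriminator probabilities.
#' @return Scalar loss (nonnegative).
#' @export
discriminator_loss <- function(d_real, d_fake) {
  d_real <- clamp_prob(d_real); d_fake <- clamp_prob(d_fake)
  -mean(log(d_real) + log(1 - d_fake))
}

#' Generator (encoder) loss
#'
#' `-log D(z)`, averaged over the batch: the encoder is trained to fool the
#' discriminator by driving D's output on encoded points toward 1.
#'
#' @param d_fake Vector of discriminator probabilities on encoder outputs.
#' @return Scalar loss; strictly decreasing in `d_fake`.
#' @export
generator_loss <- function(d_fake) {
  -mean(log(clamp_prob(d_fake)))
}

# One adversarial training step on a batch: exactly three optimizer updates
# in order. `st` carries params and the three Adam states; returns the
# updated `st` plus the three batch losses.
aae_training_step <- function(st, idx_batch, prior, config, vocab_size, lr) {
  x <- onehot_tensor(idx_batch, vocab_size)
  B <- nrow(idx_batch)

  # step 1: encoder + decoder on reconstruction loss
  ef <- encoder_fwd(x, st$params$enc, config)
  z <- ef$out
  df <- decoder_fwd(z, idx_batch, st$params$dec, config, vocab_size)
  sm <- softmax_xent_fwd(df$logits, idx_batch)
  recon_loss <- sm$loss
  if (!is.finite(recon_loss)) stop("reconstruction loss is not finite; aborting")
  dlogits <- softmax_xent_bwd(sm)
  db <- decoder_bwd(dlogits, df, st$params$dec, config)
  eb <- encoder_bwd(db$dz, ef, st$params$enc)
  up <- adam_step(list(enc = st$params$enc, dec = st$params$dec),
                  list(enc = eb$grad, dec = db$grad), st$opt_ae, lr = lr)
  st$params$enc <- up$params$enc
  st$params$dec <- up$params$dec
  st$opt_ae <- up$state

  # step 2: discriminator on fresh prior samples vs current encodings
  z_fake <- encoder_fwd(x, st$params$enc, config)$out
  z_real <- sample_prior(prior, B, config$latent_dim)
  fr <- disc_fwd(z_real, st$params$disc)
  ff <- disc_fwd(z_fake, st$params$disc)
  d_loss <- discriminator_loss(fr$prob, ff$prob)
  if (!is.finite(d_loss)) stop("discriminator loss is not finite; aborting")
  # d/dlogit of -log(sigmoid) is -(1 - p); of -log(1 - sigmoid) is p
  g_real <- disc_bwd(-(1 - fr$prob) / B, fr, st$params$disc)$grad
  g_fake <- disc_bwd(ff$prob / B, ff, st$params$disc)$grad
  up <- adam_step(st$params$disc, grad_add(g_real, g_fake), st$opt_disc, lr = lr)
  st$params$disc <- up$params
  st$opt_disc <- up$state

  # step 3: encoder fools the (frozen) discriminator
  ef3 <- encoder_fwd(x, st$params$enc, config)
  f3 <- disc_fwd(ef3$out, st$params$disc)
  g_loss <- generator_loss(f3$prob)
  if (!is.finite(g_loss)) stop("generator loss is not finite; aborting")
  dz <- disc_bwd(-(1 - f3$prob) / B, f3, st$params$disc)$dz
  eb3 <- encoder_bwd(dz, ef3, st$params$enc)
  up <- adam_step(st$params$enc, eb3$grad, st$opt_gen, lr = lr)
  st$params$enc <- up$params
  st$opt_gen <- up$state

  st$losses <- c(reconstruction_loss = recon_loss,
                 discriminator_loss = d_loss,
                 generator_loss = g_loss)
  st
}
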