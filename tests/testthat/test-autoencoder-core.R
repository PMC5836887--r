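# Core network mathematics: closed-form KL against quadrature, the
# variational loss identities, posterior determinism, reparameterization
# statistics, and finite-difference verification of the hand-written
# backward passes.

test_that("KL closed form matches per-coordinate quadrature on random posteriors", {
  # per-coordinate KL integrand: q(x) log(q(x)/p(x))
  kl_quadrature <- function(mu, lv) {
    s <- exp(0.5 * lv)
    f <- function(x) {
      q <- stats::dnorm(x, mu, s)
      p <- stats::dnorm(x)
      ifelse(q > 0, q * (log(q) - log(p)), 0)
    }
    stats::integrate(f, mu - 12 * s, mu + 12 * s, rel.tol = 1e-10)$value
  }
  set.seed(101)
  max_err <- 0
  for (i in 1:100) {
    d <- sample(1:4, 1)
    mu <- matrix(stats::rnorm(d, sd = 1.5), 1)
    lv <- matrix(stats::runif(d, -2, 2), 1)
    closed <- kl_to_standard_normal(mu, lv)
    quad <- sum(vapply(seq_len(d), function(j) kl_quadrature(mu[j], lv[j]),
                       numeric(1)))
    max_err <- max(max_err, abs(closed - quad))
  }
  expect_lt(max_err, 1e-6)
})

test_that("KL is zero at the prior and nonnegative everywhere", {
  expect_equal(kl_to_standard_normal(matrix(0, 1, 5), matrix(0, 1, 5)), 0)
  set.seed(7)
  mu <- matrix(rnorm(200), 20)
  lv <- matrix(runif(200, -3, 3), 20)
  expect_true(all(kl_to_standard_normal(mu, lv) >= 0))
})

test_that("variational loss reduces to its closed forms", {
  V <- 5L; L <- 8L
  idx <- matrix(sample.int(V, L, replace = TRUE), 1, L)
  # perfect predictions: huge logit on the target token
  logits <- array(-50, c(1, L, V))
  for (t in seq_len(L)) logits[1, t, idx[1, t]] <- 50
  q0 <- list(mean = matrix(0, 1, 3), log_variance = matrix(0, 1, 3))
  expect_equal(vae_loss(logits, idx, q0, kl_weight = 1), 0, tolerance = 1e-8)

  # uniform predictions: reconstruction term is L * log(V)
  logits_u <- array(0, c(1, L, V))
  expect_equal(vae_loss(logits_u, idx, q0, kl_weight = 1), L * log(V),
               tolerance = 1e-10)

  # kl_weight 0 drops the KL term entirely
  q1 <- list(mean = matrix(2, 1, 3), log_variance = matrix(1, 1, 3))
  expect_equal(vae_loss(logits_u, idx, q1, kl_weight = 0), L * log(V),
               tolerance = 1e-10)
  expect_equal(vae_loss(logits_u, idx, q1, kl_weight = 2),
               L * log(V) + 2 * mean(kl_to_standard_normal(q1$mean, q1$log_variance)),
               tolerance = 1e-10)
})

test_that("reparameterized sampling has the right statistics and determinism", {
  post <- list(mean = matrix(c(1, -2), 1), log_variance = matrix(c(0.5, -1), 1))
  z1 <- with_seed <- local({ set.seed(5); reparameterized_sample(post) })
  z2 <- local({ set.seed(5); reparameterized_sample(post) })
  expect_identical(z1, z2)

  # degenerate variance collapses to the mean
  post0 <- list(mean = matrix(c(1, -2), 1), log_variance = matrix(-745, 1, 2))
  expect_equal(reparameterized_sample(post0), post0$mean, tolerance = 1e-12)

  # Monte-Carlo mean within 4 sigma / sqrt(n) per coordinate
  set.seed(6)
  n <- 1e5
  post_big <- list(mean = matrix(rep(c(1, -2), each = n), n),
                   log_variance = matrix(rep(c(0.5, -1), each = n), n))
  draws <- reparameterized_sample(post_big)
  sig <- exp(0.5 * c(0.5, -1))
  for (j in 1:2) {
    expect_lt(abs(mean(draws[, j]) - c(1, -2)[j]), 4 * sig[j] / sqrt(n))
  }
})

test_that("decoder log-probabilities normalize and teacher forcing behaves per contract", {
  set.seed(20)
  cfg <- model_config(latent_dim = 4L, max_length = 8L,
                      conv_channels = c(3L, 3L, 3L), conv_kernels = c(2L, 2L, 2L),
                      fc_dim = 10L, gru_hidden = 6L, teacher_forcing = TRUE)
  V <- 5L
  params <- latentmol:::init_autoencoder_params(cfg, V)
  vocab <- latentmol:::new_vocabulary(c(" ", "(", ")", "C", "O"), 8L)
  model <- list(params = params, config = cfg, vocab = vocab)
  z <- matrix(rnorm(2 * 4), 2)
  tgt <- matrix(sample.int(V, 16, replace = TRUE), 2, 8)

  logp <- decode_train(model, z, tgt)
  sums <- apply(logp, c(1, 2), function(r) sum(exp(r)))
  expect_equal(unname(as.vector(sums)), rep(1, 16), tolerance = 1e-9)

  # with teacher forcing, perturbing the target at position t changes
  # predictions after t but never at or before t
  tgt2 <- tgt; tgt2[1, 4] <- (tgt[1, 4] %% V) + 1L
  logp2 <- decode_train(model, z, tgt2)
  expect_equal(logp2[1, 1:4, ], logp[1, 1:4, ], tolerance = 1e-12)
  expect_gt(max(abs(logp2[1, 5:8, ] - logp[1, 5:8, ])), 1e-8)

  # without teacher forcing, the output ignores the target entirely
  cfg_nt <- cfg; cfg_nt$teacher_forcing <- FALSE
  params_nt <- latentmol:::init_autoencoder_params(cfg_nt, V)
  model_nt <- list(params = params_nt, config = cfg_nt, vocab = vocab)
  a <- decode_train(model_nt, z, tgt)
  b <- decode_train(model_nt, z, tgt2)
  expect_equal(a, b, tolerance = 1e-15)
})

test_that("posterior encoding is deterministic with the configured latent width", {
  set.seed(21)
  cfg <- model_config(latent_dim = 56L, max_length = 20L,
                      conv_channels = c(4L, 4L, 4L), conv_kernels = c(3L, 3L, 3L),
                      fc_dim = 24L, gru_hidden = 8L)
  corpus <- c("CCOC(=O)CCC", "CC(C)CCCO")
  vocab <- build_vocabulary(corpus, max_length = 20L)
  params <- latentmol:::init_autoencoder_params(cfg, length(vocab$tokens))
  model <- list(params = params, config = cfg, vocab = vocab)
  p1 <- encode_posterior(model, corpus)
  p2 <- encode_posterior(model, corpus)
  expect_identical(p1, p2)
  expect_identical(dim(p1$mean), c(2L, 56L))
  expect_identical(dim(p1$log_variance), c(2L, 56L))
  expect_true(all(is.finite(p1$mean)), all(is.finite(p1$log_variance)))
})

test_that("analytic gradients match finite differences through the whole model", {
  set.seed(42)
  V <- 6L
  cfg <- model_config(latent_dim = 3L, max_length = 7L,
                      conv_channels = c(2L, 2L, 2L), conv_kernels = c(2L, 2L, 2L),
                      fc_dim = 5L, gru_hidden = 4L, teacher_forcing = TRUE)
  params <- latentmol:::init_autoencoder_params(cfg, V)
  B <- 2L
  idx <- matrix(sample.int(V, B * cfg$max_length, replace = TRUE), B)
  eps_fix <- matrix(rnorm(B * cfg$latent_dim), B)
  kl_w <- 0.7

  loss_fn <- function(p) {
    x <- latentmol:::onehot_tensor(idx, V)
    ef <- latentmol:::encoder_fwd(x, p$enc, cfg)
    Z <- cfg$latent_dim
    mu <- ef$out[, 1:Z, drop = FALSE]
    lv <- ef$out[, (Z + 1):(2 * Z), drop = FALSE]
    z <- mu + exp(0.5 * lv) * eps_fix
    df <- latentmol:::decoder_fwd(z, idx, p$dec, cfg, V)
    sm <- latentmol:::softmax_xent_fwd(df$logits, idx)
    sm$loss + kl_w * mean(kl_to_standard_normal(mu, lv))
  }
  grad_fn <- function(p) {
    x <- latentmol:::onehot_tensor(idx, V)
    ef <- latentmol:::encoder_fwd(x, p$enc, cfg)
    Z <- cfg$latent_dim
    mu <- ef$out[, 1:Z, drop = FALSE]
    lv <- ef$out[, (Z + 1):(2 * Z), drop = FALSE]
    sigma <- exp(0.5 * lv)
    z <- mu + sigma * eps_fix
    df <- latentmol:::decoder_fwd(z, idx, p$dec, cfg, V)
    sm <- latentmol:::softmax_xent_fwd(df$logits, idx)
    db <- latentmol:::decoder_bwd(latentmol:::softmax_xent_bwd(sm), df, p$dec, cfg)
    dz <- db$dz
    eb <- latentmol:::encoder_bwd(
      cbind(dz + kl_w * mu / B,
            dz * eps_fix * 0.5 * sigma + kl_w * 0.5 * (exp(lv) - 1) / B),
      ef, p$enc)
    list(enc = eb$grad, dec = db$grad)
  }

  g <- grad_fn(params)
  h <- 1e-5
  worst <- 0
  for (grp in c("enc", "dec")) {
    for (lay in names(params[[grp]])) {
      for (pn in names(params[[grp]][[lay]])) {
        W <- params[[grp]][[lay]][[pn]]
        gW <- g[[grp]][[lay]][[pn]]
        for (i in sample(length(W), min(4L, length(W)))) {
          pp <- params; pp[[grp]][[lay]][[pn]][i] <- W[i] + h
          pm <- params; pm[[grp]][[lay]][[pn]][i] <- W[i] - h
          num <- (loss_fn(pp) - loss_fn(pm)) / (2 * h)
          worst <- max(worst, abs(num - gW[i]) / max(1e-6, abs(num) + abs(gW[i])))
        }
      }
    }
  }
  expect_lt(worst, 1e-4)
})
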