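# Shared fixtures. Heavy objects (the fixture corpus and the four overfit
# models) are built once per test run and cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

fixture_corpus_50 <- function() {
  cached("corpus50", make_fixture_corpus(50, seed = 11, complexity = "full"))
}

fixture_corpus_500 <- function() {
  cached("corpus500", make_fixture_corpus(500, seed = 7, complexity = "full"))
}

# Desk-scale overfit configuration: short sequences (the fixture corpus has
# at most 27 tokens), narrow networks, minibatches of 25 and a raised
# learning rate. These are the shared study conditions for all overfit-based
# tests; the methods vignette documents the choices. Variational runs stop
# at 99.9% training-mode accuracy (the no-teacher-forcing variant needs a
# wider decoder, a longer low-KL horizon and a gentler, decaying learning
# rate since its decoder sees no token feedback); adversarial runs train a
# fixed 450 epochs under learning-rate decay so the encoder-prior game
# settles after reconstruction converges.
overfit_model_config <- function(variant) {
  switch(variant,
    vae_teacher = model_config(
      latent_dim = 16L, max_length = 29L,
      conv_channels = c(8L, 8L, 8L), conv_kernels = c(3L, 3L, 3L),
      fc_dim = 64L, gru_hidden = 64L,
      kl_max = 1, kl_anneal_epochs = 600L),
    vae_noteacher = model_config(
      latent_dim = 24L, max_length = 29L,
      conv_channels = c(8L, 8L, 8L), conv_kernels = c(3L, 3L, 3L),
      fc_dim = 64L, gru_hidden = 96L,
      kl_max = 1, kl_anneal_epochs = 2000L),
    model_config(  # adversarial variants
      latent_dim = 8L, max_length = 29L,
      conv_channels = c(8L, 8L, 8L), conv_kernels = c(3L, 3L, 3L),
      fc_dim = 64L, gru_hidden = 96L, disc_hidden = c(64L, 64L))
  )
}

overfit_training_config <- function(variant) {
  switch(variant,
    vae_teacher = training_config(
      batch_size = 25L, learning_rate = 5e-3, epochs = 700L,
      target_accuracy = 99.9, patience = 9000L, eval_every = 5L),
    vae_noteacher = training_config(
      batch_size = 25L, learning_rate = 4e-3, epochs = 900L,
      target_accuracy = 99.9, patience = 9000L, eval_every = 10L,
      lr_decay = 0.996),
    training_config(  # adversarial variants
      batch_size = 25L, learning_rate = 5e-3, epochs = 450L,
      patience = 9000L, eval_every = 10L, lr_decay = 0.997)
  )
}

# held-out molecules (never seen in training) for discriminator evaluation
heldout_corpus_200 <- function() {
  cached("heldout200", {
    h <- make_fixture_corpus(250, seed = 77, complexity = "full")
    h <- h[!(h$smiles %in% fixture_corpus_50()$smiles), , drop = FALSE]
    h[1:200, , drop = FALSE]
  })
}

overfit_model <- function(variant) {
  cached(paste0("model_", variant), {
    train_model(fixture_corpus_50(), variant,
                config = overfit_model_config(variant),
                train = overfit_training_config(variant),
                seed = 1L)
  })
}

with_seed_shuffle <- function(x, seed) {
  latentmol:::with_seed(seed, sample(x))
}

final_accuracy <- function(model) {
  acc <- model$log$accuracy
  utils::tail(acc[!is.na(acc)], 1)
}
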