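# Training driver shared by the four autoencoder variants:
#   vae_noteacher  variational encoder, decoder without teacher forcing
#   vae_teacher    variational encoder, teacher-forced decoder
#   aae_gauss      deterministic encoder matched to N(0, I) adversarially
#   aae_uniform    deterministic encoder matched to Uniform(-1, 1)
# Adversarial decoders always use teacher forcing.

#' The four autoencoder variant names
#'
#' `"vae_noteacher"`, `"vae_teacher"`, `"aae_gauss"`, `"aae_uniform"` — the
#' accepted values of `variant` in [train_model()].
#' @export
AE_VARIANTS <- c("vae_noteacher", "vae_teacher", "aae_gauss", "aae_uniform")

#' Optimization settings
#'
#' Defaults follow common practice for corpus-scale SMILES autoencoder
#' training: Adam, mini-batches of 500 and a learning rate of 3.1e-4.
#' Desk-scale overfitting runs typically raise the learning rate and use the
#' whole corpus as one batch.
#'
#' @param batch_size Mini-batch size (default 500).
#' @param learning_rate Adam learning rate (default 3.1e-4).
#' @param epochs Maximum training epochs.
#' @param target_accuracy Optional early-stop: halt once teacher-forced
#'   training-mode character accuracy (percent) reaches this value.
#' @param patience Epochs without training-loss improvement before stopping.
#' @param eval_every Evaluate accuracy every this many epochs.
#' @param lr_decay Per-epoch multiplicative learning-rate decay (1 = constant).
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 500L, learning_rate = 3.1e-4,
                            epochs = 200L, target_accuracy = NULL,
                            patience = 50L, eval_every = 5L, lr_decay = 1) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1,
            lr_decay > 0, lr_decay <= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 target_accuracy = target_accuracy,
                 patience = as.integer(patience),
                 eval_every = as.integer(eval_every),
                 lr_decay = lr_decay),
            class = "training_config")
}

# single VAE batch update; returns updated state and the losses
vae_training_step <- function(st, idx_batch, config, vocab_size, kl_weight, lr) {
  x <- onehot_tensor(idx_batch, vocab_size)
  B <- nrow(idx_batch)
  Z <- config$latent_dim

  ef <- encoder_fwd(x, st$params$enc, config)
  mu <- ef$out[, 1:Z, drop = FALSE]
  logvar <- ef$out[, (Z + 1):(2 * Z), drop = FALSE]
  sigma <- exp(0.5 * logvar)
  eps <- matrix(stats::rnorm(B * Z), B, Z)
  z <- mu + sigma * eps

  df <- decoder_fwd(z, idx_batch, st$params$dec, config, vocab_size)
  sm <- softmax_xent_fwd(df$logits, idx_batch)
  kl <- mean(kl_to_standard_normal(mu, logvar))
  loss <- sm$loss + kl_weight * kl
  if (!is.finite(loss)) stop("training loss is not finite; aborting")

  dlogits <- softmax_xent_bwd(sm)
  db <- decoder_bwd(dlogits, df, st$params$dec, config)
  dz <- db$dz
  dmu <- dz + kl_weight * mu / B
  dlogvar <- dz * eps * 0.5 * sigma + kl_weight * 0.5 * (exp(logvar) - 1) / B
  eb <- encoder_bwd(cbind(dmu, dlogvar), ef, st$params$enc)

  up <- adam_step(st$params, list(enc = eb$grad, dec = db$grad), st$opt, lr = lr)
  st$params <- up$params
  st$opt <- up$state
  st$losses <- c(loss = loss, reconstruction_loss = sm$loss, kl = kl)
  st
}

# teacher-forced training-mode character accuracy (percent over all padded
# positions), computed from argmax logits on the full index matrix
training_mode_accuracy <- function(params, idx, config, vocab_size) {
  x <- onehot_tensor(idx, vocab_size)
  ef <- encoder_fwd(x, params$enc, config)
  z <- if (config$variational) {
    ef$out[, 1:config$latent_dim, drop = FALSE]  # posterior mean
  } else ef$out
  df <- decoder_fwd(z, idx, params$dec, config, vocab_size)
  lg <- df$logits
  d <- dim(lg)
  dim(lg) <- c(d[1] * d[2], d[3])
  pred <- max.col(lg, ties.method = "first")
  100 * mean(pred == as.vector(idx))
}

#' Train a molecular autoencoder
#'
#' Trains one of the four variants on a prepared corpus. Training stops at
#' `epochs`, at `target_accuracy` (teacher-forced training-mode character
#' accuracy), or when the training loss has not improved for `patience`
#' epochs. For the variational variants the KL weight ramps linearly from 0
#' to `config$kl_max` over `config$kl_anneal_epochs` epochs; the adversarial
#' variants run the three-step loop every batch and always use teacher
#' forcing.
#'
#' @param corpus Character vector of canonical SMILES or data frame with a
#'   `smiles` column (see [prepare_corpus()]).
#' @param variant One of `"vae_noteacher"`, `"vae_teacher"`, `"aae_gauss"`,
#'   `"aae_uniform"`.
#' @param config A [model_config()]. `variational`/`teacher_forcing` are
#'   overridden to match the variant (adversarial decoders always teacher
#'   force).
#' @param train A [training_config()].
#' @param seed Integer seed controlling initialization, batch order and all
#'   sampling.
#' @param vocab Optional pre-built [build_vocabulary()] result; built from
#'   the corpus when omitted.
#' @return A `molecular_autoencoder` object with the trained parameters, the
#'   vocabulary, the per-epoch training log (`$log`, a tibble) and the prior
#'   specification for adversarial variants.
#' @export
train_model <- function(corpus, variant = AE_VARIANTS,
                        config = model_config(), train = training_config(),
                        seed = 1L, vocab = NULL) {
  variant <- match.arg(variant)
  smi <- as_smiles_vector(corpus)
  if (is.null(vocab)) vocab <- build_vocabulary(smi, max_length = config$max_length)
  config$max_length <- vocab$max_length
  V <- length(vocab$tokens)

  config$variational <- variant %in% c("vae_noteacher", "vae_teacher")
  if (variant %in% c("aae_gauss", "aae_uniform") && !config$teacher_forcing) {
    config$teacher_forcing <- TRUE  # always on for adversarial decoders
  }
  if (variant == "vae_noteacher") config$teacher_forcing <- FALSE
  if (variant == "vae_teacher") config$teacher_forcing <- TRUE

  prior <- switch(variant,
                  aae_gauss = prior_spec("standard_gaussian"),
                  aae_uniform = prior_spec("uniform", -1, 1),
                  NULL)

  idx <- encode_corpus(smi, vocab)
  n <- nrow(idx)

  with_seed(seed, {
    params <- init_autoencoder_params(config, V)
    st <- if (is.null(prior)) {
      list(params = params, opt = adam_init(params))
    } else {
      params$disc <- NULL
      disc <- init_discriminator_params(config$latent_dim,
                                        hidden = config$disc_hidden)
      list(params = c(params, list(disc = disc)),
           opt_ae = adam_init(list(enc = params$enc, dec = params$dec)),
           opt_disc = adam_init(disc),
           opt_gen = adam_init(params$enc))
    }

    log_rows <- list()
    best_loss <- Inf
    stall <- 0L
    for (epoch in seq_len(train$epochs)) {
      kl_weight <- if (config$kl_anneal_epochs > 0) {
        config$kl_max * min(1, epoch / config$kl_anneal_epochs)
      } else config$kl_max
      lr_epoch <- train$learning_rate * train$lr_decay^(epoch - 1)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / train$batch_size))
      ep_losses <- NULL
      for (b in batches) {
        st <- if (is.null(prior)) {
          vae_training_step(st, idx[b, , drop = FALSE], config, V,
                            kl_weight, lr_epoch)
        } else {
          aae_training_step(st, idx[b, , drop = FALSE], prior, config, V,
                            lr_epoch)
        }
        ep_losses <- rbind(ep_losses, st$losses)
      }
      ml <- colMeans(ep_losses)
      acc <- NA_real_
      if (epoch %% train$eval_every == 0 || epoch == train$epochs) {
        acc <- training_mode_accuracy(st$params, idx, config, V)
      }
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch,
        loss = unname(ml[1]),
        reconstruction_loss = unname(ml[["reconstruction_loss"]]),
        regularizer = unname(if (is.null(prior)) ml[["kl"]] else ml[["discriminator_loss"]]),
        generator_loss = unname(if (is.null(prior)) NA_real_ else ml[["generator_loss"]]),
        kl_weight = if (is.null(prior)) kl_weight else NA_real_,
        accuracy = acc
      )
      if (!is.na(acc) && !is.null(train$target_accuracy) &&
          acc >= train$target_accuracy) break
      track <- unname(ml[["reconstruction_loss"]])
      if (track < best_loss - 1e-6) { best_loss <- track; stall <- 0L }
      else { stall <- stall + 1L; if (stall >= train$patience) break }
    }

    structure(
      list(variant = variant, config = config, vocab = vocab,
           params = st$params, prior = prior,
           log = dplyr::bind_rows(log_rows), seed = seed),
      class = "molecular_autoencoder"
    )
  })
}

#' @export
print.molecular_autoencoder <- function(x, ...) {
  last <- utils::tail(x$log, 1)
  cat("<molecular_autoencoder>", x$variant, "\n")
  cat("  latent_dim:", x$config$latent_dim,
      " max_length:", x$config$max_length,
      " vocab:", length(x$vocab$tokens), "tokens\n")
  if (nrow(x$log) > 0) {
    cat(sprintf("  trained %d epochs; final loss %.4f; training-mode accuracy %.1f%%\n",
                nrow(x$log), last$loss,
                max(x$log$accuracy, na.rm = TRUE)))
  }
  invisible(x)
}

#' Tidy the training log of an autoencoder
#'
#' @param x A `molecular_autoencoder`.
#' @param ... Unused.
#' @return The per-epoch training log as a tibble.
#' @export
tidy.molecular_autoencoder <- function(x, ...) x$log

#' One-row model summary
#'
#' @param x A `molecular_autoencoder`.
#' @param ... Unused.
#' @return A one-row tibble: variant, latent dimension, epochs trained,
#'   final loss and best training-mode accuracy.
#' @export
glance.molecular_autoencoder <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    latent_dim = x$config$latent_dim,
    epochs = nrow(x$log),
    final_loss = utils::tail(x$log$loss, 1),
    training_accuracy = if (all(is.na(x$log$accuracy))) NA_real_
                        else max(x$log$accuracy, na.rm = TRUE)
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file with the configuration, vocabulary and
#' parameters embedded; reloading reproduces encoder outputs bitwise.
#'
#' @param model A `molecular_autoencoder`.
#' @param path File path.
#' @return `read_checkpoint` returns the restored model.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "molecular_autoencoder"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "molecular_autoencoder"))
  model
}
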