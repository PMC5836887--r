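# Generation-mode decoding. Each latent point is decoded by sampling the
# token distribution at every position (temperature 1); teacher-forcing
# architectures feed the sampled token back into the last GRU layer at the
# next step. Repeated sampling at one latent point yields a frequency table
# of strings; the most frequently sampled valid SMILES is the consensus
# output for that point.

# upper-triangular ones matrix turning row-softmax into row-cumsums via BLAS
cumsum_mat <- function(V) {
  m <- matrix(0, V, V)
  m[upper.tri(m, diag = TRUE)] <- 1
  m
}

# Sample one token sequence per row of zmat. Returns [nrow(zmat), L] index
# matrix. Uses the current RNG stream.
sample_sequences <- function(model, zmat) {
  config <- model$config
  p <- model$params$dec
  V <- length(model$vocab$tokens)
  B <- nrow(zmat)
  L <- config$max_length
  H <- config$gru_hidden

  fc <- linear_fwd(zmat, p$fc)
  h0 <- selu(fc$y)
  h1 <- h0[, 1:H, drop = FALSE]
  h2 <- h0[, (H + 1):(2 * H), drop = FALSE]
  h3 <- h0[, (2 * H + 1):(3 * H), drop = FALSE]
  yprev <- matrix(0, B, V)
  out_idx <- matrix(0L, B, L)

  for (t in seq_len(L)) {
    h1 <- gru_step(zmat, h1, p$gru1)
    h2 <- gru_step(h1, h2, p$gru2)
    x3 <- if (config$teacher_forcing) cbind(h2, yprev) else h2
    h3 <- gru_step(x3, h3, p$gru3)
    logits <- add_bias(h3 %*% p$out$W, p$out$b)
    pr <- exp(logits - row_max(logits))
    pr <- pr / rowSums(pr)
    cs <- pr %*% cumsum_mat(V)   # row-wise cumulative sums
    tok <- rowSums(cs < stats::runif(B)) + 1L
    tok[tok > V] <- V
    out_idx[, t] <- tok
    if (config$teacher_forcing) {
      yprev <- matrix(0, B, V)
      yprev[cbind(seq_len(B), tok)] <- 1
    }
  }
  out_idx
}

#' Generate molecules from a latent point
#'
#' Decodes `n_samples` token sequences from one latent point, checks each for
#' chemical validity, and selects the most frequently sampled valid SMILES as
#' the consensus output (ties broken lexicographically; `NA` when no sample
#' is valid).
#'
#' @param model A trained `molecular_autoencoder`.
#' @param z Numeric latent vector of length `latent_dim`.
#' @param n_samples Number of sequences to sample (default 500).
#' @param seed Optional integer seed for reproducible sampling.
#' @return A `generation_report`: list with `latent`, `samples` (decoded
#'   strings), `valid` (logical), `valid_fraction`, `frequency_table`
#'   (tibble: smiles, count, valid) and `consensus_smiles`.
#' @export
generate <- function(model, z, n_samples = 500L, seed = NULL) {
  stopifnot(length(z) == model$config$latent_dim, n_samples >= 1)
  zmat <- matrix(rep(as.numeric(z), each = n_samples), nrow = n_samples)
  idx <- if (is.null(seed)) sample_sequences(model, zmat)
         else with_seed(seed, sample_sequences(model, zmat))
  smiles <- apply(idx, 1, decode_indices, vocab = model$vocab)
  generation_report(z, smiles)
}

# Build the report from decoded strings (validity checked once per unique
# string).
generation_report <- function(z, smiles) {
  uniq <- unique(smiles)
  valid_uniq <- is_valid_smiles(uniq)
  valid <- valid_uniq[match(smiles, uniq)]
  counts <- table(smiles)
  freq <- tibble::tibble(
    smiles = names(counts),
    count = as.integer(counts),
    valid = valid_uniq[match(names(counts), uniq)]
  )
  freq <- freq[order(-freq$count, freq$smiles), ]
  consensus <- NA_character_
  vf <- freq[freq$valid & nzchar(freq$smiles), , drop = FALSE]
  if (nrow(vf) > 0) consensus <- vf$smiles[1]  # max count, lexicographic tie-break
  structure(
    list(latent = z, samples = smiles, valid = valid,
         valid_fraction = mean(valid),
         frequency_table = freq, consensus_smiles = consensus),
    class = "generation_report"
  )
}

#' @export
print.generation_report <- function(x, ...) {
  cat("<generation_report>", length(x$samples), "samples,",
      sprintf("%.1f%% valid;", 100 * x$valid_fraction),
      "consensus:", if (is.na(x$consensus_smiles)) "<none>" else x$consensus_smiles,
      "\n")
  invisible(x)
}

#' Position-to-position character reconstruction accuracy
#'
#' Both strings are padded with spaces (or truncated) to `max_length`
#' characters and compared position by position; the result is the
#' percentage of agreeing positions.
#'
#' @param predicted,target Single strings.
#' @param max_length Comparison length in characters (default 120).
#' @return Percentage in \[0, 100\].
#' @export
character_reconstruction_accuracy <- function(predicted, target, max_length = 120L) {
  pad <- function(s) {
    s <- substr(s, 1, max_length)
    paste0(s, strrep(" ", max_length - nchar(s)))
  }
  a <- strsplit(pad(predicted), "", fixed = TRUE)[[1]]
  b <- strsplit(pad(target), "", fixed = TRUE)[[1]]
  100 * mean(a == b)
}

#' Reconstruction and validity metrics over a corpus
#'
#' In training mode, scores teacher-forced argmax predictions against the
#' target sequences (token-position accuracy over the full padded length).
#' In generation mode, maps each molecule to its latent point (posterior mean
#' for variational models), samples `n_samples` sequences per molecule, and
#' reports the mean character accuracy of all samples against their targets,
#' the percentage of valid SMILES among all reconstruction attempts, and the
#' percentage of molecules whose consensus SMILES equals the target.
#'
#' @param model A trained `molecular_autoencoder`.
#' @param corpus Character vector of canonical SMILES or data frame with a
#'   `smiles` column.
#' @param mode `"training"` or `"generation"`.
#' @param n_samples Samples per molecule in generation mode (default 500).
#' @param seed Optional seed for generation-mode sampling.
#' @return One-row tibble: `mode`, `mean_character_accuracy`,
#'   `valid_smiles_pct` (`NA` in training mode), `consensus_accuracy_pct`
#'   (`NA` in training mode), `n_molecules`, `n_samples`.
#' @export
corpus_metrics <- function(model, corpus, mode = c("training", "generation"),
                           n_samples = 500L, seed = NULL) {
  mode <- match.arg(mode)
  smi <- as_smiles_vector(corpus)
  vocab <- model$vocab
  idx <- encode_corpus(smi, vocab)
  V <- length(vocab$tokens)

  if (mode == "training") {
    acc <- training_mode_accuracy(model$params, idx, model$config, V)
    return(tibble::tibble(mode = mode, mean_character_accuracy = acc,
                          valid_smiles_pct = NA_real_,
                          consensus_accuracy_pct = NA_real_,
                          n_molecules = length(smi),
                          n_samples = NA_integer_))
  }

  post <- encode_posterior(model, idx)
  z <- post$mean
  n <- length(smi)
  zbig <- z[rep(seq_len(n), each = n_samples), , drop = FALSE]
  sample_idx <- if (is.null(seed)) sample_sequences(model, zbig)
                else with_seed(seed, sample_sequences(model, zbig))
  strings <- apply(sample_idx, 1, decode_indices, vocab = vocab)
  mol_of <- rep(seq_len(n), each = n_samples)

  uniq <- unique(strings)
  valid_uniq <- is_valid_smiles(uniq)
  valid <- valid_uniq[match(strings, uniq)]

  acc <- vapply(seq_along(strings), function(i) {
    character_reconstruction_accuracy(strings[i], smi[mol_of[i]],
                                      max_length = vocab$max_length)
  }, numeric(1))

  consensus_ok <- vapply(seq_len(n), function(m) {
    rep_m <- generation_report(z[m, ], strings[mol_of == m])
    identical(rep_m$consensus_smiles, smi[m])
  }, logical(1))

  tibble::tibble(mode = mode,
                 mean_character_accuracy = mean(acc),
                 valid_smiles_pct = 100 * mean(valid),
                 consensus_accuracy_pct = 100 * mean(consensus_ok),
                 n_molecules = n, n_samples = as.integer(n_samples))
}
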