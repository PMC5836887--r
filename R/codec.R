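# SMILES <-> fixed-length token-index sequences. The sequence alphabet is
# corpus-derived; two-character halogen atoms ("Cl", "Br") are single tokens,
# everything else is one character. Sequences are padded with spaces to a
# fixed maximum length and the pad token doubles as the terminator.

PAD_TOKEN <- " "

#' Build a token vocabulary from a SMILES corpus
#'
#' The vocabulary is the union of tokens observed in the corpus plus the pad
#' token (a space). Ordering is deterministic: pad first, then the remaining
#' tokens in C-locale lexicographic order, so vocabularies built from shuffled
#' corpora are identical.
#'
#' @param corpus Character vector of SMILES strings (or a data frame with a
#'   `smiles` column).
#' @param max_length Tokens per encoded sequence; shorter SMILES are padded
#'   with spaces at the end (default 120).
#' @return A `token_vocabulary` object.
#' @export
build_vocabulary <- function(corpus, max_length = 120L) {
  corpus <- as_smiles_vector(corpus)
  if (length(corpus) == 0L) stop("cannot build a vocabulary from an empty corpus")
  toks <- unique(unlist(lapply(corpus, tokenize_smiles)))
  toks <- sort(setdiff(toks, PAD_TOKEN), method = "radix")
  new_vocabulary(c(PAD_TOKEN, toks), max_length)
}

new_vocabulary <- function(tokens, max_length) {
  stopifnot(!anyDuplicated(tokens), PAD_TOKEN %in% tokens, max_length >= 1)
  structure(
    list(
      tokens = tokens,
      index = stats::setNames(seq_along(tokens), tokens), # 1-based
      pad_token = PAD_TOKEN,
      max_length = as.integer(max_length)
    ),
    class = "token_vocabulary"
  )
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat("<token_vocabulary>", length(x$tokens), "tokens, max_length",
      x$max_length, "\n")
  cat("  tokens:", paste(sub("^ $", "<pad>", x$tokens), collapse = " "), "\n")
  invisible(x)
}

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into single-character tokens, except the
#' two-character atoms `"Cl"` and `"Br"` which are kept whole. Concatenating
#' the returned tokens reproduces the input exactly.
#'
#' @param smiles A single SMILES string.
#' @param vocab Optional `token_vocabulary`; when given, any token absent from
#'   it raises an error naming the position and fragment.
#' @return Character vector of tokens (zero-length for the empty string).
#' @examples
#' tokenize_smiles("Clc1ccccc1")
#' @export
tokenize_smiles <- function(smiles, vocab = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) return(character(0))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  two_char <- (chars == "C" & c(chars[-1], "") == "l") |
              (chars == "B" & c(chars[-1], "") == "r")
  keep <- rep(TRUE, n)
  toks <- chars
  for (i in which(two_char)) {
    toks[i] <- paste0(chars[i], chars[i + 1])
    keep[i + 1] <- FALSE
  }
  toks <- toks[keep]
  if (!is.null(vocab)) {
    unknown <- which(!(toks %in% vocab$tokens))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown token '%s' at token position %d of '%s'",
                   toks[unknown[1]], unknown[1], smiles))
    }
  }
  toks
}

#' One-hot encode a SMILES string
#'
#' Tokenizes, pads with spaces to `vocab$max_length`, and returns both the
#' integer index sequence and the one-hot matrix. Each one-hot row contains
#' exactly one 1.
#'
#' @param smiles A single SMILES string.
#' @param vocab A `token_vocabulary`.
#' @return A `one_hot_sequence`: list with `indices` (length `max_length`,
#'   1-based), `onehot` (`max_length` x `|tokens|` binary matrix) and
#'   `source_smiles`.
#' @export
encode_smiles <- function(smiles, vocab) {
  toks <- tokenize_smiles(smiles, vocab)
  L <- vocab$max_length
  if (length(toks) > L) {
    stop(sprintf("SMILES has %d tokens, exceeding max_length %d",
                 length(toks), L))
  }
  idx <- c(vocab$index[toks], rep(vocab$index[[vocab$pad_token]], L - length(toks)))
  names(idx) <- NULL
  onehot <- matrix(0L, nrow = L, ncol = length(vocab$tokens))
  onehot[cbind(seq_len(L), idx)] <- 1L
  structure(
    list(indices = as.integer(idx), onehot = onehot, source_smiles = smiles),
    class = "one_hot_sequence"
  )
}

#' Decode a token-index sequence to a SMILES string
#'
#' Concatenates the tokens for `indices`, cutting the sequence at the first
#' pad token (the pad doubles as terminator). No validity check is applied:
#' malformed strings are returned verbatim so that validity can be assessed
#' separately.
#'
#' @param indices Integer vector of 1-based token indices.
#' @param vocab A `token_vocabulary`.
#' @return A single string (empty for an all-pad sequence).
#' @export
decode_indices <- function(indices, vocab) {
  if (any(indices < 1L | indices > length(vocab$tokens))) {
    stop("token index out of range for vocabulary")
  }
  pad <- vocab$index[[vocab$pad_token]]
  stop_at <- match(pad, indices)
  if (!is.na(stop_at)) indices <- indices[seq_len(stop_at - 1L)]
  paste(vocab$tokens[indices], collapse = "")
}

# Encode a whole corpus as an index matrix (n x max_length). One-hot tensors
# are materialized lazily where the networks need them.
encode_corpus <- function(corpus, vocab) {
  corpus <- as_smiles_vector(corpus)
  t(vapply(corpus, function(s) encode_smiles(s, vocab)$indices,
           integer(vocab$max_length), USE.NAMES = FALSE))
}

#' Persist a vocabulary as JSON
#'
#' @param vocab A `token_vocabulary`.
#' @param path File path to write.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(
    list(tokens = vocab$tokens, max_length = vocab$max_length),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#'
#' @param path File path to read.
#' @return A `token_vocabulary` with the persisted token order.
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_vocabulary(x$tokens, x$max_length)
}

# Accept either a character vector or a data frame with a `smiles` column.
as_smiles_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!"smiles" %in% names(x)) stop("data frame input must have a 'smiles' column")
    x <- x$smiles
  }
  stopifnot(is.character(x))
  x
}
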