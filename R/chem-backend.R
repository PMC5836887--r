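# Thin bridge to OpenBabel through ChemmineOB. All chemistry (parsing,
# canonical SMILES, validity, fingerprints, ring perception) funnels through
# here so the rest of the package never touches the toolkit directly.

# A few SWIG bindings used below (istreamFromString, OBConversion_AddOption)
# are not exported by ChemmineOB; they are stable parts of its OpenBabel
# wrapper and accessed via `:::`.
ob_convert <- function(text, from = "SMI", to = "CAN", out_options = character()) {
  in_str <- ChemmineOB:::istreamFromString(text)
  out_str <- ChemmineOB:::ostreamToString()
  conv <- ChemmineOB:::OBConversion(in_str, out_str)
  if (!ChemmineOB:::OBConversion_SetInAndOutFormats(conv, from, to)) {
    stop("OpenBabel cannot convert from ", from, " to ", to)
  }
  # continue with the next record after a parse error: a batch may mix valid
  # and invalid strings (generation-mode output routinely does)
  ChemmineOB:::OBConversion_AddOption(conv, "e", "GENOPTIONS", "")
  for (opt in out_options) {
    ChemmineOB:::OBConversion_AddOption(conv, opt, "OUTOPTIONS", "")
  }
  ChemmineOB:::OBConversion_Convert(conv)
  ChemmineOB:::stringFromOstream(out_str)
}

# Convert a character vector of SMILES in one OpenBabel pass, using the SMILES
# title field to keep the input/output correspondence when some entries fail
# to parse. Returns a character vector aligned with `smiles`; NA where the
# toolkit rejected the input.
ob_smiles_batch <- function(smiles, out_options = character()) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  # whitespace would be read as a title separator; such strings are invalid
  clean <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  if (any(clean)) {
    idx <- which(clean)
    src <- paste0(smiles[idx], " id", seq_along(idx), collapse = "\n")
    res <- ob_convert(paste0(src, "\n"), "SMI", "CAN", out_options)
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    for (line in lines) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2 && grepl("^id[0-9]+$", parts[2])) {
        k <- as.integer(sub("^id", "", parts[2]))
        out[idx[k]] <- parts[1]
      }
    }
  }
  out
}

#' Check SMILES validity
#'
#' A string is valid when the chemistry toolkit (OpenBabel) parses it as a
#' molecule. Malformed ring closures, unbalanced branches and empty strings
#' all return `FALSE`; no error is ever thrown.
#'
#' @param smiles Character vector of candidate SMILES strings.
#' @return Logical vector, one entry per input.
#' @examples
#' is_valid_smiles(c("c1ccccc1", "c33c12", ""))
#' @export
is_valid_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(logical(0))
  out <- ob_smiles_batch(smiles)
  !is.na(out) & nzchar(out)
}

#' Canonicalize SMILES strings
#'
#' Rewrites each SMILES in the toolkit's canonical form, optionally removing
#' stereochemistry (cis/trans bond and chirality markers). Canonicalization is
#' idempotent: applying it to its own output is a fixed point.
#'
#' @param smiles Character vector of SMILES strings; every entry must parse.
#' @param strip_stereo Drop stereochemistry markers (default `TRUE`).
#' @return Character vector of canonical SMILES.
#' @examples
#' canonicalize_smiles(c("C(C)C", "CCC"))          # same canonical form
#' canonicalize_smiles("F/C=C/F")                   # stereo removed
#' @export
canonicalize_smiles <- function(smiles, strip_stereo = TRUE) {
  opts <- if (strip_stereo) "i" else character()
  out <- ob_smiles_batch(smiles, out_options = opts)
  bad <- is.na(out) | !nzchar(out)
  if (any(bad)) {
    stop("cannot parse SMILES: ", paste(utils::head(smiles[bad], 5), collapse = ", "))
  }
  out
}

# SDF container for downstream ChemmineR operations (rings). One molecule per
# input SMILES; errors if any input is invalid.
smiles_to_sdf <- function(smiles) {
  if (any(!is_valid_smiles(smiles))) stop("invalid SMILES passed to smiles_to_sdf")
  nm <- paste0("m", seq_along(smiles))
  ChemmineR::smiles2sdf(stats::setNames(smiles, nm))
}

#' Largest ring size of a molecule
#'
#' Ring sizes are taken from the smallest set of smallest rings, so fused
#' aromatic systems report their individual ring sizes rather than the outer
#' envelope. Acyclic molecules return 0.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Integer vector of largest SSSR ring size per molecule.
#' @export
largest_ring_size <- function(smiles) {
  sdf <- smiles_to_sdf(smiles)
  vapply(seq_along(smiles), function(i) {
    r <- ChemmineR::rings(sdf[i], upper = Inf, type = "all", inner = TRUE)
    if (length(r) == 0L) 0L else max(vapply(r, length, integer(1)))
  }, integer(1))
}
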