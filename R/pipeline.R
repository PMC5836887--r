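# Corpus preparation and the synthetic fixture-corpus generator. The
# preparation filters mirror a typical training-corpus recipe for SMILES
# autoencoders: canonicalize, strip stereochemistry, drop small fragments
# (< 10 heavy atoms), drop over-long token sequences (> 120 tokens by
# default), drop an explicit exclusion list (e.g. known actives held out for
# later searching), and deduplicate on canonical form.

#' Corpus preparation settings
#'
#' @param min_heavy_atoms Minimum heavy-atom count to keep a molecule
#'   (default 10).
#' @param max_tokens Maximum token-sequence length to keep (default 120).
#' @param exclusion_list Character vector of SMILES to remove; matched by
#'   canonical-SMILES equality.
#' @param strip_stereo Remove stereochemistry during canonicalization
#'   (default `TRUE`).
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(min_heavy_atoms = 10L, max_tokens = 120L,
                        exclusion_list = character(), strip_stereo = TRUE) {
  stopifnot(min_heavy_atoms >= 1L, max_tokens >= 1L)
  structure(
    list(min_heavy_atoms = as.integer(min_heavy_atoms),
         max_tokens = as.integer(max_tokens),
         exclusion_list = exclusion_list,
         strip_stereo = strip_stereo),
    class = "corpus_spec"
  )
}

#' Prepare a SMILES corpus for training
#'
#' Canonicalizes (optionally stripping stereochemistry), deduplicates, and
#' applies the corpus filters in [corpus_spec()]. The per-rule removal counts
#' are attached as the `"filter_report"` attribute (see [filter_report()]);
#' their total always equals `length(input) - nrow(output)`.
#'
#' @param raw Character vector of SMILES, or a data frame with a `smiles`
#'   column.
#' @param spec A [corpus_spec()].
#' @return A tibble with a `smiles` column of unique canonical SMILES.
#' @export
prepare_corpus <- function(raw, spec = corpus_spec()) {
  raw <- as_smiles_vector(raw)
  if (length(raw) == 0L) stop("empty input corpus")
  n_in <- length(raw)

  valid <- is_valid_smiles(raw)
  smi <- canonicalize_smiles(raw[valid], strip_stereo = spec$strip_stereo)
  n_invalid <- n_in - length(smi)

  dup <- duplicated(smi)
  smi <- smi[!dup]
  n_dup <- sum(dup)

  n_small <- 0L
  if (length(smi) > 0L) {
    heavy <- count_heavy_atoms(smi)
    small <- heavy < spec$min_heavy_atoms
    n_small <- sum(small)
    smi <- smi[!small]
  }

  n_long <- 0L
  if (length(smi) > 0L) {
    toolong <- vapply(smi, function(s) length(tokenize_smiles(s)), integer(1)) >
      spec$max_tokens
    n_long <- sum(toolong)
    smi <- smi[!toolong]
  }

  n_excl <- 0L
  if (length(spec$exclusion_list) > 0L && length(smi) > 0L) {
    excl <- canonicalize_smiles(spec$exclusion_list,
                                strip_stereo = spec$strip_stereo)
    drop <- smi %in% excl
    n_excl <- sum(drop)
    smi <- smi[!drop]
  }

  if (length(smi) == 0L) stop("no molecules survive the corpus filters")

  report <- tibble::tibble(
    rule = c("unparseable", "duplicate", "min_heavy_atoms", "max_tokens",
             "exclusion_list"),
    removed = c(n_invalid, n_dup, n_small, n_long, n_excl)
  )
  out <- tibble::tibble(smiles = smi)
  attr(out, "filter_report") <- report
  out
}

#' Per-rule removal counts from [prepare_corpus()]
#'
#' @param corpus A tibble returned by [prepare_corpus()].
#' @return A tibble with columns `rule` and `removed`.
#' @export
filter_report <- function(corpus) {
  rep <- attr(corpus, "filter_report")
  if (is.null(rep)) stop("no filter report attached; was this corpus prepared by prepare_corpus()?")
  rep
}

# Heavy atom count per molecule from the toolkit's atom table (hydrogens
# excluded).
count_heavy_atoms <- function(smiles) {
  sdf <- smiles_to_sdf(smiles)
  counts <- ChemmineR::atomcount(sdf)
  vapply(counts, function(x) sum(x[names(x) != "H"]), numeric(1))
}

#' Split a corpus into training and validation sets
#'
#' @param corpus Character vector or data frame with a `smiles` column.
#' @param validation_fraction Fraction held out for validation (0 < f < 1).
#' @param seed Integer seed; the same seed always reproduces the same split.
#' @return A list with tibbles `train` and `validation`; disjoint and jointly
#'   exhaustive.
#' @export
split_corpus <- function(corpus, validation_fraction = 0.125, seed = 1L) {
  smi <- as_smiles_vector(corpus)
  stopifnot(validation_fraction > 0, validation_fraction < 1)
  n <- length(smi)
  n_val <- round(validation_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_val))
  list(train = tibble::tibble(smiles = smi[setdiff(seq_len(n), idx)]),
       validation = tibble::tibble(smiles = smi[sort(idx)]))
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- synthetic fixture corpus ----------------------------------------------

# Substituent pools. Suffix substituents are written to be valid when
# attached after a ring atom or inside a branch, e.g. "c1ccc(X)cc1" or
# "CC(X)C"; prefix substituents are valid when the scaffold continues after
# them at the start of the string, e.g. "XCCC". The distinction matters:
# "C(F)(F)F" is fine as a branch but hypervalent as a prefix. Sizes (heavy
# atoms) are chosen so scaffold + substituents lands at 10+ heavy atoms.
fixture_substituents <- function(complexity, position = c("suffix", "prefix")) {
  position <- match.arg(position)
  if (position == "suffix") {
    base <- c("C", "CC", "CCC", "C(C)C", "CO", "CCO", "OC", "OCC", "N", "NC",
              "CN(C)C", "CCN", "C(=O)OC", "C(=O)NC", "OC(=O)C", "CC(C)O")
    halo <- c("Cl", "Br", "F", "C(F)(F)F", "CCl", "CBr")
  } else {
    base <- c("C", "CC", "CCC", "CC(C)", "CO", "OC", "CN(C)", "COC(=O)",
              "CC(=O)N", "OCC")
    halo <- c("Cl", "Br", "F", "FC(F)(F)", "ClC", "BrC")
  }
  if (complexity == "full") c(base, halo) else base
}

# Scaffold templates: "{1}"/"{2}" are suffix slots, "{P}" is a prefix slot.
fixture_scaffolds <- function(complexity) {
  simple <- c("CC({1})CC{2}", "{P}CCC(C){2}", "CC(=O)NC({1}){2}",
              "CCOC(=O)C({1}){2}", "{P}CC(O)C{2}", "CC(C)C({1})C{2}")
  ringed <- c("c1ccc({1})cc1{2}", "C1CCC({1})CC1{2}", "O=C1CCC({1})CC1",
              "c1cc({1})ccc1{2}", "C1CCCCC1C({1}){2}")
  full <- c("c1ccc2cc({1})ccc2c1", "c1cc({1})ncc1{2}", "c1cc({1})sc1{2}",
            "O=C(NCc1cc[nH]n1){1}", "O=C(c1ccc({1})cc1){2}", "c1oc({1})cc1{2}")
  switch(complexity,
         simple = simple,
         ringed = c(simple, ringed),
         full = c(simple, ringed, full))
}

#' Generate a synthetic SMILES fixture corpus
#'
#' Builds molecules by seeded assembly from a curated scaffold and substituent
#' set, guaranteeing chemical validity by construction. The `"ringed"` tier
#' adds carbo- and heteroaromatic ring systems (ring-closure digits, branch
#' parentheses, aromatic atoms); the `"full"` tier additionally guarantees
#' two-character halogen tokens (`Cl`, `Br`) and bracket atoms (`[nH]`), so
#' every codec path is exercised. The corpus emulates the shape of a small
#' drug-like training set (10-25 heavy atoms, short token sequences); it does
#' not emulate the structural diversity of a real screening corpus.
#'
#' @param n Number of unique molecules to generate.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param complexity One of `"simple"`, `"ringed"`, `"full"`.
#' @return A tibble with a `smiles` column of `n` unique canonical SMILES,
#'   all valid.
#' @export
make_fixture_corpus <- function(n, seed = 1L, complexity = c("full", "ringed", "simple")) {
  complexity <- match.arg(complexity)
  stopifnot(n >= 1L)
  scaffolds <- fixture_scaffolds(complexity)
  suff <- fixture_substituents(complexity, "suffix")
  pref <- fixture_substituents(complexity, "prefix")

  candidates <- with_seed(seed, {
    # guaranteed token coverage up front for the "full" tier
    guaranteed <- if (complexity == "full") {
      c("Clc1ccc(CC(C)C)cc1", "Brc1ccc(OCC)cc1CC", "O=C(NCc1cc[nH]n1)CCC")
    } else character()
    m <- 0L
    out <- character(0)
    while (length(out) < 4L * n && m < 200L) {
      sc <- sample(scaffolds, 4L * n, replace = TRUE)
      fill <- function(x, slot, pool) {
        mapply(function(a, b) sub(slot, b, a, fixed = TRUE),
               x, sample(pool, length(x), replace = TRUE), USE.NAMES = FALSE)
      }
      built <- fill(fill(fill(sc, "{P}", pref), "{1}", suff), "{2}", suff)
      out <- unique(c(out, built))
      m <- m + 1L
    }
    c(guaranteed, out)
  })

  canon <- unique(canonicalize_smiles(candidates, strip_stereo = TRUE))
  # keep the fixture desk-scale: short sequences, 10+ heavy atoms
  ntok <- vapply(canon, function(s) length(tokenize_smiles(s)), integer(1))
  canon <- canon[ntok <= 60L]
  heavy <- count_heavy_atoms(canon)
  canon <- canon[heavy >= 10]
  if (length(canon) < n) {
    stop("fixture generator produced only ", length(canon),
         " unique molecules; requested ", n)
  }
  tibble::tibble(smiles = canon[seq_len(n)])
}
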