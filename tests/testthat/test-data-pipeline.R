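# Corpus preparation, splitting and the synthetic fixture generator.

test_that("corpus preparation applies every filter and accounts for removals", {
  fix <- fixture_corpus_50()
  raw <- c("c1ccccc1",            # benzene: 6 heavy atoms, dropped
           fix$smiles[1:20],
           fix$smiles[1],         # duplicate
           "F/C=C/F",             # stereo + small
           "not_a_smiles")
  prep <- prepare_corpus(raw, corpus_spec())
  rep <- filter_report(prep)
  expect_identical(sum(rep$removed), length(raw) - nrow(prep))
  expect_identical(rep$removed[rep$rule == "unparseable"], 1L)
  expect_identical(rep$removed[rep$rule == "duplicate"], 1L)
  expect_false("c1ccccc1" %in% prep$smiles)
  expect_false(any(grepl("[/\\\\]", prep$smiles)))
  # idempotent on its own output
  prep2 <- prepare_corpus(prep, corpus_spec())
  expect_identical(prep2$smiles, prep$smiles)
  expect_identical(sum(filter_report(prep2)$removed), 0L)
})

test_that("exclusion list removes by canonical equality", {
  fix <- fixture_corpus_50()
  spec <- corpus_spec(exclusion_list = fix$smiles[3])
  prep <- prepare_corpus(fix$smiles[1:10], spec)
  expect_false(fix$smiles[3] %in% prep$smiles)
  expect_identical(filter_report(prep)$removed[5], 1L)
})

test_that("over-long sequences are filtered by token count", {
  long <- paste0("CCCCCCCCCC", strrep("C", 30))  # 40 tokens
  prep <- prepare_corpus(c(long, fixture_corpus_50()$smiles[1:5]),
                         corpus_spec(max_tokens = 30L))
  expect_identical(filter_report(prep)$removed[4], 1L)
  expect_false(long %in% prep$smiles)
})

test_that("splits are disjoint, exhaustive and seed-reproducible", {
  smi <- fixture_corpus_500()$smiles
  sp <- split_corpus(smi, validation_fraction = 0.125, seed = 4)
  expect_identical(nrow(sp$train), 438L)   # round(0.125 * 500) held out
  expect_identical(nrow(sp$validation), 62L)
  expect_length(intersect(sp$train$smiles, sp$validation$smiles), 0)
  expect_setequal(c(sp$train$smiles, sp$validation$smiles), smi)
  sp2 <- split_corpus(smi, validation_fraction = 0.125, seed = 4)
  expect_identical(sp, sp2)
  smi1000 <- make_fixture_corpus(1000, seed = 3, complexity = "ringed")$smiles
  sp3 <- split_corpus(smi1000, 0.125, seed = 1)
  expect_identical(nrow(sp3$train), 875L)
  expect_identical(nrow(sp3$validation), 125L)
})

test_that("the fixture generator is deterministic, valid and filter-proof", {
  a <- make_fixture_corpus(50, seed = 11, complexity = "full")
  b <- make_fixture_corpus(50, seed = 11, complexity = "full")
  expect_identical(a, b)
  expect_identical(nrow(a), 50L)
  expect_identical(anyDuplicated(a$smiles), 0L)
  expect_true(all(is_valid_smiles(a$smiles)))
  # canonical fixed point
  expect_identical(canonicalize_smiles(a$smiles), a$smiles)
  # full tier guarantees the two-character and ring/branch token paths
  expect_true(any(grepl("Cl", a$smiles)) || any(grepl("Br", a$smiles)))
  expect_true(any(grepl("[0-9]", a$smiles)))
  expect_true(any(grepl("\\(", a$smiles)))
  # survives corpus preparation unchanged in count
  prep <- prepare_corpus(a, corpus_spec())
  expect_identical(nrow(prep), 50L)
})

test_that("fixture tiers grade in structural complexity", {
  simple <- make_fixture_corpus(30, seed = 2, complexity = "simple")
  expect_false(any(grepl("[0-9]", simple$smiles)))  # acyclic tier
  ringed <- make_fixture_corpus(30, seed = 2, complexity = "ringed")
  expect_true(any(grepl("1", ringed$smiles)))
})

test_that("checkpoints round-trip to identical encoder outputs", {
  m <- overfit_model("vae_teacher")
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  corpus <- fixture_corpus_50()[1:5, ]
  expect_identical(encode_posterior(m, corpus), encode_posterior(m2, corpus))
})
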