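# Fingerprints, the SVM activity model, the two-branch score and the
# macrocycle filter.

test_that("fingerprints are canonical-invariant and Tanimoto matches set arithmetic", {
  f <- fingerprint_ecfp6(c("C(C)C", "CCC", "c1ccccc1CC", "c1ccccc1CCO"))
  expect_identical(f[1, ], f[2, ])          # same molecule, different notation
  expect_equal(tanimoto(f[3, ], f[3, ]), 1)
  a <- which(f[3, ] == 1); b <- which(f[4, ] == 1)
  expect_equal(tanimoto(f[3, ], f[4, ]),
               length(intersect(a, b)) / length(union(a, b)))
  expect_error(fingerprint_ecfp6("xx(("), "invalid SMILES")
})

test_that("fingerprint folding preserves bit count bounds", {
  f4096 <- fingerprint_ecfp6("c1ccccc1CCO", nbits = 4096)
  f1024 <- fingerprint_ecfp6("c1ccccc1CCO", nbits = 1024)
  expect_identical(ncol(f4096), 4096L)
  expect_identical(ncol(f1024), 1024L)
  expect_lte(sum(f1024), sum(f4096))
  expect_gt(sum(f1024), 0)
})

test_that("two-branch score matches a brute-force oracle on random multisets", {
  expect_equal(activity_score_values(c(0.6, 0.8, 0.2))$score, 0.7)
  expect_equal(activity_score_values(c(0.1, 0.3))$score, 0.2)
  expect_equal(activity_score_values(numeric(0))$score, 0)
  oracle <- function(p) {
    if (length(p) == 0) return(0)
    if (any(p > 0.5)) mean(p[p > 0.5]) else mean(p)
  }
  set.seed(80)
  for (i in 1:1000) {
    p <- runif(sample(0:8, 1))
    r <- activity_score_values(p)
    expect_identical(r$score, oracle(p))
    expect_lte(r$n_active, r$n_valid)
    expect_true(r$score >= 0 && r$score <= 1)
  }
})

test_that("macrocycle filter allows 8-rings, removes 9-rings, keeps acyclics", {
  expect_true(macrocycle_filter("C1CCCCCCC1"))    # cyclooctane
  expect_false(macrocycle_filter("C1CCCCCCCC1"))  # cyclononane
  expect_true(macrocycle_filter("CCCC"))
  # fused bicyclic: individual small rings, not the envelope, are counted
  expect_true(macrocycle_filter("c1ccc2ccccc2c1"))
  # a molecule with a small ring and a macrocycle is removed
  expect_false(macrocycle_filter("C1CCCCCCCCC1c1ccccc1"))
})

test_that("SVM separates separable fingerprint classes and not shuffled labels", {
  fix <- make_fixture_corpus(120, seed = 5, complexity = "full")
  # aromatic vs aliphatic molecules occupy disjoint ECFP bit blocks
  d <- data.frame(smiles = fix$smiles, label = as.integer(grepl("c", fix$smiles)))
  expect_gt(min(table(d$label)), 20)
  am <- train_activity_model(d, cost = 10, gamma = 1e-3, folds = 3, seed = 1)
  expect_gt(am$cv_auroc, 0.95)
  # training actives are memorized in the overfit limit
  p_act <- predict(am, d$smiles[d$label == 1][1:10])
  expect_true(all(p_act > 0.5))

  d_shuf <- d
  d_shuf$label <- with_seed_shuffle(d$label, 2)
  am_shuf <- train_activity_model(d_shuf, cost = 10, gamma = 1e-3, folds = 3,
                                  seed = 1)
  expect_lt(abs(am_shuf$cv_auroc - 0.5), 0.15)
  expect_error(train_activity_model(data.frame(smiles = "CCO", label = 1)),
               "both an active and an inactive class")
})

test_that("scoring a generation report applies validity and ring filters", {
  rep <- latentmol:::generation_report(
    rep(0, 3),
    c("CCCCCCCCCC", "CCCCCCCCCC", "C1CCCCCCCC1", "((bad", "c1ccccc1CCCC"))
  fix <- make_fixture_corpus(60, seed = 6, complexity = "full")
  d <- data.frame(smiles = fix$smiles, label = as.integer(grepl("c", fix$smiles)))
  am <- train_activity_model(d, cost = 10, gamma = 1e-3, folds = 3, seed = 1)
  sc <- activity_score(rep, am)
  # cyclononane and the invalid string are excluded: 2 unique survivors
  expect_identical(nrow(sc$per_smiles), 2L)
  expect_false("C1CCCCCCCC1" %in% sc$per_smiles$smiles)
  expect_true(sc$score >= 0 && sc$score <= 1)
})
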