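test_that("validity separates parseable structures from syntax/valence junk", {
  expect_equal(compute_validity(c("C", "CO"))$validity, 1)
  v <- compute_validity(c("C", "C(", "O"))
  expect_equal(v$n_valid, 2)
  expect_equal(v$validity, 2 / 3)
  expect_error(compute_validity(character(0)), "empty")

  # unterminated strings count as sampled and invalid
  v2 <- compute_validity(c("C", "CC"), terminated = c(TRUE, FALSE))
  expect_equal(v2$n_valid, 1)

  corpus <- toy_smiles_corpus(50, seed = 6)
  expect_equal(compute_validity(corpus)$validity, 1)
})

test_that("uniqueness deduplicates by canonical structure (or raw string on request)", {
  u <- compute_uniqueness(c("CCO", "OCC"))
  expect_equal(u$n_unique, 1)
  expect_equal(u$uniqueness, 0.5)
  expect_equal(compute_uniqueness(c("C", "N"))$uniqueness, 1)
  expect_equal(compute_uniqueness(c("CCO", "OCC"), dedup = "string")$uniqueness, 1)
})

test_that("novelty applies the strict MACCS/Tanimoto threshold rule", {
  ref <- c("c1ccccc1", "CCO")
  # literal training-set member: similarity 1, never novel
  nv <- compute_novelty(c("c1ccccc1", "C"), ref)
  expect_false(nv$novel[1])
  expect_equal(nv$max_similarity[1], 1)
  # methane vs benzene/ethanol: far below 0.85
  expect_true(nv$novel[2])
  expect_lt(nv$max_similarity[2], 0.85)
  expect_equal(nv$novelty, 0.5)

  # threshold 1 with strict '<': only exact fingerprint matches non-novel
  nv1 <- compute_novelty(c("c1ccccc1", "CCN"), ref, threshold = 1)
  expect_equal(nv1$novel, c(FALSE, TRUE))

  expect_warning(nv0 <- compute_novelty("CCO", character(0)), "empty reference")
  expect_equal(nv0$novelty, 1)
})

test_that("novelty equals a brute-force double-loop Tanimoto oracle", {
  gen <- unique(canonical_smiles(toy_smiles_corpus(40, seed = 51)))
  ref <- toy_smiles_corpus(40, seed = 52)
  nv <- compute_novelty(gen, ref)

  qf <- maccs_fingerprints(gen)
  rf <- maccs_fingerprints(ref)
  brute <- vapply(seq_len(nrow(qf)), function(i) {
    max(vapply(seq_len(nrow(rf)), function(j) {
      inter <- sum(qf[i, ] & rf[j, ])
      uni <- sum(qf[i, ] | rf[j, ])
      if (uni == 0) 1 else inter / uni
    }, numeric(1)))
  }, numeric(1))
  expect_identical(nv$max_similarity, brute)
  expect_identical(nv$novel, brute < 0.85)
})

test_that("the metric chain is conserved and order-invariant", {
  sampled <- c(toy_smiles_corpus(60, seed = 61), "C((", "CC(", "N((")
  ref <- toy_smiles_corpus(40, seed = 62)
  lm1 <- library_metrics(sampled, reference = ref)
  expect_true(lm1$n_novel <= lm1$n_unique)
  expect_true(lm1$n_unique <= lm1$n_valid)
  expect_true(lm1$n_valid <= lm1$n_sampled)
  expect_equal(lm1$validity, lm1$n_valid / lm1$n_sampled)
  expect_equal(lm1$uniqueness, lm1$n_unique / lm1$n_valid)
  expect_equal(lm1$novelty, lm1$n_novel / lm1$n_unique)

  perm <- with(list(), {set.seed(3); sample(length(sampled))})
  lm2 <- library_metrics(sampled[perm], reference = ref)
  for (f in c("n_sampled", "n_valid", "n_unique", "n_novel",
              "validity", "uniqueness", "novelty")) {
    expect_identical(lm1[[f]], lm2[[f]])
  }
})

test_that("descriptors use the published definitions and flag failures", {
  d <- mol_descriptors(c("C", "c1ccccc1", "C(("))
  expect_equal(d$MW[1], 16.04, tolerance = 0.01 / 16.04)
  expect_equal(d$TPSA[2], 0)
  expect_true(d$QED[2] >= 0 && d$QED[2] <= 1)
  expect_true(d$SA[2] >= 1 && d$SA[2] <= 10)
  expect_false(d$ok[3])
  expect_equal(nrow(d), 3)  # failed row kept, not dropped

  s <- descriptor_summary(d)
  expect_equal(s$mean[s$descriptor == "MW"], mean(d$MW[1:2]))
  expect_equal(s$sd[s$descriptor == "MW"], sd(d$MW[1:2]))
})

test_that("2-D embedding is deterministic and keeps duplicates together", {
  set.seed(10)
  x <- matrix(rnorm(20 * 4), 20, 4)
  x[20, ] <- x[1, ]  # exact duplicate row
  e1 <- embed_2d(x, seed = 4, perplexity = 5)
  e2 <- embed_2d(x, seed = 4, perplexity = 5)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(20, 2))
  dup <- sqrt(sum((e1[1, ] - e1[20, ])^2))
  spread <- max(dist(e1))
  expect_lt(dup, spread / 20)

  expect_error(embed_2d(x[1:4, ]), "at least 5")
  x[3, 2] <- NaN
  expect_error(embed_2d(x), "non-finite feature rows: 3")

  g <- embed_2d(x[-3, ], seed = 1, perplexity = 4,
                group = rep(c("a", "b"), c(10, 9)))
  expect_equal(attr(g, "group"), rep(c("a", "b"), c(10, 9)))
})
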