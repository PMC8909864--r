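test_that("temperature reshaping matches its closed form", {
  p <- c(0.5, 0.3, 0.2)
  expect_identical(apply_temperature(p, 1), p)
  # q_i = p_i^2 / sum p^2 at T = 0.5
  expect_equal(apply_temperature(p, 0.5), c(0.6579, 0.2368, 0.1053),
               tolerance = 1e-4)
  # T -> 0 collapses onto the argmax
  expect_equal(apply_temperature(p, 1e-3), c(1, 0, 0), tolerance = 1e-12)
  # large T flattens towards uniform
  expect_equal(apply_temperature(p, 1e3), rep(1 / 3, 3), tolerance = 1e-3)

  expect_error(apply_temperature(p, 0), "positive")
  expect_error(apply_temperature(p, -1), "positive")
  expect_error(apply_temperature(c(0.5, 0.4), 1), "summing to 1")
})

test_that("temperature reshaping preserves probability ordering", {
  set.seed(8)
  for (i in 1:25) {
    p <- as.vector(stats::rgamma(6, 1)); p <- p / sum(p)
    for (Temp in c(0.2, 0.5, 1, 1.5, 3)) {
      q <- apply_temperature(p, Temp)
      expect_equal(sum(q), 1, tolerance = 1e-9)
      expect_identical(order(q), order(p))
    }
  }
})

test_that("sampling is seeded, prefix-preserving, and flags overruns", {
  m <- quick_model()
  a <- sample_smiles(m, n = 20, temperature = 1, seed = 5)
  b <- sample_smiles(m, n = 20, temperature = 1, seed = 5)
  expect_identical(a, b)
  expect_length(a, 20)
  expect_type(attr(a, "terminated"), "logical")

  prefix <- "C1CC"
  s <- sample_smiles(m, n = 10, temperature = 1, prefix = prefix, seed = 2)
  expect_true(all(startsWith(s, prefix)))

  # a hard length cap leaves unterminated strings flagged, at the cap
  short <- sample_smiles(m, n = 30, temperature = 2, max_len = 5, seed = 3)
  expect_true(all(nchar(short) <= 5))
  over <- !attr(short, "terminated")
  expect_true(any(over))
  expect_true(all(nchar(short[over]) == 5))

  expect_error(sample_smiles(m, n = 2, prefix = "C%C", seed = 1),
               "not in the vocabulary")
})

test_that("a memorized deterministic transition table is reproduced", {
  # train on one repeated string; at low temperature the chain G -> C -> O
  # -> E is effectively deterministic
  m <- smiles_lm(rep("CO", 12), units = 8, epochs = 120, batch_size = 12,
                 dropout = 0, learning_rate = 5e-3, seed = 1)
  s <- sample_smiles(m, n = 25, temperature = 0.1, seed = 9)
  expect_true(all(s == "CO"))
  expect_true(all(attr(s, "terminated")))
})

test_that("campaign plan bookkeeping multiplies out exactly", {
  plan <- campaign_plan(c(10, 20, 40, 100), c(0.5, 1, 1.2, 1.5), 1:7, 2000)
  expect_equal(nrow(plan), 4 * 4 * 7)
  expect_equal(sum(plan$n_samples), 224000)
  expect_equal(nrow(campaign_plan(1, 1, 1, 5, expand = TRUE)), 5)
})

test_that("campaigns enumerate cells, derive per-cell seeds, and reproduce", {
  m <- quick_model()
  rooted <- c(a = "CC", b = "CO")
  tbl <- run_campaign(list(e1 = m), rooted, temperatures = c(0.7, 1.3),
                      n_samples = 5, seed = 17, max_len = 30)
  expect_equal(nrow(tbl), 1 * 2 * 2 * 5)
  expect_equal(sort(unique(tbl$site)), c("a", "b"))
  expect_true(all(startsWith(tbl$smiles[tbl$site == "a"], "CC")))

  tbl2 <- run_campaign(list(e1 = m), rooted, temperatures = c(0.7, 1.3),
                       n_samples = 5, seed = 17, max_len = 30)
  expect_identical(tbl, tbl2)

  # any single cell is independently reproducible from its derived sub-seed
  cell <- sample_smiles(m, n = 5, temperature = 1.3, prefix = "CO",
                        max_len = 30,
                        seed = molgen:::derive_seed(17, "e1", 1.3, "b"))
  expect_identical(tbl$smiles[tbl$temperature == 1.3 & tbl$site == "b"],
                   as.character(cell))

  expect_error(run_campaign(list(m), c(a = NA_character_), 1, 2, 1),
               "unverified")
})
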