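test_that("trainable parameter count matches the per-layer closed forms", {
  expect_identical(count_trainable_params(256, 29), 825629)
  # U=2, V=3: 4*(2*(3+2)+2) + 4*(2*(2+2)+2) + (2*3+3) = 48 + 40 + 9
  expect_identical(count_trainable_params(2, 3), 97L + 0)

  # closed form equals the number of allocated weights for random (U, V)
  set.seed(4)
  for (i in 1:20) {
    U <- sample(1:40, 1); V <- sample(3:30, 1)
    params <- molgen:::lstm_init_params(U, V)
    expect_equal(sum(vapply(params, length, integer(1))),
                 count_trainable_params(U, V))
  }
})

test_that("model construction is seeded and reports its parameter budget", {
  v <- vocab29()
  expect_length(v, 29)
  m <- smiles_lm("CCO", vocab = v, units = 256, epochs = 0, seed = 5)
  s <- summary(m)
  expect_equal(s$trainable_params, 825629)
  expect_equal(unname(s$layer_params),
               c(4 * (256 * (29 + 256) + 256), 4 * (256 * (256 + 256) + 256),
                 256 * 29 + 29))

  m2 <- smiles_lm("CCO", vocab = v, units = 256, epochs = 0, seed = 5)
  expect_identical(m$params, m2$params)
  m3 <- smiles_lm("CCO", vocab = v, units = 256, epochs = 0, seed = 6)
  expect_false(identical(m$params, m3$params))
})

test_that("next-token tensors shift by one and mask padding", {
  v <- smiles_vocabulary(c("C", "CO"))
  tt <- make_next_token_tensors("C", v)
  expect_equal(dim(tt$inputs), c(1, 2))
  expect_equal(v$tokens[tt$inputs[1, ]], c("G", "C"))
  expect_equal(v$tokens[tt$targets[1, ]], c("C", "E"))
  expect_equal(tt$mask[1, ], c(1, 1))

  corpus <- toy_smiles_corpus(40, seed = 5)
  vv <- smiles_vocabulary(corpus)
  tt <- make_next_token_tensors(corpus, vv)
  expect_equal(sum(tt$mask), sum(nchar(corpus) + 1))
  expect_error(make_next_token_tensors(character(0), vv), "empty")
  expect_error(make_next_token_tensors("CZ", vv), "line 1")
})

test_that("training converges on the toy corpus and logs one record per epoch", {
  m <- toy_model()
  h <- m$history
  expect_equal(nrow(h), 30)
  expect_equal(h$epoch, 1:30)
  expect_true(all(h$train_loss >= 0 & h$val_loss >= 0))
  expect_true(all(h$train_acc >= 0 & h$train_acc <= 1))
  # validation loss is non-increasing over the last five epochs (tol 0.05)
  tail5 <- tail(h$val_loss, 5)
  expect_true(all(diff(tail5) <= 0.05))
  # and training clearly beat the untrained uniform baseline log(V)
  expect_lt(tail(h$val_loss, 1), log(length(m$vocab)) * 0.6)
})

test_that("training is deterministic and epochs = 0 leaves the model untouched", {
  corpus <- quick_corpus()
  a <- smiles_lm(corpus, units = 16, epochs = 2, batch_size = 64, seed = 11)
  b <- smiles_lm(corpus, units = 16, epochs = 2, batch_size = 64, seed = 11)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)

  m0 <- smiles_lm(corpus, units = 16, epochs = 0, seed = 11)
  expect_equal(nrow(m0$history), 0)
})

test_that("checkpoints round-trip through the manifest directory", {
  dir <- withr::local_tempdir()
  corpus <- quick_corpus()
  m <- smiles_lm(corpus, units = 16, epochs = 2, batch_size = 64, seed = 3,
                 checkpoint_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  ck <- load_checkpoint(dir, 2)
  expect_identical(ck$params, m$params)
  expect_identical(ck$vocab, m$vocab)
  expect_error(load_checkpoint(dir, 99), "epoch 99")

  r <- resume_training(ck, corpus, epochs = 1, batch_size = 64, seed = 4)
  expect_equal(nrow(r$history), 1)
  expect_equal(r$history$phase, "resume")
})

test_that("diagnostics: uniform model scores log(V); trained beats untrained", {
  val <- toy_smiles_corpus(150, seed = 99)
  v <- smiles_vocabulary(val)
  m0 <- smiles_lm(val, vocab = v, units = 8, epochs = 0, seed = 1)
  m0$params <- lapply(m0$params, function(p) p * 0)  # exactly uniform output
  d0 <- epoch_diagnostics(m0, val, n_samples = 16, seed = 1)
  expect_equal(unname(d0["log_loss"]), log(length(v)), tolerance = 1e-10)
  expect_error(epoch_diagnostics(m0, character(0)), "empty validation")

  # both diagnostics improve from epoch 1 to epoch 30 of the toy run
  m <- toy_model()
  m1 <- m; m1$params <- m$checkpoints[["1"]]
  m30 <- m; m30$params <- m$checkpoints[["30"]]
  d1 <- epoch_diagnostics(m1, val, n_samples = 64, seed = 2)
  d30 <- epoch_diagnostics(m30, val, n_samples = 64, seed = 2)
  expect_lt(d30[["log_loss"]], d1[["log_loss"]])
  expect_lt(d30[["wasserstein"]], d1[["wasserstein"]])
})

test_that("Wasserstein token-frequency distance behaves like a metric", {
  w <- molgen:::wasserstein_1d
  expect_equal(w(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(w(c(1, 0), c(0, 1)), 1)   # unit mass moved one step
  expect_equal(w(c(1, 0, 0), c(0, 0, 1)), 2)
  p <- c(0.1, 0.6, 0.3); q <- c(0.5, 0.2, 0.3)
  expect_equal(w(p, q), w(q, p))
})

test_that("a high-capacity model overfits a small corpus more than a small one", {
  corpus <- toy_smiles_corpus(150, seed = 31)
  gap <- function(units) {
    m <- smiles_lm(corpus, units = units, epochs = 12, batch_size = 16,
                   seed = 31, dropout = 0)
    h <- tail(m$history, 1)
    h$val_loss - h$train_loss
  }
  expect_gt(gap(96), gap(16))
})

test_that("the network can drive training loss towards zero on one batch", {
  corpus <- rep("CCONCC", 12)  # a single repeated string is fully learnable
  m <- smiles_lm(corpus, units = 32, epochs = 150, batch_size = 12,
                 val_fraction = 0.25, dropout = 0, learning_rate = 5e-3,
                 seed = 2)
  expect_lt(tail(m$history$train_loss, 1), 0.1)
})

test_that("predict returns a temperature-shaped next-token distribution", {
  m <- quick_model()
  p <- predict(m, prefix = "CC")
  expect_named(p, m$vocab$tokens)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  p_cold <- predict(m, prefix = "CC", temperature = 0.2)
  expect_equal(which.max(p_cold), which.max(p))
  expect_gt(max(p_cold), max(p))
})
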