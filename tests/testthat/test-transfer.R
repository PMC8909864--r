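test_that("freezing strategies set flags and parameter budgets exactly", {
  v <- vocab29()
  m <- smiles_lm("CCO", vocab = v, units = 256, epochs = 0, seed = 1)
  expect_equal(summary(freeze_layers(m, "none"))$trainable_params, 825629)
  # first-layer closed form 4*(256*(29+256)+256) = 292,864
  expect_equal(summary(freeze_layers(m, "first_lstm"))$trainable_params,
               825629 - 292864)
  expect_equal(summary(freeze_layers(m, "both_lstm"))$trainable_params,
               256 * 29 + 29)
  expect_error(freeze_layers(m, "half"), "arg")
})

test_that("fine-tuning freezes exactly, trains the rest, and keeps the shape", {
  base <- quick_model()
  target <- toy_smiles_corpus(60, seed = 77)
  ft <- finetune(base, target, freeze = "first_lstm", epochs = 2,
                 batch_size = 32, seed = 5)
  # frozen tensors are bit-identical; unfrozen layers moved
  expect_identical(ft$params$Wx1, base$params$Wx1)
  expect_identical(ft$params$Wh1, base$params$Wh1)
  expect_identical(ft$params$b1, base$params$b1)
  expect_false(identical(ft$params$Wx2, base$params$Wx2))
  expect_false(identical(ft$params$Wd, base$params$Wd))
  # architecture and vocabulary untouched
  expect_identical(ft$vocab, base$vocab)
  expect_identical(dim(ft$params$Wd), dim(base$params$Wd))
  expect_equal(ft$history$phase[nrow(ft$history)], "finetune")

  ft0 <- finetune(base, target, freeze = "first_lstm", epochs = 0)
  expect_identical(ft0$params, base$params)
})

test_that("characters outside the base vocabulary are a hard error", {
  base <- quick_model()
  expect_error(finetune(base, c("CCO", "CC[S]"), epochs = 1),
               "absent from the model vocabulary.*\\[")
})

test_that("strategy comparison runs the full grid and collects curves", {
  base <- quick_model()
  target <- toy_smiles_corpus(60, seed = 78)
  rep <- compare_strategies(base, target,
                            strategies = c("first_lstm", "both_lstm"),
                            batch_sizes = c(16, 48), epochs = 2, seed = 3)
  expect_equal(nrow(rep), 2 * 2 * 2)
  expect_setequal(unique(rep$strategy), c("first_lstm", "both_lstm"))
  expect_setequal(unique(rep$batch_size), c(16, 48))
  expect_true(all(c("train_loss", "val_loss", "train_acc", "val_acc")
                  %in% names(rep)))
  expect_error(compare_strategies(base, target, strategies = character(0)),
               "length")
})

test_that("keeping one LSTM adaptable fits the target at least as well as freezing both", {
  base <- toy_model()
  target <- target_corpus()[1:300]
  rep <- compare_strategies(base, target,
                            strategies = c("first_lstm", "both_lstm"),
                            batch_sizes = 128, epochs = 8, seed = 21)
  final <- sapply(split(rep, rep$strategy), function(d) tail(d$val_loss, 1))
  # soft qualitative expectation: a small tolerance absorbs run-to-run noise
  expect_lte(final[["first_lstm"]], final[["both_lstm"]] + 0.05)
})
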