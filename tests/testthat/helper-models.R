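# Shared fixtures, built once per test run and cached. The "toy" model is
# the desk-scale reference generator: 2,000 grammar-generated molecules,
# 64 LSTM units, 30 epochs, small-corpus batch size 128, seed 7. Training it
# takes about a minute; every test that needs a trained generator reuses it.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache, inherits = FALSE)
}

toy_corpus <- function() cached("toy_corpus", toy_smiles_corpus(2000, seed = 7))

toy_model <- function() cached("toy_model", {
  smiles_lm(toy_corpus(), units = 64, epochs = 30, batch_size = 128,
            seed = 7, keep_epochs = c(1L, 30L))
})

# motif-enriched target corpus standing in for a small target-ligand set
indole_rooted <- "C12=C(C=CC=C2)NC=C1"

target_corpus <- function() cached("target_corpus", {
  motif_enriched_corpus(950, seed = 11, enrichment = 1.0)
})

# the t-model: toy model fine-tuned on the motif corpus with the first LSTM
# frozen (40 epochs, batch 128 — the transfer-learning defaults)
transfer_model <- function() cached("transfer_model", {
  finetune(toy_model(), target_corpus(), freeze = "first_lstm",
           epochs = 40, batch_size = 128, seed = 13)
})

# small fast model for interface-level tests
quick_corpus <- function() cached("quick_corpus",
                                  toy_smiles_corpus(300, seed = 42))

quick_model <- function() cached("quick_model", {
  smiles_lm(quick_corpus(), units = 16, epochs = 3, batch_size = 64,
            seed = 1)
})

# 29-token vocabulary (27 chemistry characters + sentinels) for parameter
# count checks at the reference architecture size
vocab29 <- function() {
  smiles_vocabulary(paste(c(letters[1:26], "0"), collapse = ""))
}
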