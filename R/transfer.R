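# Transfer learning: selective layer freezing and fine-tuning of a trained
# generator on a small target-specific corpus (g-model -> t-model).

FREEZE_STRATEGIES <- list(
  none = c(lstm1 = TRUE, lstm2 = TRUE, dense = TRUE),
  first_lstm = c(lstm1 = FALSE, lstm2 = TRUE, dense = TRUE),
  both_lstm = c(lstm1 = FALSE, lstm2 = FALSE, dense = TRUE))

#' Freeze layers of a SMILES language model
#'
#' Sets the per-layer trainable flags according to a freezing strategy and
#' recomputes the trainable parameter count. `"first_lstm"` freezes the
#' first LSTM layer (its parameters are kept constant while the second LSTM
#' and the dense layer may change); `"both_lstm"` leaves only the dense
#' output layer trainable; `"none"` unfreezes everything.
#'
#' @param model A `smiles_lm`.
#' @param strategy One of `"none"`, `"first_lstm"`, `"both_lstm"`.
#' @return The model with updated `trainable` flags.
#' @export
#' @examples \dontrun{
#' m <- smiles_lm(toy_smiles_corpus(50), units = 16, epochs = 0)
#' summary(freeze_layers(m, "first_lstm"))
#' }
freeze_layers <- function(model, strategy = c("none", "first_lstm",
                                              "both_lstm")) {
  stopifnot(inherits(model, "smiles_lm"))
  if (length(strategy) != 1 || !strategy %in% names(FREEZE_STRATEGIES)) {
    strategy <- match.arg(strategy)
  }
  model$trainable <- FREEZE_STRATEGIES[[strategy]]
  model
}

#' Fine-tune a generator on a target-specific corpus
#'
#' Continues training a fitted model on a small target corpus with the
#' requested layer-freezing strategy, producing a target-focused generator.
#' Frozen layers are bit-identical before and after. The target corpus must
#' be encodable with the model's existing vocabulary: characters outside it
#' are a hard error (silent vocabulary growth would corrupt the one-hot
#' input semantics), listed in the message. A fresh Adam optimizer is used;
#' the architecture and vocabulary are never altered.
#'
#' @param model A fitted `smiles_lm`.
#' @param corpus Target-specific SMILES corpus (character vector or `.smi`
#'   path).
#' @param freeze Freezing strategy, see [freeze_layers()]; default freezes
#'   the first LSTM.
#' @param epochs Fine-tuning epochs (default 40).
#' @param batch_size Mini-batch size (default 128, suited to small target
#'   corpora; 512 matches the pre-training default).
#' @param learning_rate Adam learning rate.
#' @param val_fraction Validation split fraction.
#' @param seed Integer seed.
#' @param ... Passed to the training loop (`checkpoint_dir`, `keep_epochs`,
#'   `diagnostics`, `verbose`).
#' @return The fine-tuned `smiles_lm`; fine-tuning epochs are appended to
#'   `model$history` with phase `"finetune"`.
#' @export
finetune <- function(model, corpus, freeze = "first_lstm", epochs = 40,
                     batch_size = 128, learning_rate = 1e-3,
                     val_fraction = 0.2, seed = 1, ...) {
  stopifnot(inherits(model, "smiles_lm"), epochs >= 0)
  if (is.character(corpus) && length(corpus) == 1 && file.exists(corpus)) {
    corpus <- read_smiles_file(corpus)
  }
  unknown <- setdiff(unique(unlist(strsplit(corpus, "", fixed = TRUE))),
                     model$vocab$tokens)
  if (length(unknown) > 0) {
    stop("target corpus contains characters absent from the model ",
         "vocabulary: ", paste(unknown, collapse = " "),
         " (rebuild the base model with a vocabulary covering them)",
         call. = FALSE)
  }
  model <- freeze_layers(model, freeze)
  if (epochs == 0) return(model)
  args <- list(...)
  fit_lm(model, corpus, epochs = epochs, batch_size = batch_size,
         learning_rate = learning_rate, val_fraction = val_fraction,
         seed = seed, phase = "finetune",
         checkpoint_dir = args$checkpoint_dir,
         keep_epochs = args$keep_epochs %||% integer(0),
         diagnostics = isTRUE(args$diagnostics),
         verbose = isTRUE(args$verbose))
}

#' Compare fine-tuning strategies
#'
#' Fine-tunes copies of a base model over a grid of freezing strategies and
#' batch sizes and collects the per-epoch loss/accuracy curves in one data
#' frame. No ranking is imposed; inspect the curves.
#'
#' @param model A fitted `smiles_lm`.
#' @param corpus Target corpus.
#' @param strategies Character vector of freezing strategies.
#' @param batch_sizes Integer vector of batch sizes.
#' @param epochs Fine-tuning epochs per configuration.
#' @param seed Integer seed (shared; each configuration still derives its
#'   own sub-seeds via its phase coordinates).
#' @param ... Passed to [finetune()].
#' @return Data frame with columns `strategy`, `batch_size`, `epoch`,
#'   `train_loss`, `val_loss`, `train_acc`, `val_acc`.
#' @export
compare_strategies <- function(model, corpus,
                               strategies = c("first_lstm", "both_lstm"),
                               batch_sizes = c(128, 512), epochs = 10,
                               seed = 1, ...) {
  stopifnot(length(strategies) >= 1, length(batch_sizes) >= 1)
  grid <- expand.grid(strategy = strategies, batch_size = batch_sizes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ft <- finetune(model, corpus, freeze = grid$strategy[i],
                   epochs = epochs, batch_size = grid$batch_size[i],
                   seed = derive_seed(seed, grid$strategy[i],
                                      grid$batch_size[i]), ...)
    h <- ft$history[ft$history$phase == "finetune", ]
    out[[i]] <- data.frame(strategy = grid$strategy[i],
                           batch_size = grid$batch_size[i],
                           epoch = h$epoch, train_loss = h$train_loss,
                           val_loss = h$val_loss, train_acc = h$train_acc,
                           val_acc = h$val_acc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
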