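# The g-model: a character-level next-token language model over SMILES with
# two LSTM layers, a dropout layer between them, and a dense softmax output.

#' Closed-form trainable parameter count
#'
#' Sums the per-layer closed forms for the two-LSTM architecture:
#' `4*(U*(V+U)+U)` for the first LSTM (input width V), `4*(U*(U+U)+U)` for
#' the second (input width U), and `U*V+V` for the dense softmax output.
#' The dropout layer contributes no parameters. With `units = 256` and a
#' 29-token vocabulary this is 825,629.
#'
#' @param units LSTM width U (both layers).
#' @param vocab_size Vocabulary size V (sentinels included).
#' @return Integer total of trainable parameters.
#' @export
#' @examples count_trainable_params(256, 29)
count_trainable_params <- function(units, vocab_size) {
  stopifnot(units >= 1, vocab_size >= 1)
  sum(layer_param_counts(units, vocab_size))
}

#' Fit (or initialize) a SMILES language model
#'
#' Builds the two-layer LSTM next-character model and trains it by
#' mini-batch Adam on a SMILES corpus. Each training string is framed with
#' begin/end sentinels; inputs are positions `1..L-1` and targets positions
#' `2..L`, with padded positions masked out of the loss. The corpus is split
#' into training and validation parts (default 80/20, seeded), and one
#' history record is written per epoch. With `epochs = 0` the model is
#' returned initialized but untrained.
#'
#' All randomness (weight initialization, the split, shuffling, dropout)
#' derives from `seed`, so identical calls give bit-identical models and
#' histories in single-threaded BLAS.
#'
#' @param corpus Character vector of SMILES strings, or a path to a `.smi`
#'   file.
#' @param vocab Optional [smiles_vocabulary()]; built from `corpus` when
#'   `NULL`. Supply one covering extra characters if the model will later be
#'   fine-tuned on corpora with a wider alphabet.
#' @param units LSTM width (default 256; 64 is a practical desk-scale width,
#'   512 reproduces the overcapacity comparison).
#' @param dropout Dropout rate between the LSTM layers, in (0, 1).
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param val_fraction Held-out validation fraction in (0, 1).
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed for all randomness.
#' @param checkpoint_dir Optional directory; when given, per-epoch weights
#'   plus a JSON manifest are written there and recorded in the history.
#' @param keep_epochs Integer epochs whose weights are additionally retained
#'   in memory (`model$checkpoints`), e.g. for sampling campaigns.
#' @param diagnostics If `TRUE`, per-epoch validation log-loss and the
#'   token-frequency Wasserstein diagnostic (see [epoch_diagnostics()]) are
#'   recorded; sampling for the diagnostic uses `diag_samples` draws.
#' @param diag_samples Samples drawn per epoch for the Wasserstein
#'   diagnostic.
#' @param verbose Print per-epoch progress.
#' @return An object of class `smiles_lm`.
#' @seealso [simulate.smiles_lm()], [finetune()], [freeze_layers()]
#' @export
smiles_lm <- function(corpus, vocab = NULL, units = 256, dropout = 0.3,
                      epochs = 100, batch_size = 512, val_fraction = 0.2,
                      learning_rate = 1e-3, seed = 1, checkpoint_dir = NULL,
                      keep_epochs = integer(0), diagnostics = FALSE,
                      diag_samples = 64, verbose = FALSE) {
  if (is.character(corpus) && length(corpus) == 1 && file.exists(corpus)) {
    corpus <- read_smiles_file(corpus)
  }
  stopifnot(is.character(corpus), length(corpus) >= 1,
            units >= 1, dropout >= 0, dropout < 1, epochs >= 0,
            batch_size >= 1, val_fraction > 0, val_fraction < 1)
  if (is.null(vocab)) vocab <- smiles_vocabulary(corpus)
  V <- length(vocab)
  if (V < 3) stop("vocabulary must contain the sentinels plus at least one ",
                  "chemistry character", call. = FALSE)
  params <- with_seed(derive_seed(seed, "init"), lstm_init_params(units, V))
  model <- structure(list(
    vocab = vocab, units = units, dropout = dropout, params = params,
    trainable = c(lstm1 = TRUE, lstm2 = TRUE, dense = TRUE),
    config = list(units = units, dropout = dropout, batch_size = batch_size,
                  val_fraction = val_fraction, learning_rate = learning_rate,
                  seed = seed),
    history = empty_history(), checkpoints = list(), call = match.call()),
    class = "smiles_lm")
  if (epochs == 0) return(model)
  if (length(corpus) < 10) {
    stop("training requires a corpus of at least 10 strings", call. = FALSE)
  }
  fit_lm(model, corpus, epochs = epochs, batch_size = batch_size,
         learning_rate = learning_rate, val_fraction = val_fraction,
         seed = seed, phase = "train", checkpoint_dir = checkpoint_dir,
         keep_epochs = keep_epochs, diagnostics = diagnostics,
         diag_samples = diag_samples, verbose = verbose)
}

empty_history <- function() {
  data.frame(phase = character(0), epoch = integer(0),
             train_loss = numeric(0), val_loss = numeric(0),
             train_acc = numeric(0), val_acc = numeric(0),
             log_loss = numeric(0), wasserstein = numeric(0),
             checkpoint = character(0), stringsAsFactors = FALSE)
}

encode_corpus <- function(corpus, vocab) {
  lapply(seq_along(corpus), function(i) {
    tryCatch(smiles_to_indices(corpus[[i]], vocab),
             error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
}

#' Next-token training tensors for a corpus
#'
#' Packs a corpus into the shifted-by-one training pairs: for each framed
#' sequence `G, s, E`, inputs are positions `1..L-1` and targets positions
#' `2..L`. Sequences are padded to the batch maximum and a mask marks real
#' target positions; the total unmasked count is `sum(nchar(s) + 1)`.
#'
#' @param corpus Character vector of SMILES strings.
#' @param vocab A [smiles_vocabulary()].
#' @return List with integer matrices `inputs`, `targets` and numeric `mask`
#'   (rows = strings, columns = time steps).
#' @export
make_next_token_tensors <- function(corpus, vocab) {
  if (length(corpus) == 0) stop("empty corpus", call. = FALSE)
  b <- pack_batch(encode_corpus(corpus, vocab))
  list(inputs = b$X, targets = b$Y, mask = b$M)
}

# shared training loop (initial fit and fine-tuning); appends to history
fit_lm <- function(model, corpus, epochs, batch_size, learning_rate,
                   val_fraction, seed, phase, checkpoint_dir = NULL,
                   keep_epochs = integer(0), diagnostics = FALSE,
                   diag_samples = 64, verbose = FALSE) {
  seqs <- encode_corpus(corpus, model$vocab)
  n <- length(seqs)
  n_val <- max(1L, floor(val_fraction * n))
  val_ix <- with_seed(derive_seed(seed, phase, "split"), sample(n, n_val))
  train_ix <- setdiff(seq_len(n), val_ix)
  seqs_train <- seqs[train_ix]
  seqs_val <- seqs[val_ix]
  val_corpus <- corpus[val_ix]

  opt <- adam_init(model$params)
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  }
  hist_rows <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, phase, "shuffle", ep),
                     sample(length(seqs_train)))
    tr_loss <- 0; tr_n <- 0; tr_correct <- 0
    res <- with_seed(derive_seed(seed, phase, "dropout", ep), {
      for (ix in split(ord, ceiling(seq_along(ord) / batch_size))) {
        batch <- pack_batch(seqs_train[ix])
        r <- lstm_batch_pass(model$params, batch, model$units,
                             dropout = model$dropout, training = TRUE,
                             want_grads = TRUE)
        if (!is.finite(r$loss_sum)) {
          stop("non-finite training loss at epoch ", ep,
               "; inspect learning rate and corpus", call. = FALSE)
        }
        up <- adam_update(model$params, r$grads, opt, model$trainable,
                          lr = learning_rate)
        model$params <- up$params
        opt <- up$opt
        tr_loss <- tr_loss + r$loss_sum
        tr_n <- tr_n + r$n_pos
        tr_correct <- tr_correct + r$correct
      }
      list(params = model$params, opt = opt,
           loss = tr_loss, n = tr_n, correct = tr_correct)
    })
    model$params <- res$params; opt <- res$opt
    val <- lstm_evaluate(model$params, seqs_val, model$units)
    dia <- c(log_loss = unname(val["loss"]), wasserstein = NA_real_)
    if (diagnostics) {
      dia <- epoch_diagnostics(model, val_corpus, n_samples = diag_samples,
                               seed = derive_seed(seed, phase, "diag", ep))
    }
    ckpt <- NA_character_
    if (!is.null(checkpoint_dir)) {
      ckpt <- file.path(checkpoint_dir, sprintf("epoch_%04d.rds", ep))
      saveRDS(model$params, ckpt)
    }
    if (ep %in% keep_epochs) {
      model$checkpoints[[as.character(ep)]] <- model$params
    }
    hist_rows[[ep]] <- data.frame(
      phase = phase, epoch = ep, train_loss = res$loss / res$n,
      val_loss = unname(val["loss"]), train_acc = res$correct / res$n,
      val_acc = unname(val["acc"]), log_loss = unname(dia[["log_loss"]]),
      wasserstein = unname(dia[["wasserstein"]]), checkpoint = ckpt,
      stringsAsFactors = FALSE)
    if (verbose) {
      message(sprintf("[%s] epoch %d/%d loss %.4f val %.4f acc %.3f",
                      phase, ep, epochs, res$loss / res$n, val["loss"],
                      val["acc"]))
    }
  }
  model$history <- rbind(model$history, do.call(rbind, hist_rows))
  if (!is.null(checkpoint_dir)) {
    manifest <- list(config = model$config, tokens = model$vocab$tokens,
                     phase = phase, epochs = seq_len(epochs),
                     trainable = as.list(model$trainable))
    jsonlite::write_json(manifest, file.path(checkpoint_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  model
}

#' Continue training an existing model
#'
#' Resumes mini-batch training of a fitted or checkpoint-loaded model on a
#' corpus, appending to its history (phase `"resume"`). A fresh Adam
#' optimizer is instantiated.
#'
#' @param model A `smiles_lm` object.
#' @param corpus SMILES corpus (character vector or `.smi` path).
#' @param epochs Additional epochs.
#' @param ... Passed to the internal training loop: `batch_size`,
#'   `learning_rate`, `val_fraction`, `seed`, `checkpoint_dir`,
#'   `keep_epochs`, `diagnostics`, `verbose`.
#' @return The updated `smiles_lm`.
#' @export
resume_training <- function(model, corpus, epochs, ...) {
  stopifnot(inherits(model, "smiles_lm"), epochs >= 1)
  if (is.character(corpus) && length(corpus) == 1 && file.exists(corpus)) {
    corpus <- read_smiles_file(corpus)
  }
  args <- list(...)
  fit_lm(model, corpus, epochs = epochs,
         batch_size = args$batch_size %||% model$config$batch_size,
         learning_rate = args$learning_rate %||% model$config$learning_rate,
         val_fraction = args$val_fraction %||% model$config$val_fraction,
         seed = args$seed %||% model$config$seed, phase = "resume",
         checkpoint_dir = args$checkpoint_dir,
         keep_epochs = args$keep_epochs %||% integer(0),
         diagnostics = isTRUE(args$diagnostics),
         verbose = isTRUE(args$verbose))
}

#' Load model weights from a checkpoint directory
#'
#' Reads the JSON manifest and the requested epoch's weight file written
#' during training with `checkpoint_dir` set.
#'
#' @param dir Checkpoint directory.
#' @param epoch Epoch number to load.
#' @return A `smiles_lm` object (history empty).
#' @export
load_checkpoint <- function(dir, epoch) {
  mf_path <- file.path(dir, "manifest.json")
  wt_path <- file.path(dir, sprintf("epoch_%04d.rds", epoch))
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  if (!file.exists(wt_path)) {
    stop("missing checkpoint for epoch ", epoch, " in ", dir, call. = FALSE)
  }
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  tokens <- as.character(mf$tokens)
  vocab <- structure(list(tokens = tokens,
                          index = stats::setNames(seq_along(tokens), tokens)),
                     class = "smiles_vocabulary")
  structure(list(vocab = vocab, units = mf$config$units,
                 dropout = mf$config$dropout, params = readRDS(wt_path),
                 trainable = c(lstm1 = TRUE, lstm2 = TRUE, dense = TRUE),
                 config = mf$config, history = empty_history(),
                 checkpoints = list(), call = NULL),
            class = "smiles_lm")
}

#' Per-epoch generator diagnostics
#'
#' Computes two diagnostics on a validation corpus: `log_loss`, the mean
#' categorical cross-entropy (nats) over unmasked validation positions, and
#' `wasserstein`, the 1-D Wasserstein distance between the character
#' frequency distribution of `n_samples` seeded model samples and that of
#' the validation corpus, with characters ordered by vocabulary index. The
#' Wasserstein quantity is a convergence diagnostic for the sampled
#' character statistics, not a structure-level distance.
#'
#' @param model A `smiles_lm`.
#' @param val_corpus Character vector of validation SMILES.
#' @param n_samples Number of samples drawn for the frequency comparison.
#' @param seed Seed for the sampling draw.
#' @return Named numeric vector `c(log_loss =, wasserstein =)`.
#' @export
epoch_diagnostics <- function(model, val_corpus, n_samples = 64, seed = 1) {
  stopifnot(inherits(model, "smiles_lm"))
  if (length(val_corpus) == 0) stop("empty validation set", call. = FALSE)
  seqs <- encode_corpus(val_corpus, model$vocab)
  ev <- lstm_evaluate(model$params, seqs, model$units)
  draws <- sample_smiles(model, n = n_samples, temperature = 1,
                         seed = seed)
  w <- wasserstein_1d(token_frequencies(draws, model$vocab),
                      token_frequencies(val_corpus, model$vocab))
  c(log_loss = unname(ev["loss"]), wasserstein = w)
}

# character frequency distribution over the vocabulary's chemistry tokens
token_frequencies <- function(strings, vocab) {
  toks <- setdiff(vocab$tokens, c(SENTINEL_BEGIN, SENTINEL_END))
  chars <- unlist(strsplit(paste(strings, collapse = ""), "", fixed = TRUE))
  counts <- table(factor(chars, levels = toks))
  if (sum(counts) == 0) return(stats::setNames(rep(0, length(toks)), toks))
  as.numeric(counts) / sum(counts)
}

# first Wasserstein distance between two distributions on the same ordered
# support with unit spacing: sum of |CDF differences|
wasserstein_1d <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(cumsum(p - q)))
}

#' @export
print.smiles_lm <- function(x, ...) {
  V <- length(x$vocab)
  cat("SMILES language model (2 x LSTM(", x$units, ") + dropout ",
      x$dropout, " + dense softmax)\n", sep = "")
  cat("  vocabulary:", V, "tokens;",
      format(trainable_params(x), big.mark = ","), "of",
      format(count_trainable_params(x$units, V), big.mark = ","),
      "parameters trainable\n")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epoch(s); last val loss %.4f, val acc %.3f\n",
                nrow(x$history), last$val_loss, last$val_acc))
  } else {
    cat("  untrained (initialized weights)\n")
  }
  invisible(x)
}

# trainable parameter total respecting per-layer freeze flags
trainable_params <- function(model) {
  counts <- layer_param_counts(model$units, length(model$vocab))
  sum(counts[names(model$trainable)[model$trainable]])
}

#' @export
summary.smiles_lm <- function(object, ...) {
  counts <- layer_param_counts(object$units, length(object$vocab))
  out <- list(units = object$units, vocab_size = length(object$vocab),
              layer_params = counts, trainable = object$trainable,
              trainable_params = trainable_params(object),
              total_params = sum(counts), history = object$history)
  class(out) <- "summary.smiles_lm"
  out
}

#' @export
print.summary.smiles_lm <- function(x, ...) {
  cat("Layers (U =", x$units, ", V =", x$vocab_size, "):\n")
  for (nm in names(x$layer_params)) {
    cat(sprintf("  %-6s %9s parameters  [%s]\n", nm,
                format(x$layer_params[[nm]], big.mark = ","),
                if (x$trainable[[nm]]) "trainable" else "frozen"))
  }
  cat("  total", format(x$total_params, big.mark = ","), "/ trainable",
      format(x$trainable_params, big.mark = ","), "\n")
  if (nrow(x$history) > 0) {
    cat("Training history (last 5 epochs):\n")
    print(utils::tail(x$history[, c("phase", "epoch", "train_loss",
                                    "val_loss", "train_acc", "val_acc")], 5),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.smiles_lm <- function(object, ...) object$params

#' @export
plot.smiles_lm <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    stop("model has no training history to plot", call. = FALSE)
  }
  i <- seq_len(nrow(h))
  graphics::matplot(i, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy (nats)", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Next-token probability distribution
#'
#' Runs the model over `G` plus the prefix characters and returns the
#' predicted distribution for the next character.
#'
#' @param object A `smiles_lm`.
#' @param prefix Prefix string (possibly empty).
#' @param temperature Optional temperature reshaping (default 1 = none).
#' @param ... Unused.
#' @return Named numeric vector over the vocabulary tokens, summing to 1.
#' @export
predict.smiles_lm <- function(object, prefix = "", temperature = 1, ...) {
  idx <- smiles_to_indices(paste0(prefix, ""), object$vocab)
  idx <- idx[-length(idx)]  # drop the end sentinel; keep G + prefix
  state <- lstm_zero_state(1, object$units)
  for (t in idx) {
    st <- lstm_step(object$params, t, state, object$units)
    state <- st$state
  }
  p <- apply_temperature(drop(st$p), temperature)
  stats::setNames(p, object$vocab$tokens)
}

#' @export
logLik.smiles_lm <- function(object, corpus, ...) {
  seqs <- encode_corpus(corpus, object$vocab)
  ev <- lstm_evaluate(object$params, seqs, object$units)
  n <- sum(lengths(seqs) - 1)
  structure(-unname(ev["loss"]) * n, nobs = n, df = trainable_params(object),
            class = "logLik")
}
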