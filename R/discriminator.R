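# MACCS-fingerprint MLP activity discriminator: Ki-based labelling, training
# set assembly (actives + inactives + decoys), a hand-written
# three-hidden-layer perceptron, k-fold cross-validation and scoring.

#' Split activity records by a Ki cutoff
#'
#' Actives are molecules with reported Ki strictly below the cutoff
#' (default 100 nM); a boundary Ki equal to the cutoff is inactive. Rows
#' with missing or non-positive Ki are rejected and reported via the
#' `"rejected"` attribute.
#'
#' @param records Data frame with columns `smiles` and `ki_nm` (nM).
#' @param cutoff_nm Activity cutoff in nM.
#' @return The records with a logical `active` column appended; rejected
#'   rows (with a `reason` column) in `attr(, "rejected")`.
#' @export
#' @examples
#' label_by_ki(data.frame(smiles = c("CCO", "CCN", "CCC"),
#'                        ki_nm = c(50, 100, 150)))
label_by_ki <- function(records, cutoff_nm = 100) {
  stopifnot(is.data.frame(records),
            all(c("smiles", "ki_nm") %in% names(records)))
  bad <- is.na(records$ki_nm) | records$ki_nm <= 0
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- ifelse(is.na(rejected$ki_nm), "missing Ki",
                              "non-positive Ki")
  }
  out <- records[!bad, , drop = FALSE]
  out$active <- out$ki_nm < cutoff_nm
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Assemble a labelled fingerprint training set
#'
#' Computes MACCS keys for actives, inactives and decoys and stacks them
#' into one [labeled_fingerprints] set. Decoys (random drug-like molecules)
#' are always labelled nonactive. Unparseable SMILES are dropped with a
#' message, never silently.
#'
#' @param actives,inactives Character vectors of SMILES.
#' @param decoys Character vector of decoy SMILES (may be empty).
#' @return A `labeled_fingerprints` object with per-row `provenance`
#'   (`active` / `inactive` / `decoy`).
#' @export
assemble_training_set <- function(actives, inactives, decoys = character(0)) {
  if (length(actives) == 0) stop("at least one active is required",
                                 call. = FALSE)
  if (length(inactives) + length(decoys) == 0) {
    stop("at least one nonactive (inactive or decoy) is required",
         call. = FALSE)
  }
  smiles <- c(actives, inactives, decoys)
  provenance <- rep(c("active", "inactive", "decoy"),
                    c(length(actives), length(inactives), length(decoys)))
  fp <- maccs_fingerprints(smiles)
  ok <- stats::complete.cases(fp)
  if (any(!ok)) {
    message(sum(!ok), " SMILES failed to parse and were dropped: ",
            paste(utils::head(smiles[!ok], 5), collapse = ", "),
            if (sum(!ok) > 5) ", ..." else "")
  }
  labeled_fingerprints(fp[ok, , drop = FALSE],
                       label = ifelse(provenance[ok] == "active", "active",
                                      "nonactive"),
                       provenance = provenance[ok])
}

# ---- MLP internals ----

mlp_init <- function(widths) {
  params <- list()
  for (i in seq_len(length(widths) - 1)) {
    params[[paste0("W", i)]] <- glorot(widths[i], widths[i + 1])
    params[[paste0("b", i)]] <- numeric(widths[i + 1])
  }
  params
}

mlp_forward <- function(params, x, n_layers) {
  acts <- list(x)
  h <- x
  for (i in seq_len(n_layers)) {
    z <- h %*% params[[paste0("W", i)]] +
      rep(params[[paste0("b", i)]], each = nrow(h))
    h <- if (i < n_layers) pmax(z, 0) else sigmoid(z)
    acts[[i + 1]] <- h
  }
  list(p = drop(h), acts = acts)
}

mlp_backward <- function(params, acts, y, n_layers) {
  n <- length(y)
  grads <- list()
  delta <- matrix((acts[[n_layers + 1]] - y) / n, ncol = 1)
  for (i in rev(seq_len(n_layers))) {
    grads[[paste0("W", i)]] <- crossprod(acts[[i]], delta)
    grads[[paste0("b", i)]] <- colSums(delta)
    if (i > 1) {
      delta <- (delta %*% t(params[[paste0("W", i)]])) * (acts[[i]] > 0)
    }
  }
  grads
}

#' Fit the MACCS MLP discriminator
#'
#' A multilayer perceptron on 166-bit MACCS fingerprints: three densely
#' connected ReLU hidden layers of 166 units each (configurable) and a
#' sigmoid output giving the active-class probability, trained with Adam on
#' binary cross-entropy. Scores are deterministic given the seed and
#' invariant to row order at prediction time.
#'
#' @param x N x 166 fingerprint matrix, or a `labeled_fingerprints` object
#'   (in which case `y` is taken from it).
#' @param y Binary labels (logical, 0/1, or factor with level `"active"`).
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed.
#' @return An object of class `maccs_mlp`.
#' @export
maccs_mlp <- function(x, y = NULL, hidden = c(166, 166, 166), epochs = 60,
                      batch_size = 64, learning_rate = 1e-3, seed = 1) {
  if (inherits(x, "labeled_fingerprints")) {
    y <- x$label == "active"
    x <- x$fingerprints
  }
  x <- as.matrix(x)
  y <- as_binary_label(y)
  stopifnot(nrow(x) == length(y), length(hidden) >= 1, epochs >= 1)
  widths <- c(ncol(x), hidden, 1)
  n_layers <- length(widths) - 1
  params <- with_seed(derive_seed(seed, "mlp-init"), mlp_init(widths))
  opt <- list(m = lapply(params, `*`, 0), v = lapply(params, `*`, 0), t = 0)
  n <- nrow(x)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "mlp-shuffle", ep), sample(n))
    ep_loss <- 0
    for (ix in split(ord, ceiling(seq_along(ord) / batch_size))) {
      fw <- mlp_forward(params, x[ix, , drop = FALSE], n_layers)
      p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - sum(y[ix] * log(p) + (1 - y[ix]) * log(1 - p))
      grads <- mlp_backward(params, fw$acts, y[ix], n_layers)
      opt$t <- opt$t + 1
      for (nm in names(params)) {
        g <- grads[[nm]]
        opt$m[[nm]] <- 0.9 * opt$m[[nm]] + 0.1 * g
        opt$v[[nm]] <- 0.999 * opt$v[[nm]] + 0.001 * g * g
        params[[nm]] <- params[[nm]] - learning_rate *
          (opt$m[[nm]] / (1 - 0.9^opt$t)) /
          (sqrt(opt$v[[nm]] / (1 - 0.999^opt$t)) + 1e-7)
      }
    }
    losses[ep] <- ep_loss / n
  }
  structure(list(params = params, hidden = hidden, n_layers = n_layers,
                 input_width = ncol(x), losses = losses,
                 config = list(epochs = epochs, batch_size = batch_size,
                               learning_rate = learning_rate, seed = seed)),
            class = "maccs_mlp")
}

as_binary_label <- function(y) {
  if (is.factor(y)) return(as.numeric(y == "active"))
  if (is.logical(y)) return(as.numeric(y))
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  y
}

#' @export
print.maccs_mlp <- function(x, ...) {
  cat("MACCS MLP discriminator: 166 ->",
      paste(x$hidden, collapse = " -> "), "-> 1 (sigmoid)\n")
  cat(sprintf("  %d epochs, final training BCE %.4f\n", length(x$losses),
              x$losses[length(x$losses)]))
  invisible(x)
}

#' Predicted activity likelihood
#'
#' Per-molecule active-class probability in [0, 1].
#'
#' @param object A fitted `maccs_mlp`.
#' @param newdata Fingerprint matrix, `labeled_fingerprints` object, or
#'   character vector of SMILES (fingerprinted on the fly; unparseable
#'   molecules score `NA`).
#' @param ... Unused.
#' @return Numeric vector of probabilities (`NA` where fingerprinting
#'   failed).
#' @export
predict.maccs_mlp <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_fingerprints")) {
    newdata <- newdata$fingerprints
  }
  if (is.character(newdata)) newdata <- maccs_fingerprints(newdata)
  x <- as.matrix(newdata)
  ok <- stats::complete.cases(x)
  out <- rep(NA_real_, nrow(x))
  if (any(ok)) {
    out[ok] <- mlp_forward(object$params, x[ok, , drop = FALSE],
                           object$n_layers)$p
  }
  out
}

#' @rdname predict.maccs_mlp
#' @param model A fitted `maccs_mlp`.
#' @param molecules As `newdata`.
#' @export
predict_likelihood <- function(model, molecules) {
  predict(model, molecules)
}

#' Decile histogram of likelihood scores
#'
#' Bins scores into ten equal-width bins over [0, 1], optionally per group
#' (e.g. per scaffold attachment position).
#'
#' @param scores Numeric scores in [0, 1] (NA dropped).
#' @param group Optional grouping vector.
#' @return A table of counts (bins x groups).
#' @export
score_histogram <- function(scores, group = NULL) {
  keep <- !is.na(scores)
  bins <- cut(scores[keep], breaks = seq(0, 1, 0.1), include.lowest = TRUE)
  if (is.null(group)) table(bins) else table(bins, group = group[keep])
}

#' Confusion-matrix classification metrics
#'
#' Standard definitions: precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, F1
#' their harmonic mean, accuracy `(tp+tn)/total`, Cohen's kappa from
#' observed vs chance agreement, and the Matthews correlation coefficient
#' from the 2x2 determinant form. A ratio with zero denominator is reported
#' as 0 and named in the `"undefined"` attribute.
#'
#' @param tp,fp,tn,fn Non-negative confusion-matrix counts (total > 0).
#' @return Named numeric vector `precision`, `recall`, `f1`, `accuracy`,
#'   `kappa`, `mcc`, with attribute `"undefined"`.
#' @export
#' @examples classification_metrics(40, 10, 45, 5)
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  stopifnot(all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty confusion table", call. = FALSE)
  undefined <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      0
    } else num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  accuracy <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- safe(accuracy - pe, 1 - pe, "kappa")
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "mcc")
  structure(c(precision = precision, recall = recall, f1 = f1,
              accuracy = accuracy, kappa = kappa, mcc = mcc),
            undefined = undefined)
}

#' ROC curve and AUC
#'
#' Computes ROC points over all distinct score thresholds and the area
#' under the curve (rank-based, equal to the Mann-Whitney statistic, with
#' ties handled by mid-ranks).
#'
#' @param scores Numeric classifier scores (higher = more active).
#' @param labels Binary labels (see [maccs_mlp()] conventions).
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_label(labels)
  stopifnot(length(scores) == length(y))
  pos <- sum(y == 1); neg <- sum(y == 0)
  if (pos == 0 || neg == 0) stop("ROC needs both classes", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(cumsum(yy), grp, max)
  fp <- tapply(cumsum(1 - yy), grp, max)
  points <- data.frame(threshold = c(Inf, s[!duplicated(s)]),
                       fpr = c(0, unname(fp) / neg),
                       tpr = c(0, unname(tp) / pos))
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - pos * (pos + 1) / 2) / (pos * neg)
  list(points = points, auc = auc)
}

#' Stratified k-fold cross-validation of the discriminator
#'
#' Splits each class into k folds (seeded), trains the MLP on k-1 folds and
#' evaluates on the held-out fold at the 0.5 probability threshold. The
#' fold assignment is a partition: every row appears in exactly one test
#' fold. Held-out scores are pooled across folds for the ROC curve. The
#' class imbalance is reported; no re-weighting or oversampling is applied.
#'
#' @param dataset A `labeled_fingerprints` object.
#' @param k Number of folds (default 6). Each class must have at least k
#'   members.
#' @param seed Integer seed (fold assignment and per-fold model seeds).
#' @param ... Passed to [maccs_mlp()] (`hidden`, `epochs`, `batch_size`,
#'   `learning_rate`).
#' @return An object of class `cv_report`: per-fold metrics, their means,
#'   pooled ROC points and AUC, fold assignment and class counts.
#' @export
cross_validate <- function(dataset, k = 6, seed = 1, ...) {
  stopifnot(inherits(dataset, "labeled_fingerprints"), k >= 2)
  y <- dataset$label == "active"
  n <- length(y)
  if (min(sum(y), sum(!y)) < k) {
    stop("each class needs at least k = ", k, " members for stratified ",
         k, "-fold CV", call. = FALSE)
  }
  fold <- integer(n)
  for (cls in c(TRUE, FALSE)) {
    ix <- which(y == cls)
    ix <- with_seed(derive_seed(seed, "fold", cls), sample(ix))
    fold[ix] <- rep(seq_len(k), length.out = length(ix))
  }
  per_fold <- vector("list", k)
  scores <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- maccs_mlp(dataset$fingerprints[!test, , drop = FALSE],
                     y[!test], seed = derive_seed(seed, "cvfit", f), ...)
    p <- predict(fit, dataset$fingerprints[test, , drop = FALSE])
    scores[test] <- p
    pred <- p >= 0.5
    m <- classification_metrics(tp = sum(pred & y[test]),
                                fp = sum(pred & !y[test]),
                                tn = sum(!pred & !y[test]),
                                fn = sum(!pred & y[test]))
    per_fold[[f]] <- data.frame(fold = f, t(m))
  }
  folds <- do.call(rbind, per_fold)
  roc <- roc_curve(scores, y)
  structure(list(folds = folds,
                 mean = colMeans(folds[, -1, drop = FALSE]),
                 roc = roc$points, auc = roc$auc, scores = scores,
                 fold = fold,
                 class_counts = c(active = sum(y), nonactive = sum(!y)),
                 k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold stratified cross-validation (%d active / %d ",
              x$k, x$class_counts[["active"]],
              x$class_counts[["nonactive"]]), "nonactive)\n", sep = "")
  cat("  mean metrics:\n")
  print(round(x$mean, 4))
  cat(sprintf("  pooled AUC: %.4f\n", x$auc))
  invisible(x)
}

#' Export a cross-validation report as JSON
#'
#' @param report A `cv_report`.
#' @param path Output file.
#' @export
write_cv_report <- function(report, path) {
  jsonlite::write_json(list(
    k = report$k, class_counts = as.list(report$class_counts),
    per_fold = report$folds, mean = as.list(report$mean),
    auc = report$auc, roc = report$roc), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}
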