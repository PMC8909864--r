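test_that("Ki labelling is strict at the cutoff and rejects bad rows", {
  rec <- data.frame(smiles = c("a", "b", "c", "d", "e"),
                    ki_nm = c(50, 100, 150, -1, NA))
  lab <- label_by_ki(rec, cutoff_nm = 100)
  expect_equal(lab$active, c(TRUE, FALSE, FALSE))  # boundary Ki is inactive
  expect_equal(sum(lab$active), 1)
  rej <- attr(lab, "rejected")
  expect_equal(nrow(rej), 2)
  expect_setequal(rej$reason, c("non-positive Ki", "missing Ki"))
})

test_that("training-set assembly labels decoys nonactive and drops junk loudly", {
  set <- suppressMessages(
    assemble_training_set(actives = c("CCO", "CCN"),
                          inactives = c("CCC", "bad(("),
                          decoys = c("c1ccccc1", "CCCC")))
  expect_s3_class(set, "labeled_fingerprints")
  expect_equal(nrow(set$fingerprints), 5)  # one inactive failed to parse
  expect_equal(sum(set$label == "active"), 2)
  expect_true(all(set$label[set$provenance == "decoy"] == "nonactive"))
  expect_message(assemble_training_set("CCO", c("CCC", "((")), "1 SMILES")

  noDecoys <- assemble_training_set("CCO", "CCC")
  expect_equal(nrow(noDecoys$fingerprints), 2)
  expect_error(assemble_training_set(character(0), "CCC"),
               "at least one active")
})

test_that("classification metrics match their closed forms", {
  m <- classification_metrics(40, 10, 45, 5)
  expect_equal(unname(m["precision"]), 0.800, tolerance = 1e-3)
  expect_equal(unname(m["recall"]), 0.8889, tolerance = 1e-3)
  expect_equal(unname(m["f1"]), 0.8421, tolerance = 1e-3)
  expect_equal(unname(m["accuracy"]), 0.850, tolerance = 1e-3)
  expect_equal(unname(m["mcc"]), 0.7035, tolerance = 1e-3)

  perfect <- classification_metrics(10, 0, 10, 0)
  expect_true(all(perfect == 1))

  # constant majority-class prediction: accuracy without agreement
  maj <- classification_metrics(tp = 90, fp = 10, tn = 0, fn = 0)
  expect_equal(unname(maj["kappa"]), 0)

  degenerate <- classification_metrics(0, 0, 5, 5)
  expect_equal(unname(degenerate["precision"]), 0)
  expect_true("precision" %in% attr(degenerate, "undefined"))
  expect_error(classification_metrics(0, 0, 0, 0), "empty")
})

test_that("metrics agree with independent formula evaluation on random tables", {
  set.seed(14)
  for (i in 1:100) {
    ct <- as.numeric(rmultinom(1, size = sample(20:200, 1), prob = runif(4)))
    tp <- ct[1]; fp <- ct[2]; tn <- ct[3]; fn <- ct[4]
    if (sum(ct) == 0) next
    m <- classification_metrics(tp, fp, tn, fn)
    n <- tp + fp + tn + fn
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    acc <- (tp + tn) / n
    pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
    kap <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
    den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(as.numeric(m), c(prec, rec, f1, acc, kap, mcc),
                 tolerance = 1e-9)
  }
})

test_that("ROC/AUC match the pROC oracle and handle ties", {
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- round(runif(150), 2)  # rounding forces ties
  labels <- rbinom(150, 1, 0.4)
  mine <- roc_curve(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", levels = c(0, 1),
                   quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(mine$points$fpr[1], 0)
  expect_equal(tail(mine$points$tpr, 1), 1)
  expect_true(all(diff(mine$points$fpr) >= 0))
  expect_error(roc_curve(scores, rep(1, 150)), "both classes")
})

test_that("cross-validation is a stratified partition with pooled ROC", {
  ds <- separable_fingerprint_dataset(60, 90, flip_rate = 0.05, seed = 5)
  cv <- cross_validate(ds, k = 6, seed = 5, epochs = 15)
  # every row sits in exactly one test fold; folds are stratified
  expect_equal(length(cv$fold), 150)
  expect_true(all(cv$fold %in% 1:6))
  expect_equal(as.vector(table(cv$fold)), rep(25, 6))
  per_fold_actives <- tapply(ds$label == "active", cv$fold, sum)
  expect_true(all(per_fold_actives == 10))
  expect_equal(nrow(cv$folds), 6)
  expect_true(all(cv$mean >= 0 & cv$mean <= 1))
  expect_error(cross_validate(ds, k = 70), "at least k")

  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv, path)
  expect_equal(jsonlite::read_json(path)$k, 6)
})

test_that("randomly permuted labels give chance-level AUC", {
  ds <- separable_fingerprint_dataset(150, 150, flip_rate = 0.05, seed = 3)
  perm <- with(list(), {set.seed(8); sample(length(ds$label))})
  ds$label <- ds$label[perm]  # break the fingerprint-label association
  cv <- cross_validate(ds, k = 6, seed = 3, epochs = 10)
  expect_equal(cv$auc, 0.5, tolerance = 0.07 / 0.5)
})

test_that("likelihood scores separate the classes and are stable", {
  ds <- separable_fingerprint_dataset(120, 120, flip_rate = 0.05, seed = 7)
  fit <- maccs_mlp(ds, epochs = 25, seed = 7)
  p <- predict(fit, ds)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p[ds$label == "active"]), mean(p[ds$label == "nonactive"]))

  # identical input rows score identically; order does not matter
  two <- predict(fit, ds$fingerprints[c(1, 1), , drop = FALSE])
  expect_equal(two[1], two[2])
  perm <- rev(seq_len(nrow(ds$fingerprints)))
  expect_equal(predict(fit, ds$fingerprints[perm, ]), p[perm])

  # SMILES input: unparseable molecules get NA, parseable get scores
  sc <- predict_likelihood(fit, c("CCO", "(bad", "CCN"))
  expect_true(is.na(sc[2]) && !anyNA(sc[c(1, 3)]))
  h <- score_histogram(p, group = ds$label)
  expect_equal(sum(h), 240)
})
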