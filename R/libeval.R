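# Generated-library quality metrics and chemical-space diagnostics.
#
# The three headline metrics form a chain of conditional fractions:
#   validity   = n_valid  / n_sampled   (parses + sanitizes)
#   uniqueness = n_unique / n_valid     (distinct canonical structures)
#   novelty    = n_novel  / n_unique    (max MACCS/Tanimoto similarity to
#                                        the reference set < threshold)
# so n_novel <= n_unique <= n_valid <= n_sampled always holds.

#' Validity of a generated set
#'
#' A string is valid iff it can be conveyed back to a molecular structure
#' (parse + sanitize). Strings flagged as non-terminated (generation hit the
#' length cap without the end sentinel) count as sampled and invalid.
#'
#' @param strings Character vector of sampled SMILES.
#' @param terminated Optional logical vector; `FALSE` entries are counted
#'   invalid without parsing.
#' @return List with `n_valid`, `validity` and the logical vector `valid`.
#' @export
compute_validity <- function(strings, terminated = NULL) {
  if (length(strings) == 0) stop("empty input", call. = FALSE)
  valid <- is_valid_smiles(strings)
  if (!is.null(terminated)) {
    stopifnot(length(terminated) == length(strings))
    valid <- valid & terminated
  }
  list(n_valid = sum(valid), validity = mean(valid), valid = valid)
}

#' Uniqueness of a valid set
#'
#' Deduplicates by canonical structure by default (`"CCO"` and `"OCC"` are
#' one molecule); `dedup = "string"` compares raw strings instead.
#'
#' @param valid_strings Character vector of valid SMILES.
#' @param dedup `"structure"` (canonical SMILES) or `"string"`.
#' @return List with `n_unique`, `uniqueness` (= n_unique / n_valid) and
#'   `unique_smiles` (canonical spellings under structure dedup).
#' @export
compute_uniqueness <- function(valid_strings,
                               dedup = c("structure", "string")) {
  dedup <- match.arg(dedup)
  if (length(valid_strings) == 0) {
    return(list(n_unique = 0L, uniqueness = NaN, unique_smiles = character(0)))
  }
  keys <- if (dedup == "structure") {
    canonical_smiles(valid_strings)
  } else {
    valid_strings
  }
  if (anyNA(keys)) stop("compute_uniqueness expects valid SMILES only",
                        call. = FALSE)
  uni <- unique(keys)
  list(n_unique = length(uni), uniqueness = length(uni) / length(keys),
       unique_smiles = uni)
}

#' Novelty of a unique set against a reference collection
#'
#' A molecule is novel iff its maximum Tanimoto similarity over the
#' reference (training) set, computed on 166-bit MACCS keys, is strictly
#' below `threshold` (default 0.85). A molecule literally present in the
#' reference has similarity 1 and is never novel; with `threshold = 1` only
#' exact fingerprint matches are non-novel.
#'
#' @param unique_smiles Character vector of unique valid SMILES.
#' @param reference_smiles Reference SMILES collection. An empty reference
#'   marks every molecule novel, with a warning.
#' @param threshold Similarity threshold in (0, 1], strict less-than.
#' @return List with `n_novel`, `novelty` (= n_novel / n_unique), `novel`
#'   (logical) and `max_similarity` (per molecule).
#' @export
compute_novelty <- function(unique_smiles, reference_smiles,
                            threshold = 0.85) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(unique_smiles) == 0) stop("empty unique set", call. = FALSE)
  if (length(reference_smiles) == 0) {
    warning("empty reference set: all molecules counted novel",
            call. = FALSE)
    return(list(n_novel = length(unique_smiles), novelty = 1,
                novel = rep(TRUE, length(unique_smiles)),
                max_similarity = rep(0, length(unique_smiles))))
  }
  qf <- maccs_fingerprints(unique_smiles)
  rf <- maccs_fingerprints(reference_smiles)
  rf <- rf[stats::complete.cases(rf), , drop = FALSE]
  sim <- tanimoto_max(qf, rf)
  novel <- sim < threshold
  novel[is.na(novel)] <- FALSE
  list(n_novel = sum(novel), novelty = mean(novel), novel = novel,
       max_similarity = sim)
}

# row-wise maximum Tanimoto similarity of query fingerprints against a
# reference fingerprint matrix, via bit-count algebra:
#   T(a,b) = |a & b| / (|a| + |b| - |a & b|)
tanimoto_max <- function(query, reference) {
  if (nrow(reference) == 0) return(rep(0, nrow(query)))
  q <- query; q[is.na(q)] <- 0L
  inter <- q %*% t(reference)                       # n_q x n_r
  qs <- rowSums(q)
  rs <- rowSums(reference)
  union <- outer(qs, rs, `+`) - inter
  sim <- ifelse(union == 0, 1, inter / union)       # two empty fps: identical
  out <- unname(apply(sim, 1, max))
  out[!stats::complete.cases(query)] <- NA_real_
  out
}

#' Score a generated library
#'
#' One-call evaluation of a sampled set: validity, uniqueness and (when a
#' reference collection is given) novelty, with the conservation chain
#' `n_novel <= n_unique <= n_valid <= n_sampled`. Metrics are invariant to
#' input order.
#'
#' @param sampled Character vector of sampled strings, or a sample table
#'   from [run_campaign()] (its `terminated` flags are used).
#' @param reference Optional reference/training SMILES for novelty.
#' @param threshold MACCS/Tanimoto novelty threshold (strict less-than).
#' @param dedup Uniqueness mode, see [compute_uniqueness()].
#' @param terminated Optional logical vector matching `sampled`.
#' @return An object of class `library_metrics`: counts, the three
#'   fractions, and the similarity configuration metadata.
#' @export
library_metrics <- function(sampled, reference = NULL, threshold = 0.85,
                            dedup = c("structure", "string"),
                            terminated = NULL) {
  dedup <- match.arg(dedup)
  if (is.data.frame(sampled)) {
    terminated <- sampled$terminated
    sampled <- sampled$smiles
  }
  v <- compute_validity(sampled, terminated = terminated)
  u <- compute_uniqueness(sampled[v$valid], dedup = dedup)
  nv <- if (!is.null(reference) && u$n_unique > 0) {
    compute_novelty(u$unique_smiles, reference, threshold = threshold)
  }
  structure(list(
    n_sampled = length(sampled), n_valid = v$n_valid,
    n_unique = u$n_unique, n_novel = if (is.null(nv)) NA_integer_ else
      nv$n_novel,
    validity = v$validity, uniqueness = u$uniqueness,
    novelty = if (is.null(nv)) NA_real_ else nv$novelty,
    unique_smiles = u$unique_smiles,
    config = list(fingerprint = "MACCS-166", coefficient = "Tanimoto",
                  threshold = threshold, dedup = dedup)),
    class = "library_metrics")
}

#' @export
print.library_metrics <- function(x, ...) {
  cat("Library metrics (", x$n_sampled, " sampled)\n", sep = "")
  cat(sprintf("  validity   %d/%d = %.3f\n", x$n_valid, x$n_sampled,
              x$validity))
  cat(sprintf("  uniqueness %d/%d = %.3f\n", x$n_unique, x$n_valid,
              x$uniqueness))
  if (!is.na(x$novelty)) {
    cat(sprintf("  novelty    %d/%d = %.3f  (%s/%s < %.2f)\n", x$n_novel,
                x$n_unique, x$novelty, x$config$fingerprint,
                x$config$coefficient, x$config$threshold))
  }
  invisible(x)
}

#' Physico-chemical descriptors, SA and QED
#'
#' Computes molecular weight (g/mol), topological polar surface area
#' (Ertl TPSA, A^2), molar refractivity and octanol-water partition estimate
#' (Crippen SMR / SlogP), the Ertl-Schuffenhauer synthetic-accessibility
#' score (about 1 = easy to 10 = hard, fragment contributions plus a
#' complexity penalty) and the QED drug-likeness desirability product (0-1),
#' all via their standard published implementations. Molecules on which a
#' descriptor fails are flagged (`ok = FALSE`), not dropped.
#'
#' @param smiles Character vector of SMILES.
#' @return Data frame with columns `smiles`, `MW`, `TPSA`, `SMR`, `SlogP`,
#'   `SA`, `QED`, `ok`.
#' @export
mol_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  out <- chem_helper("desc", input = smiles)
  if (length(out) != length(smiles)) {
    out <- c(out, rep(paste(rep("NA", 6), collapse = "\t"),
                      length(smiles) - length(out)))
  }
  vals <- do.call(rbind, lapply(strsplit(out, "\t", fixed = TRUE),
                                function(p) suppressWarnings(as.numeric(p))))
  colnames(vals) <- c("MW", "TPSA", "SMR", "SlogP", "SA", "QED")
  df <- data.frame(smiles = smiles, vals, ok = stats::complete.cases(vals),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Column summary of a descriptor table
#'
#' @param descriptors Output of [mol_descriptors()].
#' @return Data frame of per-descriptor mean and SD over rows with `ok =
#'   TRUE`.
#' @export
descriptor_summary <- function(descriptors) {
  cols <- c("MW", "TPSA", "SMR", "SlogP", "SA", "QED")
  d <- descriptors[descriptors$ok, cols, drop = FALSE]
  data.frame(descriptor = cols,
             mean = vapply(d, mean, numeric(1)),
             sd = vapply(d, stats::sd, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 2-D chemical-space embedding (t-SNE)
#'
#' Standardizes a numeric feature table (zero mean, unit variance per
#' column; constant columns are left centred) and embeds it into two
#' dimensions with t-distributed stochastic neighbour embedding. The exact
#' method is used, so a fixed seed gives identical coordinates across runs.
#'
#' @param features Numeric matrix or data frame (rows = molecules); all
#'   values must be finite.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity; must be below `nrow(features)`.
#' @param group Optional vector of group labels (e.g. training vs generated,
#'   or per-scaffold colours) attached to the result for plotting.
#' @return N x 2 numeric matrix (columns `tsne1`, `tsne2`), with the `group`
#'   attribute when supplied.
#' @export
embed_2d <- function(features, seed = 1, perplexity = 30, group = NULL) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (nrow(x) < 5) stop("need at least 5 rows to embed", call. = FALSE)
  bad <- which(!stats::complete.cases(x) | !apply(is.finite(x), 1, all))
  if (length(bad) > 0) {
    stop("non-finite feature rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  perplexity <- min(perplexity, (nrow(x) - 1) / 3)
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  lines <- apply(x, 1, function(r) paste(sprintf("%.10g", r),
                                         collapse = "\t"))
  out <- chem_helper("tsne", input = lines,
                     args = c("--seed", as.integer(seed),
                              "--perplexity", format(perplexity)))
  coords <- do.call(rbind, lapply(strsplit(out, "\t", fixed = TRUE),
                                  as.numeric))
  colnames(coords) <- c("tsne1", "tsne2")
  if (!is.null(group)) attr(coords, "group") <- group
  coords
}
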