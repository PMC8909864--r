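# Autoregressive sampling with temperature, scaffold-prefix seeding, and
# campaign orchestration across checkpoints x temperatures x sites.

#' Reshape a categorical distribution by sampling temperature
#'
#' Applies `q_i = p_i^(1/T) / sum_j p_j^(1/T)` (equivalently logits divided
#' by T before the softmax). `T = 1` is the identity; `T < 1` sharpens the
#' distribution towards its mode (more conservative next-character choices),
#' `T > 1` flattens it (more diversified choices). The transform is
#' monotone: it never reorders probabilities.
#'
#' @param p Non-negative probability vector summing to 1 (tolerance 1e-9).
#' @param temperature Positive temperature T.
#' @return Reshaped probability vector of the same length.
#' @export
#' @examples apply_temperature(c(0.5, 0.3, 0.2), 0.5)
apply_temperature <- function(p, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      temperature <= 0) {
    stop("temperature must be a single positive number", call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("p must be a probability vector summing to 1", call. = FALSE)
  }
  if (all(p == 0)) stop("all-zero probability vector", call. = FALSE)
  if (temperature == 1) return(p)
  # work in log space for numerical stability at small T
  lp <- ifelse(p > 0, log(p), -Inf) / temperature
  lp <- lp - max(lp)
  q <- exp(lp)
  q / sum(q)
}

#' Sample SMILES strings from a fitted model
#'
#' Draws `n` strings autoregressively: starting from the begin sentinel plus
#' the (possibly empty) `prefix`, the next character is sampled from the
#' temperature-reshaped predictive distribution until the end sentinel is
#' produced or `max_len` characters are reached. All chains run batched, so
#' sampling thousands of strings is vectorized.
#'
#' Returned strings always start with the prefix verbatim (this is how a
#' rooted scaffold spelling pins generation to an attachment position);
#' sentinels are stripped. Strings that hit `max_len` without producing the
#' end sentinel are flagged via the `"terminated"` attribute and should be
#' counted as invalid downstream.
#'
#' @param model A fitted `smiles_lm`.
#' @param n Number of samples.
#' @param temperature Sampling temperature (> 0).
#' @param prefix Prefix string, e.g. a rooted scaffold spelling from
#'   [rooted_smiles()]. Every character must be in the vocabulary.
#' @param max_len Maximum generated length in characters, prefix included
#'   (must exceed `nchar(prefix) + 2`).
#' @param seed Optional integer seed; when given, results are reproducible
#'   and the caller's RNG state is untouched.
#' @return Character vector of length `n` with logical attribute
#'   `"terminated"` (TRUE where the end sentinel was produced).
#' @export
sample_smiles <- function(model, n = 1, temperature = 1, prefix = "",
                          max_len = 140, seed = NULL) {
  stopifnot(inherits(model, "smiles_lm"), n >= 1, max_len > nchar(prefix) + 2)
  if (!is.null(seed)) {
    return(with_seed(seed, sample_smiles(model, n = n,
                                         temperature = temperature,
                                         prefix = prefix, max_len = max_len)))
  }
  vocab <- model$vocab
  V <- length(vocab)
  i_end <- vocab$index[[SENTINEL_END]]
  i_begin <- vocab$index[[SENTINEL_BEGIN]]
  prefix_idx <- smiles_to_indices(prefix, vocab)
  prefix_idx <- prefix_idx[-length(prefix_idx)]  # G + prefix chars

  # run the shared prefix once, then replicate the state across chains
  state <- lstm_zero_state(1, model$units)
  for (t in prefix_idx) {
    st <- lstm_step(model$params, t, state, model$units)
    state <- st$state
  }
  state <- lapply(state, function(m) m[rep(1, n), , drop = FALSE])
  p <- st$p[rep(1, n), , drop = FALSE]

  lower_tri <- upper.tri(matrix(0, V, V), diag = TRUE)
  gen <- matrix(NA_integer_, n, max_len)
  active <- rep(TRUE, n)
  terminated <- rep(FALSE, n)
  budget <- max_len - nchar(prefix)
  for (step in seq_len(budget)) {
    na <- sum(active)
    if (na == 0) break
    # the begin sentinel is an input-only token and is never sampled
    p[, i_begin] <- 0
    p <- p / rowSums(p)
    q <- t(apply(p, 1, apply_temperature, temperature = temperature))
    cs <- q %*% lower_tri            # row-wise cumulative sums
    r <- stats::runif(na)
    nxt <- 1L + as.integer(rowSums(cs < r))
    nxt <- pmin(nxt, V)
    rows <- which(active)
    gen[cbind(rows, step)] <- nxt
    done <- nxt == i_end
    terminated[rows[done]] <- TRUE
    active[rows[done]] <- FALSE
    keep <- !done
    if (!any(keep)) break
    live <- rows[keep]
    sub <- lapply(state, function(m) m[live, , drop = FALSE])
    st <- lstm_step(model$params, nxt[keep], sub, model$units)
    # write the advanced state back into the full-state rows still active
    for (nm in names(state)) state[[nm]][live, ] <- st$state[[nm]]
    p <- st$p
  }
  out <- vapply(seq_len(n), function(b) {
    idx <- gen[b, ]
    idx <- idx[!is.na(idx)]
    paste0(prefix, decode_indices(c(vocab$index[[SENTINEL_BEGIN]], idx),
                                  vocab))
  }, character(1))
  attr(out, "terminated") <- terminated
  out
}

#' Simulate method: draw SMILES samples
#'
#' `simulate()` on a fitted `smiles_lm` is an alias for [sample_smiles()].
#'
#' @param object A fitted `smiles_lm`.
#' @param nsim Number of strings to draw.
#' @param seed Optional integer seed.
#' @param ... Passed to [sample_smiles()] (`temperature`, `prefix`,
#'   `max_len`).
#' @return Character vector with attribute `"terminated"`.
#' @export
simulate.smiles_lm <- function(object, nsim = 1, seed = NULL, ...) {
  sample_smiles(object, n = nsim, seed = seed, ...)
}

#' Lay out a sampling campaign
#'
#' Builds the full factorial plan over training checkpoints, sampling
#' temperatures and attachment sites, with `n_samples` draws per cell. The
#' planned table size (`sum(plan$n_samples)`, or `nrow()` after
#' `expand = TRUE`) is exactly
#' `|checkpoints| * |temperatures| * |sites| * n_samples`; the study-scale
#' plan 4 x 4 x 7 x 2000 gives 224,000 rows.
#'
#' @param checkpoints Checkpoint identifiers (e.g. epoch numbers).
#' @param temperatures Sampling temperatures.
#' @param sites Attachment-site identifiers.
#' @param n_samples Draws per cell.
#' @param expand If `TRUE`, return one row per planned sample rather than
#'   one row per cell.
#' @return Data frame; per-cell with an `n_samples` column (default) or
#'   fully expanded.
#' @export
#' @examples
#' plan <- campaign_plan(c(10, 20, 40, 100), c(0.5, 1, 1.2, 1.5), 1:7, 2000)
#' sum(plan$n_samples)  # 224000
campaign_plan <- function(checkpoints, temperatures, sites, n_samples,
                          expand = FALSE) {
  stopifnot(length(checkpoints) >= 1, length(temperatures) >= 1,
            length(sites) >= 1, n_samples >= 1)
  plan <- expand.grid(checkpoint = checkpoints, temperature = temperatures,
                      site = sites, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (!expand) {
    plan$n_samples <- n_samples
    return(plan)
  }
  plan[rep(seq_len(nrow(plan)), each = n_samples), , drop = FALSE]
}

#' Run a sampling campaign
#'
#' Samples every cell of the checkpoints x temperatures x sites grid. Each
#' cell draws `n_samples` strings with a sub-seed derived deterministically
#' from `(seed, checkpoint, temperature, site)`, so any cell can be
#' regenerated independently and identical seeds give identical tables.
#'
#' @param models Named list of fitted `smiles_lm` objects (names are the
#'   checkpoint ids), or a checkpoint directory path combined with numeric
#'   `checkpoints`.
#' @param rooted A data frame from [rooted_library()] (columns `atom_index`,
#'   `smiles`), or a named character vector of rooted prefixes.
#' @param temperatures Vector of sampling temperatures.
#' @param n_samples Draws per cell.
#' @param seed Campaign master seed.
#' @param checkpoints Epoch numbers, required when `models` is a checkpoint
#'   directory.
#' @param max_len Maximum string length per draw.
#' @return A sample table: data frame with columns `checkpoint`,
#'   `temperature`, `site`, `smiles`, `terminated`; row count is exactly
#'   `|models| * |temperatures| * |sites| * n_samples`.
#' @export
run_campaign <- function(models, rooted, temperatures, n_samples, seed = 1,
                         checkpoints = NULL, max_len = 140) {
  if (is.character(models) && length(models) == 1) {
    if (is.null(checkpoints)) {
      stop("supply `checkpoints` when `models` is a checkpoint directory",
           call. = FALSE)
    }
    dir <- models
    models <- stats::setNames(lapply(checkpoints, function(ep)
      load_checkpoint(dir, ep)), as.character(checkpoints))
  }
  if (inherits(models, "smiles_lm")) models <- list(model = models)
  stopifnot(is.list(models), length(models) >= 1)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- as.character(seq_along(models))
  }
  if (is.data.frame(rooted)) {
    prefixes <- stats::setNames(rooted$smiles, rooted$atom_index)
  } else {
    prefixes <- rooted
    if (is.null(names(prefixes))) {
      names(prefixes) <- as.character(seq_along(prefixes))
    }
  }
  if (anyNA(prefixes)) {
    stop("rooted library contains unverified (NA) spellings", call. = FALSE)
  }
  cells <- expand.grid(checkpoint = names(models),
                       temperature = temperatures,
                       site = names(prefixes), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    ck <- cells$checkpoint[i]; tt <- cells$temperature[i]
    si <- cells$site[i]
    draws <- sample_smiles(models[[ck]], n = n_samples, temperature = tt,
                           prefix = unname(prefixes[[si]]), max_len = max_len,
                           seed = derive_seed(seed, ck, tt, si))
    out[[i]] <- data.frame(checkpoint = ck, temperature = tt, site = si,
                           smiles = as.character(draws),
                           terminated = attr(draws, "terminated"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
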