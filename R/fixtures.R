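# Seeded synthetic-data generators.
#
# Corpus molecules are assembled from valid-by-construction grammar rules
# (single-bonded chains, one optional branch, one optional ring closure)
# rather than rejection sampling, so validity is 1.0 by construction and
# generation is fast. These emulate the *format and learnability* of a real
# training collection, not its property distributions.

#' Generate a toy SMILES corpus
#'
#' Draws `n` small acyclic or monocyclic molecules over a reduced element
#' alphabet. Every emitted string parses and sanitizes (validity 1.0 by
#' construction); duplicates are allowed, as in real corpora.
#'
#' @param n Number of molecules.
#' @param seed Integer seed; the corpus is bit-reproducible from it.
#' @param min_heavy_atoms,max_heavy_atoms Heavy-atom count range per
#'   molecule (chain length, or ring plus tail). Fragment-to-lead-sized
#'   molecules (6-14 heavy atoms) keep the valid chemical space large
#'   relative to typical sampling depths.
#' @param alphabet Element symbols to draw from (single-character; default C,
#'   N, O).
#' @param alphabet_weights Draw probabilities per element. The carbon-heavy
#'   default mirrors the elemental composition of organic drug-like
#'   molecules; a skewed character distribution is also what gives sampling
#'   temperature its leverage (temperature reshaping is a no-op on a uniform
#'   distribution).
#' @param ring_fraction Probability that a molecule is built around a 5- or
#'   6-membered ring (closure digit 1 or 2, both in common use).
#' @param branch_fraction Probability that a chain molecule carries one
#'   single-atom branch, or (equally often) one C=C double bond, so the
#'   corpus covers the branch, ring-closure and bond-order characters of
#'   typical drug-like SMILES.
#' @return Character vector of `n` SMILES strings.
#' @export
#' @examples \dontrun{toy_smiles_corpus(5, seed = 1)}
toy_smiles_corpus <- function(n, seed = 1, min_heavy_atoms = 6,
                              max_heavy_atoms = 14,
                              alphabet = c("C", "N", "O"),
                              alphabet_weights = c(0.7, 0.15, 0.15),
                              ring_fraction = 0.3, branch_fraction = 0.3) {
  stopifnot(n >= 1, max_heavy_atoms >= min_heavy_atoms, min_heavy_atoms >= 2,
            ring_fraction >= 0, ring_fraction <= 1,
            branch_fraction >= 0, branch_fraction <= 1,
            all(nchar(alphabet) == 1),
            length(alphabet_weights) == length(alphabet),
            all(alphabet_weights > 0))
  if (any(alphabet %in% c("G", "E"))) {
    stop("alphabet collides with sentinel characters", call. = FALSE)
  }
  with_seed(seed, vapply(seq_len(n), function(i) {
    one_toy_smiles(min_heavy_atoms, max_heavy_atoms, alphabet,
                   alphabet_weights, ring_fraction, branch_fraction)
  }, character(1)))
}

# one molecule under the current RNG state
one_toy_smiles <- function(min_heavy_atoms, max_heavy_atoms, alphabet,
                           weights, ring_fraction, branch_fraction) {
  draw <- function(k) sample(alphabet, k, replace = TRUE, prob = weights)
  size_target <- sample(min_heavy_atoms:max_heavy_atoms, 1)
  if (stats::runif(1) < ring_fraction && size_target >= 5) {
    size <- sample(5:min(6, size_target), 1)
    digit <- sample(c("1", "2"), 1)
    # first and last ring atoms are carbons so the closure and any appended
    # tail never exceed valence; interior atoms are free
    interior <- draw(size - 2)
    s <- paste0("C", digit, paste(interior, collapse = ""), "C", digit)
    tail_len <- size_target - size
    if (tail_len > 0) {
      s <- paste0(s, paste(draw(tail_len), collapse = ""))
    }
    s
  } else {
    atoms <- draw(size_target)
    s <- paste(atoms, collapse = "")
    if (size_target >= 4 && stats::runif(1) < branch_fraction) {
      if (stats::runif(1) < 0.5) {
        # branch hangs off an interior C or N (O would exceed valence 2)
        pos <- which(atoms[2:(size_target - 1)] %in% c("C", "N")) + 1L
        if (length(pos) > 0) {
          at <- if (length(pos) == 1) pos else sample(pos, 1)
          br <- draw(1)
          s <- paste0(substr(s, 1, at), "(", br, ")",
                      substr(s, at + 1, nchar(s)))
        }
      } else {
        # one C=C double bond between adjacent chain carbons
        pos <- which(atoms[-size_target] == "C" & atoms[-1] == "C")
        if (length(pos) > 0) {
          at <- if (length(pos) == 1) pos else sample(pos, 1)
          s <- paste0(substr(s, 1, at), "=", substr(s, at + 1, nchar(s)))
        }
      }
    }
    s
  }
}

#' Generate a motif-enriched target corpus
#'
#' Emulates a small target-specific ligand collection in which a privileged
#' scaffold recurs: a requested fraction of molecules contain `motif_smiles`
#' as a substructure. Motif-bearing molecules are built by appending a short
#' substituent chain to an append-ready (rooted) spelling of the motif, so
#' they are valid by construction; the remainder come from
#' [toy_smiles_corpus()].
#'
#' @inheritParams toy_smiles_corpus
#' @param motif_smiles A rooted spelling of the motif: appending atom
#'   characters to it must grow a substituent (e.g. the indole spelling
#'   `"C12=C(C=CC=C2)NC=C1"`, which extends at ring position 3; see
#'   [rooted_smiles()]).
#' @param enrichment Fraction of the corpus required to contain the motif,
#'   in (0, 1].
#' @param max_tail Maximum length of the appended substituent chain.
#' @return Character vector of `n` SMILES strings (motif-bearing entries
#'   first).
#' @export
motif_enriched_corpus <- function(n, seed = 1,
                                  motif_smiles = "C12=C(C=CC=C2)NC=C1",
                                  enrichment = 0.8, max_tail = 4,
                                  alphabet = c("C", "N", "O"),
                                  max_heavy_atoms = 9) {
  stopifnot(n >= 1, enrichment > 0, enrichment <= 1, max_tail >= 1)
  if (!is_valid_smiles(motif_smiles) ||
      !is_valid_smiles(paste0(motif_smiles, "C"))) {
    stop("motif_smiles must be a valid, append-ready (rooted) SMILES ",
         "spelling", call. = FALSE)
  }
  n_motif <- ceiling(enrichment * n)
  with_motif <- with_seed(derive_seed(seed, "motif"),
    vapply(seq_len(n_motif), function(i) {
      tail_len <- sample(seq_len(max_tail), 1)
      atoms <- sample(alphabet, tail_len, replace = TRUE)
      # keep interior-chain valence safe: O only as the terminal atom
      if (tail_len > 1) {
        atoms[-tail_len][atoms[-tail_len] == "O"] <- "C"
      }
      paste0(motif_smiles, paste(atoms, collapse = ""))
    }, character(1)))
  rest <- if (n_motif < n) {
    toy_smiles_corpus(n - n_motif, seed = derive_seed(seed, "base"),
                      max_heavy_atoms = max_heavy_atoms, alphabet = alphabet)
  } else character(0)
  c(with_motif, rest)
}

#' Generate a separable labelled fingerprint dataset
#'
#' Builds a two-class 166-bit dataset for discriminator testing: each class
#' has a fixed bit template (maximally separated) and every row is its class
#' template with independent bit flips at `flip_rate`.
#'
#' @param n_active,n_nonactive Rows per class.
#' @param flip_rate Per-bit flip probability, in [0, 0.5).
#' @param seed Integer seed.
#' @return A `labeled_fingerprints` object: list with `fingerprints`
#'   (N x 166 integer matrix), `label` (factor active/nonactive) and
#'   `provenance` (character).
#' @export
separable_fingerprint_dataset <- function(n_active, n_nonactive,
                                          flip_rate = 0.05, seed = 1) {
  stopifnot(n_active >= 1, n_nonactive >= 1)
  if (flip_rate < 0 || flip_rate >= 0.5) {
    stop("flip_rate must be in [0, 0.5): at 0.5 the classes are not ",
         "separable", call. = FALSE)
  }
  t_active <- rep(c(1L, 0L), length.out = 166)
  t_nonactive <- rep(c(0L, 1L), length.out = 166)
  n <- n_active + n_nonactive
  fp <- with_seed(seed, {
    base <- rbind(matrix(t_active, n_active, 166, byrow = TRUE),
                  matrix(t_nonactive, n_nonactive, 166, byrow = TRUE))
    flips <- matrix(stats::runif(n * 166) < flip_rate, n, 166)
    ifelse(flips, 1L - base, base)
  })
  labeled_fingerprints(fp,
                       label = rep(c("active", "nonactive"),
                                   c(n_active, n_nonactive)),
                       provenance = rep(c("active", "inactive"),
                                        c(n_active, n_nonactive)))
}

# constructor shared with discriminator::assemble_training_set
labeled_fingerprints <- function(fingerprints, label, provenance) {
  stopifnot(ncol(fingerprints) == 166,
            nrow(fingerprints) == length(label),
            length(label) == length(provenance))
  label <- factor(label, levels = c("nonactive", "active"))
  if (any(label == "active" & provenance == "decoy")) {
    stop("decoys can never carry the active label", call. = FALSE)
  }
  structure(list(fingerprints = fingerprints, label = label,
                 provenance = provenance),
            class = "labeled_fingerprints")
}

#' @export
print.labeled_fingerprints <- function(x, ...) {
  cat("Labelled MACCS fingerprint set:", nrow(x$fingerprints), "rows\n")
  print(table(label = x$label, provenance = x$provenance))
  invisible(x)
}
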