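# SMILES character vocabulary and one-hot codec.
#
# Tokenization is raw single characters ("Cl" is 'C','l'; "Br" is 'B','r').
# Two sentinel tokens frame every sequence: 'G' (begin) and 'E' (end); both
# are counted in the vocabulary size V.

SENTINEL_BEGIN <- "G"
SENTINEL_END <- "E"

#' Build a SMILES character vocabulary
#'
#' Collects the set of characters occurring in a corpus, orders it
#' deterministically (lexicographic by byte, locale-independent) and appends
#' the begin/end sentinels `'G'` and `'E'` last. Token indices are the
#' 1-based positions in this ordering.
#'
#' @param corpus Character vector of SMILES strings (non-empty, each string
#'   non-empty).
#' @return An object of class `smiles_vocabulary`: a list with `tokens`
#'   (ordered character vector, sentinels last) and `index` (named integer
#'   map token -> position).
#' @export
#' @examples \dontrun{smiles_vocabulary(c("CO", "CN"))  # tokens C,N,O,G,E}
smiles_vocabulary <- function(corpus) {
  if (!is.character(corpus) || length(corpus) == 0) {
    stop("corpus must be a non-empty character vector", call. = FALSE)
  }
  if (any(!nzchar(corpus)) || anyNA(corpus)) {
    stop("corpus contains empty or missing strings", call. = FALSE)
  }
  chars <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE))),
                method = "radix")
  clash <- intersect(chars, c(SENTINEL_BEGIN, SENTINEL_END))
  if (length(clash) > 0) {
    stop("corpus uses reserved sentinel character(s): ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  tokens <- c(chars, SENTINEL_BEGIN, SENTINEL_END)
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "smiles_vocabulary")
}

#' @export
length.smiles_vocabulary <- function(x) length(x$tokens)

#' @export
print.smiles_vocabulary <- function(x, ...) {
  cat("SMILES vocabulary:", length(x$tokens), "tokens (incl. sentinels)\n")
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

# 1-based token index sequence G, chars(smiles), E; errors name the first
# unknown character and its position
smiles_to_indices <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  idx <- vocab$index[chars]
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("character '", chars[bad], "' at position ", bad,
         " is not in the vocabulary", call. = FALSE)
  }
  unname(c(vocab$index[[SENTINEL_BEGIN]], idx, vocab$index[[SENTINEL_END]]))
}

#' One-hot encode a SMILES string
#'
#' Produces the L x V binary matrix for the framed sequence
#' `G, s[1], ..., s[n], E` with `L = nchar(s) + 2`; every row has exactly one
#' 1 at the token's vocabulary index.
#'
#' @param smiles A single SMILES string.
#' @param vocab A [smiles_vocabulary()].
#' @return An object of class `encoded_smiles`: list with `matrix` (L x V,
#'   0/1, columns named by token) and `source` (the input string).
#' @export
encode_smiles <- function(smiles, vocab) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  idx <- smiles_to_indices(smiles, vocab)
  m <- matrix(0L, nrow = length(idx), ncol = length(vocab$tokens),
              dimnames = list(NULL, vocab$tokens))
  m[cbind(seq_along(idx), idx)] <- 1L
  structure(list(matrix = m, source = smiles), class = "encoded_smiles")
}

#' Decode a token index sequence to a SMILES string
#'
#' Strips the begin sentinel and truncates at the first end sentinel
#' (everything after a generated `'E'` is discarded, matching the sampling
#' contract).
#'
#' @param indices Integer vector of 1-based token indices, or an
#'   `encoded_smiles` object.
#' @param vocab A [smiles_vocabulary()].
#' @return The decoded SMILES string.
#' @export
decode_indices <- function(indices, vocab) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  if (inherits(indices, "encoded_smiles")) {
    indices <- max.col(indices$matrix, ties.method = "first")
  }
  indices <- as.integer(indices)
  if (any(indices < 1L | indices > length(vocab$tokens))) {
    stop("token index out of range 1..", length(vocab$tokens), call. = FALSE)
  }
  toks <- vocab$tokens[indices]
  e <- match(SENTINEL_END, toks)
  if (!is.na(e)) toks <- toks[seq_len(e - 1L)]
  paste(toks[toks != SENTINEL_BEGIN], collapse = "")
}

#' Read a .smi file
#'
#' One SMILES per line, optionally followed by a tab and an identifier;
#' lines starting with `#` and blank lines are skipped.
#'
#' @param path File path.
#' @return Character vector of SMILES; identifiers (when present) as names.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "",
                character(1))
  if (any(nzchar(ids))) names(smi) <- ids
  smi
}

#' Write a .smi file
#'
#' @param smiles Character vector (names, if set, are written as tab-separated
#'   identifiers).
#' @param path File path.
#' @export
write_smiles_file <- function(smiles, path) {
  out <- if (!is.null(names(smiles)) && any(nzchar(names(smiles)))) {
    paste(smiles, names(smiles), sep = "\t")
  } else {
    as.character(smiles)
  }
  writeLines(out, path)
  invisible(path)
}

#' Save / load a vocabulary as JSON
#'
#' The JSON stores the ordered token list; indices are implied by position.
#'
#' @param vocab A [smiles_vocabulary()].
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "smiles_vocabulary"))
  jsonlite::write_json(list(tokens = vocab$tokens), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- as.character(jsonlite::read_json(path, simplifyVector = TRUE)$tokens)
  if (sum(tokens == SENTINEL_BEGIN) != 1 || sum(tokens == SENTINEL_END) != 1) {
    stop("vocabulary file must contain each sentinel exactly once",
         call. = FALSE)
  }
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens)),
            class = "smiles_vocabulary")
}
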