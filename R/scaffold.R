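# Scaffold attachment enumeration and rooted SMILES spellings.
#
# A "rooted" spelling of a scaffold is a SMILES string arranged so that a
# character appended to it bonds to one chosen attachment atom: feeding the
# string to the generator as a sampling prefix therefore grows a substituent
# at exactly that position. One molecule admits many spellings (different
# starting atoms and directions); the backend searches canonical, random and
# branch-wrapped traversals and keeps only spellings that pass verification.
# Correctness is defined by the methyl-append test, not by the construction:
# the spelling must parse back to the scaffold itself, and the spelling with
# "C" appended must parse to the scaffold carrying one methyl at the
# designated atom (compared on canonical SMILES against an independent
# graph-edit construction).

#' Enumerate attachment sites on a scaffold
#'
#' Returns one site per heavy atom bearing at least one hydrogen, in atom
#' order, with no symmetry reduction (the indole spelling
#' `"C12=C(C=CC=C2)NC=C1"` yields 7 positions; benzene yields 6 equivalent
#' ones).
#'
#' @param scaffold_smiles Scaffold SMILES string.
#' @return Data frame with columns `atom_index` (0-based heavy-atom index in
#'   the parsed scaffold), `element`, `available_h`.
#' @export
#' @examples \dontrun{enumerate_attachment_sites("C12=C(C=CC=C2)NC=C1")}
enumerate_attachment_sites <- function(scaffold_smiles) {
  stopifnot(is.character(scaffold_smiles), length(scaffold_smiles) == 1)
  out <- tryCatch(
    chem_helper("sites", args = c("--query", shQuote(scaffold_smiles))),
    error = function(e) stop("scaffold SMILES does not parse: ",
                             scaffold_smiles, call. = FALSE))
  parts <- strsplit(out, "\t", fixed = TRUE)
  atoms <- data.frame(
    atom_index = vapply(parts, function(p) as.integer(p[[1]]), integer(1)),
    element = vapply(parts, `[[`, character(1), 2),
    available_h = vapply(parts, function(p) as.integer(p[[3]]), integer(1)),
    stringsAsFactors = FALSE)
  sites <- atoms[atoms$available_h >= 1, , drop = FALSE]
  sites <- sites[order(sites$atom_index), , drop = FALSE]
  rownames(sites) <- NULL
  if (nrow(sites) == 0) {
    warning("scaffold has no hydrogen-bearing heavy atoms; no attachment ",
            "sites", call. = FALSE)
  }
  sites
}

# backend search: one candidate rooted spelling per H-bearing atom; the
# search itself admits only spellings passing the methyl-append test
rooted_candidates <- function(scaffold_smiles, extra_tries = 300) {
  out <- tryCatch(
    chem_helper("rooted", args = c("--query", shQuote(scaffold_smiles),
                                   "--extra", extra_tries)),
    error = function(e) stop("scaffold SMILES does not parse: ",
                             scaffold_smiles, call. = FALSE))
  parts <- strsplit(out, "\t", fixed = TRUE)
  data.frame(
    atom_index = vapply(parts, function(p) as.integer(p[[1]]), integer(1)),
    smiles = vapply(parts, function(p) if (length(p) > 1) p[[2]] else "",
                    character(1)),
    stringsAsFactors = FALSE)
}

#' Verify a rooted scaffold spelling
#'
#' Checks the two defining invariants of a rooted spelling: it parses to a
#' molecule canonical-SMILES-identical to the scaffold, and appending `"C"`
#' parses to the scaffold plus one methyl bonded at `atom_index` (reference
#' built by an independent graph edit).
#'
#' @param scaffold_smiles The parent scaffold.
#' @param rooted Candidate spelling(s).
#' @param atom_index 0-based attachment atom index (recycled against
#'   `rooted`).
#' @return Logical vector, one element per candidate.
#' @export
verify_rooted <- function(scaffold_smiles, rooted, atom_index) {
  verify_rooted_all(scaffold_smiles, rooted, atom_index)
}

# vectorized verification: one canonicalisation batch and one graph-edit
# batch for the whole library
verify_rooted_all <- function(scaffold_smiles, rooted, atom_index) {
  out <- logical(length(rooted))
  has <- !is.na(rooted) & nzchar(rooted)
  if (!any(has)) return(out)
  k <- sum(has)
  cans <- canonical_smiles(c(scaffold_smiles, rooted[has],
                             paste0(rooted[has], "C")))
  c_scaffold <- cans[1]
  c_self <- cans[1 + seq_len(k)]
  c_methyl <- cans[1 + k + seq_len(k)]
  refs <- add_methyl_at(rep(scaffold_smiles, k), atom_index[has])
  out[has] <- !is.na(c_self) & !is.na(c_scaffold) & c_self == c_scaffold &
    !is.na(c_methyl) & !is.na(refs) & c_methyl == refs
  out
}

#' Rooted spelling for one attachment site
#'
#' Emits a SMILES spelling of the scaffold arranged so that appended
#' characters grow a substituent at `atom_index`. Kekulé (uppercase)
#' spellings are used for aromatic systems so that appending to an N-H
#' nitrogen needs no bracket-H bookkeeping. The result is verified by the
#' methyl-append test before being returned.
#'
#' @inheritParams verify_rooted
#' @param atom_index 0-based index of an H-bearing heavy atom (as returned
#'   by [enumerate_attachment_sites()]).
#' @return The rooted SMILES string.
#' @export
rooted_smiles <- function(scaffold_smiles, atom_index) {
  lib <- rooted_library(scaffold_smiles, warn = FALSE)
  row <- lib[lib$atom_index == atom_index, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("atom ", atom_index, " is not an attachment site of the scaffold",
         call. = FALSE)
  }
  if (is.na(row$smiles)) {
    stop("no verified rooted spelling found for atom ", atom_index,
         call. = FALSE)
  }
  row$smiles
}

#' Rooted spellings for every attachment site
#'
#' Enumerates the attachment sites of a scaffold and finds one verified
#' rooted spelling per site. Sites for which no spelling passes verification
#' get `NA` in the `smiles` column (a partial result) with a warning; other
#' sites are unaffected.
#'
#' @inheritParams enumerate_attachment_sites
#' @param extra_tries Random traversals attempted per scaffold on top of the
#'   deterministic ones.
#' @param warn Warn about unverified sites.
#' @return Data frame with columns `atom_index`, `element`, `available_h`,
#'   `smiles`, `verified`.
#' @export
#' @examples \dontrun{rooted_library("C12=C(C=CC=C2)NC=C1")  # 7 spellings}
rooted_library <- function(scaffold_smiles, extra_tries = 300, warn = TRUE) {
  sites <- enumerate_attachment_sites(scaffold_smiles)
  if (nrow(sites) == 0) {
    sites$smiles <- character(0)
    sites$verified <- logical(0)
    return(sites)
  }
  cand <- rooted_candidates(scaffold_smiles, extra_tries = extra_tries)
  sites$smiles <- cand$smiles[match(sites$atom_index, cand$atom_index)]
  # the search only emits spellings that passed the methyl-append test;
  # verify_rooted() re-checks any spelling independently on demand
  sites$verified <- !is.na(sites$smiles) & nzchar(sites$smiles)
  sites$smiles[!sites$verified] <- NA_character_
  if (warn && any(!sites$verified)) {
    warning("no verified rooted spelling found for atom(s) ",
            paste(sites$atom_index[!sites$verified], collapse = ", "),
            call. = FALSE)
  }
  sites
}
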