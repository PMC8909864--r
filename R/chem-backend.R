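# Chemistry backend: batched calls into the bundled RDKit helper script.
# All chemistry in the package flows through this one file so that
# canonicalisation, fingerprints and descriptors are mutually consistent.

chem_python <- function() {
  p <- getOption("molgen.python", "")
  if (nzchar(p)) return(p)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) return(unname(path))
  }
  stop("no python interpreter found on the PATH; the chemistry backend ",
       "requires python with rdkit installed", call. = FALSE)
}

chem_helper_path <- function() {
  path <- system.file("python", "chem_helper.py", package = "molgen")
  if (!nzchar(path)) stop("chem_helper.py not found in the installed package",
                          call. = FALSE)
  path
}

#' @noRd
chem_helper <- function(command, input = NULL, args = character()) {
  out <- suppressWarnings(system2(
    chem_python(), c(shQuote(chem_helper_path()), command, args),
    stdout = TRUE, stderr = FALSE,
    input = if (is.null(input)) "" else input))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry helper '", command, "' failed (exit ", status, ")",
         call. = FALSE)
  }
  as.character(out)
}

#' Canonical SMILES via the RDKit backend
#'
#' Parses each SMILES string and returns its canonical spelling, or `NA` for
#' strings that do not parse and sanitize (valence or aromaticity failures).
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @export
#' @examples \dontrun{canonical_smiles(c("CCO", "OCC", "C("))}
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  stopifnot(is.character(smiles))
  out <- chem_helper("canon", input = smiles)
  if (length(out) != length(smiles)) {
    # trailing invalid entries can drop the final empty stdout line
    out <- c(out, rep("", length(smiles) - length(out)))
  }
  ifelse(nzchar(out), out, NA_character_)
}

#' Test SMILES validity
#'
#' A string is valid iff it can be parsed back to a molecular structure
#' (RDKit parse + sanitize).
#'
#' @inheritParams canonical_smiles
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) !is.na(canonical_smiles(smiles))

#' MACCS structural-key fingerprints
#'
#' Computes the 166-bit MACCS substructure-key fingerprint for each molecule.
#'
#' @inheritParams canonical_smiles
#' @return Integer matrix with one row per input and 166 columns; rows for
#'   invalid SMILES are all `NA`.
#' @export
maccs_fingerprints <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  out <- chem_helper("maccs", input = smiles)
  if (length(out) != length(smiles)) {
    out <- c(out, rep("", length(smiles) - length(out)))
  }
  fp <- matrix(NA_integer_, nrow = length(smiles), ncol = 166)
  ok <- nzchar(out)
  if (any(ok)) {
    bits <- vapply(strsplit(out[ok], ""), function(b) as.integer(b),
                   integer(166))
    fp[ok, ] <- t(bits)
  }
  rownames(fp) <- smiles
  fp
}

#' Substructure search
#'
#' @inheritParams canonical_smiles
#' @param pattern A SMARTS (or SMILES, which is valid SMARTS) query pattern.
#' @return Logical vector; `NA` for SMILES that do not parse.
#' @export
has_substructure <- function(smiles, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  if (length(smiles) == 0) return(logical(0))
  out <- chem_helper("substruct", input = smiles,
                     args = c("--query", shQuote(pattern)))
  if (length(out) != length(smiles)) {
    out <- c(out, rep("NA", length(smiles) - length(out)))
  }
  ifelse(out == "NA", NA, out == "1")
}

# scaffold + methyl at a 0-based atom index, built by graph edit (the
# independent reference for the methyl-append verification)
add_methyl_at <- function(smiles, atom_index) {
  stopifnot(length(smiles) == length(atom_index))
  out <- chem_helper("addmethyl",
                     input = paste(smiles, atom_index, sep = "\t"))
  if (length(out) != length(smiles)) {
    out <- c(out, rep("", length(smiles) - length(out)))
  }
  ifelse(nzchar(out), out, NA_character_)
}
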