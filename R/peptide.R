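#' Parse a peptide string into residue tokens
#'
#' Grammar: one uppercase letter per residue, oxidized methionine written
#' `"M(ox)"`. Carbamidomethylation of cysteine is implicit in the `C` mass.
#'
#' @param x Peptide string, or an already-tokenized character vector
#'   (returned unchanged after validation).
#' @return Character vector of residue tokens.
#' @examples
#' parse_peptide("ACM(ox)K")
#' @export
parse_peptide <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (length(x) > 1L) {
    tokens <- x
  } else {
    if (!is.character(x) || length(x) != 1L || is.na(x))
      stop("peptide must be a single string or a token vector")
    tokens <- regmatches(x, gregexpr("M\\(ox\\)|.", x))[[1]]
  }
  bad <- setdiff(unique(tokens), names(.aa_masses))
  if (length(bad))
    stop("unknown residue token(s): ", paste(bad, collapse = ", "))
  tokens
}

#' Collapse residue tokens back to a peptide string
#' @param tokens Character vector of residue tokens.
#' @export
peptide_string <- function(tokens) paste(tokens, collapse = "")

# compact single-byte encoding ("M(ox)" -> "m"); used for adist and sampling
pep_encode <- function(tokens) paste(.aa_byte[tokens], collapse = "")
pep_decode <- function(s) unname(.byte_aa[strsplit(s, "", fixed = TRUE)[[1]]])

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water. The empty peptide has the mass of
#' water.
#'
#' @param p Peptide string or token vector.
#' @return Mass in Da.
#' @examples
#' peptide_mass("G")        # 75.03202
#' peptide_mass("PEPTIDE")  # 799.35995
#' @export
peptide_mass <- function(p) {
  tokens <- if (length(p) == 1L && !nzchar(p)) character(0) else parse_peptide(p)
  sum(.aa_masses[tokens]) + WATER_MASS
}

#' Levenshtein distance between two peptides
#'
#' Unit-cost insertions, deletions and substitutions over residue tokens;
#' `"M(ox)"` counts as a single token. I and L are distinct here (I/L
#' collapsing is an evaluation-layer concern, see [peptide_correct()]).
#'
#' @param a,b Peptide strings or token vectors.
#' @return Non-negative integer edit distance.
#' @export
levenshtein <- function(a, b) {
  ea <- if (length(a) == 1L && !nzchar(a)) "" else pep_encode(parse_peptide(a))
  eb <- if (length(b) == 1L && !nzchar(b)) "" else pep_encode(parse_peptide(b))
  as.integer(utils::adist(ea, eb))
}

#' Is a peptide/charge pair eligible for the pipeline?
#'
#' Eligibility mirrors the preprocessing filters: peptide length 7--30 and
#' precursor charge at most 6.
#'
#' @param p Peptide string or token vector.
#' @param charge Precursor charge state.
#' @export
peptide_eligible <- function(p, charge) {
  n <- length(parse_peptide(p))
  n >= 7L && n <= 30L && !is.na(charge) && charge >= 1L && charge <= 6L
}
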