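# package-level cache (isobaric table, simulator defaults, etc.)
.seqmend_env <- new.env(parent = emptyenv())

# Enumerate all residue multisets of size 1..3 over the 21 tokens, with
# exact masses. ~2,000 rows; built lazily once per session.
isobaric_table <- function() {
  if (!is.null(.seqmend_env$iso_table)) return(.seqmend_env$iso_table)
  toks <- names(.aa_masses)
  sets <- list()
  for (size in 1:3) {
    idx <- utils::combn(length(toks) + size - 1L, size)
    # combinations with repetition via the stars-and-bars shift
    idx <- idx - (seq_len(size) - 1L)
    sets[[size]] <- lapply(seq_len(ncol(idx)), function(j) toks[idx[, j]])
  }
  sets <- do.call(c, sets)
  mass <- vapply(sets, function(s) sum(.aa_masses[s]), numeric(1))
  .seqmend_env$iso_table <- list(sets = sets, mass = mass,
                                 size = lengths(sets))
  .seqmend_env$iso_table
}

#' Isobaric replacements for a short residue window
#'
#' Returns every residue multiset of size 1--3 whose exact mass is within
#' `tol_ppm` (measured relative to the whole-peptide mass, as in the
#' mutation operator that keeps the total precursor mass match) of the
#' window's mass. The window's own multiset is always included.
#'
#' @param window Peptide window (string or tokens) of 1--3 residues.
#' @param peptide_mass Mass of the full peptide the window sits in (Da);
#'   sets the absolute tolerance `tol_ppm * peptide_mass * 1e-6`.
#' @param tol_ppm Mass tolerance in ppm (default 20).
#' @return List of character vectors (sorted residue multisets).
#' @examples
#' # N and GG are exact isobars (114.04293 Da)
#' isobaric_replacements("N", 1000, 20)
#' @export
isobaric_replacements <- function(window, peptide_mass, tol_ppm = 20) {
  tokens <- parse_peptide(window)
  if (length(tokens) < 1L || length(tokens) > 3L)
    stop("window must hold 1 to 3 residues")
  if (tol_ppm < 0) stop("tol_ppm must be non-negative")
  tab <- isobaric_table()
  wmass <- sum(.aa_masses[tokens])
  tol <- tol_ppm * peptide_mass * 1e-6
  hit <- abs(tab$mass - wmass) <= tol
  out <- lapply(tab$sets[hit], function(s) sort(s))
  self <- sort(tokens)
  if (!any(vapply(out, identical, logical(1), y = self)))
    out <- c(out, list(self))
  unique(out)
}
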