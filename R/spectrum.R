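#' Construct an MS/MS spectrum object
#'
#' Peaks are stored sorted by m/z. The experimental peptide (neutral) mass
#' is derived as `charge * precursor_mz - charge * proton`.
#'
#' @param spectrum_id Identifier string (MGF TITLE).
#' @param mz Numeric vector of peak m/z values (Da).
#' @param intensity Numeric vector of non-negative peak intensities.
#' @param precursor_mz Precursor m/z (Da).
#' @param precursor_charge Integer precursor charge. Charges outside 1--6
#'   are retained (the reader keeps them) but flagged ineligible downstream.
#' @return Object of class `seqmend_spectrum`.
#' @export
spectrum <- function(spectrum_id, mz, intensity, precursor_mz,
                     precursor_charge) {
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ")
  if (any(intensity < 0)) stop("negative intensities")
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge)),
            class = "seqmend_spectrum")
}

#' @export
print.seqmend_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum %s: %d peaks, precursor %.4f m/z, charge %d+, mass %.4f Da>\n",
              x$spectrum_id, length(x$mz), x$precursor_mz,
              x$precursor_charge, experimental_peptide_mass(x)))
  invisible(x)
}

#' Neutral peptide mass implied by precursor m/z and charge
#' @param s A `seqmend_spectrum`.
#' @return Mass in Da.
#' @export
experimental_peptide_mass <- function(s) {
  s$precursor_charge * s$precursor_mz - s$precursor_charge * PROTON_MASS
}

#' Base-peak normalization with a low-intensity floor
#'
#' Divides intensities by the maximum (base peak) and zeroes everything
#' below 0.02 afterwards; idempotent for spectra already on that scale.
#'
#' @param s A `seqmend_spectrum` with at least one positive-intensity peak.
#' @param floor_at Relative intensity below which peaks are zeroed.
#' @return Normalized `seqmend_spectrum`.
#' @export
base_peak_normalize <- function(s, floor_at = 0.02) {
  if (!length(s$intensity) || max(s$intensity) <= 0)
    stop("cannot base-peak normalize an all-zero spectrum")
  s$intensity <- s$intensity / max(s$intensity)
  s$intensity[s$intensity < floor_at] <- 0
  s
}

#' Bin a spectrum onto a 1-Da grid
#'
#' Bin `b` covers `[b, b+1)` Da (0-based floor convention); intensities of
#' peaks falling in the same bin are summed, peaks at or above `max_mz`
#' are dropped.
#'
#' @param s A `seqmend_spectrum`.
#' @param max_mz Upper m/z limit in Da (default 2000, i.e. 2000 bins).
#' @return Object of class `seqmend_binned`: list with `bins` (numeric
#'   vector of length `max_mz`) and `max_mz`.
#' @export
bin_spectrum <- function(s, max_mz = 2000) {
  if (max_mz <= 0) stop("max_mz must be positive")
  nb <- as.integer(max_mz)
  idx <- floor(s$mz)
  keep <- idx >= 0 & idx < nb
  bins <- numeric(nb)
  if (any(keep)) {
    agg <- vapply(split(s$intensity[keep], idx[keep]), sum, numeric(1))
    bins[as.integer(names(agg)) + 1L] <- agg
  }
  structure(list(bins = bins, max_mz = nb), class = "seqmend_binned")
}
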