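#' Monoisotopic residue masses and physical constants
#'
#' The 21 sequencing tokens are the 20 canonical amino acids plus oxidized
#' methionine, written `"M(ox)"`. Cysteine carries a fixed carbamidomethyl
#' group (+57.02146 Da), so the `C` entry is the modified residue mass.
#' Leucine and isoleucine are distinct tokens with identical mass.
#'
#' @format Named numeric vector of residue masses in Da.
#' @examples
#' aa_masses()[["G"]]
#' @export
aa_masses <- function() .aa_masses

.aa_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, L = 113.08406, I = 113.08406, N = 114.04293, D = 115.02694,
  Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, # C below includes fixed carbamidomethyl
  C = 160.03065, Y = 163.06333, W = 186.07931,
  "M(ox)" = 147.03540
)

#' @rdname aa_masses
#' @export
PROTON_MASS <- 1.00728

#' @rdname aa_masses
#' @export
WATER_MASS <- 18.01056

# single-byte alias used in compact encodings (adist, simulator sampling)
.aa_byte <- c(setNames(names(.aa_masses)[1:20], names(.aa_masses)[1:20]),
              "M(ox)" = "m")
.byte_aa <- setNames(names(.aa_byte), .aa_byte)

#' Integer-discretized residue masses (1-Da bins)
#'
#' Discretization is `floor()`, matching the bin convention where bin `b`
#' covers `[b, b+1)` Da. K and Q collide at 128, F and M(ox) at 147;
#' tryptophan has the largest value, 186.
#'
#' @return Named integer vector over the 21 tokens.
#' @export
aa_bins <- function() {
  b <- as.integer(floor(.aa_masses))
  names(b) <- names(.aa_masses)
  b
}
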