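#' Theoretical b/y fragment ions of a peptide
#'
#' Singly charged ladders follow `b_k = sum(first k residues) + proton`
#' and `y_k = sum(last k residues) + water + proton`; doubly charged ions
#' use `(neutral + 2 proton) / 2`. The complementarity identity
#' `b_k + y_(n-k) - 2 proton = peptide mass` holds for all k.
#'
#' @param p Peptide string or token vector, length >= 2.
#' @param max_charge Highest fragment charge to emit (1 or 2).
#' @return data.frame with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz`.
#' @export
theoretical_ions <- function(p, max_charge = 1L) {
  tokens <- parse_peptide(p)
  n <- length(tokens)
  if (n < 2L) stop("peptide must have at least 2 residues")
  if (!max_charge %in% 1:2) stop("max_charge must be 1 or 2")
  rm <- .aa_masses[tokens]
  b_neutral <- cumsum(rm)[-n]                 # b_k neutral fragment mass
  y_neutral <- cumsum(rev(rm))[-n] + WATER_MASS   # y_k: last k residues
  out <- list()
  for (z in seq_len(max_charge)) {
    out[[length(out) + 1L]] <- data.frame(
      series = "b", index = seq_len(n - 1L), charge = z,
      mz = (b_neutral + z * PROTON_MASS) / z)
    out[[length(out) + 1L]] <- data.frame(
      series = "y", index = seq_len(n - 1L), charge = z,
      mz = (y_neutral + z * PROTON_MASS) / z)
  }
  do.call(rbind, out)
}

#' Ground-truth bin labels for a peptide
#'
#' Marks the 1-Da bins (floor convention) holding singly charged b- and
#' y-ions of `p`, within `[0, max_mz)`.
#'
#' @param p Peptide string or token vector.
#' @param max_mz Number of 1-Da bins (default 2000).
#' @return List with integer 0/1 vectors `b` and `y`, each of length
#'   `max_mz`.
#' @export
label_bins <- function(p, max_mz = 2000) {
  nb <- as.integer(max_mz)
  ions <- theoretical_ions(p, max_charge = 1L)
  lab <- list(b = integer(nb), y = integer(nb))
  for (ser in c("b", "y")) {
    bins <- floor(ions$mz[ions$series == ser])
    bins <- bins[bins >= 0 & bins < nb]
    lab[[ser]][bins + 1L] <- 1L
  }
  lab
}

#' Deterministic surrogate fragment-intensity predictor
#'
#' A fixed parametric stand-in for learned spectrum predictors: the
#' y-series is stronger than the b-series (base 1.0 vs 0.5), intensities
#' follow a triangular positional profile peaking mid-sequence, and
#' charge-2 ions (emitted only for precursor charge >= 2) are attenuated
#' by 0.3. Output is base-peak normalized; no contamination peaks.
#'
#' @param p Peptide string or token vector (2--30 residues).
#' @param charge Precursor charge state.
#' @return data.frame as [theoretical_ions()] plus an `intensity` column
#'   in `[0, 1]` with maximum 1.
#' @export
surrogate_predict <- function(p, charge) {
  tokens <- parse_peptide(p)
  n <- length(tokens)
  if (n < 2L || n > 30L) stop("surrogate predictor handles lengths 2 to 30")
  zmax <- if (charge >= 2L) 2L else 1L
  ions <- theoretical_ions(tokens, max_charge = zmax)
  base <- ifelse(ions$series == "y", 1.0, 0.5)
  tri <- 1 - abs(2 * ions$index / n - 1)     # peak at k/n = 0.5
  inten <- base * tri * ifelse(ions$charge == 2L, 0.3, 1.0)
  ions$intensity <- inten / max(inten)
  ions
}

#' Bin a predicted fragment spectrum
#'
#' Sums the predicted intensities of all ions (fragment charges 1--2) per
#' 1-Da bin; this is the predicted-intensity input channel of the bin
#' reclassifier.
#'
#' @param ions data.frame from a spectrum predictor (needs `mz`,
#'   `intensity`).
#' @param max_mz Number of 1-Da bins.
#' @return Numeric vector of length `max_mz`.
#' @export
bin_predicted <- function(ions, max_mz = 2000) {
  nb <- as.integer(max_mz)
  bins <- numeric(nb)
  idx <- floor(ions$mz)
  keep <- idx >= 0 & idx < nb
  if (any(keep)) {
    agg <- vapply(split(ions$intensity[keep], idx[keep]), sum, numeric(1))
    bins[as.integer(names(agg)) + 1L] <- agg
  }
  bins
}

#' Spectrum-predictor registry
#'
#' Predictors are functions `(peptide, charge) -> data.frame` with the
#' [surrogate_predict()] contract. `"surrogate"` is registered by default;
#' adapters for learned predictors can be plugged in by name.
#'
#' @param name Registry key.
#' @param fn Predictor function (for `register_predictor`).
#' @return `get_predictor` returns the predictor function.
#' @export
get_predictor <- function(name = "surrogate") {
  reg <- .predictor_registry()
  if (!name %in% names(reg)) stop("unknown predictor '", name, "'")
  reg[[name]]
}

#' @rdname get_predictor
#' @export
register_predictor <- function(name, fn) {
  stopifnot(is.function(fn))
  reg <- .predictor_registry()
  reg[[name]] <- fn
  .seqmend_env$predictors <- reg
  invisible(name)
}

.predictor_registry <- function() {
  if (is.null(.seqmend_env$predictors))
    .seqmend_env$predictors <- list(surrogate = surrogate_predict)
  .seqmend_env$predictors
}
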