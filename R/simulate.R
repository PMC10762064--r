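#' Simulator configuration
#'
#' Defines the synthetic study conditions: tryptic peptides (uniform
#' length 7--30, C-terminal K/R, 20% of methionines oxidized), charge
#' states drawn from a tryptic-like distribution over 1--6 (dominated by
#' 2+/3+), singly/doubly charged b/y fragment peaks from the surrogate
#' predictor with ppm-level m/z jitter, random peak dropout, uniform-m/z
#' contamination peaks with exponentially distributed intensities, and
#' corrupted candidate peptides generated by isobaric window rewrites
#' (1--3 residues, 20 ppm) and adjacent-residue swaps.
#'
#' @param num_peptides Number of peptides/spectra.
#' @param length_range Peptide length range (inclusive).
#' @param charge_probs Probabilities for charges 1..6.
#' @param dropout Per-peak dropout probability.
#' @param contamination_rate Mean number of contamination peaks per
#'   spectrum (Poisson).
#' @param contamination_mean Mean relative intensity of contamination
#'   peaks (exponential law, on the base-peak scale).
#' @param jitter_ppm Gaussian m/z noise, in ppm.
#' @param corruption_probs Mix of corruption operators applied to produce
#'   incorrect candidates: isobaric window rewrite, adjacent swap, or a
#'   composite of two operators.
#' @param tol_ppm Mass tolerance for isobaric rewrites.
#' @param max_mz Upper m/z bound of simulated peaks.
#' @param seed Optional RNG seed; fixed seeds reproduce byte-identical
#'   output files.
#' @return List of class `seqmend_sim_config`.
#' @export
sim_config <- function(num_peptides = 100L, length_range = c(7L, 30L),
                       charge_probs = c(0.05, 0.50, 0.30, 0.10, 0.04, 0.01),
                       dropout = 0.10, contamination_rate = 10,
                       contamination_mean = 0.05, jitter_ppm = 5,
                       corruption_probs = c(isobaric = 0.5, swap = 0.3,
                                            composite = 0.2),
                       tol_ppm = 20, max_mz = 2000, seed = NULL) {
  if (length_range[1] > length_range[2]) stop("empty length range")
  stopifnot(length(charge_probs) == 6L, all(charge_probs >= 0),
            dropout >= 0, dropout <= 1)
  structure(as.list(environment()), class = "seqmend_sim_config")
}

.sim_peptide <- function(len) {
  toks <- sample(names(.aa_masses)[1:20], len - 1L, replace = TRUE)
  toks[toks == "M"] <- ifelse(stats::runif(sum(toks == "M")) < 0.2,
                              "M(ox)", "M")
  c(toks, sample(c("K", "R"), 1L))
}

# corruption operators; each returns a token vector differing from input
.corrupt_isobaric <- function(tokens, tol_ppm) {
  pm <- peptide_mass(tokens)
  for (try in 1:25) {
    wlen <- sample.int(min(3L, length(tokens)), 1L)
    at <- sample.int(length(tokens) - wlen + 1L, 1L)
    win <- tokens[at:(at + wlen - 1L)]
    reps <- isobaric_replacements(win, pm, tol_ppm)
    reps <- reps[!vapply(reps, identical, logical(1), y = sort(win))]
    if (!length(reps)) next
    new <- reps[[sample.int(length(reps), 1L)]]
    new <- new[sample.int(length(new))]   # random residue order
    out <- append(tokens[-(at:(at + wlen - 1L))], new, after = at - 1L)
    if (!identical(out, tokens)) return(out)
  }
  tokens
}

.corrupt_swap <- function(tokens) {
  for (try in 1:25) {
    i <- sample.int(length(tokens) - 1L, 1L)
    if (tokens[i] != tokens[i + 1L]) {
      tokens[c(i, i + 1L)] <- tokens[c(i + 1L, i)]
      return(tokens)
    }
  }
  tokens
}

.corrupt_candidate <- function(tokens, config) {
  op <- sample(names(config$corruption_probs), 1L,
               prob = config$corruption_probs)
  out <- switch(op,
    isobaric = .corrupt_isobaric(tokens, config$tol_ppm),
    swap = .corrupt_swap(tokens),
    composite = .corrupt_swap(.corrupt_isobaric(tokens, config$tol_ppm)))
  if (identical(out, tokens)) out <- .corrupt_swap(tokens)
  out
}

#' Simulate a synthetic de novo sequencing dataset
#'
#' For each peptide: surrogate fragment ions, peak dropout, ppm m/z
#' jitter, contamination peaks, and a random absolute base-peak scale;
#' plus a truth table and a candidate table holding the correct peptide
#' (`tool = "sim_true"`) and one corrupted candidate
#' (`tool = "sim_corrupt"`) per spectrum with its recorded true
#' Levenshtein distance.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; writes `spectra.mgf`,
#'   `truth.tsv`, `candidates.tsv`.
#' @return List with `spectra` (list of `seqmend_spectrum`), `truth`
#'   (data.frame spectrum_id, peptide, charge) and `candidates`
#'   (data.frame spectrum_id, peptide, tool, true_distance).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$num_peptides
  peps <- character(n)
  seen <- character(0)
  for (i in seq_len(n)) {
    repeat {
      len <- sample(config$length_range[1]:config$length_range[2], 1L)
      p <- peptide_string(.sim_peptide(len))
      if (!p %in% seen) break
    }
    seen <- c(seen, p)
    peps[i] <- p
  }
  charges <- sample(1:6, n, replace = TRUE, prob = config$charge_probs)
  spectra <- vector("list", n)
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("sim_%05d", i)
    tokens <- parse_peptide(peps[i])
    z <- charges[i]
    ions <- surrogate_predict(tokens, z)
    keep <- stats::runif(nrow(ions)) >= config$dropout
    mz <- ions$mz[keep]
    inten <- ions$intensity[keep]
    mz <- mz * (1 + stats::rnorm(length(mz)) * config$jitter_ppm * 1e-6)
    nc <- stats::rpois(1L, config$contamination_rate)
    if (nc > 0) {
      mz <- c(mz, stats::runif(nc, 100, config$max_mz))
      inten <- c(inten, stats::rexp(nc, rate = 1 / config$contamination_mean))
    }
    scale <- 10^stats::runif(1L, 3, 6)
    spectra[[i]] <- spectrum(id, mz, inten * scale,
                             precursor_mz = (peptide_mass(tokens) +
                                             z * PROTON_MASS) / z,
                             precursor_charge = z)
    bad <- .corrupt_candidate(tokens, config)
    cand[[i]] <- data.frame(
      spectrum_id = id,
      peptide = c(peps[i], peptide_string(bad)),
      tool = c("sim_true", "sim_corrupt"),
      true_distance = c(0L, levenshtein(tokens, bad)))
  }
  names(spectra) <- vapply(spectra, `[[`, "", "spectrum_id")
  out <- list(spectra = spectra,
              truth = data.frame(spectrum_id = names(spectra),
                                 peptide = peps, charge = charges),
              candidates = do.call(rbind, cand))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_mgf(out$spectra, file.path(dir, "spectra.mgf"))
    for (nm in c("truth", "candidates"))
      utils::write.table(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Split a dataset by unique peptide
#'
#' Assigns unique peptides (not spectra) to train / validation / test, so
#' no peptide is shared between sets; split sizes follow the fractions to
#' within rounding.
#'
#' @param truth Truth table from [simulate_dataset()].
#' @param fractions Three non-negative fractions summing to 1 (default
#'   80/10/10).
#' @return List of spectrum-id vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(truth, fractions = c(0.8, 0.1, 0.1)) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  peps <- unique(truth$peptide)
  if (length(peps) < sum(fractions > 0))
    stop("fewer unique peptides than requested splits")
  peps <- sample(peps)
  bounds <- round(cumsum(c(0, fractions)) * length(peps))
  grp <- rep(1:3, times = diff(bounds))
  assign_of <- setNames(grp, peps)
  ids <- split(truth$spectrum_id, assign_of[truth$peptide])
  list(train = as.character(ids[["1"]] %||% character(0)),
       validation = as.character(ids[["2"]] %||% character(0)),
       test = as.character(ids[["3"]] %||% character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a bin-reclassification training set
#'
#' Pairs each candidate's 4-channel input with the ground-truth peptide's
#' bin labels. Candidates whose computed mass differs from the
#' precursor-derived mass by more than `ppm_filter` are excluded (the
#' training-set mass filter); set `ppm_filter = NULL` to keep all.
#'
#' @param spectra Named list of spectra.
#' @param candidates Candidate table (spectrum_id, peptide, ...).
#' @param truth Truth table (spectrum_id, peptide).
#' @param predictor Spectrum predictor.
#' @param max_mz Number of bins.
#' @param ppm_filter Training mass filter in ppm (default 20).
#' @return List with `x` (4 x max_mz x n array), `yb`, `yy` (max_mz x n
#'   0/1 matrices) and `meta` (data.frame of retained rows).
#' @export
build_reclass_dataset <- function(spectra, candidates, truth,
                                  predictor = get_predictor("surrogate"),
                                  max_mz = 2000, ppm_filter = 20) {
  truth_of <- setNames(truth$peptide, truth$spectrum_id)
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    s <- spectra[[candidates$spectrum_id[i]]]
    if (is.null(s)) next
    if (!peptide_eligible(candidates$peptide[i], s$precursor_charge)) next
    if (!is.null(ppm_filter)) {
      dm <- abs(peptide_mass(candidates$peptide[i]) -
                experimental_peptide_mass(s))
      if (dm / experimental_peptide_mass(s) * 1e6 > ppm_filter) next
    }
    keep[i] <- TRUE
  }
  rows <- which(keep)
  nb <- as.integer(max_mz)
  x <- array(0, c(4L, nb, length(rows)))
  yb <- matrix(0L, nb, length(rows))
  yy <- matrix(0L, nb, length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    s <- spectra[[candidates$spectrum_id[i]]]
    x[, , k] <- make_reclass_input(s, candidates$peptide[i], predictor, nb)
    lab <- label_bins(truth_of[[candidates$spectrum_id[i]]], nb)
    yb[, k] <- lab$b
    yy[, k] <- lab$y
  }
  list(x = x, yb = yb, yy = yy,
       meta = candidates[rows, , drop = FALSE])
}
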