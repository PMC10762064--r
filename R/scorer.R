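#' Match theoretical to experimental peaks within a ppm window
#'
#' For each theoretical peak `k`, the matched experimental intensity is
#' that of its closest experimental peak `j` when
#' `|M_k_theo - M_j_exp| < delta_ppm * M_k_theo * 1e-6`, else 0.
#'
#' @param theo data.frame of predicted ions (`mz`, `intensity`, `series`),
#'   base-peak normalized.
#' @param exp_spec A base-peak-normalized `seqmend_spectrum`.
#' @param delta_ppm Mass tolerance in ppm (default 20).
#' @return `theo` with an extra `matched` column of experimental
#'   intensities.
#' @export
match_peaks <- function(theo, exp_spec, delta_ppm = 20) {
  mz_exp <- exp_spec$mz
  matched <- numeric(nrow(theo))
  if (length(mz_exp)) {
    # closest experimental peak via the sorted peak list
    pos <- findInterval(theo$mz, mz_exp)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(mz_exp))
    d_lo <- abs(theo$mz - mz_exp[lo])
    d_hi <- abs(theo$mz - mz_exp[hi])
    j <- ifelse(d_hi < d_lo, hi, lo)
    dist <- pmin(d_lo, d_hi)
    ok <- dist < delta_ppm * theo$mz * 1e-6
    matched[ok] <- exp_spec$intensity[j[ok]]
  }
  theo$matched <- matched
  theo
}

#' Normalized spectral angle between two intensity vectors
#'
#' `1 - 2 * arccos(cosine similarity) / pi`: 1 for identical directions,
#' 0 for orthogonal vectors. An all-zero vector has no direction; the
#' value is imputed as 0 (with attribute `degenerate = TRUE`).
#'
#' @param a,b Non-negative intensity vectors of equal length.
#' @return Value in `[0, 1]`.
#' @export
spectral_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    return(structure(0, degenerate = TRUE))
  cs <- min(1, max(-1, sum(a * b) / (na * nb)))
  1 - 2 * acos(cs) / pi
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

.safe_cor <- function(a, b) {
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

.change_thresholds <- c(0.25, 0.30, 0.35, 0.40, 0.45, 0.50)
.quantile_grid <- seq(0.05, 0.95, by = 0.05)

#' Names of the 114 PSM scoring features, in vector order
#'
#' Three feature families: for each ion group (`all`, `b`, `y`) 26
#' similarity features (spectral angle, Pearson, cosine; mean, sd, min,
#' max of the absolute intensity differences; their 5%--95% quantiles in
#' 5% steps) and 8 counting features (peak counts in the four zero /
#' nonzero theoretical x experimental intensity cells, absolute and
#' relative to the group's number of predicted peaks), then 12 bin-change
#' counts (predicted label changes at thresholds 0.25--0.50, b then y).
#'
#' @return Character vector of length 114 with unique names.
#' @export
feature_registry <- function() {
  sim <- c("spectral_angle", "pearson", "cosine",
           "absdiff_mean", "absdiff_sd", "absdiff_min", "absdiff_max",
           sprintf("absdiff_q%02d", round(100 * .quantile_grid)))
  cnt <- c("n_theo1_exp1", "n_theo1_exp0", "n_theo0_exp1", "n_theo0_exp0",
           "rel_theo1_exp1", "rel_theo1_exp0", "rel_theo0_exp1",
           "rel_theo0_exp0")
  per_group <- unlist(lapply(c("all", "b", "y"), function(g)
    paste(c(sim, cnt), g, sep = "_")))
  changes <- c(sprintf("changes_b_t%02d", round(100 * .change_thresholds)),
               sprintf("changes_y_t%02d", round(100 * .change_thresholds)))
  c(per_group, changes)
}

.group_features <- function(theo_int, exp_int, n_pred) {
  d <- abs(exp_int - theo_int)
  qs <- if (length(d)) stats::quantile(d, .quantile_grid, names = FALSE)
        else rep(0, length(.quantile_grid))
  cells <- c(sum(theo_int > 0 & exp_int > 0), sum(theo_int > 0 & exp_int == 0),
             sum(theo_int == 0 & exp_int > 0),
             sum(theo_int == 0 & exp_int == 0))
  rel <- if (n_pred > 0) cells / n_pred else rep(0, 4)
  c(as.numeric(spectral_angle(theo_int, exp_int)),
    .safe_cor(theo_int, exp_int), .cosine(theo_int, exp_int),
    if (length(d)) c(mean(d), stats::sd(d), min(d), max(d)) else rep(0, 4),
    qs, cells, rel)
}

#' Extract the 114 scoring features for one peptide-spectrum match
#'
#' Similarity and counting features compare the predictor's fragment
#' intensities with the matched experimental intensities ([match_peaks()],
#' 20 ppm), jointly and for the b / y series separately; both spectra are
#' base-peak normalized with intensities below 0.02 zeroed. The
#' bin-change features count predicted label changes of the bin
#' reclassifier at probability thresholds 0.25--0.50 (strictly greater).
#'
#' @param spec A `seqmend_spectrum`.
#' @param candidate Candidate peptide (string or tokens); must be
#'   pipeline-eligible.
#' @param reclassifier A `seqmend_reclassifier`.
#' @param predictor Spectrum predictor (default surrogate).
#' @param delta_ppm Peak-matching tolerance in ppm.
#' @param bins_pred Optional precomputed [predict_bins()] output for this
#'   PSM (saves a network pass when scoring populations).
#' @return Named numeric vector of length 114 ([feature_registry()]
#'   order).
#' @export
extract_features <- function(spec, candidate, reclassifier,
                             predictor = get_predictor("surrogate"),
                             delta_ppm = 20, bins_pred = NULL) {
  tokens <- parse_peptide(candidate)
  if (!peptide_eligible(tokens, spec$precursor_charge))
    stop("candidate not pipeline-eligible (length 7-30, charge <= 6)")
  s <- base_peak_normalize(spec)
  ions <- predictor(tokens, spec$precursor_charge)
  ions$intensity[ions$intensity < 0.02] <- 0
  ions <- match_peaks(ions, s, delta_ppm)
  n_all <- nrow(ions)
  feats <- c(.group_features(ions$intensity, ions$matched, n_all),
             unlist(lapply(c("b", "y"), function(ser) {
               sel <- ions$series == ser
               .group_features(ions$intensity[sel], ions$matched[sel],
                               sum(sel))
             })))
  max_mz <- reclassifier$config$max_mz
  if (is.null(bins_pred)) {
    x <- make_reclass_input(spec, tokens, predictor, max_mz)
    bins_pred <- predict_bins(reclassifier, x)
  }
  lab <- label_bins(tokens, max_mz)
  ch_b <- change_probs(bins_pred$p_b, lab$b)
  ch_y <- change_probs(bins_pred$p_y, lab$y)
  changes <- c(vapply(.change_thresholds, function(t) sum(ch_b > t),
                      numeric(1)),
               vapply(.change_thresholds, function(t) sum(ch_y > t),
                      numeric(1)))
  out <- c(feats, changes)
  names(out) <- feature_registry()
  out
}

#' Train the PSM scoring regressor
#'
#' Random forest regression of `log2(d + 1)` on the 114 features, where
#' `d` is the Levenshtein distance of the candidate to the correct
#' peptide (variance-minimizing splits). The `"paper"` preset uses the
#' full-scale optimum (86 trees, depth 175, 36 split candidates, minimum
#' node size 112); the `"desk"` preset suits a few thousand training
#' PSMs.
#'
#' @param features Numeric matrix (PSMs x 114), columns in
#'   [feature_registry()] order.
#' @param distances True Levenshtein distances, length `nrow(features)`;
#'   must contain more than one distinct value.
#' @param preset `"desk"` or `"paper"`.
#' @param ... Overrides passed to [ranger::ranger()] (`num.trees`,
#'   `mtry`, `min.node.size`, `max.depth`).
#' @return Object of class `seqmend_scorer`.
#' @export
train_scorer <- function(features, distances, preset = c("desk", "paper"),
                         ...) {
  preset <- match.arg(preset)
  stopifnot(nrow(features) == length(distances))
  if (length(unique(distances)) < 2L)
    stop("training distances are single-valued; cannot fit a regressor")
  args <- if (preset == "paper")
    list(num.trees = 86L, max.depth = 175L, mtry = 36L,
         min.node.size = 112L)
  else list(num.trees = 200L, min.node.size = 5L)
  args[names(list(...))] <- list(...)
  df <- as.data.frame(features)
  colnames(df) <- feature_registry()
  df$.target <- log2(distances + 1)
  fit <- do.call(ranger::ranger,
                 c(list(formula = .target ~ ., data = df,
                        seed = sample.int(.Machine$integer.max, 1L)),
                   args))
  structure(list(forest = fit, registry = feature_registry(),
                 preset = preset),
            class = "seqmend_scorer")
}

#' @export
print.seqmend_scorer <- function(x, ...) {
  cat(sprintf("<PSM scorer: %d-tree random forest on %d features (%s preset), OOB R^2 %.3f>\n",
              x$forest$num.trees, length(x$registry), x$preset,
              x$forest$r.squared))
  invisible(x)
}

#' Predict the PSM score (estimated edit distance)
#'
#' @param object A `seqmend_scorer`.
#' @param features Numeric matrix or vector of 114 features.
#' @param ... Unused.
#' @return Predicted `log2(d + 1)` values; lower = more confident. Use
#'   `2^score - 1` for the distance scale.
#' @export
predict.seqmend_scorer <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  df <- as.data.frame(features)
  colnames(df) <- object$registry
  as.numeric(stats::predict(object$forest, data = df)$predictions)
}

#' Score and rank candidate peptide-spectrum matches
#'
#' Computes the 114 features for each PSM, predicts `log2(d + 1)` and
#' ranks ascending (smaller estimated distance = higher confidence) with
#' a stable sort. Ineligible PSMs (length > 30 or charge > 6) get the
#' sentinel score `Inf` and rank last.
#'
#' @param psms data.frame with columns `spectrum_id` and `peptide`
#'   (further columns are carried through).
#' @param spectra List of `seqmend_spectrum`, or a list named by
#'   spectrum id.
#' @param scorer A trained `seqmend_scorer`.
#' @param reclassifier A trained `seqmend_reclassifier`.
#' @param predictor Spectrum predictor.
#' @return `psms` with `score` and `rank` columns, ordered by rank.
#' @export
score_psms <- function(psms, spectra, scorer, reclassifier,
                       predictor = get_predictor("surrogate")) {
  if (is.null(names(spectra)))
    names(spectra) <- vapply(spectra, `[[`, "", "spectrum_id")
  feats <- matrix(NA_real_, nrow(psms), length(scorer$registry))
  eligible <- logical(nrow(psms))
  for (i in seq_len(nrow(psms))) {
    s <- spectra[[psms$spectrum_id[i]]]
    if (is.null(s)) stop("no spectrum for id ", psms$spectrum_id[i])
    eligible[i] <- peptide_eligible(psms$peptide[i], s$precursor_charge)
    if (eligible[i])
      feats[i, ] <- extract_features(s, psms$peptide[i], reclassifier,
                                     predictor)
  }
  score <- rep(Inf, nrow(psms))
  if (any(eligible))
    score[eligible] <- predict(scorer, feats[eligible, , drop = FALSE])
  psms$score <- score
  o <- order(psms$score)   # stable: ties keep input order
  psms <- psms[o, , drop = FALSE]
  psms$rank <- seq_len(nrow(psms))
  rownames(psms) <- NULL
  psms
}
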