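#' Peptide correctness up to isoleucine/leucine substitution
#'
#' True iff the two token sequences are identical after mapping I and L
#' (which are isobaric and indistinguishable by fragment masses) to a
#' common token. Oxidation state still matters.
#'
#' @param pred,truth Peptide strings or token vectors.
#' @return Logical.
#' @export
peptide_correct <- function(pred, truth) {
  il <- function(x) {
    t <- parse_peptide(x)
    t[t == "I"] <- "L"
    t
  }
  identical(il(pred), il(truth))
}

#' Peptide-level precision-recall curve
#'
#' Sweeps the score cutoff (scores estimate a distance: smaller = more
#' confident; a PSM is reported when `score <= cutoff`). Precision is the
#' fraction of reported PSMs whose peptide is correct (up to I/L);
#' recall divides by the truth-table size, so it need not reach 1 at the
#' most lenient cutoff.
#'
#' @param scored data.frame with `spectrum_id`, `peptide`, `score` (one
#'   candidate per spectrum).
#' @param truth Truth table with `spectrum_id`, `peptide`.
#' @return List of class `seqmend_pr` (`thresholds` ascending = lenient,
#'   `precision`, `recall`, `auprc`) plus `correct` flags in input order.
#' @export
peptide_pr_curve <- function(scored, truth) {
  if (!nrow(truth)) stop("empty truth table")
  truth_of <- setNames(truth$peptide, truth$spectrum_id)
  correct <- vapply(seq_len(nrow(scored)), function(i) {
    tp <- truth_of[[scored$spectrum_id[i]]]
    !is.null(tp) && peptide_correct(scored$peptide[i], tp)
  }, logical(1))
  o <- order(scored$score)
  s <- scored$score[o]; y <- correct[o]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  prec <- tp / last
  rec <- tp / nrow(truth)
  ap <- sum(diff(c(0, rec)) * prec)
  structure(list(thresholds = s[last], precision = prec, recall = rec,
                 auprc = ap, correct = correct), class = "seqmend_pr")
}

#' Recall at a target precision
#'
#' Largest recall over the curve's operating points with precision at
#' least `target`; `NA` if the precision is never attained.
#'
#' @param curve A `seqmend_pr` from [peptide_pr_curve()].
#' @param target Target precision (e.g. 0.9).
#' @return Recall value or `NA`.
#' @export
recall_at_precision <- function(curve, target = 0.9) {
  ok <- curve$precision >= target
  if (!any(ok)) return(NA_real_)
  max(curve$recall[ok])
}

#' Score cutoff attaining a target precision
#'
#' The most lenient cutoff (largest score, since smaller scores are more
#' confident) whose reported set has precision at least the target. With
#' multiple labeled batches, the per-batch cutoffs are computed and their
#' median returned.
#'
#' @param scored One scored data.frame, or a list of them (batches).
#' @param truth One truth table, or a list aligned with `scored`.
#' @param target Target precision: conventionally 0.80, 0.90 or 0.95.
#' @return Score cutoff. Errors (class `seqmend_precision_unattained`)
#'   if some batch never attains the target.
#' @export
cutoff_for_precision <- function(scored, truth, target = 0.9) {
  if (is.data.frame(scored)) {
    scored <- list(scored)
    truth <- list(truth)
  }
  cuts <- mapply(function(sc, tr) {
    curve <- peptide_pr_curve(sc, tr)
    ok <- curve$precision >= target
    if (!any(ok))
      stop(errorCondition(
        sprintf("precision %.2f not attained at any cutoff", target),
        class = c("seqmend_precision_unattained", "error")))
    max(curve$thresholds[ok])
  }, scored, truth)
  stats::median(cuts)
}
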