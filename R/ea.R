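#' Evolutionary-search configuration
#'
#' The `"paper"` preset uses the full-scale optimum (population n = 1024,
#' elite size 103, 5 generations); the `"desk"` preset (n = 64, elite 7,
#' 5 generations) runs per-spectrum in seconds on one CPU. Candidates
#' whose initial estimated edit distance falls outside
#' `gate = c(1, 7)` are returned unmodified.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ... Overrides: `generations`, `pop_size`, `elite_size`,
#'   `temperature`, `gate`, `tol_ppm`, `node_threshold`.
#' @return List of class `seqmend_ea_config`.
#' @export
ea_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(generations = 5L, pop_size = 64L, elite_size = 7L,
              temperature = 1.0, gate = c(1, 7), tol_ppm = 20,
              node_threshold = 0.35)
  if (preset == "paper") cfg[c("pop_size", "elite_size")] <- list(1024L, 103L)
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  if (cfg$elite_size >= cfg$pop_size)
    stop("elite_size must be smaller than pop_size")
  structure(cfg, class = "seqmend_ea_config")
}

#' Fitness-proportional selection weights
#'
#' `w_i = exp((f_i - f*) / T)` with fitness `f = -score` (the score
#' estimates an edit distance, so smaller is fitter) and `f*` the maximum
#' fitness; the fittest member has weight 1 and all weights lie in
#' `(0, 1]`.
#'
#' @param scores Predicted-distance scores (lower = better).
#' @param temperature Temperature `T > 0`.
#' @return Numeric weights.
#' @export
selection_weights <- function(scores, temperature = 1.0) {
  f <- -scores
  fstar <- max(f[is.finite(f)])
  w <- exp((f - fstar) / temperature)
  w[!is.finite(scores)] <- 0
  w
}

#' Initial population by random isobaric rewrites and adjacent swaps
#'
#' The unmodified initial peptide is always member 1; the remaining
#' members replace a random window of at most 3 consecutive residues by
#' an isobaric residue combination (total mass shift at most `tol_ppm`
#' relative to the peptide mass) or permute adjacent residues.
#'
#' @param initial Initial peptide (string or tokens).
#' @param n Population size.
#' @param tol_ppm Isobaric mass tolerance in ppm.
#' @return List of token vectors, length `n`.
#' @export
init_population <- function(initial, n, tol_ppm = 20) {
  tokens <- parse_peptide(initial)
  pop <- vector("list", n)
  pop[[1L]] <- tokens
  if (n == 1L) return(pop)
  for (i in seq.int(2L, n)) {
    var <- if (stats::runif(1) < 0.5) .corrupt_isobaric(tokens, tol_ppm)
           else .corrupt_swap(tokens)
    pop[[i]] <- var
  }
  pop
}

# score a population with per-peptide caching; cache maps peptide string
# -> list(score, bins_pred). Batches the network passes over uncached
# members.
.score_population <- function(pop, spec, scorer, reclassifier, predictor,
                              cache) {
  keys <- vapply(pop, peptide_string, "")
  todo <- unique(keys[!vapply(keys, function(k)
    !is.null(cache[[k]]), logical(1))])
  todo_tokens <- lapply(todo, parse_peptide)
  eligible <- vapply(todo_tokens, peptide_eligible, logical(1),
                     charge = spec$precursor_charge)
  if (any(eligible)) {
    el <- which(eligible)
    nb <- reclassifier$config$max_mz
    xs <- lapply(todo_tokens[el], function(tk)
      make_reclass_input(spec, tk, predictor, nb))
    bp <- predict_bins(reclassifier, xs)
    feats <- matrix(0, length(el), 114L)
    for (j in seq_along(el)) {
      pred_j <- list(p_b = bp$p_b[, j], p_y = bp$p_y[, j])
      feats[j, ] <- extract_features(spec, todo_tokens[[el[j]]],
                                     reclassifier, predictor,
                                     bins_pred = pred_j)
      cache[[todo[el[j]]]] <- list(score = NA_real_, bins_pred = pred_j)
    }
    sc <- predict(scorer, feats)
    for (j in seq_along(el)) cache[[todo[el[j]]]]$score <- sc[j]
  }
  for (k in todo[!eligible])
    cache[[k]] <- list(score = Inf, bins_pred = NULL)
  vapply(keys, function(k) cache[[k]]$score, numeric(1))
}

#' One generation: elitism, weighted selection, guided mutation
#'
#' The `elite_size` best-scored members are inherited unchanged;
#' `pop_size - elite_size` members are drawn with replacement with
#' probability proportional to [selection_weights()] and each drawn
#' member is replaced by one guided-mutation random walk on its own
#' spectrum graph. Members whose graph has no source-target path pass
#' through unmutated.
#'
#' @param pop List of token vectors.
#' @param scores Scores aligned with `pop`.
#' @param spec The spectrum.
#' @param config An [ea_config()].
#' @param cache Scoring cache environment (holds each member's bin
#'   predictions).
#' @return List of token vectors (next generation, same size).
#' @keywords internal
.select_and_mutate <- function(pop, scores, spec, config, cache) {
  n <- length(pop)
  elite_idx <- order(scores)[seq_len(config$elite_size)]
  w <- selection_weights(scores, config$temperature)
  if (all(w == 0)) w <- rep(1, n)
  j <- n - config$elite_size
  drawn <- sample.int(n, j, replace = TRUE, prob = w)
  nxt <- pop[elite_idx]
  for (i in drawn) {
    key <- peptide_string(pop[[i]])
    bp <- cache[[key]]$bins_pred
    mutated <- pop[[i]]
    if (!is.null(bp)) {
      mutated <- tryCatch({
        g <- prune_to_paths(build_graph(bp, spec, pop[[i]],
                                        config$node_threshold))
        guided_mutation(g, 1L)[[1L]]$peptide
      }, seqmend_unreachable = function(e) pop[[i]],
         seqmend_out_of_range = function(e) pop[[i]])
    }
    nxt[[length(nxt) + 1L]] <- mutated
  }
  nxt
}

#' Refine a candidate peptide with the evolutionary algorithm
#'
#' Picks the first candidate whose computed mass is within 1 Da of the
#' precursor-derived mass (falling back to the last candidate otherwise),
#' scores it, and -- if its estimated edit distance `2^score - 1` lies in
#' the gate `[1, 7]` and it is pipeline-eligible -- runs `generations`
#' rounds of elitist selection and guided mutation, returning the
#' best-scoring peptide. Initial peptides outside the gate are returned
#' unchanged; ineligible inputs (length > 30 or charge > 6) are returned
#' with the sentinel worst score `Inf`.
#'
#' @param spec A `seqmend_spectrum`.
#' @param candidates Character vector of candidate peptides in tool
#'   priority order (primary tool first).
#' @param scorer A trained `seqmend_scorer`.
#' @param reclassifier A trained `seqmend_reclassifier`.
#' @param config An [ea_config()].
#' @param predictor Spectrum predictor.
#' @param top_k Also return the `top_k` best distinct peptides.
#' @return List of class `seqmend_ea_result`: `peptide`, `score`,
#'   `initial_peptide`, `initial_score`, `initial_distance`, `status`
#'   (`"optimized"`, `"gated"` or `"ineligible"`), `trace` (per
#'   generation best score/peptide) and `top` (data.frame of the `top_k`
#'   best distinct peptides). Seed the R RNG for reproducibility.
#' @export
run_ea <- function(spec, candidates, scorer, reclassifier,
                   config = ea_config(),
                   predictor = get_predictor("surrogate"), top_k = 2L) {
  if (!length(candidates)) stop("no candidate peptides supplied")
  exp_mass <- experimental_peptide_mass(spec)
  ok <- vapply(candidates, function(p)
    abs(peptide_mass(p) - exp_mass) <= 1, logical(1))
  initial <- if (any(ok)) candidates[which(ok)[1L]]
             else candidates[length(candidates)]
  res <- list(initial_peptide = initial, trace = NULL, top = NULL)
  if (!peptide_eligible(initial, spec$precursor_charge)) {
    res[c("peptide", "score", "initial_score", "initial_distance",
          "status")] <- list(initial, Inf, Inf, Inf, "ineligible")
    return(structure(res, class = "seqmend_ea_result"))
  }
  cache <- new.env(parent = emptyenv())
  s0 <- .score_population(list(parse_peptide(initial)), spec, scorer,
                          reclassifier, predictor, cache)
  d0 <- 2^s0 - 1
  res$initial_score <- s0
  res$initial_distance <- d0
  if (d0 < config$gate[1] || d0 > config$gate[2]) {
    res[c("peptide", "score", "status")] <- list(initial, s0, "gated")
    return(structure(res, class = "seqmend_ea_result"))
  }
  pop <- init_population(initial, config$pop_size, config$tol_ppm)
  trace <- NULL
  for (gen in seq_len(config$generations)) {
    scores <- .score_population(pop, spec, scorer, reclassifier,
                                predictor, cache)
    best <- which.min(scores)
    trace <- rbind(trace, data.frame(
      generation = gen, best_score = scores[best],
      best_peptide = peptide_string(pop[[best]])))
    pop <- .select_and_mutate(pop, scores, spec, config, cache)
  }
  scores <- .score_population(pop, spec, scorer, reclassifier, predictor,
                              cache)
  keys <- vapply(pop, peptide_string, "")
  agg <- tapply(scores, keys, min)
  agg <- sort(agg)
  res$peptide <- names(agg)[1L]
  res$score <- unname(agg[1L])
  res$status <- "optimized"
  res$trace <- trace
  res$top <- data.frame(peptide = names(agg)[seq_len(min(top_k, length(agg)))],
                        score = unname(agg[seq_len(min(top_k, length(agg)))]))
  structure(res, class = "seqmend_ea_result")
}

#' @export
print.seqmend_ea_result <- function(x, ...) {
  cat(sprintf("<EA result [%s]: %s (score %.3f; initial %s, score %.3f)>\n",
              x$status, x$peptide, x$score, x$initial_peptide,
              x$initial_score))
  invisible(x)
}

#' Write the per-generation EA trace as TSV
#'
#' @param result A `seqmend_ea_result`.
#' @param path Output path.
#' @export
write_ea_trace <- function(result, path) {
  if (is.null(result$trace)) stop("result carries no trace (gated or ineligible)")
  utils::write.table(result$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
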