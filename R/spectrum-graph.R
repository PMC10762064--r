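#' Build the probability-weighted 1-Da spectrum graph
#'
#' Nodes are m/z bins likely to hold a singly charged y-ion of the correct
#' peptide. Predicted b-ion probabilities are first mapped to their
#' complementary y-bins via `complement(b) = floor(exp_mass + 2 proton) -
#' b_bin` (from the identity `b_k + y_(n-k) = M + 2 proton`); each bin's
#' node weight is the larger of its y probability and its complemented b
#' probability, and bins above `node_threshold` become nodes. The
#' candidate peptide's own y-ion bins are added with weight 0.01 when
#' absent, and a source node at bin 19 (water + proton) and a target node
#' at `floor(exp_mass + proton)` are added with weight 1. Directed edges
#' connect bins whose difference equals the integer mass of a residue and
#' carry all matching residue tokens as labels.
#'
#' @param pred List with `p_b`, `p_y` per-bin probability vectors (from
#'   [predict_bins()]).
#' @param spec The `seqmend_spectrum` (supplies the precursor-derived
#'   peptide mass).
#' @param candidate Candidate peptide (string or tokens).
#' @param node_threshold Minimum predicted probability for a bin to enter
#'   the graph (default 0.35).
#' @return Object of class `seqmend_graph`: `bins` (sorted node bins),
#'   `weight` (aligned node weights), `edges` (data.frame `from`, `to`,
#'   list column `labels`), `source_bin`, `target_bin`.
#' @export
build_graph <- function(pred, spec, candidate, node_threshold = 0.35) {
  nb <- length(pred$p_y)
  stopifnot(length(pred$p_b) == nb)
  exp_mass <- experimental_peptide_mass(spec)
  source_bin <- 19L
  target_bin <- as.integer(floor(exp_mass + PROTON_MASS))
  if (target_bin >= nb)
    stop(errorCondition(
      paste0("precursor-derived target bin ", target_bin,
             " outside the modeled m/z range (", nb, " bins)"),
      class = c("seqmend_out_of_range", "error")))
  comp_base <- as.integer(floor(exp_mass + 2 * PROTON_MASS))
  # map b probabilities onto complementary y bins (one-to-one)
  q <- numeric(nb)
  b_bins <- 0:(nb - 1L)
  cb <- comp_base - b_bins
  ok <- cb >= 0L & cb < nb
  q[cb[ok] + 1L] <- pred$p_b[ok]
  w <- pmax(pred$p_y, q)
  keep <- which(w > node_threshold) - 1L
  weight <- w[keep + 1L]
  # candidate y-ion bins enter with weight 0.01 when absent
  ybins <- which(label_bins(candidate, nb)$y == 1L) - 1L
  add <- setdiff(ybins, keep)
  keep <- c(keep, add)
  weight <- c(weight, rep(0.01, length(add)))
  # source and target at weight 1 (overriding any predicted weight)
  for (sb in c(source_bin, target_bin)) {
    i <- match(sb, keep)
    if (is.na(i)) {
      keep <- c(keep, sb)
      weight <- c(weight, 1)
    } else weight[i] <- 1
  }
  o <- order(keep)
  bins <- as.integer(keep[o])
  weight <- weight[o]
  g <- structure(list(bins = bins, weight = weight,
                      edges = .graph_edges(bins),
                      source_bin = source_bin, target_bin = target_bin),
                 class = "seqmend_graph")
  g
}

# all ordered bin pairs whose difference is an integer residue mass
.graph_edges <- function(bins) {
  ab <- aa_bins()
  masses <- sort(unique(as.integer(ab)))
  lab_by_mass <- lapply(masses, function(m) names(ab)[ab == m])
  names(lab_by_mass) <- masses
  from <- integer(0); to <- integer(0); labels <- list()
  for (m in masses) {
    hit <- match(bins + m, bins)
    src <- which(!is.na(hit))
    if (!length(src)) next
    from <- c(from, bins[src])
    to <- c(to, bins[hit[src]])
    labels <- c(labels, rep(lab_by_mass[as.character(m)], length(src)))
  }
  o <- order(from, to)
  data.frame(from = from, to = to)[o, , drop = FALSE] |>
    (\(d) { d$labels <- labels[o]; rownames(d) <- NULL; d })()
}

#' @export
print.seqmend_graph <- function(x, ...) {
  cat(sprintf("<spectrum graph: %d nodes, %d edges, source %d, target %d>\n",
              length(x$bins), nrow(x$edges), x$source_bin, x$target_bin))
  invisible(x)
}

#' Prune a spectrum graph to source-target paths
#'
#' Keeps exactly the nodes and edges lying on at least one directed path
#' from the source to the target bin (intersection of the
#' forward-reachable and backward-reachable subgraphs); idempotent. If no
#' path exists an error of class `seqmend_unreachable` is signalled, so
#' callers can fall back to returning the input peptide.
#'
#' @param g A `seqmend_graph` from [build_graph()].
#' @return Pruned `seqmend_graph`.
#' @export
prune_to_paths <- function(g) {
  if (!nrow(g$edges))
    stop(errorCondition("no source-target path in spectrum graph",
                        class = c("seqmend_unreachable", "error")))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$from),
               to = as.character(g$edges$to)),
    vertices = as.character(g$bins))
  fwd <- igraph::subcomponent(ig, as.character(g$source_bin), mode = "out")
  bwd <- igraph::subcomponent(ig, as.character(g$target_bin), mode = "in")
  keep_bins <- sort(as.integer(intersect(names(fwd), names(bwd))))
  if (!(g$source_bin %in% keep_bins) || !(g$target_bin %in% keep_bins) ||
      (length(keep_bins) < 2L))
    stop(errorCondition("no source-target path in spectrum graph",
                        class = c("seqmend_unreachable", "error")))
  sel_nodes <- match(keep_bins, g$bins)
  sel_edges <- g$edges$from %in% keep_bins & g$edges$to %in% keep_bins
  g$bins <- keep_bins
  g$weight <- g$weight[sel_nodes]
  g$edges <- g$edges[sel_edges, , drop = FALSE]
  rownames(g$edges) <- NULL
  g
}

#' Transition distribution over a node's outgoing edges
#'
#' For an edge `e = (v, w)`, `p_e = (p_v + p_w) / sum_w' (p_v + p_w')`
#' over the outgoing edges of `v`; positive and summing to one.
#'
#' @param g A (pruned) `seqmend_graph`.
#' @param v Node bin.
#' @return data.frame with `to`, `prob` and the label list column.
#' @export
edge_probability <- function(g, v) {
  sel <- g$edges$from == v
  if (!any(sel)) stop("node ", v, " has no outgoing edges")
  to <- g$edges$to[sel]
  pv <- g$weight[match(v, g$bins)]
  pw <- g$weight[match(to, g$bins)]
  if (anyNA(pw)) stop("dangling edge endpoint at node ", v)
  un <- pv + pw
  data.frame(to = to, prob = un / sum(un)) |>
    (\(d) { d$labels <- g$edges$labels[sel]; d })()
}

#' Generate candidate peptides by weighted random walks
#'
#' Walks start at the source bin and sample outgoing edges by
#' [edge_probability()] until the target bin is reached. The peptide is
#' read from the reversed edge-label path (the y-ion ladder runs from the
#' C terminus); when an edge carries several residue tokens one is chosen
#' uniformly at random. Walks exceeding `max_edges` edges are discarded
#' and resampled.
#'
#' @param g A pruned `seqmend_graph` (every node lies on a source-target
#'   path).
#' @param n_walks Number of walks.
#' @param max_edges Walk length cap (default 35).
#' @return List of walk results: each has `peptide` (token vector),
#'   `path` (bin sequence) and `log_prob` (sum of log edge
#'   probabilities). Seed the R RNG for reproducibility.
#' @export
guided_mutation <- function(g, n_walks = 1L, max_edges = 35L) {
  # pre-index outgoing edges once
  out_idx <- split(seq_len(nrow(g$edges)), g$edges$from)
  wt <- g$weight
  names(wt) <- g$bins
  res <- vector("list", n_walks)
  for (k in seq_len(n_walks)) {
    for (attempt in 1:100) {
      v <- g$source_bin
      path <- v
      toks <- character(0)
      lp <- 0
      ok <- TRUE
      while (v != g$target_bin) {
        if (length(toks) >= max_edges) { ok <- FALSE; break }
        ei <- out_idx[[as.character(v)]]
        if (is.null(ei)) { ok <- FALSE; break }
        to <- g$edges$to[ei]
        un <- wt[as.character(v)] + wt[as.character(to)]
        pe <- un / sum(un)
        j <- if (length(ei) == 1L) 1L else sample.int(length(ei), 1L,
                                                      prob = pe)
        lp <- lp + log(pe[j])
        labs <- g$edges$labels[[ei[j]]]
        toks <- c(toks, if (length(labs) == 1L) labs else
          labs[sample.int(length(labs), 1L)])
        v <- to[j]
        path <- c(path, v)
      }
      if (ok) break
    }
    if (!ok) stop("random walk failed to reach the target within ",
                  max_edges, " edges after 100 attempts")
    res[[k]] <- list(peptide = rev(toks), path = path, log_prob = lp)
  }
  res
}

#' Export a spectrum graph as a TSV edge list
#'
#' @param g A `seqmend_graph`.
#' @param path Output TSV path (columns from, to, labels, weight_from,
#'   weight_to).
#' @export
write_graph_tsv <- function(g, path) {
  df <- data.frame(from = g$edges$from, to = g$edges$to,
                   labels = vapply(g$edges$labels, paste, "",
                                   collapse = ","),
                   weight_from = g$weight[match(g$edges$from, g$bins)],
                   weight_to = g$weight[match(g$edges$to, g$bins)])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
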