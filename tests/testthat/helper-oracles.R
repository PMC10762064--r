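# Independent oracles and fixture builders used across the suite.

# Exhaustive edit-distance oracle: plain recursion over token vectors,
# independent of the package implementation (utils::adist).
oracle_levenshtein <- function(a, b) {
  if (!length(a)) return(length(b))
  if (!length(b)) return(length(a))
  sub <- oracle_levenshtein(a[-1], b[-1]) + (a[1] != b[1])
  del <- oracle_levenshtein(a[-1], b) + 1L
  ins <- oracle_levenshtein(a, b[-1]) + 1L
  min(sub, del, ins)
}

# Brute-force enumeration of all source->target paths in a seqmend_graph;
# returns the node and edge sets lying on at least one path.
oracle_paths <- function(g) {
  adj <- split(seq_len(nrow(g$edges)), g$edges$from)
  nodes_on <- integer(0)
  edges_on <- integer(0)
  walk <- function(v, path_nodes, path_edges) {
    if (v == g$target_bin) {
      nodes_on <<- union(nodes_on, path_nodes)
      edges_on <<- union(edges_on, path_edges)
      return(invisible())
    }
    for (ei in adj[[as.character(v)]]) {
      walk(g$edges$to[ei], c(path_nodes, g$edges$to[ei]),
           c(path_edges, ei))
    }
  }
  walk(g$source_bin, g$source_bin, integer(0))
  list(nodes = sort(nodes_on), edges = sort(edges_on))
}

# Random eligible tryptic-like peptide over the full token set.
random_peptide <- function(len = sample(7:14, 1)) {
  c(sample(names(aa_masses())[1:20], len - 1, replace = TRUE),
    sample(c("K", "R"), 1))
}

# Hand-built spectrum graph (bypasses build_graph) for pruning oracles.
make_graph <- function(bins, weight, source_bin, target_bin) {
  o <- order(bins)
  structure(list(bins = as.integer(bins[o]), weight = weight[o],
                 edges = seqmend:::.graph_edges(as.integer(bins[o])),
                 source_bin = source_bin, target_bin = target_bin),
            class = "seqmend_graph")
}

# Noise-free spectrum for a peptide: surrogate fragment peaks at exact
# m/z, absolute scale 1000.
noiseless_spectrum <- function(peptide, charge = 2L,
                               id = paste0("fix_", peptide_string(parse_peptide(peptide)))) {
  ions <- surrogate_predict(peptide, charge)
  spectrum(id, ions$mz, ions$intensity * 1000,
           precursor_mz = (peptide_mass(peptide) + charge * PROTON_MASS) /
             charge,
           precursor_charge = charge)
}

# Tiny short-peptide reclassifier training set on a reduced bin range
# (short G/A/S/T peptides keep every fragment below max_mz).
tiny_reclass_dataset <- function(n = 24, max_mz = 800, seed = 421) {
  set.seed(seed)
  xs <- vector("list", n)
  yb <- matrix(0L, max_mz, n)
  yy <- matrix(0L, max_mz, n)
  for (i in seq_len(n)) {
    truth <- c(sample(c("G", "A", "S", "T"), 6, replace = TRUE), "K")
    cand <- seqmend:::.corrupt_swap(truth)
    s <- noiseless_spectrum(truth, charge = 2L, id = sprintf("tiny_%03d", i))
    xs[[i]] <- make_reclass_input(s, cand, max_mz = max_mz)
    lab <- label_bins(truth, max_mz)
    yb[, i] <- lab$b
    yy[, i] <- lab$y
  }
  list(x = simplify2array(xs), yb = yb, yy = yy)
}

# Scorer stub with (nearly) constant predictions, for exercising the EA
# gating logic deterministically.
const_scorer <- function(value, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(matrix(stats::runif(40 * 114), 40))
  colnames(df) <- feature_registry()
  df$.target <- value + stats::rnorm(40, sd = 1e-4)
  fit <- ranger::ranger(.target ~ ., data = df, num.trees = 5,
                        min.node.size = 40, seed = 1)
  structure(list(forest = fit, registry = feature_registry(),
                 preset = "stub"),
            class = "seqmend_scorer")
}
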