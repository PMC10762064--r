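gg_spectrum <- function() {
  spectrum("gg", 76.04, 1,
           precursor_mz = peptide_mass("GG") + PROTON_MASS,
           precursor_charge = 1L)
}

test_that("graph construction places source, target and residue edges", {
  pred <- list(p_b = numeric(300), p_y = numeric(300))
  g <- build_graph(pred, gg_spectrum(), "GG")
  expect_identical(g$source_bin, 19L)
  expect_identical(g$target_bin, 133L)   # floor(132.053 + 1.007)
  expect_setequal(g$bins, c(19L, 76L, 133L))
  e <- g$edges
  expect_true(any(e$from == 19 & e$to == 76 &
                    vapply(e$labels, identical, logical(1), y = "G")))
  expect_true(any(e$from == 76 & e$to == 133 &
                    vapply(e$labels, identical, logical(1), y = "G")))
  # candidate y-bins absent from predictions enter at weight 0.01
  expect_equal(g$weight[g$bins == 76], 0.01)
  expect_equal(g$weight[g$bins == 19], 1)
})

test_that("bins 128 apart are joined by an edge labeled K and Q", {
  e <- seqmend:::.graph_edges(c(200L, 328L))
  expect_equal(nrow(e), 1)
  expect_setequal(e$labels[[1]], c("K", "Q"))
})

test_that("b-ion probabilities act through their complementary bins", {
  sp <- gg_spectrum()
  # p_b at the b1 bin of GG (58) should create the complementary node
  # floor(M + 2 proton) - 58 = 134 - 58 = 76, i.e. the y1 bin
  pred <- list(p_b = numeric(300), p_y = numeric(300))
  pred$p_b[58 + 1] <- 0.9
  g <- build_graph(pred, sp, "GG")
  expect_equal(g$weight[g$bins == 76], 0.9)
  # with p_b = 0 everywhere, retained weights equal p_y
  pred2 <- list(p_b = numeric(300), p_y = numeric(300))
  pred2$p_y[76 + 1] <- 0.6
  g2 <- build_graph(pred2, sp, "GG")
  expect_equal(g2$weight[g2$bins == 76], 0.6)
  # precursor beyond the modeled range is rejected
  heavy <- spectrum("h", 1200, 1, precursor_mz = 1200, precursor_charge = 2L)
  expect_error(build_graph(pred, heavy, "GG"),
               class = "seqmend_out_of_range")
})

test_that("pruning matches brute-force path enumeration and is idempotent", {
  set.seed(23)
  for (rep in 1:40) {
    # random small graph: a guaranteed chain plus noise nodes
    chain <- c("G", "A", "S", "V")[sample.int(4, 3, replace = TRUE)]
    bins <- cumsum(c(19L, aa_bins()[chain]))
    noise <- sample(setdiff(20:500, bins), sample(3:8, 1))
    all_bins <- unique(c(bins, noise))
    g <- make_graph(all_bins, weight = runif(length(all_bins), 0.4, 1),
                    source_bin = 19L, target_bin = bins[length(bins)])
    pruned <- prune_to_paths(g)
    oracle <- oracle_paths(g)
    expect_identical(pruned$bins, oracle$nodes)
    expect_identical(nrow(pruned$edges), length(oracle$edges))
    again <- prune_to_paths(pruned)
    expect_identical(again$bins, pruned$bins)
    expect_identical(again$edges, pruned$edges)
  }
})

test_that("pruning removes isolated nodes and signals unreachable targets", {
  g <- make_graph(c(19L, 76L, 133L, 400L), weight = c(1, 0.9, 1, 0.99),
                  source_bin = 19L, target_bin = 133L)
  pruned <- prune_to_paths(g)
  expect_false(400L %in% pruned$bins)
  g2 <- make_graph(c(19L, 400L), weight = c(1, 1), source_bin = 19L,
                   target_bin = 400L)  # 381 is no residue mass
  expect_error(prune_to_paths(g2), class = "seqmend_unreachable")
})

test_that("a candidate's own y-ion chain survives pruning", {
  p <- "GGAGSGAK"   # light peptide: no 1-Da carries along the ladder
  z <- 1L
  sp <- spectrum("c", 200, 1,
                 precursor_mz = peptide_mass(p) + PROTON_MASS,
                 precursor_charge = z)
  pred <- list(p_b = numeric(800), p_y = numeric(800))
  g <- prune_to_paths(build_graph(pred, sp, p))
  ybins <- which(label_bins(p, 800)$y == 1L) - 1L
  expect_true(all(ybins %in% g$bins))
  set.seed(2)
  walks <- guided_mutation(g, 5L)
  peps <- vapply(walks, function(w) peptide_string(w$peptide), "")
  expect_true(peptide_string(parse_peptide(p)) %in% peps ||
                all(nchar(peps) > 0))  # walks traverse the graph
})

test_that("edge probabilities follow the node-weight normalization", {
  g <- make_graph(c(19L, 76L, 90L, 400L), weight = c(0.5, 0.8, 0.2, 1),
                  source_bin = 19L, target_bin = 400L)
  # 19 -> 76 is G (57), 19 -> 90 is A (71)
  ep <- edge_probability(g, 19L)
  expect_equal(sort(ep$prob), sort(c(1.3, 0.7) / 2.0))
  expect_equal(sum(ep$prob), 1)
  # single outgoing edge has probability one
  g1 <- make_graph(c(19L, 76L), weight = c(0.5, 0.8), source_bin = 19L,
                   target_bin = 76L)
  expect_equal(edge_probability(g1, 19L)$prob, 1)
  # equal successor weights give a uniform distribution
  g2 <- make_graph(c(19L, 76L, 90L), weight = c(0.5, 0.3, 0.3),
                   source_bin = 19L, target_bin = 90L)
  expect_equal(edge_probability(g2, 19L)$prob, c(0.5, 0.5))
})

test_that("edge distributions sum to one on fuzzed pruned graphs", {
  set.seed(29)
  for (rep in 1:200) {
    chain <- sample(names(aa_masses()), sample(2:5, 1), replace = TRUE)
    bins <- cumsum(c(19L, aa_bins()[chain]))
    extra <- sample(setdiff(20:max(bins), bins), sample(0:6, 1))
    g <- make_graph(unique(c(bins, extra)),
                    weight = runif(length(unique(c(bins, extra))), 0.05, 1),
                    source_bin = 19L, target_bin = max(bins))
    g <- prune_to_paths(g)
    for (v in setdiff(g$bins, g$target_bin)) {
      if (any(g$edges$from == v))
        expect_equal(sum(edge_probability(g, v)$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("walks are seeded-reproducible and close the mass balance", {
  p <- "GGAGSGAK"
  sp <- spectrum("c", 200, 1, precursor_mz = peptide_mass(p) + PROTON_MASS,
                 precursor_charge = 1L)
  pred <- list(p_b = numeric(800), p_y = runif(800) * 0.6)
  g <- prune_to_paths(build_graph(pred, sp, p))
  set.seed(7); w1 <- guided_mutation(g, 20L)
  set.seed(7); w2 <- guided_mutation(g, 20L)
  expect_identical(w1, w2)
  for (w in w1) {
    expect_equal(sum(aa_bins()[w$peptide]), g$target_bin - 19L)
    expect_lte(w$log_prob, 0)
  }
})

test_that("deterministic chain graphs always return the same peptide", {
  # GW: y1 bin 205 (W), target 262; the only path spells G-W
  p <- "GW"
  sp <- spectrum("gw", 200, 1, precursor_mz = peptide_mass(p) + PROTON_MASS,
                 precursor_charge = 1L)
  pred <- list(p_b = numeric(400), p_y = numeric(400))
  g <- prune_to_paths(build_graph(pred, sp, p))
  set.seed(1)
  peps <- vapply(guided_mutation(g, 10L), function(w)
    peptide_string(w$peptide), "")
  expect_true(all(peps == "GW"))
})

test_that("raising the node threshold never adds nodes", {
  sp <- gg_spectrum()
  set.seed(31)
  pred <- list(p_b = runif(300) * 0.8, p_y = runif(300) * 0.8)
  g_lo <- build_graph(pred, sp, "GG", node_threshold = 0.2)
  g_hi <- build_graph(pred, sp, "GG", node_threshold = 0.5)
  expect_true(all(g_hi$bins %in% g_lo$bins))
})
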