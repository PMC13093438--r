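test_that("site-pattern counting on hand-built alignments", {
  # 4 identical rows: everything is AAAA
  a0 <- aln_from(O = "ACGTACGT", P1 = "ACGTACGT", H = "ACGTACGT",
                 P2 = "ACGTACGT")
  q <- quartet_assignment("O", "P1", "H", "P2")
  c0 <- count_site_patterns(a0, q)
  expect_equal(unname(c0$counts["AAAA"]), 8)
  expect_equal(c0$n_sites_used, 8)

  # hand-classified 8 sites: 2x AABB, 1x ABAB, 1x ABBA, 4x AAAA
  a1 <- aln_from(O  = "AAAAACGT",
                 P1 = "AACGACGT",
                 H  = "CCCAACGT",
                 P2 = "CCAGACGT")
  c1 <- count_site_patterns(a1, q)
  expect_equal(unname(c1$counts["AABB"]), 2)
  expect_equal(unname(c1$counts["ABAB"]), 1)
  expect_equal(unname(c1$counts["ABBA"]), 1)
  expect_equal(unname(c1$counts["AAAA"]), 4)

  # gaps/ambiguity skip and conservation
  a2 <- aln_from(O = "AC-TAN", P1 = "ACGTA?", H = "ACGTAC", P2 = "ACGTAC")
  c2 <- count_site_patterns(a2, q)
  expect_equal(c2$n_sites_used + c2$n_sites_skipped, 6)
  expect_equal(c2$n_sites_skipped, 2)   # columns 3 (gap) and 6 (N/?)

  # duplicated identical individuals change nothing (averaging degeneracy)
  a3 <- aln_from(O = "ACGTAAGG", P1a = "ACCTAAGG", P1b = "ACCTAAGG",
                 H = "ACCTATGG", P2 = "AGGTATGG")
  q1 <- quartet_assignment("O", "P1a", "H", "P2")
  q2 <- quartet_assignment("O", c("P1a", "P1b"), "H", "P2")
  expect_equal(count_site_patterns(a3, q1)$counts,
               count_site_patterns(a3, q2)$counts)

  expect_error(quartet_assignment("O", "P1", "P1", "P2"), "disjoint")
  expect_error(quartet_assignment("O", character(0), "H", "P2"), "non-empty")
  expect_error(count_site_patterns(a0, quartet_assignment("O", "P1", "H", "X")),
               "absent")
})

test_that("pattern-count conservation on random gapped alignments", {
  set.seed(31)
  q <- quartet_assignment("O", "P1", "H", "P2")
  for (i in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 4 * 50, replace = TRUE,
                       prob = c(rep(0.2, 4), 0.1, 0.1)), 4, 50,
                dimnames = list(c("O", "P1", "H", "P2"), NULL))
    cc <- count_site_patterns(alignment(m), q)
    expect_equal(cc$n_sites_used + cc$n_sites_skipped, 50)
    expect_true(all(cc$counts >= 0))
  }
})

test_that("hils test: orientation, degeneracy and the swap identity", {
  # hybrid fully tracing P1, deep divergences: gamma_hat near 1
  tr <- parse_newick(
    "(((H:0.01,P1:0.01):0.05,P2:0.06):0.1,O:0.16);")
  a <- evolve_sequences(tr, substitution_model(), 50000, seed = 41)
  q <- quartet_assignment("O", "P1", "H", "P2")
  res <- hils_test(count_site_patterns(a, q))
  expect_gt(res$gamma, 0.9)
  expect_gt(res$z, 0)   # some AABB homoplasy excess exists but is small

  # no informative sites: flagged undefined, not zero
  a0 <- aln_from(O = strrep("A", 30), P1 = strrep("A", 30),
                 H = strrep("A", 30), P2 = strrep("A", 30))
  und <- hils_test(count_site_patterns(a0, q))
  expect_equal(und$flag, "undefined")
  expect_true(is.na(und$p))
  expect_false(und$significant)

  # swapping P1 and P2 maps gamma to 1 - gamma exactly
  set.seed(8)
  m <- matrix(sample(c("A", "C", "G", "T"), 4 * 400, replace = TRUE), 4, 400,
              dimnames = list(c("O", "P1", "H", "P2"), NULL))
  aln <- alignment(m)
  g12 <- hils_test(count_site_patterns(aln, q))$gamma_raw
  g21 <- hils_test(count_site_patterns(
    aln, quartet_assignment("O", "P2", "H", "P1")))$gamma_raw
  expect_equal(g12 + g21, 1, tolerance = 1e-9)
})

test_that("power is monotone in gamma and in site count", {
  # scaled-down power grid: a 4-taxon network, 40 gene blocks,
  # pooled sites 4k vs 16k, gamma 0.1 vs 0.5
  sp <- parse_newick("(((H:1.0,P1:1.0):5.0,P2:6.0):4.0,O:10.0);",
                     units = "coalescent")
  m <- species_tree_model(sp)
  q <- quartet_assignment("O", "P1", "H", "P2")
  zval <- function(gamma, sites_per_gene, seed) {
    ev <- hybrid_event("H", "P1", "P2", gamma, t1 = 1, t2 = 1)
    gts <- simulate_network_gene_tree(m, ev, seed = seed, n = 40)
    alns <- lapply(seq_along(gts), function(i)
      evolve_sequences(gts[[i]], substitution_model(), sites_per_gene,
                       seed = seed + i, subst_per_coal = 0.01))
    pooled <- concatenate_alignments(setNames(alns, paste0("g", 1:40)),
                                     c("O", "P1", "H", "P2"))
    hils_test(count_site_patterns(pooled$alignment, q,
                                  partitions = pooled$partitions))$z
  }
  z_lo_small <- zval(0.1, 100, 600)
  z_hi_small <- zval(0.5, 100, 700)
  z_lo_big <- zval(0.1, 400, 800)
  z_hi_big <- zval(0.5, 400, 900)
  expect_gt(z_hi_small, z_lo_small)
  expect_gt(z_hi_big, z_lo_big)
  expect_gt(z_hi_big, z_hi_small)
  expect_gt(z_lo_big, z_lo_small)
})

test_that("triple scan enumerates hybrid x unordered pairs", {
  set.seed(10)
  taxa <- c("O", "a", "b", "c", "d", "e")
  m <- matrix(sample(c("A", "C", "G", "T"), 6 * 300, replace = TRUE), 6, 300,
              dimnames = list(taxa, NULL))
  aln <- alignment(m)
  map <- data.frame(individual = taxa, taxon = taxa)
  res5 <- scan_triples(aln, map, "O")
  expect_equal(nrow(res5), 5 * choose(4, 2))
  expect_equal(attr(res5, "m_tests"), 30L)
  # each hybrid appears in choose(k-1, 2) tests; P1 < P2 lexicographically
  expect_true(all(table(res5$hybrid) == choose(4, 2)))
  expect_true(all(res5$p1 < res5$p2))

  res3 <- scan_triples(alignment(m[1:4, ]), map[1:4, ], "O")
  expect_equal(nrow(res3), 3L)

  # Bonferroni arithmetic: raw p = 0.01 with 10 tests is not significant
  expect_false(0.01 * 10 < 0.05)
  expect_equal(res5$p_adj, pmin(1, res5$p * 30))
})

test_that("node mode pools significant tests into a parent heatmap", {
  sp <- parse_newick("(((hyb,par1),par2),out);")
  mk_results <- function(df) {
    df$p_adj <- ifelse(df$significant, 0.001, 0.9)
    attr(df, "alpha") <- 0.05
    class(df) <- c("hyde_results", "data.frame")
    df
  }
  one <- mk_results(data.frame(p1 = "par1", hybrid = "hyb", p2 = "par2",
                               gamma = 0.7, significant = TRUE))
  nm <- node_mode(one, sp, "hyb")
  expect_equal(nm$mean["par1", "par2"], 0.7)
  expect_equal(nm$mean["par2", "par1"], 0.3)
  expect_equal(nm$sd["par1", "par2"], 0)
  expect_equal(nm$count["par1", "par2"], 1)
  expect_equal(nm$summary$gamma[nm$summary$parent == "par1"],
               sprintf("%.3f %s %.3f", 0.7, "±", 0))

  two <- mk_results(data.frame(p1 = c("par1", "par1"), hybrid = "hyb",
                               p2 = c("par2", "par2"), gamma = c(0.5, 0.7),
                               significant = TRUE))
  nm2 <- node_mode(two, sp, "hyb")
  expect_equal(nm2$mean["par1", "par2"], 0.6)
  expect_equal(nm2$count["par1", "par2"], 2)

  none <- mk_results(data.frame(p1 = "par1", hybrid = "hyb", p2 = "par2",
                                gamma = 0.7, significant = FALSE))
  expect_message(nm0 <- node_mode(none, sp, "hyb"), "no significant")
  expect_equal(sum(nm0$mask), 0)
})

test_that("null filter: no rejections means retained", {
  # strong designed positive on a quartet, nulls simulated on a clocklike tree
  sp <- parse_newick("(((H:1.0,P1:1.0):5.0,P2:6.0):4.0,O:10.0);",
                     units = "coalescent")
  m <- species_tree_model(sp)
  ev <- hybrid_event("H", "P1", "P2", 0.5, t1 = 1, t2 = 1)
  gts <- simulate_network_gene_tree(m, ev, seed = 55, n = 40)
  alns <- lapply(seq_along(gts), function(i)
    evolve_sequences(gts[[i]], substitution_model(), 300, seed = 100 + i,
                     subst_per_coal = 0.01))
  pooled <- concatenate_alignments(setNames(alns, paste0("g", 1:40)),
                                   c("O", "P1", "H", "P2"))
  map <- data.frame(individual = c("O", "P1", "H", "P2"),
                    taxon = c("O", "P1", "H", "P2"))
  res <- scan_triples(pooled$alignment, map, "O",
                      partitions = pooled$partitions)
  expect_true(any(res$significant))
  subst <- parse_newick("(((H:0.01,P1:0.01):0.05,P2:0.06):0.04,O:0.10);")
  nf <- null_hypothesis_filter(res, subst, substitution_model(),
                               n_replicates = 20, seed = 77)
  expect_true(all(nf$verdict == "retained"))
  expect_true(all(nf$null_rejection_fraction == 0))
  expect_error(null_hypothesis_filter(res, subst, substitution_model(),
                                      n_replicates = 5), ">= 20")
})
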