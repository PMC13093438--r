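test_that("newick parsing, supports and round trips", {
  tr <- parse_newick("(A:1,(B:1,C:1):0.5);")
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  expect_true(all(is.na(support_values(tr))))

  tr2 <- parse_newick("((A,B)100,C);")
  expect_equal(support_values(tr2)[2], 100)

  expect_warning(tr3 <- parse_newick("((A,B)0.95,C);"),
                 "rescaling")
  expect_equal(support_values(tr3)[2], 95)

  expect_error(parse_newick("((A,B,C);"), "parenthes")
  expect_error(parse_newick("((A,A),C);"), "duplicate.*A")

  # write-parse round trip preserves topology, lengths and supports
  for (s in 1:20) {
    t0 <- rand_tree(sample(5:12, 1), seed = 100 + s)
    t0$node.label <- as.character(sample(0:100, t0$Nnode, replace = TRUE))
    back <- parse_newick(write_newick(t0))
    expect_equal(rf_distance(t0, back), 0)
    expect_equal(sort(back$edge.length), sort(t0$edge.length), tolerance = 1e-8)
    expect_setequal(back$node.label, t0$node.label)
  }
})

test_that("bipartitions match brute-force edge enumeration", {
  quartet <- parse_newick("((A,B),(C,D));")
  expect_length(bipartitions(quartet), 1L)
  star <- parse_newick("(A,B,C,D,E);")
  expect_length(bipartitions(star), 0L)
  for (s in 1:10) {
    tr <- rand_tree(8, seed = 200 + s)
    expect_setequal(bipartitions(tr), bf_splits(tr))
  }
  # invariance under re-rooting
  tr <- rand_tree(9, seed = 33)
  rerooted <- root_with_outgroup(ape::unroot(tr), "t4")
  expect_setequal(bipartitions(tr), bipartitions(rerooted))
})

test_that("RF distance equals the brute-force symmetric difference", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, parse_newick("((A,B),(C,E));")), "differ")

  for (s in 1:100) {
    a <- rand_tree(8, seed = 300 + s)
    b <- rand_tree(8, seed = 700 + s)
    expect_equal(rf_distance(a, b), bf_rf(a, b))
    # cross-check against an independent mature implementation
    expect_equal(rf_distance(a, b), phangorn::RF.dist(a, b))
  }
})

test_that("RF is a metric on random trees", {
  trees <- lapply(1:15, function(s) rand_tree(8, seed = 1200 + s))
  for (i in 1:15) expect_equal(rf_distance(trees[[i]], trees[[i]]), 0)
  for (s in 1:50) {
    ijk <- sample(15, 3, replace = TRUE)
    a <- trees[[ijk[1]]]; b <- trees[[ijk[2]]]; c <- trees[[ijk[3]]]
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_lte(rf_distance(a, c), rf_distance(a, b) + rf_distance(b, c))
    expect_lte(rf_distance(a, b), 2 * (8 - 3))
  }
})

test_that("average bootstrap support", {
  tr <- parse_newick("(((A,B)100,(C,D)80)60,E);")
  expect_equal(average_bootstrap_support(tr), 80)
  expect_equal(average_bootstrap_support(parse_newick("((A,B)75,C);")), 75)
  expect_error(average_bootstrap_support(parse_newick("((A,B),C);")),
               "undefined")
  # invariant under leaf reordering
  tr2 <- parse_newick("(((B,A)100,(D,C)80)60,E);")
  expect_equal(average_bootstrap_support(tr2), average_bootstrap_support(tr))
})

test_that("collapse_low_support contracts exactly the weak edges", {
  tr <- parse_newick("(((A,B)40,(C,D)70)90,E);")
  expect_equal(rf_distance(collapse_low_support(tr, 0), tr), 0)

  all_star <- collapse_low_support(tr, 101)
  expect_length(bipartitions(all_star), 0L)

  one_gone <- collapse_low_support(tr, 50)
  # the support-40 edge subtends (A,B), whose canonical key is "C|D|E"
  expect_setequal(bipartitions(one_gone), setdiff(bipartitions(tr), "C|D|E"))
})

test_that("outgroup rooting", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,O:2):0.5);")
  r <- root_with_outgroup(tr, "O")
  expect_true(ape::is.rooted(r))
  expect_equal(rf_distance(r, tr), 0)   # unrooted-equivalence
  # 4-taxon pendant-edge case
  q <- parse_newick("(A:1,B:1,(C:1,O:1):1);")
  rq <- root_with_outgroup(q, "O")
  og_edge <- rq$edge[, 2] == which(rq$tip.label == "O")
  expect_true(ape::is.rooted(rq))
  # non-monophyletic outgroup errors and names intruders
  bad <- parse_newick("(((A,O1),B),(O2,C));")
  expect_error(root_with_outgroup(bad, c("O1", "O2")), "monophyletic")
})

test_that("NJ fallback recovers clean signal with full support", {
  tre <- parse_newick(
    "(((A:0.02,B:0.02):0.3,(C:0.02,D:0.02):0.3):0.3,(E:0.02,F:0.02):0.3);")
  aln <- evolve_sequences(tre, substitution_model(), 4000, seed = 5)
  rec <- estimate_gene_tree_nj(aln, n_bootstrap = 50, seed = 6)
  expect_equal(rf_distance(rec$tree, tre), 0)
  expect_equal(rec$abs, 100)
  expect_true(all(support_values(rec$tree) == 100, na.rm = TRUE))
  # deterministic given seed
  rec2 <- estimate_gene_tree_nj(aln, n_bootstrap = 50, seed = 6)
  expect_identical(write_newick(rec$tree), write_newick(rec2$tree))

  # identical sequences produce a zero-length cherry
  a2 <- aln_from(A = "ACGTACGTAA", B = "ACGTACGTAA", C = "AATTAATTGG",
                 D = "GGTTGGTTAA")
  tr2 <- suppressWarnings(estimate_gene_tree_nj(a2, n_bootstrap = 5, seed = 1))$tree
  d <- ape::cophenetic.phylo(tr2)
  expect_equal(unname(d["A", "B"]), 0)

  # saturated pairs are capped with a warning
  sat <- aln_from(A = strrep("A", 40), B = strrep("C", 40),
                  C = strrep("G", 40), D = strrep("T", 40))
  expect_warning(estimate_gene_tree_nj(sat, n_bootstrap = 2, seed = 1),
                 "saturated")
})
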