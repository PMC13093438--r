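test_that("species_tree_model validates units and branch lengths", {
  sub_tree <- parse_newick("((A:1,B:1):1,C:2);")   # substitution units
  expect_error(species_tree_model(sub_tree), "coalescent")
  coal <- parse_newick("((A:1,B:1):1,C:2);", units = "coalescent")
  m <- species_tree_model(coal)
  expect_s3_class(m, "species_tree_model")
  # missing terminal branch lengths are defaulted with a warning
  na_tree <- coal
  na_tree$edge.length[na_tree$edge[, 2] <= 3] <- NA
  expect_warning(m2 <- species_tree_model(na_tree), "terminal")
  expect_true(all(!is.na(m2$tree$edge.length)))
})

test_that("MSC simulation is deterministic and respects species divergences", {
  m <- species_tree_model(parse_newick("((A:1,B:1):1,C:2);",
                                       units = "coalescent"))
  g1 <- simulate_gene_tree(m, seed = 11)
  g2 <- simulate_gene_tree(m, seed = 11)
  expect_identical(write_newick(g1), write_newick(g2))
  expect_identical(attr(g1, "units"), "coalescent")

  # gene-tree coalescence of any pair is never younger than the species
  # divergence it crosses
  sims <- simulate_gene_tree(m, seed = 12, n = 200)
  for (g in sims) {
    d <- ape::cophenetic.phylo(g) / 2   # pairwise coalescence times
    expect_gte(d["A", "B"], 1 - 1e-9)
    expect_gte(d["A", "C"], 2 - 1e-9)
    expect_gte(d["B", "C"], 2 - 1e-9)
  }
})

test_that("MSC topology frequencies match the coalescent closed form", {
  # scaled-down version of the analytic acceptance check (2,000 draws)
  m <- species_tree_model(parse_newick("((A:1,B:1):1,C:2);",
                                       units = "coalescent"))
  sims <- simulate_gene_tree(m, seed = 77, n = 2000)
  conc <- mean(vapply(sims, has_cherry, logical(1), a = "A", b = "B"))
  expect_equal(conc, 1 - (2 / 3) * exp(-1), tolerance = 0.05)

  # t -> large: complete lineage sorting
  deep <- species_tree_model(parse_newick("((A:1,B:1):20,C:21);",
                                          units = "coalescent"))
  sims_deep <- simulate_gene_tree(deep, seed = 78, n = 1000)
  expect_equal(mean(vapply(sims_deep, has_cherry, logical(1), "A", "B")), 1)
})

test_that("hybrid_event validation", {
  expect_error(hybrid_event("h", "p1", "p2", 1.2), "0, 1")
  expect_error(hybrid_event("h", "p1", "p1", 0.5), "distinct")
  expect_error(hybrid_event("p1", "p1", "p2", 0.5), "own parent")
  ev <- hybrid_event("h", "p1", "p2", 0.4)
  expect_s3_class(ev, "hybrid_event")
})

test_that("network MSC reduces to tree MSC at gamma 0 and 1", {
  sp <- parse_newick("(((hyb:1.0,par1:1.0):5.0,par2:6.0):4.0,out:10.0);",
                     units = "coalescent")
  m <- species_tree_model(sp)
  n <- 1500
  g1 <- simulate_network_gene_tree(m, hybrid_event("hyb", "par1", "par2", 1,
                                                   t1 = 1, t2 = 1),
                                   seed = 21, n = n)
  f1 <- mean(vapply(g1, has_cherry, logical(1), "hyb", "par1"))
  # attachment at age 1, parent divergence 6: P(coalesce in stem) = 1-e^-5
  expect_equal(f1, 1 - exp(-5), tolerance = 0.03)
  expect_equal(mean(vapply(g1, has_cherry, logical(1), "hyb", "par2")), 0,
               tolerance = 0.02)

  g0 <- simulate_network_gene_tree(m, hybrid_event("hyb", "par1", "par2", 0,
                                                   t1 = 1, t2 = 1),
                                   seed = 22, n = n)
  expect_equal(mean(vapply(g0, has_cherry, logical(1), "hyb", "par2")),
               1 - exp(-5), tolerance = 0.03)

  # gamma = 0.5 with symmetric attachments: the two sister frequencies agree
  gh <- simulate_network_gene_tree(m, hybrid_event("hyb", "par1", "par2", 0.5,
                                                   t1 = 1, t2 = 1),
                                   seed = 23, n = 3000)
  fa <- mean(vapply(gh, has_cherry, logical(1), "hyb", "par1"))
  fb <- mean(vapply(gh, has_cherry, logical(1), "hyb", "par2"))
  p <- (1 - exp(-5)) / 2
  sigma3 <- 3 * sqrt(p * (1 - p) / 3000)
  expect_lt(abs(fa - p), sigma3)
  expect_lt(abs(fb - p), sigma3)

  expect_error(simulate_network_gene_tree(m, hybrid_event("x", "par1", "par2",
                                                          0.5), seed = 1),
               "not in species tree")
})

test_that("multiple sampled individuals coalesce within their taxon", {
  m <- species_tree_model(parse_newick("((A:2,B:2):1,C:3);",
                                       units = "coalescent"))
  g <- simulate_gene_tree(m, individuals_per_taxon = list(A = 3), seed = 9)
  expect_setequal(g$tip.label, c("A_1", "A_2", "A_3", "B", "C"))
})
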