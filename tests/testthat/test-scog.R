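make_table <- function(presence) {
  orthogroup_table(presence)
}

test_that("occupancy filter reproduces the printed cutoff and a recount", {
  # 47 samples at 70%: floor(32.9) = 32, the protocol's printed threshold
  pres <- matrix(TRUE, 3, 47, dimnames = list(paste0("g", 1:3), paste0("s", 1:47)))
  pres["g1", 1:16] <- FALSE   # present in 31 -> dropped
  pres["g2", 1:15] <- FALSE   # present in 32 -> kept
  tab <- make_table(pres)
  expect_message(kept <- filter_by_occupancy(tab, 0.7), ">= 32 of 47")
  expect_setequal(rownames(kept), c("g2", "g3"))

  # gene present everywhere is always retained; brute-force recount
  set.seed(42)
  pres2 <- matrix(runif(10 * 20) < 0.6, 10, 20,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  pres2[1, ] <- TRUE
  tab2 <- make_table(pres2)
  for (f in c(0.3, 0.5, 0.9)) {
    kept2 <- suppressMessages(filter_by_occupancy(tab2, f))
    expect_setequal(rownames(kept2),
                    rownames(pres2)[rowSums(pres2) >= floor(f * 20)])
    expect_true("g1" %in% rownames(kept2))
  }
  expect_warning(suppressMessages(
    filter_by_occupancy(make_table(pres2[0, , drop = FALSE]), 0.7)), "empty")
})

test_that("orthogroup tables round-trip through the TSV layout", {
  set.seed(7)
  pres <- matrix(runif(6 * 5) < 0.7, 6, 5,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  tab <- make_table(pres)
  f <- tempfile(fileext = ".tsv")
  write_orthogroups(tab, f)
  back <- read_orthogroups(f)
  expect_equal(unclass(back)[, ], unclass(tab)[, ])
})

test_that("organellar k-mer screen", {
  set.seed(1)
  ref <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  inside <- substr(ref, 501, 900)                   # verbatim substring
  random <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  chimera <- paste0(substr(ref, 1001, 1200),
                    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                          collapse = ""))
  genes <- c(plastid_like = inside, nuclear = random, mixed = chimera)
  res <- screen_organellar(genes, ref, k = 21, min_shared_frac = 0.5)
  expect_true("plastid_like" %in% res$removed)
  expect_true("nuclear" %in% res$kept)
  expect_equal(res$report$shared_frac[res$report$gene == "plastid_like"], 1)
  expect_lt(res$report$shared_frac[res$report$gene == "nuclear"], 0.01)

  # chimera: brute-force k-mer intersection oracle
  km <- substring(chimera, 1:(nchar(chimera) - 20), 21:nchar(chimera))
  refkm <- substring(ref, 1:(nchar(ref) - 20), 21:nchar(ref))
  expect_equal(res$report$shared_frac[res$report$gene == "mixed"],
               mean(unique(km) %in% refkm))
  expect_warning(screen_organellar(c(short = "ACGT"), ref, k = 21), "shorter")
  expect_error(screen_organellar(genes, character(0)), "reference")
})

test_that("column missing-data filter uses the strict > rule", {
  rows <- c(paste0(strrep("A", 12)), paste0(strrep("C", 12)))
  m <- matrix("A", 10, 10, dimnames = list(paste0("t", 1:10), NULL))
  m[1:2, 1] <- "-"   # exactly 20% missing: kept (rule is strictly >)
  m[1:3, 2] <- "-"   # 30%: removed
  m[, 3] <- "-"      # all gap: removed
  a <- alignment(m)
  out <- filter_alignment_columns(a, 0.2)
  expect_equal(attr(out, "kept_columns"), c(1L, 4:10))
  expect_identical(unclass(out)[, 1], unclass(a)[, 1])  # columns verbatim

  # 8x12 manual fixture with known per-column gap counts
  set.seed(9)
  mm <- matrix(sample(c("A", "C", "G", "T"), 96, replace = TRUE), 8, 12,
               dimnames = list(paste0("x", 1:8), NULL))
  gaps <- c(0, 1, 2, 3, 4, 5, 0, 8, 2, 1, 3, 0)
  for (j in 1:12) if (gaps[j] > 0) mm[seq_len(gaps[j]), j] <- "-"
  out2 <- filter_alignment_columns(alignment(mm), 0.25)
  expect_equal(attr(out2, "kept_columns"), which(gaps / 8 <= 0.25))
  expect_warning(filter_alignment_columns(alignment(matrix("-", 4, 2,
    dimnames = list(letters[1:4], NULL))), 0.2), "all columns")
})

test_that("length classes are non-disjoint >= threshold sets", {
  lens <- c(g1 = 500, g2 = 1500, g3 = 2500, g4 = 999, g5 = 2000)
  alns <- lapply(lens, function(L)
    alignment(matrix("A", 2, L, dimnames = list(c("a", "b"), NULL))))
  cls <- partition_by_length(alns, c(1000, 2000))
  expect_setequal(names(cls[["1000"]]), c("g2", "g3", "g5"))
  expect_setequal(names(cls[["2000"]]), c("g3", "g5"))
  expect_true("g2" %in% names(cls[["1000"]]) && !"g2" %in% names(cls[["2000"]]))
  expect_setequal(names(partition_by_length(alns, 1)[["1"]]), names(lens))
  set.seed(4)
  rl <- sample(100:3000, 30); names(rl) <- paste0("r", 1:30)
  ral <- lapply(rl, function(L)
    alignment(matrix("A", 2, L, dimnames = list(c("a", "b"), NULL))))
  expect_equal(lengths(partition_by_length(ral, c(500, 1500))),
               c("500" = sum(rl >= 500), "1500" = sum(rl >= 1500)))
  expect_error(partition_by_length(alns, c(2000, 1000)), "ascending")
})

test_that("ABS filter is strictly greater-than", {
  recs <- lapply(c(55, 61, 60), function(v)
    gene_tree_record(paste0("g", v), NULL, v, 100))
  kept <- filter_by_abs(recs, 60)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$abs, 61)
  # the rule is strictly "exceeding": ABS = 100 survives any threshold < 100
  expect_length(filter_by_abs(list(gene_tree_record("g", NULL, 100, 1)), 99.9), 1L)
})

test_that("long-branch flagging", {
  eq <- gene_tree_record("eq", parse_newick("((A:1,B:1):1,(C:1,D:1):1);"), 90, 10)
  expect_length(flag_long_branches(eq, factor = 1.5)$flagged, 0L)

  lb <- gene_tree_record("lb",
    parse_newick("((A:10,B:1):1,(C:1,D:1):1);"), 90, 10)
  fl <- flag_long_branches(lb, factor = 5)
  expect_equal(fl$flagged, "A")
  expect_warning(out <- flag_long_branches(lb, factor = 5, prune = TRUE),
                 "fewer than 4")
  expect_null(out$record)
})

test_that("supermatrix concatenation", {
  a1 <- aln_from(A = "ACG", B = "CCG", C = "GGG")
  a2 <- aln_from(A = "TTTTT", B = "AAAAA", D = "CCCCC")
  sm <- concatenate_alignments(list(g1 = a1, g2 = a2), c("A", "B", "C", "D"))
  expect_equal(sm$partitions$start, c(1L, 4L))
  expect_equal(sm$partitions$end, c(3L, 8L))
  expect_equal(paste(unclass(sm$alignment)["C", ], collapse = ""), "GGG?????")
  expect_equal(paste(unclass(sm$alignment)["D", ], collapse = ""), "???CCCCC")
  # string-join oracle on the shared taxa
  expect_equal(paste(unclass(sm$alignment)["A", ], collapse = ""), "ACGTTTTT")
  one <- concatenate_alignments(list(solo = a1), c("A", "B", "C"))
  expect_identical(unclass(one$alignment)[, ], unclass(a1)[, ])
  expect_error(concatenate_alignments(setNames(list(a1, a1), c("g", "g")),
                                      c("A", "B", "C")), "unique")
  f <- tempfile()
  write_partitions(sm$partitions, f)
  expect_equal(readLines(f), c("DNA, g1 = 1-3", "DNA, g2 = 4-8"))
})

test_that("filters are idempotent and commute pairwise", {
  set.seed(12)
  m <- matrix(sample(c("A", "C", "G", "T", "-"), 8 * 40, replace = TRUE,
                     prob = c(rep(0.22, 4), 0.12)), 8, 40,
              dimnames = list(paste0("t", 1:8), NULL))
  a <- alignment(m)
  once <- filter_alignment_columns(a, 0.2)
  twice <- filter_alignment_columns(once, 0.2)
  expect_identical(unclass(once)[, ], unclass(twice)[, ])

  pres <- matrix(runif(12 * 10) < 0.7, 12, 10,
                 dimnames = list(paste0("g", 1:12), paste0("s", 1:10)))
  tab <- make_table(pres)
  f1 <- suppressWarnings(suppressMessages(filter_by_occupancy(tab, 0.6)))
  f2 <- suppressWarnings(suppressMessages(filter_by_occupancy(f1, 0.6)))
  expect_identical(rownames(f1), rownames(f2))

  # occupancy and ABS filters commute (they act on disjoint attributes)
  recs <- lapply(seq_len(nrow(pres)), function(i)
    gene_tree_record(rownames(pres)[i], NULL, 40 + 5 * i, 100))
  names(recs) <- rownames(pres)
  keep_abs_then_occ <- intersect(
    vapply(filter_by_abs(recs, 60), `[[`, character(1), "gene_id"),
    rownames(f1))
  keep_occ_then_abs <- vapply(
    filter_by_abs(recs[intersect(names(recs), rownames(f1))], 60),
    `[[`, character(1), "gene_id")
  expect_setequal(keep_abs_then_occ, keep_occ_then_abs)
})
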