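# independent oracles and small fixture builders used across test files;
# deliberately written with different machinery than the package internals

# random resolved tree with branch lengths, deterministic by seed
rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  attr(tr, "units") <- "substitution"
  tr
}

# brute-force nontrivial splits of a tree: drop each edge from the edge list
# and flood-fill connected components of the remaining graph
bf_splits <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  edges <- tree$edge
  keys <- character(0)
  for (e in seq_len(nrow(edges))) {
    rest <- edges[-e, , drop = FALSE]
    # flood fill from one endpoint
    comp <- edges[e, 2]
    repeat {
      nb <- unique(c(rest[rest[, 1] %in% comp, 2], rest[rest[, 2] %in% comp, 1]))
      grown <- union(comp, nb)
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    block <- tree$tip.label[intersect(comp, seq_len(nt))]
    if (length(block) < 2 || length(block) > nt - 2) next
    other <- setdiff(tree$tip.label, block)
    first <- sort(tree$tip.label)[1]
    if (first %in% block) block <- other
    keys <- c(keys, paste(sort(block), collapse = "|"))
  }
  unique(keys)
}

# brute-force RF: symmetric difference of brute-force split sets
bf_rf <- function(t1, t2) {
  s1 <- bf_splits(t1); s2 <- bf_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# brute-force split compatibility on a shared taxon set
bf_compatible <- function(key1, key2, labels) {
  b1 <- strsplit(key1, "|", fixed = TRUE)[[1]]
  b2 <- strsplit(key2, "|", fixed = TRUE)[[1]]
  any(c(length(intersect(b1, b2)),
        length(intersect(b1, setdiff(labels, b2))),
        length(intersect(setdiff(labels, b1), b2)),
        length(intersect(setdiff(labels, b1), setdiff(labels, b2)))) == 0)
}

# brute-force concordance classification of one gene tree at one species
# split: "concordant", "conflict" or "uninformative"
bf_classify <- function(sp_key, gene_tree, sp_labels) {
  gtaxa <- gene_tree$tip.label
  blk <- intersect(strsplit(sp_key, "|", fixed = TRUE)[[1]], gtaxa)
  rest <- setdiff(gtaxa, blk)
  if (length(blk) < 2 || length(rest) < 2) return("uninformative")
  first <- sort(gtaxa)[1]
  rkey <- paste(sort(if (first %in% blk) rest else blk), collapse = "|")
  gkeys <- bf_splits(gene_tree)
  if (rkey %in% gkeys) return("concordant")
  for (k in gkeys) if (!bf_compatible(k, rkey, gtaxa)) return("conflict")
  "uninformative"
}

# is a rooted 3+-taxon tree displaying (a,b) as a cherry?
has_cherry <- function(tree, a, b) {
  nt <- length(tree$tip.label)
  for (v in unique(tree$edge[, 1])) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    if (all(kids <= nt) && length(kids) == 2 &&
        setequal(tree$tip.label[kids], c(a, b))) return(TRUE)
  }
  FALSE
}

# alignment from a named character vector of strings
aln_from <- function(...) alignment(c(...))

# small GTR-free model for fast sequence simulation in tests
jc_model <- function(...) substitution_model(...)
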