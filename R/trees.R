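#' Newick parsing and writing
#'
#' Trees are `ape` `phylo` objects. Numeric internal-node labels are
#' interpreted as support values on a 0-100 scale; labels that all fall in
#' \[0,1\] are rescaled to \[0,100\] with a warning. A tree-level `units`
#' attribute tracks whether branch lengths are in substitutions/site or
#' coalescent units.
#'
#' @param text a Newick string.
#' @param units branch-length units tag, `"substitution"` or `"coalescent"`.
#' @return a `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1)95:0.5,C:1.5);")
#' average_bootstrap_support(tr)
#' @export
parse_newick <- function(text, units = "substitution") {
  text <- trimws(text)
  no <- nchar(gsub("[^(]", "", text))
  nc <- nchar(gsub("[^)]", "", text))
  if (no != nc)
    stopf("unbalanced parentheses in Newick ('(' x %d vs ')' x %d)", no, nc)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stopf("could not parse Newick string")
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate leaf label(s): %s",
          paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0, na.rm = TRUE))
    stopf("negative branch length in input tree")
  tr <- normalize_supports(tr)
  attr(tr, "units") <- units
  tr
}

normalize_supports <- function(tr) {
  sv <- support_values(tr)
  ok <- !is.na(sv)
  if (any(ok) && all(sv[ok] >= 0 & sv[ok] <= 1) && any(sv[ok] < 1)) {
    warnf("internal-node supports look like proportions; rescaling [0,1] -> [0,100]")
    tr$node.label[ok] <- format(sv[ok] * 100, trim = TRUE)
  }
  tr
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(file)
}

#' Support values of internal nodes
#'
#' Numeric internal-node labels parsed as supports (0-100); `NA` where a node
#' carries no (or a non-numeric) label.
#'
#' @param tree a `phylo` object.
#' @return numeric vector of length `tree$Nnode`.
#' @export
support_values <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Mean bootstrap support across internal nodes (ABS)
#'
#' The per-gene-tree reliability statistic: the arithmetic mean of the
#' bootstrap values over internal nodes that carry one; unsupported nodes are
#' excluded from numerator and denominator. Used to keep only gene trees with
#' ABS strictly above a threshold (60 in the reference protocol).
#'
#' @param tree a `phylo` object with numeric internal-node labels.
#' @return a single numeric value in \[0, 100\].
#' @export
average_bootstrap_support <- function(tree) {
  sv <- support_values(tree)
  if (all(is.na(sv)))
    stopf("no internal node carries a support value; ABS is undefined")
  mean(sv, na.rm = TRUE)
}

# ---- bipartition algebra ----------------------------------------------------

# logical matrix (rows = nodes incl. tips, cols = tips): which tips descend
# from each node
descendant_tips <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  m <- matrix(FALSE, nn, nt)
  m[cbind(seq_len(nt), seq_len(nt))] <- TRUE
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1]; c <- eo$edge[i, 2]
    m[p, ] <- m[p, ] | m[c, ]
  }
  colnames(m) <- tree$tip.label
  m
}

# canonical key of one block of a bipartition over `labels`: the block NOT
# containing the lexicographically first taxon, sorted, joined by "|"
split_key <- function(block, labels) {
  first <- sort(labels)[1]
  if (first %in% block) block <- setdiff(labels, block)
  paste(sort(block), collapse = "|")
}

# internal: data.frame(node, key) of nontrivial bipartitions, one per internal
# edge (deduplicated; on a rooted binary tree the two root edges coincide)
bipartition_table <- function(tree) {
  nt <- length(tree$tip.label)
  labels <- tree$tip.label
  if (nt < 4)
    return(data.frame(node = integer(), key = character(),
                      stringsAsFactors = FALSE))
  m <- descendant_tips(tree)
  internal <- (nt + 1):(nt + tree$Nnode)
  keys <- character(0); nodes <- integer(0)
  for (v in internal) {
    blk <- labels[m[v, ]]
    if (length(blk) < 2 || length(blk) > nt - 2) next
    k <- split_key(blk, labels)
    if (!k %in% keys) { keys <- c(keys, k); nodes <- c(nodes, v) }
  }
  data.frame(node = nodes, key = keys, stringsAsFactors = FALSE)
}

#' Nontrivial bipartitions of a tree
#'
#' One canonical bipartition key per internal edge of the unrooted topology;
#' trivial splits (blocks of size < 2) are excluded. The key is the sorted,
#' `|`-joined block that does not contain the alphabetically first taxon.
#'
#' @param tree a `phylo` object.
#' @return character vector of canonical split keys (possibly empty).
#' @export
bipartitions <- function(tree) bipartition_table(tree)$key

# are two splits (keys over the same taxon set) compatible?
splits_compatible <- function(key1, key2, labels) {
  b1 <- strsplit(key1, "|", fixed = TRUE)[[1]]
  b2 <- strsplit(key2, "|", fixed = TRUE)[[1]]
  c1 <- setdiff(labels, b1); c2 <- setdiff(labels, b2)
  length(intersect(b1, b2)) == 0 || length(intersect(b1, c2)) == 0 ||
    length(intersect(c1, b2)) == 0 || length(intersect(c1, c2)) == 0
}

#' Robinson-Foulds distance
#'
#' Unweighted RF distance: the size of the symmetric difference between the
#' two trees' sets of nontrivial bipartitions (unrooted topologies;
#' polytomies contribute only the bipartitions they actually display).
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return a non-negative integer, at most `2 * (n - 3)`.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stopf("leaf sets differ (only in t1: %s; only in t2: %s)",
          paste(only1, collapse = ",") , paste(only2, collapse = ","))
  }
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# ---- tree surgery -----------------------------------------------------------

# recursive newick builder from a children-list representation
build_newick <- function(children, labels, bl, supports, node, root) {
  kids <- children[[node]]
  if (length(kids) == 0) {
    s <- labels[node]
  } else {
    inner <- vapply(kids, function(k)
      build_newick(children, labels, bl, supports, k, root), character(1))
    lab <- if (!is.na(supports[node])) supports[node] else ""
    s <- paste0("(", paste(inner, collapse = ","), ")", lab)
  }
  if (node != root && !is.na(bl[node]))
    s <- paste0(s, ":", format(bl[node], digits = 12, trim = TRUE, scientific = FALSE))
  s
}

#' Collapse poorly supported edges into polytomies
#'
#' Internal edges whose (child-node) support is strictly below `threshold`
#' are contracted; a missing support counts as 0. Branch lengths of the
#' surviving edges are unchanged.
#'
#' @param tree a `phylo` object with supports as internal-node labels.
#' @param threshold support cutoff on the 0-100 scale.
#' @return a `phylo` object (possibly multifurcating).
#' @export
collapse_low_support <- function(tree, threshold) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  parent <- integer(nn); parent[root] <- NA_integer_
  bl <- rep(NA_real_, nn)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    if (!is.null(tree$edge.length)) bl[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  sv <- support_values(tree)
  supp <- rep(NA_real_, nn); supp[(nt + 1):nn] <- sv
  supp_lab <- rep(NA_character_, nn)
  if (!is.null(tree$node.label)) supp_lab[(nt + 1):nn] <- tree$node.label
  drop <- rep(FALSE, nn)
  for (v in (nt + 1):nn) {
    if (v == root) next
    s <- supp[v]; if (is.na(s)) s <- 0
    if (s < threshold) drop[v] <- TRUE
  }
  # reattach children of dropped nodes to nearest kept ancestor
  eff_parent <- parent
  for (v in seq_len(nn)) {
    if (v == root) next
    p <- parent[v]
    while (!is.na(p) && p != root && drop[p]) p <- parent[p]
    eff_parent[v] <- p
  }
  keep <- !drop
  children <- vector("list", nn)
  for (v in seq_len(nn)) {
    if (v == root || !keep[v]) next
    p <- eff_parent[v]
    children[[p]] <- c(children[[p]], v)
  }
  labels <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  txt <- paste0(build_newick(children, labels, bl, supp_lab, root, root), ";")
  out <- ape::read.tree(text = txt)
  attr(out, "units") <- attr(tree, "units")
  out
}

#' Root a tree on the edge separating an outgroup
#'
#' @param tree a `phylo` object.
#' @param outgroup character vector of outgroup taxa, present in the tree and
#'   monophyletic in the unrooted sense.
#' @return a rooted `phylo` object.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stopf("outgroup taxa not in tree: %s", paste(missing, collapse = ", "))
  nt <- length(tree$tip.label)
  if (length(outgroup) > 1 && nt - length(outgroup) > 1) {
    key <- split_key(outgroup, tree$tip.label)
    if (!key %in% bipartitions(tree)) {
      utree <- ape::unroot(tree)
      rt <- ape::root(utree, outgroup = outgroup[1], resolve.root = TRUE)
      node <- ape::getMRCA(rt, outgroup)
      clade <- rt$tip.label[descendant_tips(rt)[node, ]]
      stopf("outgroup is not monophyletic; intruding taxa: %s",
            paste(setdiff(clade, outgroup), collapse = ", "))
    }
  }
  out <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  attr(out, "units") <- attr(tree, "units")
  out
}

# ---- depths / ultrametric utilities ----------------------------------------

# age of every node = max path length to a descendant tip
node_ages <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  ages <- numeric(nn)
  eo <- ape::reorder.phylo(tree, "postorder")
  el <- eo$edge.length %||% rep(1, nrow(eo$edge))
  for (i in seq_len(nrow(eo$edge))) {
    p <- eo$edge[i, 1]; c <- eo$edge[i, 2]
    ages[p] <- max(ages[p], ages[c] + el[i])
  }
  ages
}

# proportional-depth ultrametricization: node age := max path to tip,
# then rescale to unit root height
make_ultrametric_unit <- function(tree) {
  ages <- node_ages(tree)
  root <- length(tree$tip.label) + 1L
  h <- ages[root]
  if (h <= 0) stopf("tree has zero depth; cannot rescale")
  out <- tree
  out$edge.length <- (ages[tree$edge[, 1]] - ages[tree$edge[, 2]]) / h
  # terminal ages forced to zero
  nt <- length(tree$tip.label)
  tipedge <- tree$edge[, 2] <= nt
  out$edge.length[tipedge] <- ages[tree$edge[tipedge, 1]] / h
  out
}
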