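#' Per-node concordance accounting of gene trees against a species tree
#'
#' For every nontrivial species-tree bipartition, each gene tree is counted
#' as concordant (after restriction to the shared taxa it displays the
#' bipartition), conflicting (it displays a bipartition incompatible with
#' it), or uninformative (after collapsing gene-tree edges with support
#' below `support_collapse`, it displays neither; also gene trees sharing
#' fewer than 4 taxa with the bipartition's tree). The most common
#' conflicting bipartition is tracked separately, giving the four-way
#' pie-chart decomposition used in PhyParts-style plots.
#'
#' @param species a rooted species tree (`phylo`).
#' @param genes list of `gene_tree_record`s or `phylo` objects; leaf sets
#'   must be subsets of the species leaf set.
#' @param support_collapse gene-tree support threshold below which edges are
#'   collapsed before classification (default 50; 0 disables).
#' @return a `concordance_summary`: data frame with one row per species-tree
#'   internal node (`node`, `key`, `n_concordant`, `n_top_conflict`,
#'   `top_conflict_key`, `n_other_conflict`, `n_uninformative`, `total`).
#' @export
map_concordance <- function(species, genes, support_collapse = 50) {
  trees <- lapply(genes, function(g) if (inherits(g, "gene_tree_record")) g$tree else g)
  bad <- vapply(trees, function(t) length(setdiff(t$tip.label, species$tip.label)) > 0,
                logical(1))
  if (any(bad)) stopf("%d gene tree(s) contain taxa absent from the species tree",
                      sum(bad))
  sp_tab <- bipartition_table(species)
  n_nodes <- nrow(sp_tab)
  total <- length(trees)
  out <- data.frame(node = sp_tab$node, key = sp_tab$key,
                    n_concordant = 0L, n_top_conflict = 0L,
                    top_conflict_key = NA_character_, n_other_conflict = 0L,
                    n_uninformative = 0L, total = total,
                    stringsAsFactors = FALSE)
  conflict_tally <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) conflict_tally[[i]] <- list()
  warned <- FALSE
  for (g in trees) {
    gt <- if (support_collapse > 0 && !is.null(g$node.label))
      collapse_low_support(g, support_collapse) else g
    gtaxa <- gt$tip.label
    if (length(gtaxa) < 4) {
      if (!warned) {
        warnf("gene tree(s) with < 4 taxa counted uninformative at every node")
        warned <- TRUE
      }
      out$n_uninformative <- out$n_uninformative + 1L
      next
    }
    gsup <- support_values(gt)
    gtab <- bipartition_table(gt)
    gkeys <- gtab$key
    gsupport <- gsup[gtab$node - length(gt$tip.label)]
    for (i in seq_len(n_nodes)) {
      blk <- strsplit(sp_tab$key[i], "|", fixed = TRUE)[[1]]
      b_in <- intersect(blk, gtaxa)
      b_out <- setdiff(gtaxa, b_in)
      if (length(b_in) < 2 || length(b_out) < 2) {
        out$n_uninformative[i] <- out$n_uninformative[i] + 1L
        next
      }
      rkey <- split_key(b_in, gtaxa)
      if (rkey %in% gkeys) {
        out$n_concordant[i] <- out$n_concordant[i] + 1L
        next
      }
      incompat <- !vapply(gkeys, splits_compatible, logical(1),
                          key2 = rkey, labels = gtaxa)
      if (any(incompat)) {
        # the gene's single representative conflicting split: highest
        # support, ties broken lexicographically
        cand <- gkeys[incompat]
        cs <- gsupport[incompat]
        cs[is.na(cs)] <- -1
        pick <- cand[order(-cs, cand)][1]
        conflict_tally[[i]][[pick]] <- (conflict_tally[[i]][[pick]] %||% 0L) + 1L
      } else {
        out$n_uninformative[i] <- out$n_uninformative[i] + 1L
      }
    }
  }
  for (i in seq_len(n_nodes)) {
    tal <- unlist(conflict_tally[[i]])
    if (is.null(tal) || !length(tal)) next
    top <- order(-tal, names(tal))[1]
    out$n_top_conflict[i] <- tal[top]
    out$top_conflict_key[i] <- names(tal)[top]
    out$n_other_conflict[i] <- sum(tal) - tal[top]
  }
  stopifnot(all(out$n_concordant + out$n_top_conflict + out$n_other_conflict +
                out$n_uninformative == out$total))
  class(out) <- c("concordance_summary", "data.frame")
  out
}

#' Pie-chart fractions from a concordance summary
#'
#' @param summary a `concordance_summary`.
#' @return data frame with per-node fractions (`f_concordant`,
#'   `f_top_conflict`, `f_other_conflict`, `f_uninformative`) summing to 1.
#' @export
pie_fractions <- function(summary) {
  if (any(summary$total <= 0)) stopf("concordance summary has zero total")
  out <- data.frame(node = summary$node, key = summary$key,
                    f_concordant = summary$n_concordant / summary$total,
                    f_top_conflict = summary$n_top_conflict / summary$total,
                    f_other_conflict = summary$n_other_conflict / summary$total,
                    f_uninformative = summary$n_uninformative / summary$total,
                    stringsAsFactors = FALSE)
  stopifnot(all(abs(rowSums(out[, 3:6]) - 1) < 1e-12))
  out
}

#' Prepare gene trees for a cloud-tree plot
#'
#' Only gene trees carrying the full taxon set are eligible; each is made
#' ultrametric by proportional depth adjustment (node age = maximum path to
#' a descendant tip) and scaled to unit root height. This replaces formal
#' time calibration: the cloud plot is qualitative.
#'
#' @param genes list of `gene_tree_record`s or `phylo` objects.
#' @param taxa the full taxon set required for eligibility.
#' @return list with `trees` (a `multiPhylo` of unit-height ultrametric
#'   trees) and `excluded` (names/indices of ineligible trees).
#' @export
prepare_cloud_trees <- function(genes, taxa) {
  trees <- lapply(genes, function(g) if (inherits(g, "gene_tree_record")) g$tree else g)
  eligible <- vapply(trees, function(t) setequal(t$tip.label, taxa), logical(1))
  scaled <- lapply(trees[eligible], make_ultrametric_unit)
  if (length(scaled))
    scaled <- structure(scaled, class = "multiPhylo")
  message(sprintf("cloud trees: %d of %d gene trees carry the full taxon set",
                  sum(eligible), length(trees)))
  list(trees = scaled, excluded = which(!eligible))
}

#' Reduce a tree to one representative individual per taxon
#'
#' Tree-level analyses (concordance, distance distributions) operate on one
#' tip per taxon; this keeps the alphabetically first individual of each
#' taxon and renames it to the taxon label.
#'
#' @param tree a `phylo` whose tips are individual ids.
#' @param taxon_map data.frame (`individual`, `taxon`) or named vector.
#' @return the pruned, relabelled `phylo`.
#' @export
representative_tree <- function(tree, taxon_map) {
  map <- map_individuals(taxon_map)
  tx <- map[tree$tip.label]
  if (anyNA(tx))
    stopf("individuals missing from the taxon map: %s",
          paste(tree$tip.label[is.na(tx)], collapse = ", "))
  keep <- vapply(split(tree$tip.label, tx), function(ids) sort(ids)[1],
                 character(1))
  out <- ape::keep.tip(tree, unname(keep))
  out$tip.label <- unname(map[out$tip.label])
  attr(out, "units") <- attr(tree, "units")
  out
}

#' @rdname representative_tree
#' @param aln an [alignment()] whose rows are individual ids.
#' @export
representative_alignment <- function(aln, taxon_map) {
  map <- map_individuals(taxon_map)
  tx <- map[rownames(aln)]
  if (anyNA(tx))
    stopf("individuals missing from the taxon map: %s",
          paste(rownames(aln)[is.na(tx)], collapse = ", "))
  keep <- vapply(split(rownames(aln), tx), function(ids) sort(ids)[1],
                 character(1))
  out <- unclass(aln)[unname(keep), , drop = FALSE]
  rownames(out) <- unname(map[rownames(out)])
  alignment(out)
}
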