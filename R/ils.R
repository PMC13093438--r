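#' Tree-distance distribution relative to a reference tree
#'
#' One unweighted RF distance per tree, order-preserving. Trees whose leaf
#' set is a superset of the reference's are restricted to the shared taxa
#' (and vice versa); the restriction is recorded.
#'
#' @param trees list/`multiPhylo` of `phylo` objects.
#' @param reference a `phylo`.
#' @param source label, e.g. `"empirical"` or `"simulated"`.
#' @param reference_id identifier stored on the result.
#' @return a `distance_distribution`: list with `source`, `values`,
#'   `reference_id`, `n_taxa`, `restricted` (how many trees were restricted).
#' @export
distance_distribution <- function(trees, reference, source = "empirical",
                                  reference_id = "species") {
  restricted <- 0L
  vals <- vapply(trees, function(t) {
    shared <- intersect(t$tip.label, reference$tip.label)
    tt <- t; rr <- reference
    if (length(shared) < length(t$tip.label) ||
        length(shared) < length(reference$tip.label)) {
      restricted <<- restricted + 1L
      tt <- ape::keep.tip(t, shared)
      rr <- ape::keep.tip(reference, shared)
    }
    rf_distance(tt, rr)
  }, numeric(1))
  structure(list(source = source, values = as.integer(vals),
                 reference_id = reference_id,
                 n_taxa = length(reference$tip.label),
                 restricted = restricted),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<%s RF distances to %s: n = %d, mean = %.2f>\n",
              x$source, x$reference_id, length(x$values), mean(x$values)))
  invisible(x)
}

#' Compare empirical and simulated distance distributions
#'
#' Quantitative twin of a histogram comparison: shared binning, moments, the
#' overlap coefficient (sum of bin-wise minimum proportions) and a
#' two-sample Kolmogorov-Smirnov test. The verdict text calls ILS a
#' sufficient explanation when the overlap coefficient reaches
#' `overlap_threshold`.
#'
#' @param empirical,simulated `distance_distribution`s on the same reference.
#' @param overlap_threshold verdict cutoff on the overlap coefficient.
#' @return a `distribution_comparison` list: `histogram` (data frame of
#'   per-bin counts and proportions), `mean_empirical`, `mean_simulated`,
#'   `var_empirical`, `var_simulated`, `overlap`, `ks_statistic`, `ks_p`,
#'   `verdict`.
#' @export
compare_distributions <- function(empirical, simulated,
                                  overlap_threshold = 0.5) {
  if (!length(empirical$values) || !length(simulated$values))
    stopf("both distributions must be non-empty")
  if (!identical(empirical$reference_id, simulated$reference_id))
    stopf("distributions were computed against different reference trees")
  breaks <- seq(-0.5, max(empirical$values, simulated$values) + 0.5, by = 1)
  he <- hist(empirical$values, breaks = breaks, plot = FALSE)
  hs <- hist(simulated$values, breaks = breaks, plot = FALSE)
  pe <- he$counts / sum(he$counts)
  ps <- hs$counts / sum(hs$counts)
  ks <- suppressWarnings(ks.test(empirical$values, simulated$values))
  overlap <- sum(pmin(pe, ps))
  structure(list(
    histogram = data.frame(distance = he$mids, n_empirical = he$counts,
                           n_simulated = hs$counts, p_empirical = pe,
                           p_simulated = ps),
    mean_empirical = mean(empirical$values),
    mean_simulated = mean(simulated$values),
    var_empirical = var(empirical$values),
    var_simulated = var(simulated$values),
    overlap = overlap,
    ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
    verdict = if (overlap >= overlap_threshold)
      "ILS sufficient to explain most discordance"
    else "discordance exceeds the coalescent expectation"),
    class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf(paste0("<distance comparison: mean %.2f (empirical) vs %.2f ",
                     "(simulated), overlap %.3f, KS D = %.3f (p = %.3g)>\n%s\n"),
              x$mean_empirical, x$mean_simulated, x$overlap, x$ks_statistic,
              x$ks_p, x$verdict))
  invisible(x)
}

#' Attribute cyto-nuclear conflicts to incomplete lineage sorting
#'
#' Simulates `n_sim` gene trees under the MSC on the nuclear species-tree
#' model and, for every plastid-tree bipartition absent from the nuclear
#' tree (a conflicting node), reports the fraction of simulated gene trees
#' displaying that bipartition — the "contribution of ILS" to the conflict.
#' A fraction at or above `threshold` marks ILS as a plausible cause.
#'
#' @param nuclear_species a [species_tree_model()] (coalescent units).
#' @param plastid the plastid tree (`phylo`), same taxa as the nuclear tree.
#' @param n_sim number of MSC simulations (reference protocol: 10,000).
#' @param seed integer seed.
#' @param threshold plausibility cutoff on the fraction (default 0.05).
#' @return a `conflict_attribution` data frame: `node`, `key` (conflicting
#'   bipartition), `fraction`, `se` (Monte-Carlo standard error), `n_sim`,
#'   `verdict`; zero rows (with a message) when the trees agree.
#' @export
attribute_conflicts <- function(nuclear_species, plastid, n_sim = 10000,
                                seed = NULL, threshold = 0.05) {
  if (!inherits(nuclear_species, "species_tree_model"))
    nuclear_species <- species_tree_model(nuclear_species)
  nuc <- nuclear_species$tree
  if (!setequal(nuc$tip.label, plastid$tip.label))
    stopf("plastid and nuclear trees must share their taxon set")
  ptab <- bipartition_table(plastid)
  conflict <- ptab[!ptab$key %in% bipartitions(nuc), , drop = FALSE]
  if (!nrow(conflict)) {
    message("plastid topology displays no bipartition absent from the nuclear tree")
    return(structure(data.frame(node = integer(), key = character(),
                                fraction = numeric(), se = numeric(),
                                n_sim = integer(), verdict = character(),
                                stringsAsFactors = FALSE),
                     class = c("conflict_attribution", "data.frame")))
  }
  sims <- simulate_gene_tree(nuclear_species, seed = seed, n = n_sim)
  hits <- setNames(numeric(nrow(conflict)), conflict$key)
  for (g in sims) {
    bk <- bipartitions(g)
    present <- conflict$key %in% bk
    hits[present] <- hits[present] + 1
  }
  frac <- hits / n_sim
  out <- data.frame(node = conflict$node, key = conflict$key,
                    fraction = unname(frac),
                    se = sqrt(unname(frac) * (1 - unname(frac)) / n_sim),
                    n_sim = n_sim,
                    verdict = ifelse(frac >= threshold, "ILS plausible",
                                     "ILS implausible"),
                    stringsAsFactors = FALSE)
  class(out) <- c("conflict_attribution", "data.frame")
  out
}
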