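PATTERN_CLASSES <- c("AAAA", "AAAB", "AABA", "AABB", "AABC",
                     "ABAA", "ABAB", "ABAC", "ABBA", "ABBB",
                     "ABBC", "ABCA", "ABCB", "ABCC", "ABCD")

#' Quartet assignment for hybridization testing
#'
#' Groups individuals into the four roles of an outgroup-anchored quartet:
#' outgroup, first candidate parent (P1), putative hybrid, second candidate
#' parent (P2).
#'
#' @param outgroup,p1,hybrid,p2 character vectors of individual ids; the
#'   four groups must be disjoint and non-empty.
#' @param taxa optional named character vector of the taxon of each group
#'   (for reporting).
#' @return an object of class `quartet_assignment`.
#' @export
quartet_assignment <- function(outgroup, p1, hybrid, p2, taxa = NULL) {
  groups <- list(outgroup = outgroup, p1 = p1, hybrid = hybrid, p2 = p2)
  if (any(lengths(groups) == 0)) stopf("all four quartet groups must be non-empty")
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids))
    stopf("quartet groups must be disjoint (duplicated: %s)",
          paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(c(groups, list(taxa = taxa)), class = "quartet_assignment")
}

#' Count quartet site patterns
#'
#' Classifies every site with unambiguous `A/C/G/T` in all four quartet
#' positions into the 15 outgroup-anchored site-pattern classes (`AAAA`,
#' `AAAB`, ..., `ABCD`: set partitions of the four bases with the outgroup
#' labelled `A`). Sites with a gap or ambiguity are skipped and tallied.
#' With several individuals per group, counts are averaged over individual
#' combinations (fractional counts), uniformly subsampled when the number of
#' combinations exceeds `max_combos`.
#'
#' @param aln an [alignment()] containing every assigned individual.
#' @param q a [quartet_assignment()].
#' @param max_combos combination cap (default 10000).
#' @param seed seed for combination subsampling (only used above the cap).
#' @param partitions optional gene-block structure of the alignment: either
#'   a data.frame with `start`/`end` columns (1-based inclusive, as returned
#'   by [concatenate_alignments()]) or an integer block id per site. When
#'   given, per-block counts are retained so [hils_test()] can use a
#'   linkage-aware (between-gene) variance.
#' @return a `site_pattern_counts`: list with `counts` (named 15-vector),
#'   `n_sites_used`, `n_sites_skipped`, `n_combos`, `assignment`,
#'   `block_counts` (15 x blocks matrix, or `NULL`).
#' @export
count_site_patterns <- function(aln, q, max_combos = 10000, seed = NULL,
                                partitions = NULL) {
  enc <- if (identical(attr(aln, "encoded"), TRUE)) aln else encode_dna(aln)
  count_patterns_encoded(enc, q, max_combos = max_combos, seed = seed,
                         partitions = partitions)
}

# expand a partitions data.frame (start/end) into a per-site block id vector
site_blocks <- function(partitions, n_sites) {
  if (is.null(partitions)) return(rep.int(1L, n_sites))
  if (is.data.frame(partitions)) {
    ids <- rep.int(1L, n_sites)
    for (i in seq_len(nrow(partitions)))
      ids[partitions$start[i]:partitions$end[i]] <- i
    ids
  } else {
    stopifnot(length(partitions) == n_sites)
    as.integer(factor(partitions))
  }
}

# internal workhorse on a pre-encoded integer matrix (see encode_dna), so
# triple scans encode the alignment once
count_patterns_encoded <- function(enc, q, max_combos = 10000, seed = NULL,
                                   partitions = NULL) {
  ids <- c(q$outgroup, q$p1, q$hybrid, q$p2)
  missing <- setdiff(ids, rownames(enc))
  if (length(missing))
    stopf("individuals absent from the alignment: %s",
          paste(missing, collapse = ", "))
  grp <- list(enc[q$outgroup, , drop = FALSE], enc[q$p1, , drop = FALSE],
              enc[q$hybrid, , drop = FALSE], enc[q$p2, , drop = FALSE])
  sizes <- vapply(grp, nrow, integer(1))
  n_comb <- prod(sizes)
  if (n_comb <= max_combos) {
    combos <- as.matrix(expand.grid(seq_len(sizes[1]), seq_len(sizes[2]),
                                    seq_len(sizes[3]), seq_len(sizes[4])))
  } else {
    combos <- with_seed(seed, {
      message(sprintf("subsampling %d of %.0f individual combinations", max_combos,
                      n_comb))
      cbind(sample.int(sizes[1], max_combos, replace = TRUE),
            sample.int(sizes[2], max_combos, replace = TRUE),
            sample.int(sizes[3], max_combos, replace = TRUE),
            sample.int(sizes[4], max_combos, replace = TRUE))
    })
  }
  blocks <- site_blocks(partitions, ncol(enc))
  nb <- max(blocks)
  res <- .pattern_counts_cpp(grp[[1]], grp[[2]], grp[[3]], grp[[4]],
                             t(unname(combos)), blocks, nb)
  bc <- res$counts
  rownames(bc) <- PATTERN_CLASSES
  counts <- setNames(rowSums(bc), PATTERN_CLASSES)
  structure(list(counts = counts, n_sites_used = sum(counts),
                 n_sites_skipped = sum(res$skipped), n_combos = res$n_combos,
                 assignment = q,
                 block_counts = if (nb > 1) bc else NULL),
            class = "site_pattern_counts")
}

#' @export
print.site_pattern_counts <- function(x, ...) {
  cat(sprintf("<site patterns: %.1f used, %.1f skipped; ABBA %.1f, ABAB %.1f, AABB %.1f>\n",
              x$n_sites_used, x$n_sites_skipped, x$counts["ABBA"],
              x$counts["ABAB"], x$counts["AABB"]))
  invisible(x)
}

#' Invariants-based hybridization test with gamma estimation
#'
#' Tests H0: no hybridization against a hybrid-speciation alternative using
#' the two outgroup-anchored linear invariants `X1 = n(ABBA) - n(ABAB)`
#' (excess hybrid/P1 sharing) and `X2 = n(AABB) - n(ABAB)` (excess hybrid/P2
#' sharing); under any purely treelike history at least one of the two has
#' expectation zero, while under hybridization both are positive. The
#' statistic is the ratio-weighted combination `z = X2 / sd(rho * X1 - X2)`
#' with plug-in `rho = X2 / X1`, asymptotically standard normal under H0
#' (one-sided).
#' Variances are multinomial for unpartitioned (unlinked-site) data; when
#' per-gene block counts are available (>= 10 blocks) a cluster-robust
#' between-gene estimator is used instead, because sites within a gene share
#' one genealogy and the multinomial variance would understate the null
#' variance. The inheritance-probability estimate is
#' `gamma_hat = X1 / (X1 + X2)`, which tends to 1 as the hybrid becomes
#' sister to P1 and maps to `1 - gamma_hat` when P1 and P2 are swapped.
#' See `system.file("notes", "hils_derivation.txt", package = "phylodisc")`.
#'
#' @param counts a [count_site_patterns()] result.
#' @param alpha nominal one-sided level (pre-correction).
#' @return a `hils_result`: list with `z`, `p`, `gamma` (clamped to
#'   \[0, 1\]), `gamma_raw`, `n_sites`, `flag` (`"ok"`, `"undefined"` or
#'   `"model-violation suspect"`), `significant` (at `alpha`, uncorrected).
#' @export
hils_test <- function(counts, alpha = 0.05) {
  N <- counts$n_sites_used
  if (N <= 0) stopf("no usable sites in the pattern counts")
  p9 <- counts$counts[["ABBA"]] / N
  p7 <- counts$counts[["ABAB"]] / N
  p4 <- counts$counts[["AABB"]] / N
  x1 <- N * (p9 - p7)
  x2 <- N * (p4 - p7)
  if (x1 == 0) { x1 <- x1 + 1; x2 <- x2 + 1 }   # reference guard
  bc <- counts$block_counts
  if (!is.null(bc) && ncol(bc) >= 10) {
    # linkage-aware variance: sites within a gene share a genealogy, so the
    # multinomial (unlinked-site) variance is too small; estimate the
    # variance of the invariants from their independent per-gene increments
    variance <- "cluster"
    b <- ncol(bc)
    x1b <- bc["ABBA", ] - bc["ABAB", ]
    x2b <- bc["AABB", ] - bc["ABAB", ]
    infl <- b / (b - 1)
    v1 <- infl * sum((x1b - mean(x1b))^2)
    v2 <- infl * sum((x2b - mean(x2b))^2)
    c12 <- infl * sum((x1b - mean(x1b)) * (x2b - mean(x2b)))
  } else {
    variance <- "multinomial"
    v1 <- N * (p9 * (1 - p9) + p7 * (1 - p7) + 2 * p9 * p7)
    v2 <- N * (p4 * (1 - p4) + p7 * (1 - p7) + 2 * p4 * p7)
    c12 <- N * (-p9 * p4 + p9 * p7 + p4 * p7 + p7 * (1 - p7))
  }
  ratio <- x2 / x1
  denom2 <- v1 * ratio^2 - 2 * c12 * ratio + v2
  base <- list(outgroup = counts$assignment$outgroup,
               p1 = counts$assignment$p1, hybrid = counts$assignment$hybrid,
               p2 = counts$assignment$p2, n_sites = N, alpha = alpha,
               variance = variance)
  if (!is.finite(denom2) || denom2 <= 0) {
    res <- c(base, list(z = NA_real_, p = NA_real_, gamma = NA_real_,
                        gamma_raw = NA_real_, flag = "undefined",
                        significant = FALSE))
    return(structure(res, class = "hils_result"))
  }
  z <- x2 / sqrt(denom2)        # x1 * ratio == x2
  p <- pnorm(z, lower.tail = FALSE)
  gamma_raw <- if (x1 + x2 != 0) x1 / (x1 + x2) else NA_real_
  flag <- if (is.na(gamma_raw)) "undefined"
          else if (gamma_raw < 0 || gamma_raw > 1) "model-violation suspect"
          else "ok"
  gamma <- if (is.na(gamma_raw)) NA_real_ else min(1, max(0, gamma_raw))
  structure(c(base, list(z = z, p = p, gamma = gamma, gamma_raw = gamma_raw,
                         flag = flag, significant = is.finite(p) && p < alpha)),
            class = "hils_result")
}

#' @export
print.hils_result <- function(x, ...) {
  cat(sprintf("<hils test: z = %.3f, p = %.3g, gamma_hat = %.3f [%s]>\n",
              x$z, x$p, x$gamma, x$flag))
  invisible(x)
}

map_individuals <- function(taxon_map) {
  if (is.data.frame(taxon_map)) {
    setNames(as.character(taxon_map$taxon), as.character(taxon_map$individual))
  } else if (!is.null(names(taxon_map))) {
    taxon_map
  } else stopf("`taxon_map` must be a data.frame(individual, taxon) or named vector")
}

#' Scan all ingroup triples for hybridization
#'
#' One test per candidate hybrid per unordered pair of remaining ingroup
#' taxa (`k * choose(k - 1, 2)` tests for `k` ingroup taxa), each against
#' the fixed outgroup, with all mapped individuals per taxon contributing to
#' the averaged pattern counts. P1 is the lexicographically smaller taxon of
#' each pair.
#'
#' @param aln the (typically concatenated) [alignment()].
#' @param taxon_map data.frame with columns `individual`, `taxon` (or a
#'   named vector individual -> taxon).
#' @param outgroup the outgroup taxon label.
#' @param alpha family-wise level after correction.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param max_combos per-test individual-combination cap.
#' @param seed seed for combination subsampling.
#' @return a `hyde_results` data frame (one row per test, sorted by p):
#'   `p1`, `hybrid`, `p2`, `n_sites`, `z`, `p`, `p_adj`, `gamma`,
#'   `gamma_raw`, `flag`, `significant`; attributes `m_tests`, `alpha`,
#'   `outgroup`, `correction`, `aln_sites`, `assignments`.
#' @export
scan_triples <- function(aln, taxon_map, outgroup, alpha = 0.05,
                         correction = c("bonferroni", "none"),
                         max_combos = 10000, seed = NULL,
                         partitions = NULL) {
  correction <- match.arg(correction)
  enc <- encode_dna(aln)
  blocks <- site_blocks(partitions, ncol(aln))
  map <- map_individuals(taxon_map)
  map <- map[names(map) %in% rownames(aln)]
  taxa <- sort(unique(unname(map)))
  if (!outgroup %in% taxa) stopf("outgroup '%s' has no individuals in the alignment",
                                 outgroup)
  ingroup <- setdiff(taxa, outgroup)
  if (length(ingroup) < 3) stopf("need >= 3 ingroup taxa")
  og_ids <- names(map)[map == outgroup]
  inds_of <- lapply(setNames(ingroup, ingroup), function(tx) names(map)[map == tx])
  rows <- list(); assignments <- list(); r <- 0L
  for (h in ingroup) {
    others <- setdiff(ingroup, h)
    prs <- combn(sort(others), 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      q <- quartet_assignment(og_ids, inds_of[[a]], inds_of[[h]], inds_of[[b]],
                              taxa = c(outgroup = outgroup, p1 = a, hybrid = h,
                                       p2 = b))
      res <- hils_test(count_patterns_encoded(enc, q, max_combos = max_combos,
                                              seed = seed,
                                              partitions = blocks),
                       alpha = alpha)
      r <- r + 1L
      assignments[[r]] <- q
      rows[[r]] <- data.frame(p1 = a, hybrid = h, p2 = b,
                              n_sites = res$n_sites, z = res$z, p = res$p,
                              gamma = res$gamma, gamma_raw = res$gamma_raw,
                              flag = res$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adj <- if (correction == "bonferroni") pmin(1, out$p * m) else out$p
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  ord <- order(out$p)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignments") <- assignments[ord]
  attr(out, "m_tests") <- m
  attr(out, "alpha") <- alpha
  attr(out, "outgroup") <- outgroup
  attr(out, "correction") <- correction
  attr(out, "aln_sites") <- ncol(aln)
  attr(out, "partitions") <- partitions
  class(out) <- c("hyde_results", "data.frame")
  out
}

#' Aggregate triple tests to a species-tree node ("Node Mode")
#'
#' Pools significant tests whose hybrid taxon descends from a target MRCA
#' node and summarizes, for each candidate parent pair, the mean and SD of
#' the inheritance probability from the row taxon (P1): cell `[P1, P2]`
#' receives `gamma_hat`, the mirror cell `1 - gamma_hat`.
#'
#' @param results a [scan_triples()] result.
#' @param species the species tree (`phylo`).
#' @param hybrid_target taxa whose MRCA defines the target hybrid node.
#' @return a `node_mode_heatmap`: list with matrices `mean`, `sd`, `count`,
#'   `mask` (count >= 1 and mean defined) and a `summary` data frame with
#'   per-parent `"mean +/- sd"` strings; empty (with a message) when no test
#'   is significant.
#' @export
node_mode <- function(results, species, hybrid_target) {
  if (!all(hybrid_target %in% species$tip.label))
    stopf("hybrid_target taxa must be species-tree leaves")
  target_taxa <- hybrid_target
  if (length(target_taxa) > 1) {
    mrca <- ape::getMRCA(species, target_taxa)
    target_taxa <- species$tip.label[descendant_tips(species)[mrca, ]]
  }
  sig <- results[results$significant & results$hybrid %in% target_taxa, ,
                 drop = FALSE]
  parents <- sort(unique(c(results$p1, results$p2)))
  empty <- matrix(NA_real_, length(parents), length(parents),
                  dimnames = list(parents, parents))
  if (!nrow(sig)) {
    message("no significant tests pool to the target node")
    zero <- empty; zero[] <- 0
    return(structure(list(mean = empty, sd = empty,
                          count = zero, mask = zero > 0,
                          summary = data.frame(parent = character(),
                                               gamma = character()),
                          target = target_taxa),
                     class = "node_mode_heatmap"))
  }
  vals <- vector("list", 0)
  key <- function(a, b) paste(a, b, sep = "\r")
  for (i in seq_len(nrow(sig))) {
    vals[[key(sig$p1[i], sig$p2[i])]] <-
      c(vals[[key(sig$p1[i], sig$p2[i])]], sig$gamma[i])
    vals[[key(sig$p2[i], sig$p1[i])]] <-
      c(vals[[key(sig$p2[i], sig$p1[i])]], 1 - sig$gamma[i])
  }
  mean_m <- empty; sd_m <- empty; count_m <- 0 * empty
  for (k in names(vals)) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1]]
    v <- vals[[k]]
    mean_m[ab[1], ab[2]] <- mean(v)
    sd_m[ab[1], ab[2]] <- if (length(v) > 1) sd(v) else 0
    count_m[ab[1], ab[2]] <- length(v)
  }
  per_parent <- lapply(setNames(parents, parents), function(px) {
    v <- unlist(vals[startsWith(names(vals), paste0(px, "\r"))])
    if (is.null(v)) NULL
    else sprintf("%.3f ± %.3f", mean(v), if (length(v) > 1) sd(v) else 0)
  })
  per_parent <- per_parent[!vapply(per_parent, is.null, logical(1))]
  structure(list(mean = mean_m, sd = sd_m, count = count_m,
                 mask = count_m >= 1 & !is.na(mean_m),
                 summary = data.frame(parent = names(per_parent),
                                      gamma = unlist(per_parent),
                                      stringsAsFactors = FALSE),
                 target = target_taxa),
            class = "node_mode_heatmap")
}

#' @export
print.node_mode_heatmap <- function(x, ...) {
  cat(sprintf("<node-mode heatmap: target {%s}, %d significant cell(s)>\n",
              paste(x$target, collapse = ","), sum(x$mask)))
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Null-simulation false-positive filter
#'
#' For each empirically significant triple, simulates `n_replicates`
#' hybridization-free alignments on the empirical substitution-unit species
#' tree (whose branch lengths carry any real lineage-rate heterogeneity),
#' reruns the invariants test at the same corrected level, and filters the
#' triple when the null rejection fraction exceeds `cutoff`: its empirical
#' significance is then attainable by rate variation alone.
#'
#' @param observed a [scan_triples()] result.
#' @param species_subst_tree `phylo` with substitutions/site branch lengths
#'   and the alignment's individuals as tips.
#' @param model a [substitution_model()] for the null simulations.
#' @param n_replicates number of null replicates (>= 20; default 100).
#' @param seed integer seed.
#' @param cutoff verdict threshold on the null rejection fraction.
#' @param taxon_map individual-to-taxon map (data.frame or named vector);
#'   required when `species_subst_tree` is a species-level tree (one tip per
#'   taxon) while the scan ran on individuals. The null test then uses one
#'   sequence per taxon. A taxon-level null tree is the protocol's intent: a
#'   sample-level tree estimated from hybrid-containing data places the
#'   hybrid individuals paraphyletically and would smuggle the reticulation
#'   into the "no hybridization" null.
#' @return a `null_filter_report` data frame: the significant triples with
#'   `null_rejection_fraction` and `verdict` (`"retained"`/`"filtered"`).
#' @export
null_hypothesis_filter <- function(observed, species_subst_tree, model,
                                   n_replicates = 100, seed = NULL,
                                   cutoff = 0.05, taxon_map = NULL) {
  if (n_replicates < 20) stopf("`n_replicates` must be >= 20")
  alpha <- attr(observed, "alpha") %||% 0.05
  m <- attr(observed, "m_tests") %||% nrow(observed)
  n_sites <- attr(observed, "aln_sites") %||% max(observed$n_sites)
  sig_idx <- which(observed$significant)
  out <- observed[sig_idx, c("p1", "hybrid", "p2", "z", "p", "p_adj", "gamma"),
                  drop = FALSE]
  if (!nrow(out)) {
    out$null_rejection_fraction <- numeric(0)
    out$verdict <- character(0)
    class(out) <- c("null_filter_report", "data.frame")
    return(out)
  }
  assignments <- attr(observed, "assignments")[sig_idx]
  tips <- species_subst_tree$tip.label
  assignments <- lapply(assignments, function(q) {
    ids <- unlist(q[c("outgroup", "p1", "hybrid", "p2")])
    if (all(ids %in% tips)) return(q)
    if (is.null(taxon_map))
      stopf("null-tree tips do not match the scanned individuals; supply `taxon_map`")
    map <- map_individuals(taxon_map)
    tr <- function(g) unique(unname(map[g]))
    q2 <- quartet_assignment(tr(q$outgroup), tr(q$p1), tr(q$hybrid),
                             tr(q$p2), taxa = q$taxa)
    still <- setdiff(unlist(q2[c("outgroup", "p1", "hybrid", "p2")]), tips)
    if (length(still))
      stopf("taxa absent from the null species tree: %s",
            paste(still, collapse = ", "))
    q2
  })
  units <- attr(species_subst_tree, "units") %||% "substitution"
  if (units != "substitution")
    stopf("null filter needs a substitution-unit species tree")
  blocks <- site_blocks(attr(observed, "partitions"), n_sites)
  rejections <- numeric(nrow(out))
  for (r in seq_len(n_replicates)) {
    null_aln <- evolve_sequences(species_subst_tree, model, n_sites,
                                 seed = if (is.null(seed)) NULL
                                        else derive_seed(seed, r))
    null_enc <- encode_dna(null_aln)
    for (i in seq_len(nrow(out))) {
      res <- hils_test(count_patterns_encoded(null_enc, assignments[[i]],
                                              partitions = blocks),
                       alpha = alpha)
      if (!is.na(res$p) && res$p * m < alpha) rejections[i] <- rejections[i] + 1
    }
  }
  out$null_rejection_fraction <- rejections / n_replicates
  out$verdict <- ifelse(out$null_rejection_fraction > cutoff, "filtered",
                        "retained")
  rownames(out) <- NULL
  attr(out, "n_replicates") <- n_replicates
  attr(out, "cutoff") <- cutoff
  class(out) <- c("null_filter_report", "data.frame")
  out
}
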