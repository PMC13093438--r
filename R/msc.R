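#' Species-tree model for coalescent simulation
#'
#' Wraps a rooted species tree whose branch lengths are in coalescent units
#' (time / 2N generations) together with per-branch population-size scalers
#' theta. Missing terminal branch lengths (as produced by summary-coalescent
#' species-tree methods, which do not estimate them) are replaced by a
#' configurable constant with a warning.
#'
#' @param tree a rooted `phylo` with coalescent-unit branch lengths
#'   (`attr(tree, "units") == "coalescent"`).
#' @param theta population scaling; a single value or one value per edge of
#'   `tree` (ordered as `tree$edge`). Default 1 (pure coalescent units).
#' @param terminal_default branch length substituted for missing terminal
#'   branches, in coalescent units.
#' @return an object of class `species_tree_model`.
#' @export
species_tree_model <- function(tree, theta = 1, terminal_default = 2) {
  if (!inherits(tree, "phylo")) stopf("`tree` must be a phylo object")
  units <- attr(tree, "units") %||% "coalescent"
  if (units != "coalescent")
    stopf("species tree branch lengths must be in coalescent units (got '%s')",
          units)
  if (is.null(tree$edge.length))
    stopf("species tree has no branch lengths")
  nt <- length(tree$tip.label)
  isna <- is.na(tree$edge.length)
  if (any(isna)) {
    terminal <- tree$edge[, 2] <= nt
    if (any(isna & !terminal))
      stopf("missing internal branch length(s) in species tree")
    warnf("missing terminal branch length(s) set to %g coalescent units",
          terminal_default)
    tree$edge.length[isna] <- terminal_default
  }
  if (any(tree$edge.length < 0)) stopf("negative branch length in species tree")
  if (!length(theta) %in% c(1L, nrow(tree$edge)))
    stopf("`theta` must have length 1 or one value per edge")
  if (any(theta <= 0)) stopf("theta must be positive")
  attr(tree, "units") <- "coalescent"
  structure(list(tree = tree, theta = theta), class = "species_tree_model")
}

#' @export
print.species_tree_model <- function(x, ...) {
  cat(sprintf("<species tree model: %d taxa, coalescent units, theta %s>\n",
              length(x$tree$tip.label),
              if (length(x$theta) == 1) format(x$theta) else "per-branch"))
  invisible(x)
}

#' A single reticulation event
#'
#' Describes one hybrid taxon receiving a fraction `gamma` of its genome from
#' `parent1` and `1 - gamma` from `parent2`. Attachment ages on the two
#' parental branches default to the midpoints of those branches (measured on
#' the species tree with the hybrid leaf removed).
#'
#' @param hybrid,parent1,parent2 taxon labels; parents must be distinct.
#' @param gamma inheritance probability toward `parent1`, in \[0, 1\].
#' @param t1,t2 optional attachment ages (coalescent units above the present)
#'   on the parent1/parent2 branches.
#' @return an object of class `hybrid_event`.
#' @export
hybrid_event <- function(hybrid, parent1, parent2, gamma, t1 = NULL, t2 = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1 || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    stopf("`gamma` must be a single value in [0, 1]")
  if (identical(parent1, parent2)) stopf("parents must be distinct taxa")
  if (hybrid %in% c(parent1, parent2)) stopf("hybrid cannot be its own parent")
  structure(list(hybrid = hybrid, parent1 = parent1, parent2 = parent2,
                 gamma = gamma, t1 = t1, t2 = t2), class = "hybrid_event")
}

#' @export
print.hybrid_event <- function(x, ...) {
  cat(sprintf("<hybrid event: %s = %.3f x %s + %.3f x %s>\n",
              x$hybrid, x$gamma, x$parent1, 1 - x$gamma, x$parent2))
  invisible(x)
}

# ---- internal population-tree representation -------------------------------

# parent pointers + ages + per-edge theta; tips carry labels
as_poptree <- function(model) {
  tree <- model$tree
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  parent <- rep(NA_integer_, nn)
  theta_edge <- rep(NA_real_, nn)   # theta of edge above each node
  th <- if (length(model$theta) == 1) rep(model$theta, nrow(tree$edge)) else model$theta
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    theta_edge[tree$edge[i, 2]] <- th[i]
  }
  ages <- node_ages(tree)
  label <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  list(parent = parent, age = ages, theta = theta_edge, label = label,
       root = nt + 1L, n = nn, root_theta = if (length(model$theta) == 1) model$theta else 1)
}

# coalesce `ids` (gene-tree node ids) within [t0, t1] at rate choose(k,2)/theta;
# `st` is the growing gene-tree state environment
coalesce_interval <- function(st, ids, t0, t1, theta) {
  t <- t0
  while (length(ids) >= 2) {
    k <- length(ids)
    w <- rexp(1, rate = k * (k - 1) / 2 / theta)
    if (t + w > t1) break
    t <- t + w
    pair <- sample.int(k, 2)
    st$count <- st$count + 1L
    new <- st$count
    st$height[new] <- t
    st$child1[new] <- ids[pair[1]]
    st$child2[new] <- ids[pair[2]]
    ids <- c(ids[-pair], new)
  }
  ids
}

# simulate one gene tree on a poptree; `tip_inds` = list over node ids of
# individual labels sampled from that tip
sim_on_poptree <- function(pt, tip_inds) {
  total_tips <- sum(lengths(tip_inds))
  st <- new.env(parent = emptyenv())
  maxn <- 2L * total_tips
  st$height <- numeric(maxn); st$child1 <- rep(NA_integer_, maxn)
  st$child2 <- rep(NA_integer_, maxn); st$label <- rep(NA_character_, maxn)
  st$count <- 0L
  children <- vector("list", pt$n)
  tips_of <- integer(0)
  for (v in seq_len(pt$n)) {
    p <- pt$parent[v]
    if (!is.na(p)) children[[p]] <- c(children[[p]], v)
  }
  process <- function(v) {
    kids <- children[[v]]
    inds <- tip_inds[[v]]
    ids <- integer(0)
    if (!is.null(inds) && length(inds)) {
      for (lab in inds) {
        st$count <- st$count + 1L
        st$height[st$count] <- pt$age[v]
        st$label[st$count] <- lab
        ids <- c(ids, st$count)
      }
    }
    for (k in kids) {
      lk <- process(k)
      ids <- c(ids, coalesce_interval(st, lk, pt$age[k], pt$age[v], pt$theta[k]))
    }
    ids
  }
  surv <- process(pt$root)
  surv <- coalesce_interval(st, surv, pt$age[pt$root], Inf, pt$root_theta)
  build_phylo_from_state(st)
}

# assemble an ape phylo from the merge records
build_phylo_from_state <- function(st) {
  n <- st$count
  is_tip <- !is.na(st$label[seq_len(n)])
  tips <- which(is_tip)
  internals <- which(!is_tip)
  # root = the internal node that is nobody's child
  kids <- c(st$child1[internals], st$child2[internals])
  root_old <- setdiff(internals, kids)
  ord <- internals[order(-st$height[internals])]
  ord <- c(root_old, setdiff(ord, root_old))
  ntip <- length(tips)
  newid <- integer(n)
  newid[tips] <- seq_len(ntip)
  newid[ord] <- ntip + seq_along(ord)
  edge <- matrix(0L, n - 1L, 2L)
  elen <- numeric(n - 1L)
  r <- 0L
  for (v in internals) for (ch in c(st$child1[v], st$child2[v])) {
    r <- r + 1L
    edge[r, ] <- c(newid[v], newid[ch])
    elen[r] <- st$height[v] - st$height[ch]
  }
  tr <- list(edge = edge, edge.length = elen, Nnode = length(internals),
             tip.label = st$label[tips])
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "units") <- "coalescent"
  tr
}

expand_individuals <- function(pt, individuals_per_taxon) {
  tip_inds <- vector("list", pt$n)
  for (v in which(!is.na(pt$label))) {
    tx <- pt$label[v]
    k <- if (is.null(individuals_per_taxon)) 1L
         else as.integer(individuals_per_taxon[[tx]] %||% 1L)
    tip_inds[[v]] <- if (k == 1L) tx else paste0(tx, "_", seq_len(k))
  }
  tip_inds
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Lineages entering a species-tree branch coalesce at exponential rate
#' `choose(k, 2) / theta`; lineages still distinct above the root coalesce
#' there. Gene trees are returned with coalescent-unit branch lengths.
#'
#' @param model a [species_tree_model()].
#' @param individuals_per_taxon optional named list/vector giving the number
#'   of sampled individuals per taxon (default 1 each; individuals of taxon
#'   `t` are labelled `t_1, t_2, ...` when more than one is sampled).
#' @param seed integer seed (deterministic result), or `NULL` to use the
#'   current RNG stream.
#' @param n number of independent gene trees to draw.
#' @return a `phylo` when `n = 1`, otherwise a `multiPhylo` list.
#' @examples
#' m <- species_tree_model(parse_newick("((A:1,B:1):1,C:2);", units = "coalescent"))
#' simulate_gene_tree(m, seed = 1)
#' @export
simulate_gene_tree <- function(model, individuals_per_taxon = NULL,
                               seed = NULL, n = 1) {
  if (!inherits(model, "species_tree_model"))
    model <- species_tree_model(model)
  pt <- as_poptree(model)
  tip_inds <- expand_individuals(pt, individuals_per_taxon)
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) out[[i]] <- sim_on_poptree(pt, tip_inds)
    if (n == 1) out[[1]] else structure(out, class = "multiPhylo")
  })
}

# drop the hybrid tip from the poptree and splice attachment nodes into the
# two parental stems; returns the modified poptree plus ids of the two
# pseudo-tips carrying hybrid lineages
network_poptree <- function(model, event) {
  tree <- model$tree
  for (tx in c(event$hybrid, event$parent1, event$parent2))
    if (!tx %in% tree$tip.label) stopf("taxon '%s' not in species tree", tx)
  pt <- as_poptree(model)
  hyb <- which(pt$label == event$hybrid)
  pt$label[hyb] <- NA_character_   # detach: tip contributes no lineages
  # effective parental stem interval: tip age up to first ancestor that still
  # has >= 2 children carrying lineages (the detached hybrid does not count)
  stem_top <- function(tip) {
    v <- tip
    repeat {
      p <- pt$parent[v]
      if (is.na(p)) return(pt$age[v])
      sibs <- setdiff(which(pt$parent == p), c(v, hyb))
      if (length(sibs) >= 1) return(pt$age[p])
      v <- p
    }
  }
  insert_at <- function(tip, t_attach) {
    # walk up from `tip` to the edge spanning t_attach, splice in a node
    v <- tip
    repeat {
      p <- pt$parent[v]
      if (is.na(p) || pt$age[p] >= t_attach) break
      v <- p
    }
    if (is.na(pt$parent[v]))
      stopf("attachment age %.3f above the species-tree root", t_attach)
    pt$n <<- pt$n + 1L
    x <- pt$n
    pt$parent[x] <<- pt$parent[v]
    pt$age[x] <<- t_attach
    pt$theta[x] <<- pt$theta[v]
    pt$label[x] <<- NA_character_
    pt$parent[v] <<- x
    x
  }
  p1 <- which(pt$label == event$parent1)
  p2 <- which(pt$label == event$parent2)
  t1 <- event$t1 %||% (stem_top(p1) / 2)
  t2 <- event$t2 %||% (stem_top(p2) / 2)
  if (t1 > stem_top(p1) || t2 > stem_top(p2))
    stopf("attachment age outside the parental branch interval")
  x1 <- insert_at(p1, t1)
  x2 <- insert_at(p2, t2)
  # pseudo-tips holding hybrid lineages, one per parental route
  for (x in c(x1, x2)) {
    pt$n <- pt$n + 1L
    pt$parent[pt$n] <- x
    pt$age[pt$n] <- 0
    pt$theta[pt$n] <- pt$theta[hyb]
    pt$label[pt$n] <- NA_character_
  }
  list(pt = pt, route1 = pt$n - 1L, route2 = pt$n, t1 = t1, t2 = t2)
}

#' Simulate gene trees under a one-reticulation network MSC
#'
#' Each sampled hybrid lineage independently traces `parent1`'s history with
#' probability `gamma` (entering the parent1 branch at the attachment age)
#' and `parent2`'s otherwise; the process is an ordinary multispecies
#' coalescent thereafter.
#'
#' @inheritParams simulate_gene_tree
#' @param event a [hybrid_event()] referencing taxa of the model.
#' @return a `phylo` when `n = 1`, otherwise a `multiPhylo` list.
#' @export
simulate_network_gene_tree <- function(model, event, individuals_per_taxon = NULL,
                                       seed = NULL, n = 1) {
  if (!inherits(model, "species_tree_model"))
    model <- species_tree_model(model)
  if (!inherits(event, "hybrid_event")) stopf("`event` must be a hybrid_event")
  net <- network_poptree(model, event)
  pt <- net$pt
  tip_inds <- expand_individuals(pt, individuals_per_taxon)
  hyb_k <- if (is.null(individuals_per_taxon)) 1L
           else as.integer(individuals_per_taxon[[event$hybrid]] %||% 1L)
  hyb_labels <- if (hyb_k == 1L) event$hybrid
                else paste0(event$hybrid, "_", seq_len(hyb_k))
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      to1 <- runif(hyb_k) < event$gamma
      tip_inds[[net$route1]] <- hyb_labels[to1]
      tip_inds[[net$route2]] <- hyb_labels[!to1]
      out[[i]] <- sim_on_poptree(pt, tip_inds)
    }
    if (n == 1) out[[1]] else structure(out, class = "multiPhylo")
  })
}
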