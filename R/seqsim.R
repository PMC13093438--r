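#' General time-reversible substitution model with discrete-Gamma rates
#'
#' Holds the six GTR exchangeabilities (order AC, AG, AT, CG, CT, GT), the
#' four base frequencies, the Gamma shape for among-site rate variation
#' (`Inf` disables it) and optional per-branch rate multipliers used to build
#' lineage-rate-heterogeneity null scenarios. The rate matrix is normalized
#' to one expected substitution per unit branch length.
#'
#' @param rates six positive exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param base_freqs four frequencies summing to 1 (A, C, G, T).
#' @param gamma_shape Gamma shape alpha (> 0); `Inf` = equal rates.
#' @param n_cat number of discrete rate categories.
#' @param branch_rates optional named vector of rate multipliers applied to
#'   the pendant branch of each named tip (default 1 everywhere).
#' @return an object of class `substitution_model`.
#' @examples
#' m <- substitution_model()                       # Jukes-Cantor
#' m2 <- substitution_model(rates = c(1, 4, 1, 1, 4, 1), gamma_shape = 0.8)
#' @export
substitution_model <- function(rates = rep(1, 6),
                               base_freqs = rep(0.25, 4),
                               gamma_shape = Inf, n_cat = 4,
                               branch_rates = NULL) {
  if (length(rates) != 6 || any(rates <= 0))
    stopf("`rates` must be 6 positive exchangeabilities")
  if (length(base_freqs) != 4 || any(base_freqs <= 0))
    stopf("`base_freqs` must be 4 positive frequencies")
  if (abs(sum(base_freqs) - 1) > 1e-9)
    stopf("base frequencies must sum to 1 (got %.12f)", sum(base_freqs))
  if (!(is.infinite(gamma_shape) || gamma_shape > 0))
    stopf("`gamma_shape` must be > 0 or Inf")
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  pair <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pair[k, 1]; j <- pair[k, 2]
    Q[i, j] <- rates[k] * base_freqs[j]
    Q[j, i] <- rates[k] * base_freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu
  structure(list(rates = rates, base_freqs = setNames(base_freqs, bases),
                 gamma_shape = gamma_shape, n_cat = as.integer(n_cat),
                 branch_rates = branch_rates, Q = Q),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("<GTR model: alpha = %s, %d categories%s>\n",
              format(x$gamma_shape), x$n_cat,
              if (is.null(x$branch_rates)) "" else ", per-branch multipliers"))
  invisible(x)
}

#' Discrete-Gamma category rates (mean of each of k equiprobable classes)
#'
#' @param alpha Gamma shape (mean fixed at 1).
#' @param k number of categories.
#' @return k rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (is.infinite(alpha)) return(rep(1, k))
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # mean of X within each class: incomplete-gamma identity raises the shape
  k * (pgamma(q[-1], shape = alpha + 1, rate = alpha) -
       pgamma(q[-(k + 1)], shape = alpha + 1, rate = alpha))
}

# transition probability matrix via eigendecomposition of the reversible Q
transition_matrix <- function(eig, t) {
  P <- eig$U %*% (exp(eig$values * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

gtr_eigen <- function(model) {
  pi_sqrt <- sqrt(model$base_freqs)
  B <- diag(pi_sqrt) %*% model$Q %*% diag(1 / pi_sqrt)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / pi_sqrt) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(pi_sqrt)
  list(values = e$values, U = U, Uinv = Uinv)
}

#' Simulate sequences along a gene tree
#'
#' Site-independent CTMC simulation under a GTR+Gamma model. Branch lengths
#' must be in expected substitutions per site; a tree in coalescent units is
#' rescaled by the mandatory `subst_per_coal` factor. Per-branch rate
#' multipliers from the model are applied to the pendant branches of the
#' named tips.
#'
#' @param gene_tree a `phylo`.
#' @param model a [substitution_model()].
#' @param n_sites number of sites (> 0).
#' @param seed integer seed, or `NULL`.
#' @param subst_per_coal substitutions/site per coalescent unit; required
#'   when `attr(gene_tree, "units") == "coalescent"`.
#' @return an [alignment()] with one row per tip of `gene_tree`.
#' @export
evolve_sequences <- function(gene_tree, model, n_sites, seed = NULL,
                             subst_per_coal = NULL) {
  if (n_sites < 1) stopf("`n_sites` must be >= 1")
  units <- attr(gene_tree, "units") %||% "substitution"
  el <- gene_tree$edge.length
  if (is.null(el)) stopf("gene tree has no branch lengths")
  if (units == "coalescent") {
    if (is.null(subst_per_coal))
      stopf("tree is in coalescent units: `subst_per_coal` is required")
    el <- el * subst_per_coal
  }
  nt <- length(gene_tree$tip.label)
  if (!is.null(model$branch_rates)) {
    tipedge <- gene_tree$edge[, 2] <= nt
    mult <- model$branch_rates[gene_tree$tip.label[gene_tree$edge[tipedge, 2]]]
    mult[is.na(mult)] <- 1
    el[tipedge] <- el[tipedge] * mult
  }
  eig <- gtr_eigen(model)
  cat_rates <- discrete_gamma_rates(model$gamma_shape, model$n_cat)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    site_cat <- sample.int(length(cat_rates), n_sites, replace = TRUE)
    nn <- nt + gene_tree$Nnode
    states <- matrix(0L, nn, n_sites)
    root <- nt + 1L
    states[root, ] <- sample.int(4, n_sites, replace = TRUE,
                                 prob = model$base_freqs)
    eo <- ape::reorder.phylo(gene_tree, "cladewise")  # parents before children
    el_o <- el[match(paste(eo$edge[, 1], eo$edge[, 2]),
                     paste(gene_tree$edge[, 1], gene_tree$edge[, 2]))]
    for (i in seq_len(nrow(eo$edge))) {
      p <- eo$edge[i, 1]; ch <- eo$edge[i, 2]
      for (k in seq_along(cat_rates)) {
        idx <- which(site_cat == k)
        if (!length(idx)) next
        P <- transition_matrix(eig, el_o[i] * cat_rates[k])
        ps <- states[p, idx]
        u <- runif(length(idx))
        cum <- t(apply(P, 1, cumsum))
        states[ch, idx] <- 1L + as.integer(u > cum[cbind(ps, 1)]) +
          as.integer(u > cum[cbind(ps, 2)]) + as.integer(u > cum[cbind(ps, 3)])
      }
    }
    m <- matrix(bases[states[seq_len(nt), , drop = FALSE]], nt, n_sites)
    rownames(m) <- gene_tree$tip.label
    alignment(m)
  })
}
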