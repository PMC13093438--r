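#' Inject missing data into an alignment
#'
#' Each column receives a target missing fraction drawn from
#' `column_missing_profile`; cells are then gapped independently with that
#' probability. The realized per-column missingness is attached as the
#' `missingness_sidecar` attribute (a data frame), so downstream column
#' filters can be validated against ground truth.
#'
#' @param aln an [alignment()].
#' @param column_missing_profile either a function `n -> n fractions`, or a
#'   numeric vector (recycled over columns) of per-column missing fractions.
#' @param seed integer seed, or `NULL`.
#' @return the gapped alignment, with the sidecar attribute.
#' @export
inject_missingness <- function(aln, column_missing_profile, seed = NULL) {
  n <- ncol(aln)
  with_seed(seed, {
    target <- if (is.function(column_missing_profile))
      column_missing_profile(n)
    else rep_len(column_missing_profile, n)
    if (any(target < 0 | target > 1)) stopf("missing fractions must be in [0, 1]")
    out <- unclass(aln)
    for (j in seq_len(n)) {
      if (target[j] <= 0) next
      hit <- runif(nrow(out)) < target[j]
      out[hit, j] <- "-"
    }
    out <- alignment(out)
    attr(out, "missingness_sidecar") <- data.frame(
      column = seq_len(n), target_frac = target,
      realized_frac = column_missing_fraction(out))
    out
  })
}

# ---- scenario definitions ---------------------------------------------------

# a ~10-ingroup-taxon ultrametric species tree in coalescent units: one
# subclade (sp1..sp6) with short internal branches (heavy ILS), one subclade
# holding the hybrid and its two deeply diverged parents, and a distant
# outgroup; the hybrid is a recently formed population (attachment age 1.0)
# so that hybridization leaves a detectable site-pattern signal
scenario_species_newick <- function() {
  paste0("(((((hyb:1.0,par1:1.0):5.0,par2:6.0):4.0,spx:10.0):4.0,",
         "((((sp1:0.5,sp2:0.5):0.3,sp3:0.8):0.3,sp4:1.1):0.4,",
         "(sp5:0.9,sp6:0.9):0.6):12.5):6.0,out:20.0);")
}

scenario_config <- function(name) {
  base <- list(
    species_newick = scenario_species_newick(),
    outgroup = "out",
    n_genes = 100L,
    n_sites = 500L,
    subst_per_coal = 0.01,
    gtr_rates = c(1.2, 3.5, 0.9, 1.1, 4.0, 1.0),
    base_freqs = c(0.30, 0.19, 0.21, 0.30),
    gamma_shape = 1.0,
    n_cat = 4L,
    # the hybrid is sampled at the population level (several individuals),
    # as in genome-skimming studies that sequence multiple individuals per
    # site; all other taxa contribute one individual
    individuals = list(hyb = 6L),
    presence_prob = 0.92,
    core_taxa = c("out", "hyb", "par1", "par2"),
    missing_beta = c(0.6, 10),
    hybrid = NULL,
    branch_rates = NULL)
  switch(name,
    adonis_like = {
      base$hybrid <- list(hybrid = "hyb", parent1 = "par1", parent2 = "par2",
                          gamma = 0.6, t1 = 1.0, t2 = 1.0)
      base
    },
    no_hybrid = base,
    rate_artifact = {
      base$branch_rates <- c(spx = 5)
      base
    },
    stopf("unknown scenario '%s'; valid names: adonis_like, no_hybrid, rate_artifact",
          name))
}

# individual labels per taxon, matching expand_individuals() naming
scenario_samples <- function(taxa, individuals) {
  unlist(lapply(taxa, function(tx) {
    k <- as.integer(individuals[[tx]] %||% 1L)
    if (k == 1L) tx else paste0(tx, "_", seq_len(k))
  }))
}

#' Generate a complete synthetic analysis bundle
#'
#' Writes, under `dir`: `species.nwk` (coalescent units), `plastid.nwk` (a
#' synthetic organellar genealogy: one extra MSC draw), `genetrees.nwk` (the
#' true per-gene coalescent genealogies), `aln/gene_XXXX.fasta` (GTR+Gamma
#' alignments with injected missingness, restricted to the samples carrying
#' the gene), `orthogroups.tsv`, `map.tsv` (individual-to-taxon) and
#' `manifest.json` recording every stochastic truth (gamma, seeds, model
#' parameters). Regeneration from the same seed is byte-identical; per-gene
#' RNG substreams mean adding genes never perturbs earlier ones.
#'
#' Scenarios: `"adonis_like"` (one reticulation, hybrid `hyb` from `par1`
#' with gamma = 0.6 and `par2`), `"no_hybrid"` (pure MSC), `"rate_artifact"`
#' (no reticulation, lineage `spx` evolving 5x faster).
#'
#' @param name scenario name.
#' @param seed integer seed for the whole bundle.
#' @param dir output directory (created if needed).
#' @param n_genes,n_sites optional overrides of the scenario defaults
#'   (100 genes x 500 sites).
#' @return (invisibly) the bundle as returned by [load_bundle()], with the
#'   output directory in `$dir`.
#' @export
make_scenario <- function(name, seed, dir = tempfile(paste0("bundle_", name)),
                          n_genes = NULL, n_sites = NULL) {
  cfg <- scenario_config(name)
  if (!is.null(n_genes)) cfg$n_genes <- as.integer(n_genes)
  if (!is.null(n_sites)) cfg$n_sites <- as.integer(n_sites)
  dir.create(file.path(dir, "aln"), recursive = TRUE, showWarnings = FALSE)
  sp <- parse_newick(cfg$species_newick, units = "coalescent")
  model <- species_tree_model(sp)
  event <- if (!is.null(cfg$hybrid))
    hybrid_event(cfg$hybrid$hybrid, cfg$hybrid$parent1, cfg$hybrid$parent2,
                 cfg$hybrid$gamma, t1 = cfg$hybrid$t1, t2 = cfg$hybrid$t2)
  taxa <- sp$tip.label
  samples <- scenario_samples(taxa, cfg$individuals)
  sample_taxon <- setNames(rep(taxa, vapply(taxa, function(tx)
    as.integer(cfg$individuals[[tx]] %||% 1L), integer(1))), samples)
  sample_rates <- NULL
  if (!is.null(cfg$branch_rates)) {   # taxon-level multipliers -> individuals
    r <- cfg$branch_rates[sample_taxon[samples]]
    names(r) <- samples
    r <- r[!is.na(r)]
    if (length(r)) sample_rates <- r
  }
  submodel <- substitution_model(rates = cfg$gtr_rates,
                                 base_freqs = cfg$base_freqs,
                                 gamma_shape = cfg$gamma_shape,
                                 n_cat = cfg$n_cat,
                                 branch_rates = sample_rates)
  core <- samples[sample_taxon %in% cfg$core_taxa]
  # occupancy: core samples always present, others at presence_prob; one RNG
  # substream per gene so adding genes never perturbs earlier ones
  presence <- matrix(TRUE, cfg$n_genes, length(samples),
                     dimnames = list(sprintf("gene_%04d", seq_len(cfg$n_genes)),
                                     samples))
  for (i in seq_len(cfg$n_genes)) {
    presence[i, ] <- with_seed(derive_seed(seed, i, 1),
                               runif(length(samples)) < cfg$presence_prob)
    presence[i, core] <- TRUE
  }
  gene_trees <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    gt <- if (is.null(event))
      simulate_gene_tree(model, individuals_per_taxon = cfg$individuals,
                         seed = derive_seed(seed, i, 2))
    else
      simulate_network_gene_tree(model, event,
                                 individuals_per_taxon = cfg$individuals,
                                 seed = derive_seed(seed, i, 2))
    gene_trees[[i]] <- gt
    a <- evolve_sequences(gt, submodel, cfg$n_sites,
                          seed = derive_seed(seed, i, 3),
                          subst_per_coal = cfg$subst_per_coal)
    a <- inject_missingness(a, function(n) rbeta(n, cfg$missing_beta[1],
                                                 cfg$missing_beta[2]),
                            seed = derive_seed(seed, i, 4))
    keep <- samples[presence[i, ]]
    a <- alignment(unclass(a)[keep, , drop = FALSE])
    write_fasta(a, file.path(dir, "aln", sprintf("gene_%04d.fasta", i)))
  }
  plastid <- simulate_gene_tree(model, seed = derive_seed(seed, 0, 5))
  writeLines(ape::write.tree(sp, digits = 10), file.path(dir, "species.nwk"))
  writeLines(ape::write.tree(plastid, digits = 10), file.path(dir, "plastid.nwk"))
  writeLines(vapply(gene_trees, function(t) ape::write.tree(t, digits = 10),
                    character(1)), file.path(dir, "genetrees.nwk"))
  write_orthogroups(orthogroup_table(presence), file.path(dir, "orthogroups.tsv"))
  write.table(data.frame(individual = samples,
                         taxon = unname(sample_taxon[samples])),
              file.path(dir, "map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(
    scenario = name, seed = seed,
    n_genes = cfg$n_genes, n_sites = cfg$n_sites,
    subst_per_coal = cfg$subst_per_coal,
    substitution_model = list(rates = cfg$gtr_rates,
                              base_freqs = cfg$base_freqs,
                              gamma_shape = cfg$gamma_shape,
                              n_cat = cfg$n_cat),
    branch_rates = as.list(cfg$branch_rates %||% setNames(list(), character())),
    individuals = cfg$individuals,
    hybrid_event = cfg$hybrid,
    outgroup = cfg$outgroup,
    species_newick = cfg$species_newick,
    plastid_synthetic = TRUE,
    theta = 1)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(load_bundle(dir))
}

#' @rdname make_scenario
#' @export
load_bundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  species <- parse_newick(readLines(file.path(dir, "species.nwk")),
                          units = "coalescent")
  plastid_file <- file.path(dir, "plastid.nwk")
  plastid <- if (file.exists(plastid_file))
    parse_newick(readLines(plastid_file), units = "coalescent")
  gts <- ape::read.tree(file.path(dir, "genetrees.nwk"))
  if (inherits(gts, "phylo")) gts <- structure(list(gts), class = "multiPhylo")
  files <- sort(list.files(file.path(dir, "aln"), full.names = TRUE))
  alns <- lapply(files, read_fasta)
  names(alns) <- sub("\\.fasta$", "", basename(files))
  list(dir = dir, manifest = manifest, species = species, plastid = plastid,
       gene_trees = gts, alignments = alns,
       orthogroups = read_orthogroups(file.path(dir, "orthogroups.tsv")),
       map = read.table(file.path(dir, "map.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE))
}
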