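#' Analysis configuration
#'
#' Collects every path, threshold and simulation setting of the pipeline;
#' thresholds default to the reference protocol (occupancy 0.70, column
#' missingness 0.20, length classes 1000/2000 bp, ABS 60, support collapse
#' 50, alpha 0.05 with Bonferroni correction, null cutoff 0.05, 10,000 MSC
#' simulations). The seed is mandatory: every stochastic stage derives a
#' named substream from it. The config is echoed verbatim into the output
#' manifest.
#'
#' @param bundle_dir input bundle directory (see [make_scenario()] for the
#'   layout).
#' @param out_dir output directory.
#' @param seed integer master seed (mandatory).
#' @param occupancy_fraction,column_missing,length_classes,analysis_class,
#'   abs_threshold,support_collapse,alpha,correction,null_cutoff,n_sim,
#'   null_replicates,n_bootstrap,long_branch_factor,prune_long_branches,
#'   max_combos thresholds and settings; see the reference protocol above.
#' @param outgroup outgroup taxon (default: the bundle manifest's).
#' @param organelle_refs optional FASTA of organellar reference sequences
#'   for the contamination screen (skipped when `NULL`).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(bundle_dir, out_dir, seed,
                            occupancy_fraction = 0.70,
                            column_missing = 0.20,
                            length_classes = c(1000, 2000),
                            analysis_class = NULL,
                            abs_threshold = 60,
                            support_collapse = 50,
                            alpha = 0.05,
                            correction = "bonferroni",
                            null_cutoff = 0.05,
                            n_sim = 10000,
                            null_replicates = 100,
                            n_bootstrap = 500,
                            long_branch_factor = 5,
                            prune_long_branches = FALSE,
                            max_combos = 10000,
                            outgroup = NULL,
                            organelle_refs = NULL) {
  if (missing(seed) || is.null(seed)) stopf("`seed` is mandatory")
  stopifnot(occupancy_fraction > 0, occupancy_fraction <= 1,
            column_missing >= 0, column_missing <= 1,
            alpha > 0, alpha < 1, null_cutoff >= 0, null_cutoff <= 1,
            n_sim >= 1, n_bootstrap >= 1)
  cfg <- list(bundle_dir = bundle_dir, out_dir = out_dir, seed = as.integer(seed),
              occupancy_fraction = occupancy_fraction,
              column_missing = column_missing,
              length_classes = sort(length_classes),
              analysis_class = analysis_class %||% min(length_classes),
              abs_threshold = abs_threshold,
              support_collapse = support_collapse, alpha = alpha,
              correction = correction, null_cutoff = null_cutoff,
              n_sim = n_sim, null_replicates = null_replicates,
              n_bootstrap = n_bootstrap,
              long_branch_factor = long_branch_factor,
              prune_long_branches = prune_long_branches,
              max_combos = max_combos,
              outgroup = outgroup, organelle_refs = organelle_refs)
  class(cfg) <- "analysis_config"
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full discordance pipeline
#'
#' Stages, in order: ortholog filtering (occupancy, optional organellar
#' screen, column trimming, NJ gene trees with bootstrap, long-branch
#' flagging, length classes, ABS filter, supermatrix concatenation),
#' concordance accounting, ILS assessment (empirical-vs-simulated RF
#' distributions and cyto-nuclear attribution), the hybridization scan, the
#' null-simulation filter, and report TSVs plus a manifest. Reruns with an
#' identical config are byte-identical for the deterministic outputs. A
#' stage failure aborts with the stage name; partial outputs are kept under
#' a `failed/` marker.
#'
#' @param config an [analysis_config()].
#' @param stages subset of stages to run (mainly for the subcommand CLI).
#' @return (invisibly) the output directory.
#' @export
run_pipeline <- function(config,
                         stages = c("filter", "concord", "ils", "hyde",
                                    "nullfilter", "report")) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    if (!name %in% c("load", stages)) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      dir.create(file.path(out, "failed"), showWarnings = FALSE)
      writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)),
                 file.path(out, "failed", "MARKER"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  run_stage("load", function() {
    state$bundle <- load_bundle(config$bundle_dir)
    state$outgroup <- config$outgroup %||% state$bundle$manifest$outgroup
    state$samples <- state$bundle$map$individual
  })

  run_stage("filter", function() {
    b <- state$bundle
    og <- filter_by_occupancy(b$orthogroups, config$occupancy_fraction)
    alns <- b$alignments[intersect(names(b$alignments), rownames(og))]
    screen_report <- NULL
    if (!is.null(config$organelle_refs)) {
      refs <- read_fasta(config$organelle_refs)
      refseqs <- apply(unclass(refs), 1, paste, collapse = "")
      geneseqs <- vapply(alns, function(a)
        gsub("[-N?]", "", paste(unclass(a)[1, ], collapse = "")), character(1))
      scr <- screen_organellar(geneseqs, refseqs)
      screen_report <- scr$report
      alns <- alns[scr$kept]
    }
    trimmed <- lapply(alns, filter_alignment_columns,
                      max_missing_frac = config$column_missing)
    records <- vector("list", length(trimmed))
    flagged <- character(length(trimmed))
    for (i in seq_along(trimmed)) {
      rec <- estimate_gene_tree_nj(trimmed[[i]],
                                   n_bootstrap = config$n_bootstrap,
                                   seed = derive_seed(config$seed, i, 10),
                                   gene_id = names(trimmed)[i])
      fl <- flag_long_branches(rec, factor = config$long_branch_factor,
                               prune = config$prune_long_branches)
      flagged[i] <- paste(fl$flagged, collapse = ",")
      records[[i]] <- fl$record
    }
    keep <- !vapply(records, is.null, logical(1))
    records <- records[keep]; trimmed <- trimmed[keep]
    classes <- partition_by_length(trimmed, config$length_classes)
    cls <- as.character(config$analysis_class)
    in_class <- names(trimmed) %in% names(classes[[cls]])
    class_records <- records[in_class]
    retained <- filter_by_abs(class_records, config$abs_threshold)
    retained_ids <- vapply(retained, function(r) r$gene_id, character(1))
    sm <- concatenate_alignments(trimmed[retained_ids], state$samples)
    write_fasta(sm$alignment, file.path(out, "supermatrix.fasta"))
    write_partitions(sm$partitions, file.path(out, "partitions.txt"))
    summary <- data.frame(
      gene = names(trimmed),
      length_post_trim = vapply(trimmed, ncol, integer(1)),
      abs = vapply(records, function(r) r$abs, numeric(1)),
      flagged_taxa = flagged[keep],
      in_class = in_class,
      retained = names(trimmed) %in% retained_ids)
    write_tsv(summary, file.path(out, "filter_summary.tsv"))
    if (!is.null(screen_report))
      write_tsv(screen_report, file.path(out, "organelle_screen.tsv"))
    state$records <- records
    state$retained <- retained
    state$supermatrix <- sm$alignment
    state$partitions <- sm$partitions
  })

  run_stage("concord", function() {
    species <- root_with_outgroup(state$bundle$species, state$outgroup)
    # tree-level analyses use one representative individual per taxon
    state$rep_trees <- lapply(state$retained, function(r)
      representative_tree(r$tree, state$bundle$map))
    cs <- map_concordance(species, state$rep_trees,
                          support_collapse = config$support_collapse)
    pf <- pie_fractions(cs)
    write_tsv(cbind(cs, pf[, 3:6]), file.path(out, "concordance.tsv"))
    cloud <- prepare_cloud_trees(state$retained, state$samples)
    if (length(cloud$trees))
      writeLines(vapply(cloud$trees, function(t) ape::write.tree(t, digits = 10),
                        character(1)), file.path(out, "cloud_trees.nwk"))
    state$concordance <- cs
  })

  run_stage("ils", function() {
    model <- species_tree_model(state$bundle$species)
    sims <- simulate_gene_tree(model, seed = derive_seed(config$seed, 1, 20),
                               n = config$n_sim)
    rep_trees <- state$rep_trees %||% lapply(state$retained, function(r)
      representative_tree(r$tree, state$bundle$map))
    emp <- distance_distribution(rep_trees, state$bundle$species,
                                 source = "empirical")
    sim <- distance_distribution(sims, state$bundle$species, source = "simulated")
    cmp <- compare_distributions(emp, sim)
    write_tsv(cmp$histogram, file.path(out, "distance_histogram.tsv"))
    write_tsv(data.frame(statistic = c("mean_empirical", "mean_simulated",
                                       "var_empirical", "var_simulated",
                                       "overlap", "ks_statistic", "ks_p"),
                         value = c(cmp$mean_empirical, cmp$mean_simulated,
                                   cmp$var_empirical, cmp$var_simulated,
                                   cmp$overlap, cmp$ks_statistic, cmp$ks_p)),
              file.path(out, "distance_comparison.tsv"))
    if (!is.null(state$bundle$plastid)) {
      att <- attribute_conflicts(model, state$bundle$plastid,
                                 n_sim = config$n_sim,
                                 seed = derive_seed(config$seed, 2, 20))
      write_tsv(as.data.frame(att), file.path(out, "cytonuclear.tsv"))
    }
  })

  run_stage("hyde", function() {
    res <- scan_triples(state$supermatrix, state$bundle$map, state$outgroup,
                        alpha = config$alpha, correction = config$correction,
                        max_combos = config$max_combos,
                        seed = derive_seed(config$seed, 1, 25),
                        partitions = state$partitions)
    write_tsv(as.data.frame(res), file.path(out, "hyde_scan.tsv"))
    hyb <- state$bundle$manifest$hybrid_event
    if (!is.null(hyb)) {
      nm <- node_mode(res, state$bundle$species, hyb$hybrid)
      if (nrow(nm$summary))
        write_tsv(nm$summary, file.path(out, "node_mode_summary.tsv"))
    }
    state$hyde <- res
  })

  run_stage("nullfilter", function() {
    # species-level empirical tree: one representative sequence per taxon
    subst_tree <- nj_jc(representative_alignment(state$supermatrix,
                                                 state$bundle$map))
    man <- state$bundle$manifest$substitution_model
    model <- if (!is.null(man))
      substitution_model(rates = unlist(man$rates),
                         base_freqs = unlist(man$base_freqs),
                         gamma_shape = man$gamma_shape, n_cat = man$n_cat)
    else substitution_model()
    rep <- null_hypothesis_filter(state$hyde, subst_tree, model,
                                  n_replicates = config$null_replicates,
                                  seed = derive_seed(config$seed, 1, 30),
                                  cutoff = config$null_cutoff,
                                  taxon_map = state$bundle$map)
    write_tsv(as.data.frame(rep), file.path(out, "null_filter.tsv"))
    write_tsv(as.data.frame(rep[rep$verdict == "retained", , drop = FALSE]),
              file.path(out, "retained_hybridizations.tsv"))
  })

  run_stage("report", function() {
    b <- state$bundle
    inputs <- sort(c(list.files(config$bundle_dir, full.names = TRUE,
                                recursive = TRUE)))
    manifest <- list(config = unclass(config),
                     inputs = data.frame(file = sub(paste0("^", config$bundle_dir, "/?"),
                                                    "", inputs),
                                         md5 = unname(tools::md5sum(inputs))),
                     package_version = as.character(utils::packageVersion("phylodisc")))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    render_reports(out, species = root_with_outgroup(b$species, state$outgroup))
  })

  invisible(out)
}

#' Render SVG figures from pipeline TSVs
#'
#' Pure views of the stage outputs: the species tree with per-node
#' concordance pies, the empirical-versus-simulated distance histogram, and
#' the gamma heatmap (a placeholder figure when no test was significant).
#' Missing stage outputs are skipped with a warning.
#'
#' @param out_dir a [run_pipeline()] output directory containing the TSVs
#'   (and, for the pie figure, the bundle's species tree copied there by the
#'   pipeline or available via `species`).
#' @param species optional species tree (`phylo`) for the pie figure.
#' @return (invisibly) the paths of the figures written.
#' @export
render_reports <- function(out_dir, species = NULL) {
  written <- character(0)
  try_svg <- function(path, expr) {
    ok <- tryCatch({
      svg(path, width = 7, height = 6)
      on.exit(dev.off(), add = TRUE)
      expr
      TRUE
    }, error = function(e) {
      warnf("figure %s skipped: %s", basename(path), conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }
  hist_file <- file.path(out_dir, "distance_histogram.tsv")
  if (file.exists(hist_file)) {
    h <- read.table(hist_file, header = TRUE, sep = "\t")
    try_svg(file.path(out_dir, "distance_histogram.svg"), {
      plot(h$distance, h$p_empirical, type = "h", lwd = 6, col = "tomato",
           xlab = "RF distance to species tree", ylab = "proportion",
           main = "Empirical vs simulated gene-tree distances")
      points(h$distance + 0.25, h$p_simulated, type = "h", lwd = 6,
             col = "steelblue")
      legend("topleft", c("empirical", "simulated"), bty = "n",
             fill = c("tomato", "steelblue"))
    })
  } else warnf("distance_histogram.tsv missing; histogram skipped")
  conc_file <- file.path(out_dir, "concordance.tsv")
  if (file.exists(conc_file) && !is.null(species)) {
    cs <- read.table(conc_file, header = TRUE, sep = "\t")
    try_svg(file.path(out_dir, "concordance_pies.svg"), {
      plot(species, main = "Per-node gene-tree concordance")
      ape::nodelabels(node = cs$node,
                      pie = as.matrix(cs[, c("f_concordant", "f_top_conflict",
                                             "f_other_conflict",
                                             "f_uninformative")]),
                      piecol = c("forestgreen", "orange", "firebrick", "grey"),
                      cex = 0.6)
    })
  }
  hyde_file <- file.path(out_dir, "hyde_scan.tsv")
  if (file.exists(hyde_file)) {
    hs <- read.table(hyde_file, header = TRUE, sep = "\t")
    sig <- hs[hs$significant %in% TRUE, , drop = FALSE]
    try_svg(file.path(out_dir, "gamma_heatmap.svg"), {
      if (!nrow(sig)) {
        plot.new(); title("gamma heatmap")
        text(0.5, 0.5, "no significant hybridization test")
      } else {
        taxa <- sort(unique(c(sig$p1, sig$p2)))
        m <- matrix(NA_real_, length(taxa), length(taxa),
                    dimnames = list(taxa, taxa))
        for (i in seq_len(nrow(sig))) {
          m[sig$p1[i], sig$p2[i]] <- sig$gamma[i]
          m[sig$p2[i], sig$p1[i]] <- 1 - sig$gamma[i]
        }
        image(seq_along(taxa), seq_along(taxa), t(m), zlim = c(0, 1),
              axes = FALSE, xlab = "P2", ylab = "P1 (gamma from row)",
              main = "Significant inheritance probabilities")
        axis(1, seq_along(taxa), taxa, las = 2, cex.axis = 0.7)
        axis(2, seq_along(taxa), taxa, las = 2, cex.axis = 0.7)
      }
    })
  }
  invisible(written)
}

# ---- subcommand CLI ---------------------------------------------------------

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        flags[[key]] <- args[i + 1]; i <- i + 2L
      } else { flags[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a scenario bundle), `run` (full pipeline),
#' `filter`, `concord`, `ils`, `hyde`, `nullfilter` (single stages; earlier
#' stages they depend on are run too), `report` (figures only). Settings are
#' resolved as defaults, then command-line flags, then a `--config` JSON
#' file. Exit status: 0 success, 2 validation error, 3 stage failure.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (invisibly).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: phylodisc <simulate|run|filter|concord|ils|hyde|",
                 "nullfilter|report> [--bundle DIR] [--out DIR] [--seed N]",
                 "[--scenario NAME] [--config FILE.json]")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  flags <- parse_cli_flags(args[-1])
  if (!is.null(flags$config)) {
    file_cfg <- jsonlite::read_json(flags$config, simplifyVector = TRUE)
    flags[names(file_cfg)] <- file_cfg   # config file overrides flags
  }
  status <- tryCatch({
    switch(cmd,
      simulate = {
        if (is.null(flags$scenario) || is.null(flags$seed) || is.null(flags$out))
          stopf("simulate needs --scenario, --seed and --out")
        make_scenario(flags$scenario, as.integer(flags$seed), dir = flags$out,
                      n_genes = flags$n_genes, n_sites = flags$n_sites)
        0L
      },
      run = , filter = , concord = , ils = , hyde = , nullfilter = {
        if (is.null(flags$bundle) || is.null(flags$seed) || is.null(flags$out))
          stopf("%s needs --bundle, --seed and --out", cmd)
        known <- names(formals(analysis_config))
        extra <- flags[intersect(names(flags), setdiff(known, c("bundle_dir",
                                                                "out_dir", "seed")))]
        cfg <- do.call(analysis_config,
                       c(list(bundle_dir = flags$bundle, out_dir = flags$out,
                              seed = as.integer(flags$seed)), extra))
        all_stages <- c("filter", "concord", "ils", "hyde", "nullfilter", "report")
        stages <- if (cmd == "run") all_stages
                  else all_stages[seq_len(match(cmd, all_stages))]
        run_pipeline(cfg, stages = stages)
        0L
      },
      report = {
        if (is.null(flags$out)) stopf("report needs --out")
        render_reports(flags$out)
        0L
      },
      { message(usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("^pipeline stage", conditionMessage(e))) 3L else 2L
  })
  invisible(status)
}
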