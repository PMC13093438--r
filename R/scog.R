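#' Orthogroup presence tables
#'
#' A Proteinortho-like table: one row per orthogroup (gene), one column per
#' sample; each occupied cell names the sample's sequence for that gene,
#' `*` marks absence. Internally a logical presence matrix with a `pointers`
#' attribute carrying the sequence identifiers.
#'
#' @param presence logical matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param pointers optional character matrix of the same shape with sequence
#'   identifiers (`*` where absent).
#' @return an object of class `orthogroup_table`.
#' @export
orthogroup_table <- function(presence, pointers = NULL) {
  if (!is.matrix(presence) || !is.logical(presence))
    stopf("`presence` must be a logical matrix")
  if ((nrow(presence) > 0 && is.null(rownames(presence))) ||
      (ncol(presence) > 0 && is.null(colnames(presence))))
    stopf("presence matrix needs gene rownames and sample colnames")
  if (is.null(pointers)) {
    pointers <- matrix("*", nrow(presence), ncol(presence),
                       dimnames = dimnames(presence))
    pointers[presence] <- paste0(rownames(presence)[row(presence)[presence]],
                                 "|", colnames(presence)[col(presence)[presence]])
  }
  structure(presence, pointers = pointers, class = c("orthogroup_table",
                                                     "matrix", "array"))
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat(sprintf("<orthogroup table: %d genes x %d samples, occupancy %.2f>\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' @rdname orthogroup_table
#' @param tab an `orthogroup_table`.
#' @param file a TSV path.
#' @export
write_orthogroups <- function(tab, file) {
  ptr <- attr(tab, "pointers")
  df <- data.frame(`# Species` = rowSums(tab), Genes = rowSums(tab),
                   `Alg.-Conn.` = 1, check.names = FALSE)
  df <- cbind(df, as.data.frame(ptr, stringsAsFactors = FALSE))
  out <- cbind(orthogroup = rownames(tab), df)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname orthogroup_table
#' @export
read_orthogroups <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "")
  samples <- setdiff(colnames(df), c("orthogroup", "# Species", "Genes", "Alg.-Conn."))
  ptr <- as.matrix(df[, samples, drop = FALSE])
  rownames(ptr) <- df$orthogroup
  orthogroup_table(ptr != "*", pointers = ptr)
}

#' Occupancy filter for orthogroups
#'
#' Keeps genes present in at least `floor(min_fraction * n_samples)` samples.
#' With 47 samples and `min_fraction = 0.7` the integer cutoff is 32, the
#' reference protocol's printed value (consistent only with `floor`).
#'
#' @param table an [orthogroup_table()].
#' @param min_fraction required presence fraction, in (0, 1\].
#' @return a filtered `orthogroup_table`.
#' @export
filter_by_occupancy <- function(table, min_fraction) {
  if (min_fraction <= 0 || min_fraction > 1)
    stopf("`min_fraction` must be in (0, 1]")
  if (nrow(table) == 0) {
    warnf("empty orthogroup table")
    return(table)
  }
  cutoff <- floor(min_fraction * ncol(table))
  message(sprintf("occupancy filter: keeping genes present in >= %d of %d samples",
                  cutoff, ncol(table)))
  keep <- rowSums(table) >= cutoff
  orthogroup_table(unclass(table)[keep, , drop = FALSE],
                   pointers = attr(table, "pointers")[keep, , drop = FALSE])
}

# ---- organellar screening ---------------------------------------------------

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

kmer_set <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    out <- c(out, substring(s, 1:(n - k + 1), k:n))
  }
  unique(toupper(out))
}

#' Screen genes against organellar reference sequences
#'
#' Exact k-mer containment triage replacing a BLAST screen: a gene is removed
#' when the fraction of its k-mers found in any reference (either strand) is
#' at least `min_shared_frac`.
#'
#' @param genes named character vector of gene sequences.
#' @param organelle_refs character vector of reference sequences (e.g., a
#'   plastome); must be non-empty.
#' @param k k-mer size (>= 11; default 21).
#' @param min_shared_frac shared-fraction removal threshold (default 0.5).
#' @return list with `kept`, `removed` (gene names) and a `report` data frame
#'   of per-gene shared fractions.
#' @export
screen_organellar <- function(genes, organelle_refs, k = 21,
                              min_shared_frac = 0.5) {
  if (k < 11) stopf("`k` must be >= 11")
  if (!length(organelle_refs)) stopf("no organelle reference sequences given")
  refs <- kmer_set(c(organelle_refs, revcomp(organelle_refs)), k)
  frac <- vapply(genes, function(g) {
    km <- kmer_set(g, k)
    if (!length(km)) return(NA_real_)
    mean(km %in% refs)
  }, numeric(1))
  short <- is.na(frac)
  if (any(short))
    warnf("%d gene(s) shorter than k = %d kept without screening", sum(short), k)
  removed <- !short & frac >= min_shared_frac
  list(kept = names(genes)[!removed], removed = names(genes)[removed],
       report = data.frame(gene = names(genes), shared_frac = unname(frac),
                           stringsAsFactors = FALSE))
}

#' Remove alignment columns with too much missing data
#'
#' Columns whose fraction of missing symbols (`-`, `N`, `?`) is strictly
#' greater than `max_missing_frac` are deleted; surviving columns are kept
#' verbatim and their original (1-based) indices are attached as the
#' `kept_columns` attribute.
#'
#' @param aln an [alignment()].
#' @param max_missing_frac threshold in \[0, 1\] (reference protocol: 0.2,
#'   i.e., "> 20% missing" removed).
#' @return the column-filtered alignment.
#' @export
filter_alignment_columns <- function(aln, max_missing_frac = 0.2) {
  if (max_missing_frac < 0 || max_missing_frac > 1)
    stopf("`max_missing_frac` must be in [0, 1]")
  frac <- column_missing_fraction(aln)
  keep <- frac <= max_missing_frac
  if (!any(keep)) warnf("all columns removed by the missing-data filter")
  out <- alignment(unclass(aln)[, keep, drop = FALSE])
  attr(out, "kept_columns") <- which(keep)
  out
}

#' Partition genes into minimum-length classes
#'
#' One (non-disjoint) class per ascending threshold: the genes whose
#' post-trimming alignment length is at least that threshold (e.g., 1000 and
#' 2000 bp classes).
#'
#' @param alns named list of [alignment()]s.
#' @param min_lengths ascending integer thresholds.
#' @return named list (one element per threshold) of alignment subsets.
#' @export
partition_by_length <- function(alns, min_lengths) {
  if (is.unsorted(min_lengths)) stopf("`min_lengths` must be ascending")
  lens <- vapply(alns, ncol, integer(1))
  out <- lapply(min_lengths, function(th) alns[lens >= th])
  names(out) <- as.character(min_lengths)
  out
}

#' Filter gene-tree records by average bootstrap support
#'
#' Keeps records whose ABS strictly exceeds the threshold (a record with
#' ABS exactly 60.0 is removed at threshold 60).
#'
#' @param records list of `gene_tree_record`s.
#' @param threshold ABS cutoff (reference protocol: 60).
#' @return the retained records.
#' @export
filter_by_abs <- function(records, threshold = 60) {
  abs_vals <- vapply(records, function(r) r$abs, numeric(1))
  if (anyNA(abs_vals)) stopf("every record must carry an ABS value")
  records[abs_vals > threshold]
}

#' Flag (and optionally prune) unusually long terminal branches
#'
#' A leaf is flagged when its pendant branch exceeds `factor` times the
#' median pendant branch length; a simplified stand-in for a statistical
#' long-branch test, aimed at paralogy/misassembly artifacts.
#'
#' @param record a `gene_tree_record`.
#' @param factor multiple of the median pendant branch (default 5).
#' @param prune drop flagged leaves from the tree (default `FALSE`).
#' @return list with `record` (possibly pruned; `NULL` with a warning when
#'   pruning leaves fewer than 4 leaves) and `flagged` taxa.
#' @export
flag_long_branches <- function(record, factor = 5, prune = FALSE) {
  tr <- record$tree
  if (is.null(tr$edge.length)) stopf("tree has no branch lengths")
  nt <- length(tr$tip.label)
  tipedge <- tr$edge[, 2] <= nt
  pend <- setNames(tr$edge.length[tipedge], tr$tip.label[tr$edge[tipedge, 2]])
  med <- median(pend)
  flagged <- names(pend)[pend > factor * med]
  out <- record
  if (prune && length(flagged)) {
    if (nt - length(flagged) < 4) {
      warnf("gene %s dropped: fewer than 4 leaves after long-branch pruning",
            record$gene_id)
      return(list(record = NULL, flagged = flagged))
    }
    out$tree <- ape::drop.tip(tr, flagged)
  }
  list(record = out, flagged = flagged)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Taxa missing from a gene are padded with `?` across that gene's block.
#' The partition table gives 1-based inclusive start/end columns per gene.
#'
#' @param alns named list of [alignment()]s (names are gene ids, unique).
#' @param taxa taxon labels of the supermatrix rows.
#' @return list with `alignment` (the supermatrix) and `partitions`
#'   (data.frame gene/start/end).
#' @export
concatenate_alignments <- function(alns, taxa) {
  if (!length(alns)) stopf("no alignments to concatenate")
  if (is.null(names(alns)) || anyDuplicated(names(alns)))
    stopf("gene ids must be unique and named")
  blocks <- vector("list", length(alns))
  start <- integer(length(alns)); end <- integer(length(alns))
  pos <- 0L
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    block <- matrix("?", length(taxa), ncol(a), dimnames = list(taxa, NULL))
    shared <- intersect(taxa, rownames(a))
    block[shared, ] <- unclass(a)[shared, , drop = FALSE]
    blocks[[i]] <- block
    start[i] <- pos + 1L
    pos <- pos + ncol(a)
    end[i] <- pos
  }
  sm <- alignment(do.call(cbind, blocks))
  list(alignment = sm,
       partitions = data.frame(gene = names(alns), start = start, end = end,
                               stringsAsFactors = FALSE))
}

#' @rdname concatenate_alignments
#' @param partitions the partition data frame.
#' @param file output path (RAxML-style plain text).
#' @export
write_partitions <- function(partitions, file) {
  writeLines(sprintf("DNA, %s = %d-%d", partitions$gene, partitions$start,
                     partitions$end), file)
  invisible(file)
}
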