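#' Multiple sequence alignments
#'
#' An alignment is stored as an upper-case character matrix with one row per
#' taxon (rownames are the taxon labels) and one column per site, over the
#' closed alphabet `A,C,G,T,-,N,?`. `alignment()` validates and normalizes;
#' `read_fasta()`/`read_phylip()` load the two supported on-disk formats and
#' `write_fasta()`/`write_phylip()` write them back deterministically.
#'
#' @param x a character matrix (taxa in rows), or a named character vector of
#'   equal-length sequence strings.
#' @return an object of class `aln` (a character matrix).
#' @examples
#' a <- alignment(c(t1 = "ACGT", t2 = "AC-T"))
#' n_sites(a)
#' @export
alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x))) stopf("sequences must be named by taxon")
    lens <- nchar(x)
    if (length(unique(lens)) > 1L)
      stopf("rows have unequal lengths: %s", paste(unique(lens), collapse = ", "))
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
    x <- m
  }
  if (!is.matrix(x) || !is.character(x)) stopf("`x` must be a character matrix")
  if (is.null(rownames(x))) stopf("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(x))) stopf("duplicate taxon labels in alignment")
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), c("A", "C", "G", "T", "-", "N", "?"))
  if (length(bad))
    stopf("alignment contains symbols outside {A,C,G,T,-,N,?}: %s",
          paste(bad, collapse = " "))
  structure(x, class = c("aln", "matrix", "array"))
}

#' @rdname alignment
#' @param aln an `aln` object.
#' @export
n_sites <- function(aln) ncol(aln)

#' @rdname alignment
#' @export
n_taxa <- function(aln) nrow(aln)

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("<alignment: %d taxa x %d sites>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname alignment
#' @param file path to a FASTA or relaxed PHYLIP file.
#' @export
read_fasta <- function(file) {
  d <- ape::read.FASTA(file)
  m <- toupper(as.character(as.matrix(d)))
  alignment(m)
}

#' @rdname alignment
#' @export
write_fasta <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (tx in rownames(aln))
    writeLines(c(paste0(">", tx), paste(aln[tx, ], collapse = "")), con)
  invisible(file)
}

#' @rdname alignment
#' @export
read_phylip <- function(file) {
  d <- phangorn::read.phyDat(file, format = "phylip", type = "DNA")
  m <- toupper(as.character(d))
  alignment(m)
}

#' @rdname alignment
#' @export
write_phylip <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", nrow(aln), ncol(aln)), con)
  for (tx in rownames(aln))
    writeLines(paste0(tx, "  ", paste(aln[tx, ], collapse = "")), con)
  invisible(file)
}

# integer coding used by the site-pattern counter: A,C,G,T -> 0..3,
# anything else (gap/ambiguity) -> -1
encode_dna <- function(aln) {
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  m <- matrix(-1L, nrow(aln), ncol(aln), dimnames = dimnames(aln))
  hit <- aln %in% names(code)
  m[hit] <- code[aln[hit]]
  m
}

# fraction of missing symbols ({-, N, ?}) per column
column_missing_fraction <- function(aln, missing_symbols = c("-", "N", "?")) {
  colMeans(matrix(aln %in% missing_symbols, nrow(aln), ncol(aln)))
}
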