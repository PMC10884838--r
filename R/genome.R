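#' Genome container
#'
#' A small in-memory genome: named chromosome sequences plus a feature
#' table. Feature intervals are 0-based half-open internally; every
#' user-facing report and SAM/VCF output is 1-based.
#'
#' @param chroms named character vector of uppercase A/C/G/T sequences
#' @param features data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `kind` (one of
#'   `gene`, `telomere_tract`, `rdna_array`, `identical_region`,
#'   `essential_gene`), `name`
#' @return an object of class `gcr_genome`
#' @export
gcr_genome <- function(chroms, features = empty_features()) {
  g <- structure(list(chroms = chroms, features = features),
                 class = "gcr_genome")
  validate_genome(g)
  g
}

FEATURE_KINDS <- c("gene", "telomere_tract", "rdna_array",
                   "identical_region", "essential_gene")

#' Empty feature table with the canonical columns
#' @return zero-row feature data.frame
#' @export
empty_features <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
              strand = character(0), kind = character(0), name = character(0),
              stringsAsFactors = FALSE)
}

#' Validate a genome object
#'
#' Checks chromosome name uniqueness, alphabet, and that every feature
#' interval lies within its chromosome.
#' @param g a `gcr_genome`
#' @return `g`, invisibly
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "gcr_genome"))
  ch <- g$chroms
  if (length(ch) == 0 || any(nchar(ch) == 0))
    stop("genome must have non-empty chromosome sequences")
  if (is.null(names(ch)) || anyDuplicated(names(ch)))
    stop("chromosome names must be present and unique")
  if (any(grepl("[^ACGT]", ch)))
    stop("chromosome sequences must use the uppercase {A,C,G,T} alphabet")
  f <- g$features
  if (nrow(f)) {
    if (!all(f$kind %in% FEATURE_KINDS))
      stop("unknown feature kind: ",
           paste(setdiff(f$kind, FEATURE_KINDS), collapse = ", "))
    if (!all(f$chrom %in% names(ch)))
      stop("feature on unknown chromosome")
    if (!all(f$start < f$end))
      stop("feature intervals must satisfy start < end")
    if (!all(f$start >= 0 & f$end <= nchar(ch)[match(f$chrom, names(ch))]))
      stop("feature interval outside chromosome bounds")
    if (!all(f$strand %in% c("+", "-")))
      stop("feature strand must be '+' or '-'")
  }
  invisible(g)
}

#' @export
print.gcr_genome <- function(x, ...) {
  cat("gcr_genome:", length(x$chroms), "chromosome(s),",
      sum(nchar(x$chroms)), "bp,", nrow(x$features), "feature(s)\n")
  for (nm in names(x$chroms))
    cat(sprintf("  %-8s %8d bp\n", nm, nchar(x$chroms[[nm]])))
  invisible(x)
}

chrom_lengths <- function(g) setNames(nchar(g$chroms), names(g$chroms))

feature_rows <- function(g, kind = NULL, chrom = NULL, name = NULL) {
  f <- g$features
  if (!is.null(kind)) f <- f[f$kind %in% kind, , drop = FALSE]
  if (!is.null(chrom)) f <- f[f$chrom %in% chrom, , drop = FALSE]
  if (!is.null(name)) f <- f[f$name %in% name, , drop = FALSE]
  f
}

#' Extract a feature's sequence in coding orientation
#'
#' Returns the genomic substring of the feature, reverse-complemented
#' for minus-strand features.
#' @param g a `gcr_genome`
#' @param row a single feature row (`chrom`, `start`, `end`, `strand`)
#' @return character string
#' @export
feature_seq <- function(g, row) {
  s <- subseq0(g$chroms[[row$chrom]], row$start, row$end)
  if (row$strand == "-") s <- revcomp(s)
  s
}

#' Write a genome to FASTA
#' @param g a `gcr_genome`
#' @param path output FASTA path
#' @param width line width
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(g, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$chroms), path,
                              width = width)
  invisible(path)
}

#' Read a genome from FASTA (+ optional feature BED)
#'
#' @param fasta path to a FASTA file
#' @param bed optional BED path as written by [write_features_bed()]
#'   (BED6; the name column is `kind:name`)
#' @return a `gcr_genome`
#' @export
read_genome_fasta <- function(fasta, bed = NULL) {
  ss <- Biostrings::readDNAStringSet(fasta)
  chroms <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  feats <- if (!is.null(bed)) read_features_bed(bed) else empty_features()
  gcr_genome(chroms, feats)
}

#' Write features as BED6
#'
#' BED is 0-based half-open, matching the internal convention; the BED
#' name column stores `kind:name`.
#' @param g a `gcr_genome`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_features_bed <- function(g, path) {
  f <- g$features
  bed <- data.frame(chrom = f$chrom, start = f$start, end = f$end,
                    name = paste0(f$kind, ":", f$name), score = 0L,
                    strand = f$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_features_bed <- function(path) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "score", "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "integer", "character"))
  kn <- regmatches(bed$name, regexpr("^[^:]+", bed$name))
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             strand = bed$strand, kind = kn,
             name = sub("^[^:]+:", "", bed$name), stringsAsFactors = FALSE)
}
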