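#' @useDynLib gcrscope, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median mad setNames
#' @importFrom utils write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA string
#' @param n length in bases
#' @return a single uppercase A/C/G/T string of length `n`
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of character DNA
#'
#' Vectorized over its input; accepts and returns plain character vectors
#' (IUPAC codes handled by Biostrings).
#' @param x character vector of DNA strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based half-open substring
subseq0 <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

# replace seq[start, end) (0-based half-open) with `with`
splice0 <- function(seq, start, end, with) {
  stopifnot(nchar(with) == end - start)
  paste0(substring(seq, 1L, start), with, substring(seq, end + 1L, nchar(seq)))
}

# mutate a DNA string: i.i.d. substitutions at `rate`, never to the same base
mutate_dna <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  paste(ch, collapse = "")
}

# force x[pos] (1-based) to differ from seq's current base there
force_mismatch <- function(seq, pos) {
  b <- substring(seq, pos, pos)
  substring(seq, pos, pos) <- sample(setdiff(DNA_BASES, b), 1L)
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# terminal soft-clip lengths from CIGAR strings (vectorized)
clip_lens <- function(cigar) {
  l <- rep(0L, length(cigar))
  m <- regexpr("^[0-9]+S", cigar)
  l[m > 0] <- as.integer(sub("S", "", regmatches(cigar, m)))
  r <- rep(0L, length(cigar))
  m <- regexpr("[0-9]+S$", cigar)
  r[m > 0] <- as.integer(sub("S", "", regmatches(cigar, m)))
  list(left = l, right = r)
}
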