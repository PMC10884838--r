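#' Exact k-mer mappability
#'
#' For every position p (with a complete k-mer), the mappability value is
#' 1 / (number of genome positions whose k-mer lies within Hamming
#' distance `m` of the k-mer starting at p, counting p itself), so values
#' are in (0, 1] and 1 marks genome-wide unique sequence. Matching is
#' exact (no heuristics): candidate pairs are found by pigeonhole chunk
#' seeding and verified by full Hamming comparison.
#'
#' By default only forward-strand k-mers are compared (the convention of
#' index-based mappability tools); `both_strands = TRUE` additionally
#' counts reverse-strand occurrences.
#'
#' @param genome a `gcr_genome` (total length at most 5 Mb)
#' @param k k-mer length (>= 4); defaults to 100
#' @param m allowed mismatches, one of 0, 1, 2
#' @param both_strands also count reverse-strand k-mer matches
#' @return a `mappability_track`: list with `values` (per-chromosome
#'   numeric vectors, position i covering bases `[i, i+k)` 0-based),
#'   `k`, `m`, `both_strands`
#' @export
compute_mappability <- function(genome, k = 100L, m = 2L,
                                both_strands = FALSE) {
  stopifnot(inherits(genome, "gcr_genome"), k >= 4, m %in% 0:2)
  if (sum(nchar(genome$chroms)) > 5e6)
    stop("genome larger than the 5 Mb brute-force guard")
  if (k > min(nchar(genome$chroms)))
    stop("k exceeds the shortest chromosome length")
  seqs <- genome$chroms
  if (both_strands) {
    cnt <- mappability_counts_cpp(c(seqs, revcomp(seqs)), as.integer(k),
                                  as.integer(m))
    cnt <- cnt[seq_along(seqs)]
  } else {
    cnt <- mappability_counts_cpp(seqs, as.integer(k), as.integer(m))
  }
  values <- lapply(cnt, function(x) 1 / x)
  names(values) <- names(seqs)
  structure(list(values = values, k = as.integer(k), m = as.integer(m),
                 both_strands = both_strands),
            class = "mappability_track")
}

#' Extract unique regions from a mappability track
#'
#' Maximal runs of positions with mappability exactly 1 whose length is
#' strictly greater than `min_len` ("larger than" 1 kb by default).
#'
#' @param track a `mappability_track`
#' @param min_len minimum run length (exclusive bound), bp
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open,
#'   in k-mer start coordinates), sorted and non-overlapping
#' @export
extract_unique_regions <- function(track, min_len = 1000L) {
  stopifnot(inherits(track, "mappability_track"))
  out <- lapply(names(track$values), function(cn) {
    v <- track$values[[cn]]
    if (!length(v)) return(NULL)
    r <- rle(v == 1)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths > min_len
    if (!any(keep)) return(NULL)
    data.frame(chrom = cn, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  out
}
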