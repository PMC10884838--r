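#' Cluster soft-clipped reads into junction candidates
#'
#' Reads whose CIGAR carries a terminal soft clip of at least `min_clip`
#' bases are grouped by (chromosome, clip coordinate, clip side); groups
#' below `min_support` are dropped. The junction is reported as the
#' 1-based coordinate of the first retained (aligned) base adjacent to
#' the clip: the leftmost aligned base for a left clip, the rightmost for
#' a right clip. The consensus of the clipped parts is oriented 5'->3'
#' away from the retained side (left-clip sequences are
#' reverse-complemented), so for a healed chromosome end it reads into
#' the added sequence regardless of arm; per-column majority voting
#' breaks ties with `N`.
#'
#' @param alignments SAM/BAM path or [read_alignments()] result
#' @param min_clip minimum clip length considered (bp)
#' @param min_support minimum reads per cluster
#' @return data.frame: `chrom`, `junction`, `side` (left_clip /
#'   right_clip), `support`, `consensus_clip`, `mean_clip_len`
#' @export
cluster_soft_clips <- function(alignments, min_clip = 10L,
                               min_support = 3L) {
  aln <- as_alignments(alignments)
  r <- aln$reads
  r <- r[!bitwAnd(r$flag, 4L) & !is.na(r$pos), , drop = FALSE]
  empty <- data.frame(chrom = character(0), junction = integer(0),
                      side = character(0), support = integer(0),
                      consensus_clip = character(0),
                      mean_clip_len = numeric(0))
  if (!nrow(r)) return(empty)
  ok <- grepl("^([0-9]+[MIDNSHP=X])+$", r$cigar)
  if (any(!ok)) {
    warning(sum(!ok), " read(s) with malformed CIGAR skipped")
    r <- r[ok, , drop = FALSE]
  }
  if (!nrow(r)) return(empty)
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(r$cigar)
  cl <- clip_lens(r$cigar)
  lclip <- cl$left
  rclip <- cl$right
  rows <- list()
  li <- which(lclip >= min_clip)
  if (length(li))
    rows$left <- data.frame(
      chrom = r$rname[li], junction = r$pos[li], side = "left_clip",
      clip = revcomp(substring(r$seq[li], 1L, lclip[li])),
      stringsAsFactors = FALSE)
  ri <- which(rclip >= min_clip)
  if (length(ri))
    rows$right <- data.frame(
      chrom = r$rname[ri], junction = r$pos[ri] + refw[ri] - 1L,
      side = "right_clip",
      clip = substring(r$seq[ri], nchar(r$seq[ri]) - rclip[ri] + 1L),
      stringsAsFactors = FALSE)
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) return(empty)

  key <- paste(rows$chrom, rows$junction, rows$side, sep = "\r")
  out <- lapply(split(rows, key), function(g) {
    if (nrow(g) < min_support) return(NULL)
    data.frame(chrom = g$chrom[1], junction = g$junction[1],
               side = g$side[1], support = nrow(g),
               consensus_clip = consensus_string(g$clip),
               mean_clip_len = mean(nchar(g$clip)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$junction, out$side), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-column majority vote, anchored at position 1 (the junction-adjacent
# base); ties vote N
consensus_string <- function(clips) {
  L <- max(nchar(clips))
  ch <- vapply(clips, function(x) {
    v <- strsplit(x, "", fixed = TRUE)[[1]]
    c(v, rep(NA_character_, L - length(v)))
  }, character(L))
  if (is.null(dim(ch))) ch <- matrix(ch, nrow = L)
  cons <- apply(ch, 1, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_character_)
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) "N" else names(tb)[1]
  })
  paste(cons[!is.na(cons)], collapse = "")
}

#' Score telomeric repeat content of a sequence
#'
#' Finds the largest tandem chain of core-motif copies in which
#' consecutive cores are separated by at most `max_spacer` non-core
#' bases (fission-yeast telomeric repeats are degenerate: GGTTAC cores
#' with short spacers). The sequence is telomeric when the chain has at
#' least `min_copies` cores and spans at least half the sequence.
#'
#' @param seq uppercase nucleotide string
#' @param core core repeat motif
#' @param max_spacer maximum bases between consecutive cores
#' @param min_copies minimum cores for a telomeric verdict
#' @return list `(telomere_score, is_telomeric)`
#' @export
score_telomeric <- function(seq, core = "GGTTAC", max_spacer = 2L,
                            min_copies = 2L) {
  stopifnot(nzchar(seq))
  occ <- gregexpr(core, seq, fixed = TRUE)[[1]]
  if (occ[1] == -1) return(list(telomere_score = 0L, is_telomeric = FALSE))
  st <- as.integer(occ)
  en <- st + nchar(core) - 1L
  n <- length(st)
  score <- rep(1L, n)
  first <- st
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      gap <- st[i] - en[j] - 1L
      if (gap >= 0 && gap <= max_spacer && score[j] + 1L > score[i]) {
        score[i] <- score[j] + 1L
        first[i] <- first[j]
      }
    }
  }
  best <- which(score == max(score))
  span <- max(en[best] - first[best] + 1L)
  ts <- max(score)
  list(telomere_score = ts,
       is_telomeric = ts >= min_copies && span >= 0.5 * nchar(seq))
}

#' Realign a clip consensus against the genome
#'
#' Seed-and-extend: exact seeds of length `min_hit_len` are taken along
#' the clip (half-seed stride) and located on both strands; each seed
#' hit is extended ungapped over the whole clip, allowing up to
#' `max_mismatch` mismatches. `N` positions (consensus ties) are
#' excluded from seeding and identity. The reported `partner_coord` is
#' the 1-based genome base aligned to the clip's first (junction-
#' adjacent) base, and `strand` is the genome strand the clip (oriented
#' away from the retained side) matches — `-` means the partner
#' sequence runs toward lower coordinates away from the junction.
#'
#' @param consensus_clip oriented clip consensus
#' @param genome a `gcr_genome`
#' @param min_hit_len exact seed length; clips shorter than this return
#'   an empty table flagged `too_short`
#' @param max_mismatch mismatch budget for the ungapped extension
#' @return data.frame of hits (`chrom`, `pos`, `end`, `strand`,
#'   `identity`, `aln_len`, `partner_coord`), sorted by alignment length
#'   then identity
#' @export
realign_clip <- function(consensus_clip, genome, min_hit_len = 15L,
                         max_mismatch = 2L) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), aln_len = integer(0),
                      partner_coord = integer(0))
  L <- nchar(consensus_clip)
  if (L < min_hit_len) {
    attr(empty, "flag") <- "too_short"
    return(empty)
  }
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") consensus_clip else revcomp(consensus_clip)
    qch <- strsplit(q, "", fixed = TRUE)[[1]]
    offs <- unique(c(seq(1L, L - min_hit_len + 1L,
                         by = max(1L, min_hit_len %/% 2L)),
                     L - min_hit_len + 1L))
    starts <- integer(0)  # candidate genome starts per chrom handled below
    for (cn in names(genome$chroms)) {
      gseq <- genome$chroms[[cn]]
      Lg <- nchar(gseq)
      cand <- integer(0)
      for (o in offs) {
        seed <- substring(q, o, o + min_hit_len - 1L)
        if (grepl("N", seed, fixed = TRUE)) next
        mp <- Biostrings::matchPattern(seed, Biostrings::DNAString(gseq))
        if (!length(mp)) next
        cand <- c(cand, BiocGenerics::start(mp) - (o - 1L))
      }
      for (gs in unique(cand)) {
        a <- max(1L, gs)
        b <- min(Lg, gs + L - 1L)
        qa <- a - gs + 1L
        qb <- b - gs + 1L
        if (qb - qa + 1L < min_hit_len) next
        gch <- strsplit(substring(gseq, a, b), "", fixed = TRUE)[[1]]
        qq <- qch[qa:qb]
        informative <- qq != "N"
        alen <- sum(informative)
        if (alen < min_hit_len) next
        mm <- sum(qq[informative] != gch[informative])
        if (mm > max_mismatch) next
        pc <- if (strand == "+") a - (qa - 1L) else b + (qa - 1L)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = cn, pos = a, end = b, strand = strand,
          identity = 100 * (alen - mm) / alen, aln_len = alen,
          partner_coord = pc, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  h <- h[!duplicated(h[, c("chrom", "pos", "strand")]), , drop = FALSE]
  h <- h[order(-h$aln_len, -h$identity, h$chrom, h$pos), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Junction microhomology length
#'
#' Both flanks are given on the junction-forming strand:
#' `retained_flank` 5'->3' ending at the junction, `partner_flank`
#' 5'->3' starting at it. The microhomology is the longest L for which
#' the last L bases contributed by one side equal the next L bases
#' contributed by the other, making the exact junction ambiguous over L
#' bases; 0 when not even the junction-adjacent bases match. The measure
#' is symmetric under swapping roles together with reverse
#' complementation (reading the junction on the other strand).
#'
#' @param retained_flank sequence ending at the junction
#' @param partner_flank sequence starting at the junction
#' @return integer microhomology length
#' @export
measure_microhomology <- function(retained_flank, partner_flank) {
  w <- min(nchar(retained_flank), nchar(partner_flank))
  for (L in rev(seq_len(w))) {
    if (substring(retained_flank, nchar(retained_flank) - L + 1L) ==
        substring(partner_flank, 1L, L))
      return(L)
  }
  0L
}
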