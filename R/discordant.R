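#' Detect discordant read-pair groups
#'
#' A primary pair is discordant when its mates share orientation (FF/RR:
#' inversion signal), map to different chromosomes, or span more than
#' `insert_mean + 5 * insert_sd` on the same chromosome (long insert).
#' Flagged pairs are clustered per kind with a window of
#' `insert_mean + 3 * insert_sd` on both loci.
#'
#' @param alignments SAM/BAM path or [read_alignments()] result; must be
#'   paired
#' @param insert_mean,insert_sd insert statistics; when `NULL` they are
#'   estimated from proper pairs as median and MAD of the template length
#' @param min_pairs minimum supporting pairs per group
#' @return data.frame of groups: `kind` (inversion_FF, inversion_RR,
#'   inter_chromosomal, long_insert), `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB` (1-based inclusive loci), `support`
#' @export
find_discordant_pairs <- function(alignments, insert_mean = NULL,
                                  insert_sd = NULL, min_pairs = 3L) {
  aln <- as_alignments(alignments)
  r <- aln$reads
  if (!nrow(r) || !any(bitwAnd(r$flag, 1L) > 0))
    stop("unpaired input: discordant-pair detection needs a paired library")
  if (is.null(insert_mean) || is.null(insert_sd)) {
    proper <- bitwAnd(r$flag, 2L) > 0 & !is.na(r$isize) & r$isize > 0
    if (!any(proper)) stop("cannot estimate insert size: no proper pairs")
    if (is.null(insert_mean)) insert_mean <- median(r$isize[proper])
    if (is.null(insert_sd)) insert_sd <- mad(r$isize[proper])
  }
  pr <- pair_table(r)
  if (!nrow(pr)) return(empty_groups())
  span <- ifelse(pr$chrom1 == pr$chrom2,
                 pmax(pr$end1, pr$end2) - pmin(pr$pos1, pr$pos2), NA)
  kind <- rep(NA_character_, nrow(pr))
  kind[pr$chrom1 != pr$chrom2] <- "inter_chromosomal"
  same <- pr$chrom1 == pr$chrom2
  kind[same & pr$strand1 == "+" & pr$strand2 == "+"] <- "inversion_FF"
  kind[same & pr$strand1 == "-" & pr$strand2 == "-"] <- "inversion_RR"
  long <- same & pr$strand1 != pr$strand2 &
    span > insert_mean + 5 * insert_sd
  kind[is.na(kind) & long] <- "long_insert"
  pr$kind <- kind
  pr <- pr[!is.na(kind), , drop = FALSE]
  if (!nrow(pr)) return(empty_groups())

  # locusA = lexicographically smaller mate (header chromosome order)
  ord <- names(aln$seqlengths)
  flip <- (match(pr$chrom2, ord) < match(pr$chrom1, ord)) |
    (pr$chrom1 == pr$chrom2 & pr$pos2 < pr$pos1)
  sw <- function(a, b) list(ifelse(flip, b, a), ifelse(flip, a, b))
  ca <- sw(pr$chrom1, pr$chrom2); pa <- sw(pr$pos1, pr$pos2)
  ea <- sw(pr$end1, pr$end2)
  d <- data.frame(kind = pr$kind, chromA = ca[[1]], posA = pa[[1]],
                  endA = ea[[1]], chromB = ca[[2]], posB = pa[[2]],
                  endB = ea[[2]], stringsAsFactors = FALSE)
  cw <- insert_mean + 3 * insert_sd
  out <- list()
  for (k in unique(d$kind)) {
    dk <- d[d$kind == k, , drop = FALSE]
    dk <- dk[order(dk$chromA, dk$posA, dk$posB), , drop = FALSE]
    cid <- integer(nrow(dk)); cur <- 0L
    lastA <- -Inf; loB <- Inf; hiB <- -Inf; lastCA <- ""; lastCB <- ""
    for (i in seq_len(nrow(dk))) {
      if (cur == 0L || dk$chromA[i] != lastCA || dk$chromB[i] != lastCB ||
          dk$posA[i] - lastA > cw ||
          dk$posB[i] < loB - cw || dk$posB[i] > hiB + cw) {
        cur <- cur + 1L
        loB <- dk$posB[i]; hiB <- dk$posB[i]
      }
      cid[i] <- cur
      lastA <- dk$posA[i]; lastCA <- dk$chromA[i]; lastCB <- dk$chromB[i]
      loB <- min(loB, dk$posB[i]); hiB <- max(hiB, dk$posB[i])
    }
    for (g in split(dk, cid)) {
      if (nrow(g) < min_pairs) next
      out[[length(out) + 1L]] <- data.frame(
        kind = k, chromA = g$chromA[1], startA = min(g$posA),
        endA = max(g$endA), chromB = g$chromB[1], startB = min(g$posB),
        endB = max(g$endB), support = nrow(g), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_groups())
  out <- do.call(rbind, out)
  out <- out[order(out$chromA, out$startA, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_groups <- function() {
  data.frame(kind = character(0), chromA = character(0),
             startA = integer(0), endA = integer(0), chromB = character(0),
             startB = integer(0), endB = integer(0), support = integer(0))
}

# mapped primary mate pairs, one row each, with 1-based inclusive spans
pair_table <- function(r) {
  m <- r[!bitwAnd(r$flag, 4L) & !is.na(r$pos), , drop = FALSE]
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(m$cigar)
  m$endpos <- m$pos + refw - 1L
  m$strand <- ifelse(bitwAnd(m$flag, 16L) > 0, "-", "+")
  first <- m[bitwAnd(m$flag, 64L) > 0, , drop = FALSE]
  second <- m[bitwAnd(m$flag, 128L) > 0, , drop = FALSE]
  i <- match(first$qname, second$qname)
  ok <- !is.na(i)
  first <- first[ok, , drop = FALSE]
  second <- second[i[ok], , drop = FALSE]
  data.frame(qname = first$qname,
             chrom1 = first$rname, pos1 = first$pos, end1 = first$endpos,
             strand1 = first$strand, mapq1 = first$mapq,
             chrom2 = second$rname, pos2 = second$pos, end2 = second$endpos,
             strand2 = second$strand, mapq2 = second$mapq,
             cigar1 = first$cigar, cigar2 = second$cigar,
             stringsAsFactors = FALSE)
}

#' Collect read pairs supporting a chimeric gene
#'
#' A pair supports the chimera of `geneA` and `geneB` when one mate
#' anchors in one gene and the other mate in the other, with an implied
#' insert on the chimeric molecule within `insert_mean +/- 3 *
#' insert_sd` (the implied insert is measured through the shared
#' identical interval, so it does not depend on the chimera's
#' orientation). Because the two genes share the identical region, a
#' mate lying entirely inside it is consistent with both parental loci;
#' `informative` therefore counts only pairs with at least one
#' discriminating (gene-specific) base on each side, plus single reads
#' that span the switch itself (a soft clip at an identical-interval
#' edge with aligned gene-specific sequence). `support` additionally
#' admits pairs discriminating on only one side.
#'
#' @param alignments SAM/BAM path or [read_alignments()] result
#' @param geneA,geneB single feature rows (`chrom`, `start`, `end`,
#'   `strand`, `name`; 0-based half-open)
#' @param identical genomic identical interval: list with `chromA`,
#'   `startA`, `endA`, `chromB`, `startB`, `endB` (0-based half-open);
#'   mandatory — the operation is only defined for homology-mediated
#'   chimeras
#' @param insert_mean,insert_sd library insert statistics
#' @return list: `geneA`, `geneB`, `support`, `informative`, `pairs`
#'   (qnames of informative evidence)
#' @export
collect_chimera_support <- function(alignments, geneA, geneB, identical,
                                    insert_mean = 300, insert_sd = 30) {
  if (is.null(identical))
    stop("identical interval required: chimera support is only defined ",
         "for homology-mediated chimeras")
  aln <- as_alignments(alignments)
  pr <- pair_table(aln$reads)
  idw <- identical$endA - identical$startA

  ov <- function(lo, hi, s, e) pmax(0L, pmin(hi, e) - pmax(lo, s))
  side_stats <- function(chrom, lo, hi, gene, id_s, id_e) {
    # lo/hi 0-based half-open mate span; distL/distR: distance from the
    # mate's outer end to the identical interval when the gene
    # contributes its left/right side to the chimera
    ing <- chrom == gene$chrom & ov(lo, hi, gene$start, gene$end) > 0
    disc <- ing & (ov(lo, hi, gene$start, id_s) > 0 |
                   ov(lo, hi, id_e, gene$end) > 0)
    list(ing = ing, disc = disc, distL = id_s - lo, distR = hi - id_e)
  }
  ev <- function(lo1, hi1, c1, lo2, hi2, c2) {
    a <- side_stats(c1, lo1, hi1, geneA, identical$startA, identical$endA)
    b <- side_stats(c2, lo2, hi2, geneB, identical$startB, identical$endB)
    # the chimera can join any side of gene A to any side of gene B
    # through the shared interval (counted once); a pair is plausible if
    # some junction form implies a normal insert
    plaus <- rep(FALSE, length(lo1))
    for (da in list(a$distL, a$distR)) for (db in list(b$distL, b$distR))
      plaus <- plaus | abs(da + idw + db - insert_mean) <= 3 * insert_sd
    list(inform = a$disc & b$disc & plaus,
         half = a$ing & b$ing & (a$disc | b$disc) & plaus)
  }
  lo1 <- pr$pos1 - 1L; hi1 <- pr$end1
  lo2 <- pr$pos2 - 1L; hi2 <- pr$end2
  unique_ok <- pr$mapq1 > 0 & pr$mapq2 > 0
  e1 <- ev(lo1, hi1, pr$chrom1, lo2, hi2, pr$chrom2)
  e2 <- ev(lo2, hi2, pr$chrom2, lo1, hi1, pr$chrom1)
  inform <- unique_ok & (e1$inform | e2$inform)
  halfsup <- unique_ok & (e1$half | e2$half)

  # single reads spanning the switch: soft clip at an identical edge with
  # gene-specific aligned bases
  span_read <- function(chrom, lo, hi, cig, gene, id_s, id_e) {
    cl <- clip_lens(cig)
    at_edge <- (abs(lo - id_s) <= 1L & cl$left >= 5L) |
      (abs(hi - id_e) <= 1L & cl$right >= 5L)
    disc <- chrom == gene$chrom &
      (ov(lo, hi, gene$start, id_s) > 0 | ov(lo, hi, id_e, gene$end) > 0)
    at_edge & disc
  }
  sp <- (span_read(pr$chrom1, lo1, hi1, pr$cigar1, geneA,
                   identical$startA, identical$endA) |
         span_read(pr$chrom1, lo1, hi1, pr$cigar1, geneB,
                   identical$startB, identical$endB) |
         span_read(pr$chrom2, lo2, hi2, pr$cigar2, geneA,
                   identical$startA, identical$endA) |
         span_read(pr$chrom2, lo2, hi2, pr$cigar2, geneB,
                   identical$startB, identical$endB)) & unique_ok

  informative <- inform | sp
  support <- informative | halfsup
  list(geneA = geneA$name, geneB = geneB$name,
       support = sum(support), informative = sum(informative),
       pairs = pr$qname[informative])
}

#' Narrow a homology-mediated breakpoint to its identical interval
#'
#' Globally aligns the two homologous sequences (unit scores, free end
#' gaps) in chimera-forming orientation and reports the maximal run of
#' identical alignment columns containing the switch column. When the
#' switch column itself is not identical the interval has length 0 and
#' `is_exact = FALSE`.
#'
#' @param seqA,seqB homologous sequences, already oriented so the
#'   chimera reads straight through both (reverse-complement one of an
#'   inverted pair first)
#' @param approx_break 1-based coordinate in `seqA` near the switch
#' @param match,mismatch,gap alignment scores (gap given as a positive
#'   penalty)
#' @return list `(seqA_range, seqB_range, length, is_exact)`; ranges are
#'   1-based inclusive in the supplied sequences
#' @export
narrow_breakpoint_interval <- function(seqA, seqB, approx_break,
                                       match = 1, mismatch = -1, gap = 2) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seqA), Biostrings::DNAString(seqB),
    type = "overlap", substitutionMatrix = sm,
    gapOpening = 0, gapExtension = gap)
  va <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  vb <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  offA <- Biostrings::start(Biostrings::pattern(pa))
  offB <- Biostrings::start(Biostrings::subject(pa))
  posA <- offA - 1L + cumsum(va != "-")
  posB <- offB - 1L + cumsum(vb != "-")
  idcol <- va == vb & va != "-"
  none <- list(seqA_range = c(NA_integer_, NA_integer_),
               seqB_range = c(NA_integer_, NA_integer_),
               length = 0L, is_exact = FALSE)
  sc <- which(posA == approx_break & va != "-")[1]
  if (is.na(sc) || !idcol[sc]) return(none)
  l <- sc; while (l > 1L && idcol[l - 1L]) l <- l - 1L
  r <- sc; while (r < length(idcol) && idcol[r + 1L]) r <- r + 1L
  list(seqA_range = c(posA[l], posA[r]), seqB_range = c(posB[l], posB[r]),
       length = r - l + 1L, is_exact = TRUE)
}
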