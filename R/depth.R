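#' Read alignments from SAM/BAM
#'
#' SAM input is converted with `Rsamtools::asBam()` before parsing; only
#' the fields the pipeline consumes are materialized.
#'
#' @param path SAM or BAM file
#' @return list with `reads` (data.frame: qname, flag, rname, pos, mapq,
#'   cigar, mrnm, mpos, isize, seq) and `seqlengths` (named integer
#'   vector from the header)
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  reads <- data.frame(qname = x$qname, flag = x$flag,
                      rname = as.character(x$rname), pos = x$pos,
                      mapq = x$mapq, cigar = x$cigar,
                      mrnm = as.character(x$mrnm), mpos = x$mpos,
                      isize = x$isize, seq = as.character(x$seq),
                      stringsAsFactors = FALSE)
  list(reads = reads, seqlengths = hdr)
}

as_alignments <- function(alignments) {
  if (is.character(alignments) && length(alignments) == 1)
    return(read_alignments(alignments))
  stopifnot(is.list(alignments), !is.null(alignments$reads),
            !is.null(alignments$seqlengths))
  alignments
}

# reference spans (IRanges per chromosome) of the aligned (non-clipped)
# part of each mapped read
aligned_spans <- function(reads) {
  m <- reads[!bitwAnd(reads$flag, 4L) & !is.na(reads$pos), , drop = FALSE]
  ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    m$cigar, pos = m$pos, ops = c("M", "=", "X"))
  list(reads = m, spans = ir)
}

#' Sliding-window normalized depth over unique regions
#'
#' Per-base depth counts reads whose aligned (non-clipped) span covers
#' the base, after a mapping-quality filter. Windows tile each unique
#' region from its start in steps of `bin`; a trailing window shorter
#' than `bin/2` is dropped. The genome mean is the average depth over all
#' windowed unique-region bases, so the length-weighted mean of
#' `normalized_depth` is exactly 1.
#'
#' @param alignments SAM/BAM path or the result of [read_alignments()]
#' @param regions unique regions, as from [extract_unique_regions()]
#' @param bin window size (bp)
#' @param min_mapq minimum mapping quality
#' @return a `depth_profile`: list with `windows` (chrom, start, end
#'   0-based half-open, raw_depth = mean depth, normalized_depth), `bin`,
#'   `genome_mean`
#' @export
windowed_depth <- function(alignments, regions, bin = 200L, min_mapq = 0L) {
  aln <- as_alignments(alignments)
  if (nrow(aln$reads) == 0) stop("empty alignment file")
  if (nrow(regions) == 0) stop("no unique regions supplied")
  bad <- setdiff(unique(regions$chrom), names(aln$seqlengths))
  if (length(bad))
    stop("region chromosome(s) absent from alignment header: ",
         paste(bad, collapse = ", "))
  sp <- aligned_spans(aln$reads)
  keep <- sp$reads$mapq >= min_mapq
  covs <- lapply(names(aln$seqlengths), function(cn) {
    idx <- keep & sp$reads$rname == cn
    IRanges::coverage(unlist(sp$spans[idx]), width = aln$seqlengths[[cn]])
  })
  names(covs) <- names(aln$seqlengths)

  win <- lapply(seq_len(nrow(regions)), function(i) {
    rs <- regions$start[i]; re <- regions$end[i]
    ws <- seq(rs, re - 1L, by = bin)
    we <- pmin(ws + bin, re)
    ok <- (we - ws) >= bin / 2
    if (!any(ok)) return(NULL)
    data.frame(chrom = regions$chrom[i], start = ws[ok], end = we[ok],
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, win)
  if (is.null(win) || nrow(win) == 0)
    stop("no analyzable windows (regions shorter than bin/2)")

  sums <- numeric(nrow(win))
  for (cn in unique(win$chrom)) {
    i <- win$chrom == cn
    v <- IRanges::Views(covs[[cn]], start = win$start[i] + 1L,
                        end = win$end[i])
    sums[i] <- IRanges::viewSums(v)
  }
  widths <- win$end - win$start
  genome_mean <- sum(sums) / sum(widths)
  if (genome_mean <= 0) stop("no aligned bases fall in unique regions")
  win$raw_depth <- sums / widths
  win$normalized_depth <- win$raw_depth / genome_mean
  structure(list(windows = win, bin = as.integer(bin),
                 genome_mean = genome_mean),
            class = "depth_profile")
}

#' Call terminal copy-number changes from a depth profile
#'
#' Scans inward from each chromosome end over consecutive profile
#' windows. A run of at least `min_windows` windows with normalized depth
#' below `del_ratio_max` (deletion) or above `dup_ratio_min`
#' (duplication) that starts at the outermost analyzable window is
#' called. Interior CNVs are deliberately not called here; the boundary
#' is depth-resolution only (±1 bin) and is refined by soft-clip
#' evidence downstream.
#'
#' Coverage always sags over the outermost few hundred bases of a
#' chromosome because fragments must fit inside it; up to
#' `max_edge_skip` windows at the very tip may therefore be skipped
#' before a run starts (they are not counted in `mean_ratio`).
#'
#' @param profile a `depth_profile`
#' @param del_ratio_max normalized-depth ceiling for deletions
#' @param dup_ratio_min normalized-depth floor for duplications
#' @param min_windows minimum run length in windows
#' @param max_edge_skip tip windows a run may skip and still count as
#'   starting at the chromosome end
#' @return data.frame of calls: `chrom`, `side` (left/right), `kind`
#'   (deletion/duplication), `boundary` (1-based first base at normal
#'   copy for deletions / last duplicated base for duplications, i.e.
#'   the near edge of the first window breaking the run), `inner_edge`
#'   (near edge of the last window inside the run — the junction lies
#'   between `inner_edge` and `boundary`), `mean_ratio`, `n_windows`
#' @export
call_terminal_cnv <- function(profile, del_ratio_max = 0.25,
                              dup_ratio_min = 1.5, min_windows = 10L,
                              max_edge_skip = 2L) {
  stopifnot(inherits(profile, "depth_profile"))
  w <- profile$windows
  calls <- list()
  scan_side <- function(wc, side) {
    if (side == "right") wc <- wc[rev(seq_len(nrow(wc))), , drop = FALSE]
    x <- wc$normalized_depth
    for (kind in c("deletion", "duplication")) {
      inrun <- if (kind == "deletion") x < del_ratio_max else
        x > dup_ratio_min
      s <- which(inrun[seq_len(min(max_edge_skip + 1L, length(x)))])[1]
      if (is.na(s)) next
      rest <- inrun[s:length(x)]
      len <- which(!rest)[1] - 1L
      if (is.na(len)) len <- length(rest)
      if (len < min_windows) next
      last <- s + len - 1L
      inner_edge <- if (side == "left") wc$end[last] else
        wc$start[last] + 1L
      boundary <- if (last == length(x)) inner_edge
      else if (side == "left") wc$start[last + 1L] + 1L
      else wc$end[last + 1L]
      return(data.frame(chrom = wc$chrom[1], side = side, kind = kind,
                        boundary = boundary, inner_edge = inner_edge,
                        mean_ratio = mean(x[s:last]),
                        n_windows = len, stringsAsFactors = FALSE))
    }
    NULL
  }
  for (cn in unique(w$chrom)) {
    wc <- w[w$chrom == cn, , drop = FALSE]
    wc <- wc[order(wc$start), , drop = FALSE]
    calls <- c(calls, list(scan_side(wc, "left"), scan_side(wc, "right")))
  }
  calls <- calls[!vapply(calls, is.null, TRUE)]
  if (!length(calls))
    return(data.frame(chrom = character(0), side = character(0),
                      kind = character(0), boundary = integer(0),
                      inner_edge = integer(0), mean_ratio = numeric(0),
                      n_windows = integer(0)))
  do.call(rbind, calls)
}
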