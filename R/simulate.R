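#' Paired-end read simulation settings
#'
#' @param read_len read length (bp)
#' @param insert_mean,insert_sd fragment length distribution (bp); lengths
#'   are Normal, truncated at `read_len`
#' @param coverage target mean fold coverage
#' @param error_rate per-base substitution probability (no indel errors,
#'   so truth CIGARs stay exact)
#' @param seed RNG seed
#' @return an object of class `read_sim_config`
#' @export
read_sim_config <- function(read_len = 150L, insert_mean = 300,
                            insert_sd = 30, coverage = 30,
                            error_rate = 0.005, seed = 1L) {
  stopifnot(read_len <= insert_mean, error_rate >= 0, error_rate < 0.05,
            coverage > 0)
  structure(list(read_len = as.integer(read_len), insert_mean = insert_mean,
                 insert_sd = insert_sd, coverage = coverage,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "read_sim_config")
}

add_read_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  rl <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), rl, rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(rl[i], nerr[i])
    for (p in pos) {
      b <- substring(seqs[i], p, p)
      substring(seqs[i], p, p) <- sample(setdiff(DNA_BASES, b), 1L)
    }
  }
  seqs
}

# Truth alignment of a junction-spanning fragment interval [s, e) of a
# mutant chromosome. Each reference-derived block overlapping the read is
# a candidate anchor; the candidate's exact contiguous match is extended
# base-by-base against the reference beyond the block (this reproduces
# aligner behaviour at homology junctions, where the reference continues
# to match past the block boundary). The anchor with the longest exact
# match wins; ties go to the lower (chromosome, coordinate).
junction_align <- function(ref, blk, s, e, frag_chars, min_anchor = 20L) {
  best <- NULL
  ref_order <- names(ref$chroms)
  n <- e - s
  for (i in seq_len(nrow(blk))) {
    if (blk$mut_end[i] <= s || blk$mut_start[i] >= e) next
    if (is.na(blk$ref_chrom[i])) next
    ov_s <- max(s, blk$mut_start[i]); ov_e <- min(e, blk$mut_end[i])
    rc <- blk$ref_chrom[i]
    refseq <- ref$chroms[[rc]]
    Lr <- nchar(refseq)
    if (blk$strand[i] == "+") {
      r_lo <- blk$ref_start[i] + (ov_s - blk$mut_start[i])
      r_hi <- r_lo + (ov_e - ov_s)
      # left extension
      nl <- min(ov_s - s, r_lo)
      extL <- 0L
      if (nl > 0) {
        rch <- strsplit(subseq0(refseq, r_lo - nl, r_lo), "")[[1]]
        for (t in seq_len(nl)) {
          if (frag_chars[ov_s - t - s + 1L] != rch[nl - t + 1L]) break
          extL <- t
        }
      }
      nr <- min(e - ov_e, Lr - r_hi)
      extR <- 0L
      if (nr > 0) {
        rch <- strsplit(subseq0(refseq, r_hi, r_hi + nr), "")[[1]]
        for (t in seq_len(nr)) {
          if (frag_chars[ov_e + t - s] != rch[t]) break
          extR <- t
        }
      }
      cand <- list(rname = rc, strand = "+",
                   ref_lo = r_lo - extL, ref_hi = r_hi + extR,
                   al = ov_s - extL - s, ah = ov_e + extR - s)
    } else {
      # mutant x maps to ref_end - 1 - (x - mut_start)
      r_hi <- blk$ref_end[i] - (ov_s - blk$mut_start[i])
      r_lo <- blk$ref_end[i] - (ov_e - blk$mut_start[i])
      nl <- min(ov_s - s, Lr - r_hi)   # left in mutant = right in ref
      extL <- 0L
      if (nl > 0) {
        rch <- strsplit(chartr("ACGT", "TGCA",
                               subseq0(refseq, r_hi, r_hi + nl)), "")[[1]]
        for (t in seq_len(nl)) {
          if (frag_chars[ov_s - t - s + 1L] != rch[t]) break
          extL <- t
        }
      }
      nr <- min(e - ov_e, r_lo)
      extR <- 0L
      if (nr > 0) {
        rch <- strsplit(chartr("ACGT", "TGCA",
                               subseq0(refseq, r_lo - nr, r_lo)), "")[[1]]
        for (t in seq_len(nr)) {
          if (frag_chars[ov_e + t - s] != rch[nr - t + 1L]) break
          extR <- t
        }
      }
      cand <- list(rname = rc, strand = "-",
                   ref_lo = r_lo - extR, ref_hi = r_hi + extL,
                   al = ov_s - extL - s, ah = ov_e + extR - s)
    }
    cand$mlen <- cand$ah - cand$al
    if (is.null(best) || cand$mlen > best$mlen ||
        (cand$mlen == best$mlen &&
         (match(cand$rname, ref_order) < match(best$rname, ref_order) ||
          (cand$rname == best$rname && cand$ref_lo < best$ref_lo))))
      best <- cand
  }
  if (is.null(best) || best$mlen < min_anchor)
    return(list(mapped = FALSE))
  c(list(mapped = TRUE), best)
}

#' Simulate paired-end reads with truth alignments
#'
#' Fragments are drawn uniformly from the (possibly rearranged) input
#' genome; reads are reported as a standard FR library (which physical
#' fragment end becomes R1 is random). The truth SAM maps every read back
#' to the REFERENCE genome the rearrangement was applied to: reads
#' crossing a junction carry soft-clip CIGARs for the part that is not
#' contiguous on the reference, reads over novel telomeric sequence with
#' fewer than 20 exactly matching reference bases are emitted unmapped,
#' and discordant orientations / inserts arise naturally from the block
#' structure. Substitution errors are applied to read bases but never
#' change the truth CIGAR.
#'
#' @param genome a `gcr_genome`; typically the mutant returned by
#'   [apply_rearrangement()] (a plain genome simulates an unrearranged
#'   library against itself)
#' @param cfg a [read_sim_config()]
#' @param outdir output directory (created if needed)
#' @param prefix file name prefix
#' @return list with paths `fastq1`, `fastq2`, `sam`, the pair count
#'   `n_pairs`, and the sampled `fragments` table (mutant coordinates)
#' @export
simulate_reads <- function(genome, cfg, outdir, prefix = "sim") {
  stopifnot(inherits(genome, "gcr_genome"), inherits(cfg, "read_sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  blocks <- attr(genome, "blocks")
  ref <- attr(genome, "reference")
  if (is.null(blocks)) blocks <- identity_blocks(genome)
  if (is.null(ref)) ref <- genome
  rl <- cfg$read_len
  mchroms <- genome$chroms
  mlens <- nchar(mchroms)
  total <- sum(mlens)
  if (any(mlens < rl)) stop("chromosome shorter than read length")
  n <- round(cfg$coverage * total / (2 * rl))

  ci <- sample.int(length(mchroms), n, replace = TRUE, prob = mlens)
  flen <- pmax(rl, round(rnorm(n, cfg$insert_mean, cfg$insert_sd)))
  flen <- pmin(flen, mlens[ci])
  fstart <- floor(runif(n) * (mlens[ci] - flen + 1))
  swap <- runif(n) < 0.5

  s1 <- fstart; e1 <- fstart + rl
  s2 <- fstart + flen - rl; e2 <- fstart + flen
  seq1 <- substring(mchroms[ci], s1 + 1, e1)
  seq2 <- substring(mchroms[ci], s2 + 1, e2)
  seq1 <- add_read_errors(seq1, cfg$error_rate)
  seq2 <- add_read_errors(seq2, cfg$error_rate)

  align_mate <- function(s, e) {
    out <- data.frame(mapped = logical(n), rname = NA_character_,
                      ref_lo = NA_integer_, ref_hi = NA_integer_,
                      strand = NA_character_, al = 0L, ah = 0L)
    for (c in seq_along(mchroms)) {
      idx <- which(ci == c)
      if (!length(idx)) next
      blk <- blocks[[c]]
      bs <- findInterval(s[idx], blk$mut_start)
      be <- findInterval(e[idx] - 1L, blk$mut_start)
      simple <- bs == be & !is.na(blk$ref_chrom[bs])
      i2 <- idx[simple]
      if (length(i2)) {
        b2 <- bs[simple]
        str <- blk$strand[b2]
        w <- e[i2] - s[i2]
        rlo <- ifelse(str == "+",
                      blk$ref_start[b2] + (s[i2] - blk$mut_start[b2]),
                      blk$ref_end[b2] - (e[i2] - blk$mut_start[b2]))
        out$mapped[i2] <- TRUE
        out$rname[i2] <- blk$ref_chrom[b2]
        out$ref_lo[i2] <- rlo
        out$ref_hi[i2] <- rlo + w
        out$strand[i2] <- str
        out$ah[i2] <- w
      }
      for (j in idx[!simple]) {
        frag <- strsplit(subseq0(mchroms[[c]], s[j], e[j]), "")[[1]]
        ja <- junction_align(ref, blk, s[j], e[j], frag)
        if (!ja$mapped) next
        out$mapped[j] <- TRUE
        out$rname[j] <- ja$rname
        out$ref_lo[j] <- ja$ref_lo
        out$ref_hi[j] <- ja$ref_hi
        out$strand[j] <- ja$strand
        out$al[j] <- ja$al
        out$ah[j] <- ja$ah
      }
    }
    out
  }
  a1 <- align_mate(s1, e1)
  a2 <- align_mate(s2, e2)

  qname <- sprintf("frag%07d", seq_len(n))
  max_tlen <- cfg$insert_mean + 5 * cfg$insert_sd

  sam_fields <- function(a, m, mate, aother, mother) {
    # a: own alignment; m: own mutant-forward sequence (with errors)
    rev <- ifelse(a$mapped, (a$strand == "-") != (mate == 2L), mate == 2L)
    seqs <- ifelse(!a$mapped,
                   if (mate == 2L) revcomp(m) else m,
                   ifelse(a$strand == "+", m, revcomp(m)))
    mlen <- a$ah - a$al
    lclip <- ifelse(a$strand == "+", a$al, rl - a$ah)
    rclip <- rl - lclip - mlen
    cig <- ifelse(!a$mapped, "*",
                  paste0(ifelse(lclip > 0, paste0(lclip, "S"), ""),
                         mlen, "M",
                         ifelse(rclip > 0, paste0(rclip, "S"), "")))
    flag <- 1L +
      ifelse(mate == 1L, 64L, 128L) +
      ifelse(a$mapped, 0L, 4L) + ifelse(aother$mapped, 0L, 8L) +
      ifelse(rev, 16L, 0L) +
      ifelse(aother$mapped & ((aother$strand == "-") != (mate == 1L)),
             32L, 0L)
    orev <- ifelse(aother$mapped, (aother$strand == "-") != (mate == 1L),
                   NA)
    both <- a$mapped & aother$mapped & a$rname == aother$rname
    span <- ifelse(both, pmax(a$ref_hi, aother$ref_hi) -
                         pmin(a$ref_lo, aother$ref_lo), 0L)
    fr <- both & (rev != orev)
    fwd_lo <- ifelse(!rev, a$ref_lo, aother$ref_lo)
    rev_lo <- ifelse(!rev, aother$ref_lo, a$ref_lo)
    proper <- both & fr & fwd_lo <= rev_lo & span <= max_tlen & span >= rl
    flag <- flag + ifelse(!is.na(proper) & proper, 2L, 0L)
    tlen <- ifelse(both,
                   ifelse(a$ref_lo < aother$ref_lo |
                          (a$ref_lo == aother$ref_lo & mate == 1L),
                          span, -span), 0L)
    rnext <- ifelse(!aother$mapped, "*",
                    ifelse(a$mapped & a$rname == aother$rname, "=",
                           aother$rname))
    data.frame(qname = qname,
               flag = flag,
               rname = ifelse(a$mapped, a$rname, "*"),
               pos = ifelse(a$mapped, a$ref_lo + 1L, 0L),
               mapq = ifelse(a$mapped, 60L, 0L),
               cigar = cig, rnext = rnext,
               pnext = ifelse(aother$mapped, aother$ref_lo + 1L, 0L),
               tlen = tlen, seq = seqs, qual = strrep("I", rl),
               stringsAsFactors = FALSE)
  }
  r1 <- sam_fields(a1, seq1, 1L, a2, seq2)
  r2 <- sam_fields(a2, seq2, 2L, a1, seq1)

  # interleave pair lines
  fmt <- function(d) sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                             d$qname, d$flag, d$rname, d$pos, d$mapq,
                             d$cigar, d$rnext, d$pnext, d$tlen, d$seq, d$qual)
  lines <- character(2L * n)
  lines[seq(1L, 2L * n, by = 2L)] <- fmt(r1)
  lines[seq(2L, 2L * n, by = 2L)] <- fmt(r2)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$chroms),
                      nchar(ref$chroms)),
              "@PG\tID:gcrscope\tPN:gcrscope")
  sam <- file.path(outdir, paste0(prefix, ".sam"))
  writeLines(c(header, lines), sam, useBytes = TRUE)

  # FASTQ: R1 = randomly chosen physical end, R2 = the other
  fq_read1 <- ifelse(swap, revcomp(seq2), seq1)
  fq_read2 <- ifelse(swap, revcomp(seq1), seq2)
  write_fastq <- function(seqs, suffix, path) {
    out <- character(4L * n)
    out[seq(1L, 4L * n, by = 4L)] <- paste0("@", qname, "/", suffix)
    out[seq(2L, 4L * n, by = 4L)] <- seqs
    out[seq(3L, 4L * n, by = 4L)] <- "+"
    out[seq(4L, 4L * n, by = 4L)] <- strrep("I", rl)
    writeLines(out, path, useBytes = TRUE)
  }
  fq1 <- file.path(outdir, paste0(prefix, "_R1.fastq"))
  fq2 <- file.path(outdir, paste0(prefix, "_R2.fastq"))
  write_fastq(fq_read1, "1", fq1)
  write_fastq(fq_read2, "2", fq2)

  list(fastq1 = fq1, fastq2 = fq2, sam = sam, n_pairs = n,
       fragments = data.frame(chrom = names(mchroms)[ci], start = fstart,
                              length = flen, stringsAsFactors = FALSE))
}
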