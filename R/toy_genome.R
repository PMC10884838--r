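#' Configuration for the toy genome builder
#'
#' Defaults describe a ~440 kb three-chromosome genome carrying the
#' structural motifs needed to exercise every rearrangement mechanism:
#' degenerate telomeric tracts (tandem GGTTAC cores with occasional 1-2 nt
#' A/C spacers) at every chromosome end; rDNA-like tandem arrays at both
#' ends of the last chromosome; a same-orientation homologous gene pair
#' (P1) on the chrA/chrB terminal regions sharing one perfectly identical
#' internal region (default 240 bp); an inverted-orientation homologous
#' gene pair (P2) flanking a middle gene on the chrB arm, sharing a short
#' identical window (default 12 bp); and an essential gene tens of kb
#' centromeric of P2, which caps how far a terminal deletion may extend.
#'
#' Homolog pairs are genuinely homologous: the second copy is derived from
#' the first by i.i.d. point substitutions (`p1_divergence`,
#' `p2_divergence`), with the identical region copied exactly and the
#' bases immediately flanking it forced to mismatch, so the longest exact
#' shared run is exactly the configured length.
#'
#' @param chrom_sizes named integer vector of chromosome lengths (bp)
#' @param telomere_len minimum telomeric tract length at each end (bp)
#' @param spacer_prob per-core probability of a 1-2 nt A/C spacer
#' @param rdna_unit_len,rdna_copies rDNA-like unit length and tandem copy
#'   number per array
#' @param rdna_margin distance from the telomeric tract to the array (bp)
#' @param p1_geneA_start,p1_geneB_start 0-based gene starts of the P1 pair
#'   (on the first and second chromosome)
#' @param p1_gene_len P1 gene length (bp)
#' @param identical_region_len,identical_offset length and in-gene offset
#'   of the P1 perfectly identical region
#' @param p1_divergence substitution divergence of the P1 homologs outside
#'   the identical region
#' @param p2_gene1_start,p2_gene1_len,p2_middle_start,p2_middle_len,p2_gene2_start,p2_gene2_len
#'   layout of the inverted pair and the gene between them (second
#'   chromosome, 0-based)
#' @param p2_window_len,p2_window_offset length and coding-frame offset of
#'   the P2 identical window
#' @param p2_divergence substitution divergence of the P2 homologs
#' @param essential_start,essential_len most telomeric essential gene
#' @param seed RNG seed; the same seed and config give byte-identical
#'   output
#' @return a named list of class `toy_genome_config`
#' @export
toy_genome_config <- function(chrom_sizes = c(chrA = 120000L, chrB = 200000L,
                                              chrC = 120000L),
                              telomere_len = 300L,
                              spacer_prob = 0.3,
                              rdna_unit_len = 1500L,
                              rdna_copies = 3L,
                              rdna_margin = 400L,
                              p1_geneA_start = 8000L,
                              p1_geneB_start = 30000L,
                              p1_gene_len = 1800L,
                              identical_region_len = 240L,
                              identical_offset = 600L,
                              p1_divergence = 0.08,
                              p2_gene1_start = 52000L,
                              p2_gene1_len = 1600L,
                              p2_middle_start = 56000L,
                              p2_middle_len = 1400L,
                              p2_gene2_start = 60000L,
                              p2_gene2_len = 1600L,
                              p2_window_len = 12L,
                              p2_window_offset = 800L,
                              p2_divergence = 0.10,
                              essential_start = 95000L,
                              essential_len = 2000L,
                              seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "toy_genome_config"
  cfg
}

make_telomere_tract <- function(min_len, spacer_prob, core = "GGTTAC") {
  parts <- character(0)
  len <- 0L
  while (len < min_len) {
    parts <- c(parts, core)
    len <- len + nchar(core)
    if (runif(1) < spacer_prob) {
      sp <- paste(sample(c("A", "C"), sample(1:2, 1), replace = TRUE),
                  collapse = "")
      parts <- c(parts, sp)
      len <- len + nchar(sp)
    }
  }
  paste(parts, collapse = "")
}

# derive a homolog: point substitutions outside the identical span
# (1-based [id_start, id_end]), exact inside, forced mismatches at the
# immediate flanks so the maximal exact shared run is exactly the span.
make_homolog <- function(coding, divergence, id_start, id_end) {
  h <- mutate_dna(coding, divergence)
  if (id_end >= id_start) {
    substring(h, id_start, id_end) <- substring(coding, id_start, id_end)
    if (id_start > 1) {
      b <- substring(coding, id_start - 1, id_start - 1)
      substring(h, id_start - 1, id_start - 1) <-
        sample(setdiff(DNA_BASES, b), 1L)
    }
    if (id_end < nchar(coding)) {
      b <- substring(coding, id_end + 1, id_end + 1)
      substring(h, id_end + 1, id_end + 1) <-
        sample(setdiff(DNA_BASES, b), 1L)
    }
  }
  h
}

#' Build a toy genome with the structural motifs of terminal-deletion GCRs
#'
#' See [toy_genome_config()] for what is placed where. The feature table
#' records every motif (`telomere_tract`, `rdna_array`, `gene`,
#' `identical_region`, `essential_gene`); the two P1 identical-region
#' records share the name `P1_id`, the two P2 window records `P2_id`.
#'
#' @param config a [toy_genome_config()]
#' @return a `gcr_genome` with a `toy_config` attribute
#' @export
build_toy_genome <- function(config = toy_genome_config()) {
  cfg <- config
  set.seed(cfg$seed)
  sizes <- cfg$chrom_sizes
  if (length(sizes) < 3)
    stop("toy genome needs at least three chromosomes")
  if (sizes[[2]] < 50000L)
    stop("the rearranged (second) chromosome must be at least 50 kb")
  nm <- names(sizes)

  chroms <- setNames(vapply(sizes, random_dna, ""), nm)
  feats <- list()
  addf <- function(chrom, start, end, strand, kind, name) {
    feats[[length(feats) + 1L]] <<- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = strand, kind = kind, name = name, stringsAsFactors = FALSE)
  }

  # telomeric tracts at every end; left ends carry the reverse complement
  # of the G-rich tract so the G-rich strand points off the chromosome end
  for (cn in nm) {
    L <- sizes[[cn]]
    tl <- make_telomere_tract(cfg$telomere_len, cfg$spacer_prob)
    tr <- make_telomere_tract(cfg$telomere_len, cfg$spacer_prob)
    if (nchar(tl) + nchar(tr) >= L) stop("telomere tracts exceed chromosome")
    chroms[[cn]] <- splice0(chroms[[cn]], 0L, nchar(tl), revcomp(tl))
    chroms[[cn]] <- splice0(chroms[[cn]], L - nchar(tr), L, tr)
    addf(cn, 0L, nchar(tl), "+", "telomere_tract", paste0(cn, "_telL"))
    addf(cn, L - nchar(tr), L, "+", "telomere_tract", paste0(cn, "_telR"))
  }

  # rDNA-like arrays at both ends of the last chromosome
  rc <- nm[[length(nm)]]
  unit <- random_dna(cfg$rdna_unit_len)
  array_seq <- strrep(unit, cfg$rdna_copies)
  alen <- nchar(array_seq)
  Lc <- sizes[[rc]]
  a1 <- cfg$telomere_len + cfg$rdna_margin
  a2 <- Lc - cfg$telomere_len - cfg$rdna_margin - alen
  if (a2 <= a1 + alen) stop("rDNA arrays overlap: chromosome too short")
  chroms[[rc]] <- splice0(chroms[[rc]], a1, a1 + alen, array_seq)
  chroms[[rc]] <- splice0(chroms[[rc]], a2, a2 + alen, array_seq)
  addf(rc, a1, a1 + alen, "+", "rdna_array", paste0(rc, "_rdnaL"))
  addf(rc, a2, a2 + alen, "+", "rdna_array", paste0(rc, "_rdnaR"))

  # P1: same-orientation homologous gene pair with one perfectly
  # identical internal region, on the terminal regions of chrA and chrB
  ca <- nm[[1]]; cb <- nm[[2]]
  glen <- cfg$p1_gene_len
  io <- cfg$identical_offset; il <- cfg$identical_region_len
  if (io + il > glen) stop("P1 identical region outside gene")
  codA <- random_dna(glen)
  codB <- make_homolog(codA, cfg$p1_divergence, io + 1L, io + il)
  gA <- cfg$p1_geneA_start; gB <- cfg$p1_geneB_start
  chroms[[ca]] <- splice0(chroms[[ca]], gA, gA + glen, codA)
  chroms[[cb]] <- splice0(chroms[[cb]], gB, gB + glen, codB)
  addf(ca, gA, gA + glen, "+", "gene", "htA1")
  addf(cb, gB, gB + glen, "+", "gene", "htB1")
  addf(ca, gA + io, gA + io + il, "+", "identical_region", "P1_id")
  addf(cb, gB + io, gB + io + il, "+", "identical_region", "P1_id")

  # P2: inverted homologous pair flanking a middle gene on the chrB arm,
  # sharing a short identical window
  l1 <- cfg$p2_gene1_len; l2 <- cfg$p2_gene2_len
  wo <- cfg$p2_window_offset; wl <- cfg$p2_window_len
  if (wo + wl > min(l1, l2)) stop("P2 window outside gene")
  cod1 <- random_dna(l1)
  cod2 <- make_homolog(substring(cod1, 1L, l2), cfg$p2_divergence,
                       wo + 1L, wo + wl)
  s1 <- cfg$p2_gene1_start; sm <- cfg$p2_middle_start
  s2 <- cfg$p2_gene2_start
  if (!(s1 + l1 <= sm && sm + cfg$p2_middle_len <= s2))
    stop("P2 genes and middle gene must not overlap")
  chroms[[cb]] <- splice0(chroms[[cb]], s1, s1 + l1, cod1)
  chroms[[cb]] <- splice0(chroms[[cb]], sm, sm + cfg$p2_middle_len,
                          random_dna(cfg$p2_middle_len))
  chroms[[cb]] <- splice0(chroms[[cb]], s2, s2 + l2, revcomp(cod2))
  addf(cb, s1, s1 + l1, "+", "gene", "aatB1")
  addf(cb, sm, sm + cfg$p2_middle_len, "+", "gene", "alrB")
  addf(cb, s2, s2 + l2, "-", "gene", "aatB2")
  # window in genomic coordinates: gene2 is reverse-complemented, so the
  # coding window [wo, wo+wl) sits at the far end of its genomic interval
  addf(cb, s1 + wo, s1 + wo + wl, "+", "identical_region", "P2_id")
  addf(cb, s2 + l2 - wo - wl, s2 + l2 - wo, "-", "identical_region", "P2_id")

  # most telomeric essential gene, centromeric of P2
  es <- cfg$essential_start
  if (es < s2 + l2) stop("essential gene must be centromeric of P2")
  addf(cb, es, es + cfg$essential_len, "+", "essential_gene", "zasB")

  f <- do.call(rbind, feats)
  # motif overlap sanity: engineered features on one chromosome must not
  # collide (identical regions may nest in their genes)
  solid <- f[f$kind != "identical_region", ]
  for (cn in unique(solid$chrom)) {
    fc <- solid[solid$chrom == cn, ]
    fc <- fc[order(fc$start), ]
    if (nrow(fc) > 1 && any(fc$start[-1] < fc$end[-nrow(fc)]))
      stop("overlapping motifs on ", cn)
  }

  g <- gcr_genome(chroms, f)
  attr(g, "toy_config") <- cfg
  g
}
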