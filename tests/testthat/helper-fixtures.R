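# Shared fixtures built in code; nothing is stored on disk.

# ~200 kb three-chromosome toy genome: large enough to carry every
# structural motif, small enough to keep unit tests fast.
small_config <- function(seed = 7L, ...) {
  toy_genome_config(
    chrom_sizes = c(chrA = 60000L, chrB = 80000L, chrC = 60000L),
    p1_geneA_start = 6000L, p1_geneB_start = 16000L,
    p2_gene1_start = 30000L, p2_middle_start = 34000L,
    p2_gene2_start = 38000L, essential_start = 55000L,
    seed = seed, ...)
}

# simulate one event on the small genome and run the full pipeline;
# cached per (event type, seed) for the session
.sim_cache <- new.env(parent = emptyenv())
sim_event <- function(event_type, seed = 7L, sim_seed = 11L,
                      error_rate = 0.005, first_retained = NULL) {
  key <- paste(event_type, seed, sim_seed, error_rate,
               first_retained %||% "auto")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  outdir <- file.path(tempdir(), paste0("sim_", abs(sum(utf8ToInt(key)))))
  res <- suppressMessages(run_pipeline(list(
    simulate = list(event_type = event_type,
                    first_retained = first_retained,
                    genome_config = small_config(seed),
                    sim = read_sim_config(seed = sim_seed,
                                          error_rate = error_rate)),
    outdir = outdir, seed = seed)))
  res$outdir <- outdir
  .sim_cache[[key]] <- res
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-written SAM fixture around a tiny genome
write_tiny_sam <- function(records, seqlengths, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths))
  writeLines(c(hdr, records), path)
  path
}

sam_rec <- function(qname, flag, rname, pos, cigar, seq,
                    mapq = 60L, rnext = "*", pnext = 0L, tlen = 0L) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
          qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
          seq, strrep("I", nchar(seq)))
}

# O(n^2 k) reference implementation of per-position k-mer mappability
mappability_oracle <- function(chroms, k, m) {
  kmers <- unlist(lapply(chroms, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  km <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  n <- nrow(km)
  cnt <- integer(n)
  for (i in seq_len(n))
    cnt[i] <- sum(rowSums(km != matrix(km[i, ], n, k, byrow = TRUE)) <= m)
  out <- list()
  off <- 0L
  for (cn in names(chroms)) {
    np <- nchar(chroms[[cn]]) - k + 1L
    out[[cn]] <- 1 / cnt[(off + 1L):(off + np)]
    off <- off + np
  }
  out
}

# exhaustive enumeration of all tandem chains of the core motif
telomere_score_oracle <- function(seq, core = "GGTTAC", max_spacer = 2L) {
  occ <- gregexpr(core, seq, fixed = TRUE)[[1]]
  if (occ[1] == -1) return(0L)
  st <- as.integer(occ)
  en <- st + nchar(core) - 1L
  best <- 0L
  ext <- function(i, len) {
    best <<- max(best, len)
    for (j in seq_along(st)) {
      gap <- st[j] - en[i] - 1L
      if (gap >= 0 && gap <= max_spacer) ext(j, len + 1L)
    }
  }
  for (i in seq_along(st)) ext(i, 1L)
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
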