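test_that("windowed depth counts only aligned bases, mapq-filtered", {
  sl <- c(c1 = 3000L)
  seqs <- strrep("A", 150)
  recs <- c(
    sam_rec("r1", 0L, "c1", 101L, "150M", seqs),
    sam_rec("r2", 0L, "c1", 101L, "150M", seqs),
    sam_rec("r3", 0L, "c1", 401L, "50S100M", seqs),  # clip adds no depth
    sam_rec("r4", 0L, "c1", 701L, "150M", seqs, mapq = 0L))
  sam <- write_tiny_sam(recs, sl)
  reg <- data.frame(chrom = "c1", start = 0L, end = 1000L)
  prof <- windowed_depth(sam, reg, bin = 100L, min_mapq = 1L)
  w <- prof$windows
  expect_equal(nrow(w), 10L)
  expect_equal(w$raw_depth[w$start == 100], 2 * 100 / 100)   # two reads
  expect_equal(w$raw_depth[w$start == 400], 100 / 100)       # M part only
  expect_equal(w$raw_depth[w$start == 300], 0)               # clip region
  expect_equal(w$raw_depth[w$start == 700], 0)               # mapq 0 dropped
  expect_equal(w$raw_depth[w$start == 900], 0)               # no reads
})

test_that("depth errors on empty input or unknown regions", {
  sl <- c(c1 = 3000L)
  sam <- write_tiny_sam(character(0), sl)
  reg <- data.frame(chrom = "c1", start = 0L, end = 1000L)
  expect_error(windowed_depth(sam, reg), "empty")
  sam2 <- write_tiny_sam(sam_rec("r", 0L, "c1", 1L, "150M",
                                 strrep("A", 150)), sl)
  reg2 <- data.frame(chrom = "nope", start = 0L, end = 100L)
  expect_error(windowed_depth(sam2, reg2), "absent")
})

test_that("depth mass is conserved and normalization is exact", {
  res <- sim_event("telomere_addition")
  prof <- res$bundle$profile
  w <- prof$windows
  widths <- w$end - w$start
  # length-weighted mean of normalized depth is exactly 1
  expect_equal(sum(w$normalized_depth * widths) / sum(widths), 1,
               tolerance = 1e-9)
  # window depth mass equals aligned-base mass over the window footprint,
  # computed independently from the alignment spans
  sp <- aligned_spans(res$bundle$aln$reads)
  mass <- 0
  for (cn in unique(w$chrom)) {
    wins <- IRanges::IRanges(w$start[w$chrom == cn] + 1L,
                             w$end[w$chrom == cn])
    spans <- unlist(sp$spans[sp$reads$rname == cn])
    hits <- IRanges::findOverlaps(spans, wins)
    mass <- mass + sum(IRanges::width(
      IRanges::overlapsRanges(spans, wins, hits)))
  }
  expect_equal(sum(w$raw_depth * widths), mass)
})

test_that("uniform coverage yields a flat normalized profile", {
  g <- build_toy_genome(small_config(seed = 21L))
  out <- simulate_reads(g, read_sim_config(coverage = 30, seed = 22L),
                        tempfile("flat"))
  tr <- compute_mappability(g, 100, 2)
  reg <- extract_unique_regions(tr)
  prof <- windowed_depth(out$sam, reg)
  w <- prof$windows
  x <- w$normalized_depth
  expect_equal(mean(x), 1, tolerance = 0.05)
  expect_gt(mean(x > 0.6 & x < 1.4), 0.97)
  # interior windows stay well inside Poisson bounds; the outermost
  # window of a chromosome sags because fragments must fit inside it
  lens <- nchar(g$chroms)
  interior <- w$start >= 600 & w$end <= lens[w$chrom] - 600
  expect_true(all(x[interior] > 0.3 & x[interior] < 1.9))
  # and no terminal CNV is called anywhere
  expect_equal(nrow(call_terminal_cnv(prof)), 0L)
})

test_that("terminal CNV calls recover simulated events near the truth", {
  res <- sim_event("telomere_addition")
  cnv <- res$bundle$cnv
  del <- cnv[cnv$kind == "deletion", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$chrom, "chrB")
  expect_equal(del$side, "left")
  expect_lte(abs(del$boundary - res$truth$first_retained), 400L)

  tres <- sim_event("homology_translocation")
  tc <- tres$bundle$cnv
  expect_true(any(tc$kind == "deletion" & tc$chrom == "chrB" &
                  tc$side == "left"))
  dup <- tc[tc$kind == "duplication", ]
  expect_equal(dup$chrom, "chrA")
  expect_equal(dup$side, "left")
  expect_gt(dup$mean_ratio, 1.7)      # duplicated arm sits near ratio 2
  # raising del_ratio_max never decreases the number of deletion calls
  n1 <- sum(call_terminal_cnv(tres$bundle$profile,
                              del_ratio_max = 0.1)$kind == "deletion")
  n2 <- sum(call_terminal_cnv(tres$bundle$profile,
                              del_ratio_max = 0.25)$kind == "deletion")
  n3 <- sum(call_terminal_cnv(tres$bundle$profile,
                              del_ratio_max = 0.6)$kind == "deletion")
  expect_true(n1 <= n2 && n2 <= n3)
})
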