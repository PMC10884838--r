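test_that("clip clustering reports the first retained base with consensus", {
  sl <- c(c1 = 2000L)
  ref <- strrep("ACGT", 500)
  clipL <- "GGTTACGGTTAC"           # oriented away from junction: revcomp
  aligned <- substring(ref, 501, 560)
  reads <- paste0(revcomp(clipL), aligned)
  recs <- c(
    sam_rec("a", 0L, "c1", 501L, "12S60M", reads),
    sam_rec("b", 0L, "c1", 501L, "12S60M", reads),
    sam_rec("c", 0L, "c1", 501L, "12S60M", reads),
    sam_rec("d", 0L, "c1", 901L, "60M12S",
            paste0(substring(ref, 901, 960), "TTTTTTTTTTTT")))
  cl <- cluster_soft_clips(write_tiny_sam(recs, sl), min_clip = 10,
                           min_support = 3)
  expect_equal(nrow(cl), 1L)        # the right-clip singleton is dropped
  expect_equal(cl$junction, 501L)
  expect_equal(cl$side, "left_clip")
  expect_equal(cl$support, 3L)
  expect_equal(cl$consensus_clip, clipL)

  # no clips at all -> empty
  cl0 <- cluster_soft_clips(write_tiny_sam(
    sam_rec("e", 0L, "c1", 1L, "72M", strrep("A", 72)), sl))
  expect_equal(nrow(cl0), 0L)
})

test_that("consensus majority voting breaks ties with N", {
  sl <- c(c1 = 2000L)
  ref <- strrep("ACGT", 500)
  aligned <- substring(ref, 501, 560)
  mk <- function(q, clip) sam_rec(q, 0L, "c1", 501L, "12S60M",
                                  paste0(revcomp(clip), aligned))
  recs <- c(mk("a", "GGTTACGGTTAC"), mk("b", "GGTTACGGTTAC"),
            mk("c", "CGTTACGGTTAC"), mk("d", "CGTTACGGTTAC"))
  cl <- cluster_soft_clips(write_tiny_sam(recs, sl), min_support = 3)
  expect_equal(substring(cl$consensus_clip, 1, 1), "N")
  expect_equal(substring(cl$consensus_clip, 2), "GTTACGGTTAC")
})

test_that("malformed CIGARs are skipped with a warning, not a crash", {
  sl <- c(c1 = 2000L)
  recs <- c(sam_rec("ok", 0L, "c1", 1L, "60M", strrep("A", 60)),
            sam_rec("bad", 0L, "c1", 5L, "XYZ", strrep("A", 60)))
  # header-driven parsing: the malformed CIGAR survives as '*'-like junk
  path <- write_tiny_sam(recs, sl)
  aln <- list(reads = data.frame(
    qname = c("ok", "bad"), flag = c(0L, 0L), rname = "c1",
    pos = c(1L, 5L), mapq = 60L, cigar = c("60M", "6&0M"),
    mrnm = NA, mpos = NA, isize = 0L, seq = strrep("A", 60),
    stringsAsFactors = FALSE), seqlengths = sl)
  expect_warning(cl <- cluster_soft_clips(aln), "malformed")
  expect_equal(nrow(cl), 0L)
})

test_that("telomere scoring matches exhaustive chain enumeration", {
  expect_equal(score_telomeric("GGTTACGGTTACGGTTAC")$telomere_score, 3L)
  expect_true(score_telomeric("GGTTACGGTTACGGTTAC")$is_telomeric)
  expect_equal(score_telomeric("ACGTACGTACGTACGT")$telomere_score, 0L)
  expect_false(score_telomeric("ACGTACGTACGTACGT")$is_telomeric)
  s <- "GGTTACAGGTTACCGGTTAC"       # single-base spacers tolerated
  expect_equal(score_telomeric(s)$telomere_score, 3L)
  expect_true(score_telomeric(s)$is_telomeric)

  set.seed(99)
  for (i in 1:40) {
    # random mixtures of cores, near-cores and spacers, <= 60 bp
    parts <- sample(c("GGTTAC", "GGTTAC", "GGTAAC", "A", "CA", "TTG"),
                    sample(2:8, 1), replace = TRUE)
    s <- substring(paste(parts, collapse = ""), 1, 60)
    expect_equal(score_telomeric(s)$telomere_score,
                 telomere_score_oracle(s), info = s)
  }
})

test_that("clip realignment finds partners on both strands", {
  g <- build_toy_genome(small_config())
  rd <- g$features[g$features$kind == "rdna_array", ][1, ]
  clip <- subseq0(g$chroms[["chrC"]], rd$start + 200L, rd$start + 260L)
  hits <- realign_clip(clip, g)
  expect_gt(nrow(hits), 0)
  top <- hits[1, ]
  expect_equal(top$identity, 100)
  # every full-length hit lies inside an rDNA array copy
  full <- hits[hits$aln_len == 60, ]
  rda <- g$features[g$features$kind == "rdna_array", ]
  inside <- vapply(seq_len(nrow(full)), function(i)
    any(rda$start <= full$pos[i] - 1 & rda$end >= full$end[i]), TRUE)
  expect_true(all(inside))

  # reverse complement of a unique locus is found on the minus strand
  uclip <- subseq0(g$chroms[["chrA"]], 30000L, 30060L)
  h2 <- realign_clip(revcomp(uclip), g)
  expect_equal(h2$chrom[1], "chrA")
  expect_equal(h2$strand[1], "-")
  expect_equal(h2$pos[1], 30001L)

  # too-short clips come back flagged
  short <- realign_clip("ACGTACGT", g)
  expect_equal(nrow(short), 0L)
  expect_equal(attr(short, "flag"), "too_short")
})

test_that("microhomology measurement matches constructed junctions", {
  set.seed(17)
  expect_equal(measure_microhomology("AAAA", "AAAA"), 4L)  # degenerate
  for (i in 1:25) {
    L0 <- sample(0:8, 1)
    up <- random_seq(20)
    ov <- if (L0 > 0) substring(up, 21 - L0, 20) else ""
    rest <- random_seq(20 - L0)
    # force the first base after the engineered overlap to differ
    nxt <- setdiff(c("A", "C", "G", "T"),
                   substring(up, 20 - L0, 20 - L0))[1]
    down <- paste0(ov, nxt, substring(rest, 2))
    expect_equal(measure_microhomology(up, down), L0)
    # symmetric when roles are swapped on the other strand
    expect_equal(measure_microhomology(revcomp(down), revcomp(up)), L0)
  }
})

test_that("simulated fusion reads cluster exactly at the truth junction", {
  res <- sim_event("chromosome_fusion", error_rate = 0)
  cl <- res$bundle$clusters
  truth <- res$truth
  hit <- cl[cl$chrom == "chrB" & cl$side == "left_clip", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$junction, truth$first_retained)
  # the consensus clip reads into the rDNA unit, telomere-proximal side
  # facing the junction: its reverse complement is the chrC sequence
  # immediately left of the partner coordinate
  p <- truth$partner$coord
  g <- res$bundle$genome
  n <- nchar(hit$consensus_clip)
  expect_equal(revcomp(hit$consensus_clip),
               subseq0(g$chroms[["chrC"]], p - n, p))
})
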