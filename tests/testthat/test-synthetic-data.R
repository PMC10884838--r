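test_that("toy genome carries the engineered motifs and valid features", {
  g <- build_toy_genome(small_config())
  f <- g$features
  lens <- nchar(g$chroms)

  expect_true(all(f$start >= 0 & f$end <= lens[f$chrom] & f$start < f$end))
  expect_false(any(grepl("[^ACGT]", g$chroms)))
  expect_false(anyDuplicated(names(g$chroms)) > 0)

  # telomeric tracts at every end, rDNA arrays at both ends of the last
  # chromosome, the essential gene centromeric of the inverted pair
  tel <- f[f$kind == "telomere_tract", ]
  expect_equal(nrow(tel), 6)
  expect_setequal(unique(tel$chrom), names(g$chroms))
  rd <- f[f$kind == "rdna_array", ]
  expect_equal(unique(rd$chrom), "chrC")
  expect_equal(nrow(rd), 2)
  p2 <- f[f$kind == "gene" & f$name %in% c("aatB1", "aatB2"), ]
  ess <- f[f$kind == "essential_gene", ]
  expect_true(ess$start > max(p2$end))

  # the rDNA array is tandem: unit repeats exactly
  unit_len <- attr(g, "toy_config")$rdna_unit_len
  arr <- subseq0(g$chroms[["chrC"]], rd$start[1], rd$end[1])
  u1 <- substring(arr, 1, unit_len)
  expect_equal(arr, strrep(u1, attr(g, "toy_config")$rdna_copies))
})

test_that("P1 genes share exactly the configured identical region", {
  g <- build_toy_genome(small_config())
  f <- g$features
  ga <- f[f$kind == "gene" & f$name == "htA1", ]
  gb <- f[f$kind == "gene" & f$name == "htB1", ]
  sa <- subseq0(g$chroms[["chrA"]], ga$start, ga$end)
  sb <- subseq0(g$chroms[["chrB"]], gb$start, gb$end)
  ids <- f[f$kind == "identical_region" & f$name == "P1_id", ]
  off <- ids$start[1] - ga$start          # same in-gene offset for both
  expect_equal(substring(sa, off + 1, off + 240),
               substring(sb, off + 1, off + 240))
  # the shared run is exactly 240: flanking bases differ
  expect_false(substring(sa, off, off) == substring(sb, off, off))
  expect_false(substring(sa, off + 241, off + 241) ==
               substring(sb, off + 241, off + 241))
  # no longer shared exact substring anywhere between the two genes:
  # any 241-mer of gene A must be absent from gene B
  k <- 241
  ka <- substring(sa, 1:(nchar(sa) - k + 1), k:nchar(sa))
  expect_false(any(vapply(ka, grepl, TRUE, x = sb, fixed = TRUE)))
})

test_that("P2 inverted pair shares exactly the configured 12 bp window", {
  g <- build_toy_genome(small_config())
  f <- g$features
  w <- f[f$kind == "identical_region" & f$name == "P2_id", ]
  wA <- w[w$strand == "+", ]
  wB <- w[w$strand == "-", ]
  sA <- subseq0(g$chroms[["chrB"]], wA$start, wA$end)
  sB <- subseq0(g$chroms[["chrB"]], wB$start, wB$end)
  expect_equal(nchar(sA), 12L)
  expect_equal(sA, revcomp(sB))
  # flanks diverge, so the exact shared window is not longer
  sA1 <- subseq0(g$chroms[["chrB"]], wA$start - 1L, wA$end + 1L)
  sB1 <- subseq0(g$chroms[["chrB"]], wB$start - 1L, wB$end + 1L)
  expect_false(sA1 == revcomp(sB1))
})

test_that("same seed and config give byte-identical FASTA", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(build_toy_genome(small_config(seed = 3L)), f1)
  write_genome_fasta(build_toy_genome(small_config(seed = 3L)), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  f3 <- tempfile(fileext = ".fa")
  write_genome_fasta(build_toy_genome(small_config(seed = 4L)), f3)
  expect_false(tools::md5sum(f1)[[1]] == tools::md5sum(f3)[[1]])
})

test_that("invalid motif layouts and lost essential genes are rejected", {
  bad <- small_config()
  bad$p2_middle_start <- bad$p2_gene1_start + 100L  # overlaps gene 1
  expect_error(build_toy_genome(bad), "overlap|not overlap")
  g <- build_toy_genome(small_config())
  ev <- rearrangement_event("telomere_addition", "chrB",
                            first_retained = 58000L)
  expect_error(apply_rearrangement(g, ev), "essential")
})

test_that("telomere addition arithmetic and fusion microhomology hold", {
  g <- build_toy_genome(small_config())
  L <- nchar(g$chroms[["chrB"]])
  set.seed(42)
  ar <- apply_rearrangement(
    g, rearrangement_event("telomere_addition", "chrB",
                           first_retained = 25001L))
  tel <- ar$event$telomere_seq
  expect_equal(nchar(ar$genome$chroms[["chrB"]]),
               (L - 25001L + 1L) + nchar(tel))
  expect_equal(subseq0(ar$genome$chroms[["chrB"]], 0L, nchar(tel)),
               revcomp(tel))
  expect_gte(length(gregexpr("GGTTAC", tel, fixed = TRUE)[[1]]), 4L)

  set.seed(43)
  fu <- apply_rearrangement(
    g, rearrangement_event("chromosome_fusion", "chrB",
                           first_retained = 25001L))
  p <- fu$event$partner$coord
  # brute-force check: no suffix of the partner side equals what the
  # retained side contributes next, at any length up to 20
  up <- subseq0(g$chroms[["chrC"]], p - 20L, p)
  down <- subseq0(g$chroms[["chrB"]], 25000L, 25020L)
  shares <- vapply(1:20, function(Lh)
    substring(up, 21 - Lh) == substring(down, 1, Lh), TRUE)
  expect_false(any(shares))
  # junction sequence: partner base adjacent to the first retained base
  mut <- fu$genome$chroms[["chrB"]]
  expect_equal(subseq0(mut, p - 1L, p + 1L),
               paste0(subseq0(g$chroms[["chrC"]], p - 1L, p),
                      subseq0(g$chroms[["chrB"]], 25000L, 25001L)))
})

test_that("homology translocation yields a single-switch chimera", {
  g <- build_toy_genome(small_config())
  ar <- apply_rearrangement(
    g, rearrangement_event("homology_translocation", "chrB"))
  mut <- ar$genome$chroms[["chrB"]]
  hi <- ar$event$homology_interval
  # base-by-base comparison against both parents over the junction
  # neighbourhood: donor-only matches strictly precede recipient-only
  # matches, the handover happening inside the identical region where
  # both parents agree
  n0 <- 20000L
  mm <- strsplit(substring(mut, 1, n0), "")[[1]]
  a <- strsplit(substring(g$chroms[["chrA"]], 1, n0), "")[[1]]
  b <- strsplit(subseq0(g$chroms[["chrB"]], hi$startB - hi$startA,
                        hi$startB - hi$startA + n0), "")[[1]]
  match_a <- mm == a
  match_b <- mm == b
  expect_true(all(match_a | match_b))   # never matches neither parent
  aonly <- which(match_a & !match_b)
  bonly <- which(match_b & !match_a)
  expect_gt(length(aonly), 0)
  expect_gt(length(bonly), 0)
  expect_lt(max(aonly), min(bonly))     # source switches exactly once
  expect_lte(max(aonly), hi$startA)     # handover inside the region
  expect_gte(min(bonly), hi$endA + 1L)
})
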