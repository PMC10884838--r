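truth_mech <- c(telomere_addition = "de_novo_telomere_addition",
                chromosome_fusion = "homology_independent_fusion",
                homology_translocation = "homology_driven_translocation",
                inversion_plus_deletion = "complex_inversion_plus_deletion")

test_that("simulate-then-analyze recovers every mechanism and junction", {
  for (et in names(truth_mech)) {
    res <- sim_event(et)
    cc <- res$calls[res$calls$chrom == res$truth$chrom &
                    res$calls$side == "left", ]
    expect_equal(nrow(cc), 1L, info = et)
    expect_equal(cc$mechanism, truth_mech[[et]], info = et)
    expect_equal(cc$junction, res$truth$first_retained, info = et)
  }
})

test_that("fusion and translocation calls carry the right partner", {
  fu <- sim_event("chromosome_fusion")
  cc <- fu$calls[fu$calls$mechanism == "homology_independent_fusion", ]
  expect_equal(cc$partner_chrom, "chrC")
  rd <- fu$bundle$genome$features
  rd <- rd[rd$kind == "rdna_array" & rd$chrom == "chrC", ]
  expect_true(any(cc$partner_coord > rd$start & cc$partner_coord <= rd$end))
  expect_match(cc$note, "rDNA")
  expect_match(cc$evidence, "microhomology:0")

  tr <- sim_event("homology_translocation")
  tc <- tr$calls[tr$calls$mechanism == "homology_driven_translocation", ]
  expect_equal(tc$partner_chrom, "chrA")
  expect_match(tc$evidence, "cnv:chrA:duplication")
  expect_match(tc$evidence, "chimera:")
  # junction equals the telomere-side edge of the truth identical region
  hi <- tr$truth$homology_interval
  expect_equal(tc$junction, hi$startB + 1L)
})

test_that("complex inversion calls annotate genes near the new telomere", {
  inv <- sim_event("inversion_plus_deletion")
  cc <- inv$calls[inv$calls$mechanism ==
                  "complex_inversion_plus_deletion", ]
  expect_equal(nrow(cc), 1L)
  # the retained inverted chimera gene sits within 5 kb of the junction
  expect_match(cc$note, "near_new_telomere")
  expect_match(cc$evidence, "inversion_junction")
  # the truth switch lies inside the narrowed identical window
  hi <- inv$truth$homology_interval
  hom <- inv$bundle$homology
  same <- hom[vapply(hom, function(h)
    h$chromA == "chrB" && h$chromB == "chrB", TRUE)]
  expect_gte(length(same), 1L)
  h <- same[[1]]
  expect_equal(c(h$startA, h$endA), c(hi$startA, hi$endA))
  expect_equal(c(h$startB, h$endB), c(hi$startB, hi$endB))
})

test_that("classification ignores evidence-list order", {
  res <- sim_event("homology_translocation")
  b <- res$bundle
  perm <- b
  if (length(b$homology) > 1) {
    o <- rev(seq_along(b$homology))
    perm$homology <- b$homology[o]
    perm$chimeras <- b$chimeras[o]
  }
  if (nrow(b$cnv) > 1) perm$cnv <- b$cnv[rev(seq_len(nrow(b$cnv))), ]
  if (nrow(b$groups) > 1)
    perm$groups <- b$groups[rev(seq_len(nrow(b$groups))), ]
  c1 <- classify(b)
  c2 <- classify(perm)
  o1 <- c1[order(c1$chrom, c1$side), ]
  o2 <- c2[order(c2$chrom, c2$side), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1[c("chrom", "side", "mechanism", "junction")],
               o2[c("chrom", "side", "mechanism", "junction")])
})

test_that("reports are emitted in valid, deterministic form", {
  res <- sim_event("telomere_addition")
  d1 <- tempfile("rep1"); d2 <- tempfile("rep2")
  f1 <- write_reports(res$calls, res$bundle, d1)
  f2 <- write_reports(res$calls, res$bundle, d2)
  for (nm in names(f1))
    expect_identical(unname(tools::md5sum(f1[[nm]])),
                     unname(tools::md5sum(f2[[nm]])))

  # VCF DEL record: END at junction-1, MECH tag in event vocabulary
  vcf <- readLines(f1$vcf)
  del <- grep("SVTYPE=DEL", vcf, value = TRUE)
  expect_equal(length(del), 1L)
  j <- res$calls$junction[1]
  expect_match(del, sprintf("END=%d;MECH=telomere_addition", j - 1L))

  # summary TSV round-trips
  tsv <- read.delim(f1$summary)
  expect_equal(nrow(tsv), nrow(res$calls))
  expect_equal(tsv$mechanism, res$calls$mechanism)

  # empty call set still produces headered TSV and VCF
  empty <- res$calls[0, ]
  f0 <- write_reports(empty, res$bundle, tempfile("rep0"))
  expect_equal(nrow(read.delim(f0$summary)), 0L)
  vcf0 <- readLines(f0$vcf)
  expect_true(any(grepl("^#CHROM", vcf0)))
  expect_false(any(!grepl("^#", vcf0) & nzchar(vcf0)))
})

test_that("pipeline validates its configuration", {
  expect_error(run_pipeline(list(outdir = tempfile())),
               "alignments|simulate")
  expect_error(run_pipeline(list(alignments = "x.sam",
                                 outdir = tempfile())),
               "reference")
})

test_that("external alignment files analyze like simulated ones", {
  # the SAM/reference produced by one run, re-read from disk the way a
  # user would supply downloaded data, give identical calls
  res <- sim_event("chromosome_fusion")
  res2 <- suppressMessages(run_pipeline(list(
    reference = file.path(res$outdir, "reference.fasta"),
    annotation = file.path(res$outdir, "features.bed"),
    alignments = res$sim$sam,
    outdir = tempfile("ext"))))
  expect_equal(res2$calls$mechanism, res$calls$mechanism)
  expect_equal(res2$calls$junction, res$calls$junction)
})
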