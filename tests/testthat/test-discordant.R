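test_that("proper libraries produce no discordant groups", {
  for (seed in c(31L, 32L, 33L)) {
    g <- build_toy_genome(small_config(seed = seed))
    out <- simulate_reads(g, read_sim_config(coverage = 4, seed = seed),
                          tempfile("prop"))
    grp <- find_discordant_pairs(out$sam)
    expect_equal(nrow(grp), 0L, info = paste("seed", seed))
  }
})

test_that("unpaired input is rejected", {
  sl <- c(c1 = 2000L)
  sam <- write_tiny_sam(sam_rec("r", 0L, "c1", 1L, "60M",
                                strrep("A", 60)), sl)
  expect_error(find_discordant_pairs(sam, 300, 30), "unpaired")
})

test_that("simulated rearrangements yield the expected group kinds", {
  inv <- sim_event("inversion_plus_deletion")
  gi <- inv$bundle$groups
  invg <- gi[grepl("^inversion", gi$kind), ]
  expect_gte(nrow(invg), 1L)
  # the inversion group links the two inverted-homolog loci
  w <- inv$bundle$genome$features
  w <- w[w$kind == "identical_region" & w$name == "P2_id", ]
  expect_true(any(invg$chromA == "chrB" &
                  abs(invg$startA - min(w$end)) < 1500 &
                  abs(invg$startB - max(w$start)) < 1500))

  tra <- sim_event("homology_translocation")
  gt <- tra$bundle$groups
  ic <- gt[gt$kind == "inter_chromosomal", ]
  expect_gte(nrow(ic), 1L)
  expect_true(any(ic$chromA == "chrA" & ic$chromB == "chrB"))
})

test_that("breakpoint narrowing recovers planted identical runs", {
  set.seed(55)
  a <- random_seq(600)
  # homolog with ~10% divergence, identical run of exactly 12 at 301-312
  b <- a
  pos <- which(runif(600) < 0.1)
  pos <- setdiff(pos, 300:313)
  for (p in c(pos, 300, 313)) {
    cur <- substring(b, p, p)
    substring(b, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  ni <- narrow_breakpoint_interval(a, b, 305)
  expect_equal(ni$length, 12L)
  expect_true(ni$is_exact)
  expect_equal(ni$seqA_range, c(301L, 312L))
  expect_equal(ni$seqB_range, c(301L, 312L))
  # swapping the homologs leaves the interval length unchanged
  ni2 <- narrow_breakpoint_interval(b, a, 305)
  expect_equal(ni2$length, ni$length)

  # completely distinct sequences at the switch: length 0
  set.seed(56)
  d0 <- narrow_breakpoint_interval(random_seq(200), random_seq(200), 100)
  expect_equal(d0$length, 0L)
  expect_false(d0$is_exact)

  # planted 240-column identical block containing the switch
  core <- random_seq(240)
  x <- paste0(random_seq(150), core, random_seq(150))
  y <- x
  posy <- which(runif(nchar(y)) < 0.08)
  posy <- setdiff(posy, 150:392)
  for (p in c(posy, 150, 391)) {
    cur <- substring(y, p, p)
    substring(y, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  nb <- narrow_breakpoint_interval(x, y, 250)
  expect_equal(nb$length, 240L)
  expect_equal(nb$seqA_range, c(151L, 390L))
})

test_that("chimera support requires discriminating bases on both sides", {
  # parental (unrearranged) library: nothing supports the chimera
  g <- build_toy_genome(small_config())
  out <- simulate_reads(g, read_sim_config(coverage = 10, seed = 44L),
                        tempfile("par"))
  f <- g$features
  ga <- f[f$name == "htA1" & f$kind == "gene", ]
  gb <- f[f$name == "htB1" & f$kind == "gene", ]
  ids <- f[f$name == "P1_id", ]
  idl <- list(chromA = "chrA", startA = ids$start[1], endA = ids$end[1],
              chromB = "chrB", startB = ids$start[2], endB = ids$end[2])
  ch0 <- collect_chimera_support(out$sam, ga, gb, idl)
  expect_equal(ch0$informative, 0L)
  expect_error(collect_chimera_support(out$sam, ga, gb, NULL),
               "identical")

  # rearranged library: informative support appears and grows with
  # coverage; informative never exceeds support
  res30 <- sim_event("homology_translocation")
  hi <- which(vapply(res30$bundle$homology, function(h)
    h$geneA == "htA1" || h$geneB == "htA1", TRUE))[1]
  ch30 <- res30$bundle$chimeras[[hi]]
  expect_gte(ch30$informative, 2L)
  expect_lte(ch30$informative, ch30$support)

  mut <- apply_rearrangement(
    g, rearrangement_event("homology_translocation", "chrB"))
  o10 <- simulate_reads(mut$genome,
                        read_sim_config(coverage = 10, seed = 45L),
                        tempfile("c10"))
  o30 <- simulate_reads(mut$genome,
                        read_sim_config(coverage = 30, seed = 45L),
                        tempfile("c30"))
  c10 <- collect_chimera_support(o10$sam, ga, gb, idl)
  c30 <- collect_chimera_support(o30$sam, ga, gb, idl)
  expect_lte(c10$informative, c10$support)
  expect_lte(c30$informative, c30$support)
  expect_lte(c10$informative, c30$informative)
  expect_lte(c10$support, c30$support)
})
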