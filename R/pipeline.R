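MECH_VCF <- c(de_novo_telomere_addition = "telomere_addition",
              homology_driven_translocation = "homology_translocation",
              homology_independent_fusion = "chromosome_fusion",
              complex_inversion_plus_deletion = "inversion_plus_deletion",
              unresolved = "unresolved")

#' Write mechanism-call reports
#'
#' Emits a TSV summary (one row per call), a JSON evidence dump, a
#' minimal VCF (DEL record per terminal deletion, END at junction-1 for
#' a left-arm deletion, plus a BND line per partnered junction), and
#' per-chromosome depth tables (window, normalized depth) ready for
#' plotting.
#'
#' @param calls [classify()] output (may have zero rows)
#' @param bundle the matching `evidence_bundle`
#' @param outdir output directory
#' @return named list of written file paths, invisibly
#' @export
write_reports <- function(calls, bundle, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  files <- list()

  files$summary <- file.path(outdir, "mechanism_calls.tsv")
  write.table(calls, files$summary, sep = "\t", quote = FALSE,
              row.names = FALSE)

  files$evidence <- file.path(outdir, "evidence.json")
  ev <- list(
    params = bundle$params[!vapply(bundle$params, is.null, TRUE)],
    cnv = bundle$cnv,
    clusters = cbind(bundle$clusters, data.frame(
      telomere_score = vapply(bundle$clip_char, `[[`, 1L,
                              "telomere_score"),
      is_telomeric = vapply(bundle$clip_char, `[[`, TRUE, "is_telomeric"),
      microhomology_len = vapply(bundle$clip_char, function(x)
        as.integer(x$microhomology_len %||% NA), 1L),
      n_partner_hits = vapply(bundle$clip_char, function(x)
        nrow(x$partner_hits), 1L))),
    groups = bundle$groups,
    homology = bundle$homology,
    chimeras = lapply(bundle$chimeras, function(x)
      x[c("geneA", "geneB", "support", "informative")]),
    calls = calls)
  jsonlite::write_json(ev, files$evidence, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA, null = "null",
                       na = "null")

  files$vcf <- file.path(outdir, "calls.vcf")
  lens <- chrom_lengths(bundle$genome)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gcrscope",
           sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
           "##ALT=<ID=DEL,Description=\"Terminal deletion\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           paste0("##INFO=<ID=MECH,Number=1,Type=String,",
                  "Description=\"Healing mechanism\">"),
           paste0("##INFO=<ID=PARTNER,Number=1,Type=String,",
                  "Description=\"Partner locus\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(0)
  for (i in seq_len(nrow(calls))) {
    cc <- calls[i, ]
    mech <- MECH_VCF[[cc$mechanism]]
    partner <- if (!is.na(cc$partner_chrom))
      sprintf(";PARTNER=%s:%d", cc$partner_chrom, cc$partner_coord) else ""
    if (cc$side == "left") {
      pos <- 1L; endp <- cc$junction - 1L
    } else {
      pos <- cc$junction + 1L; endp <- lens[[cc$chrom]]
    }
    recs <- c(recs, sprintf(
      "%s\t%d\tDEL%d\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;MECH=%s%s",
      cc$chrom, pos, i, endp, mech, partner))
    if (!is.na(cc$partner_chrom))
      recs <- c(recs, sprintf(
        "%s\t%d\tBND%d\tN\tN]%s:%d]\t.\tPASS\tSVTYPE=BND;MECH=%s",
        cc$chrom, cc$junction, i, cc$partner_chrom, cc$partner_coord,
        mech))
  }
  writeLines(c(hdr, recs), files$vcf)

  w <- bundle$profile$windows
  for (cn in unique(w$chrom)) {
    f <- file.path(outdir, paste0("depth_", cn, ".tsv"))
    write.table(w[w$chrom == cn,
                  c("start", "end", "raw_depth", "normalized_depth")],
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[paste0("depth_", cn)]] <- f
  }
  invisible(files)
}

#' Pick a random rearrangement event for a toy genome
#'
#' Chooses event coordinates uniformly within the arm regions a real
#' terminal deletion could hit (between the P1 gene and the P2 cluster
#' for simple events; inside the middle gene for the inversion case),
#' never violating the essential-gene constraint.
#'
#' @param genome a [build_toy_genome()] genome
#' @param event_type one of the four event types
#' @param first_retained optional fixed junction (1-based)
#' @return a [rearrangement_event()] (not yet applied)
#' @export
default_event <- function(genome, event_type, first_retained = NULL) {
  cn <- names(genome$chroms)[2]
  cfg <- attr(genome, "toy_config")
  if (is.null(cfg)) stop("default_event needs a toy genome")
  lo <- cfg$p1_geneB_start + cfg$p1_gene_len + 2000L
  hi <- cfg$p2_gene1_start - 2000L
  F1 <- switch(event_type,
    telomere_addition = ,
    chromosome_fusion = first_retained %||% sample(lo:hi, 1L),
    inversion_plus_deletion = first_retained %||%
      (cfg$p2_middle_start + sample(30:(cfg$p2_middle_len - 30L), 1L)),
    homology_translocation = NA)
  rearrangement_event(event_type, cn, first_retained = F1)
}

#' Run the full detection pipeline
#'
#' Either analyzes an existing alignment file against a reference, or
#' simulates a rearranged genome first and analyzes its truth
#' alignments. Stages: mappability -> unique regions -> windowed depth
#' -> terminal CNV -> soft-clip junctions -> discordant pairs / chimeras
#' / homology narrowing -> classification -> reports. Deterministic
#' given inputs and seeds.
#'
#' @param config list with fields: `reference` (FASTA path or
#'   `gcr_genome`), `annotation` (BED path; unneeded when the reference
#'   carries features), `alignments` (SAM/BAM path) OR `simulate` (list:
#'   `event_type`, optional `first_retained`, optional `genome_config`
#'   ([toy_genome_config()]), optional `sim` ([read_sim_config()])),
#'   `outdir`, optional `params` ([gcr_params()]), optional `seed`
#' @return list: `calls`, `bundle`, `files`, and for simulations
#'   `truth` (the applied event) and `sim` (simulator outputs)
#' @export
run_pipeline <- function(config) {
  outdir <- config$outdir %||% stop("config must name an outdir")
  params <- config$params %||% gcr_params()
  seed <- config$seed %||% 1L
  truth <- NULL; sim <- NULL

  if (!is.null(config$simulate)) {
    sc <- config$simulate
    message("stage simulate: event=", sc$event_type, " seed=", seed)
    gcfg <- sc$genome_config %||% toy_genome_config(seed = seed)
    genome <- build_toy_genome(gcfg)
    set.seed(seed + 1L)
    ev <- default_event(genome, sc$event_type, sc$first_retained)
    ar <- apply_rearrangement(genome, ev)
    truth <- ar$event
    rcfg <- sc$sim %||% read_sim_config(seed = seed + 2L)
    sim <- simulate_reads(ar$genome, rcfg, outdir)
    write_genome_fasta(genome, file.path(outdir, "reference.fasta"))
    write_genome_fasta(ar$genome, file.path(outdir, "mutant.fasta"))
    write_features_bed(genome, file.path(outdir, "features.bed"))
    write_truth_json(list(truth), file.path(outdir, "truth.json"))
    alignments <- sim$sam
  } else if (!is.null(config$alignments)) {
    genome <- config$reference %||%
      stop("config must name a reference genome")
    if (is.character(genome))
      genome <- read_genome_fasta(genome, config$annotation)
    alignments <- config$alignments
    message("stage input: ", alignments)
  } else {
    stop("config must provide 'alignments' or a 'simulate' request")
  }

  bundle <- withCallingHandlers(
    build_evidence(genome, alignments, params),
    message = function(m) {
      message("stage evidence: ", conditionMessage(m), appendLF = FALSE)
      invokeRestart("muffleMessage")
    })
  message("stage classify")
  calls <- classify(bundle)
  files <- write_reports(calls, bundle, outdir)
  message("stage report: ", length(files), " file(s) in ", outdir)
  list(calls = calls, bundle = bundle, files = files, truth = truth,
       sim = sim)
}
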