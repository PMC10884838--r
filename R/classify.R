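#' Pipeline parameters
#'
#' Defaults are tuned for haploid genomes sequenced at >= 20x with
#' 2 x 150 bp paired ends. `insert_mean`/`insert_sd` are estimated from
#' proper pairs (median / MAD) when left `NULL`.
#'
#' @param k,m mappability k-mer length and mismatch budget
#' @param min_len unique-region minimum length (exclusive)
#' @param bin depth window size (bp)
#' @param min_mapq mapping-quality filter for depth (the unique-region
#'   mask already removes ambiguous placements, hence 0)
#' @param del_ratio_max,dup_ratio_min,min_windows terminal CNV thresholds
#' @param min_clip,min_support soft-clip clustering thresholds
#' @param min_pairs discordant-group support threshold
#' @param min_hit_len clip realignment seed length
#' @param min_homology minimum identical-run length treated as a
#'   homology interval
#' @param microhom_max maximum junction microhomology still called
#'   "homology-independent"
#' @param flank flank width for microhomology measurement (bp)
#' @param insert_mean,insert_sd library insert statistics or `NULL`
#' @param silencing_dist distance within which a retained gene is flagged
#'   as near a new telomere (bp)
#' @return named list of parameters
#' @export
gcr_params <- function(k = 100L, m = 2L, min_len = 1000L, bin = 200L,
                       min_mapq = 0L, del_ratio_max = 0.25,
                       dup_ratio_min = 1.5, min_windows = 10L,
                       min_clip = 10L, min_support = 3L, min_pairs = 3L,
                       min_hit_len = 15L, min_homology = 4L,
                       microhom_max = 1L, flank = 20L,
                       insert_mean = NULL, insert_sd = NULL,
                       silencing_dist = 5000L) {
  as.list(environment())
}

map_g2c <- function(pos1b, gene) {
  if (gene$strand == "+") pos1b - gene$start else gene$end - pos1b + 1L
}

map_c2g <- function(rng, gene) {
  # coding 1-based inclusive range -> genomic 0-based half-open
  if (gene$strand == "+") c(gene$start + rng[1] - 1L, gene$start + rng[2])
  else c(gene$end - rng[2], gene$end - rng[1] + 1L)
}

characterize_clips <- function(clusters, genome, params) {
  lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    cons <- cl$consensus_clip
    tel <- score_telomeric(cons)
    hits <- realign_clip(cons, genome, min_hit_len = params$min_hit_len)
    chrom_seq <- genome$chroms[[cl$chrom]]
    w <- params$flank
    # flanks on the junction-forming strand; the clip (stored reference
    # orientation) stands in for the partner sequence
    if (cl$side == "left_clip") {
      stored <- revcomp(cons)
      up <- substring(stored, max(1L, nchar(stored) - w + 1L))
      down <- substring(chrom_seq, cl$junction,
                        min(nchar(chrom_seq), cl$junction + w - 1L))
    } else {
      up <- substring(chrom_seq, max(1L, cl$junction - w + 1L),
                      cl$junction)
      down <- substring(cons, 1L, min(nchar(cons), w))
    }
    mh <- if (nzchar(up) && nzchar(down) && !grepl("N", up, fixed = TRUE) &&
              !grepl("N", down, fixed = TRUE))
      measure_microhomology(up, down) else NA_integer_
    list(telomere_score = tel$telomere_score,
         is_telomeric = tel$is_telomeric, partner_hits = hits,
         microhomology_len = mh)
  })
}

derive_homology_evidence <- function(genome, aln, groups, cnv, clusters,
                                     params) {
  genes <- feature_rows(genome, kind = "gene")
  out <- list(homology = list(), chimeras = list())
  if (!nrow(groups) || !nrow(genes)) return(out)
  pad <- 500L
  seen <- character(0)
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    if (g$kind == "long_insert") next
    hitg <- function(chrom, lo, hi)
      genes[genes$chrom == chrom & genes$start < hi + pad &
            genes$end > lo - pad, , drop = FALSE]
    gsA <- hitg(g$chromA, g$startA - 1L, g$endA)
    gsB <- hitg(g$chromB, g$startB - 1L, g$endB)
    for (ia in seq_len(nrow(gsA))) for (ib in seq_len(nrow(gsB))) {
      ga <- gsA[ia, ]; gb <- gsB[ib, ]
      if (ga$chrom == gb$chrom && ga$start == gb$start) next
      key <- paste(sort(c(paste(ga$chrom, ga$start),
                          paste(gb$chrom, gb$start))), collapse = "|")
      if (key %in% seen) next
      sa <- feature_seq(genome, ga)
      sb <- feature_seq(genome, gb)
      # candidate switch positions (coding frame of gene A): soft-clip
      # junctions inside either gene are base-exact evidence and take
      # priority; only when none resolves an interval does a grid around
      # the depth boundary / discordant locus (both +-1 bin at best)
      # stand in. Within a tier the longest interval wins.
      primary <- integer(0)
      if (nrow(clusters)) {
        for (gg in list(ga, gb)) {
          cj <- clusters$junction[clusters$chrom == gg$chrom &
                                  clusters$junction > gg$start &
                                  clusters$junction <= gg$end]
          cp <- vapply(cj, map_g2c, 1L, gene = gg)
          if (identical(gg, gb) && length(cp)) {
            # map through gene B's coding frame into gene A's: the
            # homologs are colinear in coding coordinates (no indels
            # at this divergence matters little; used as approximate
            # anchor, exactness comes from the identical-run scan)
            cp <- pmax(1L, pmin(nchar(sa), cp))
          }
          primary <- c(primary, cp)
        }
        primary <- primary[primary >= 1L & primary <= nchar(sa)]
        # a clip junction sits one base outside the identical run; probe
        # both sides
        primary <- unique(as.vector(outer(primary, c(-1L, 0L, 1L), `+`)))
        primary <- primary[primary >= 1L & primary <= nchar(sa)]
      }
      fallback <- integer(0)
      grid <- seq(-2L * params$bin, 2L * params$bin, by = 50L)
      if (nrow(cnv)) {
        for (b in cnv$boundary[cnv$chrom == ga$chrom]) {
          gpos <- b + grid
          gpos <- gpos[gpos > ga$start & gpos <= ga$end]
          fallback <- c(fallback, vapply(gpos, map_g2c, 1L, gene = ga))
        }
      }
      loc <- if (g$chromA == ga$chrom &&
                 g$startA - 1L < ga$end && g$endA > ga$start)
        c(g$startA, g$endA) else c(g$startB, g$endB)
      gpos <- as.integer(mean(loc)) + grid
      gpos <- gpos[gpos > ga$start & gpos <= ga$end]
      fallback <- c(fallback, vapply(gpos, map_g2c, 1L, gene = ga))
      fallback <- sort(unique(pmax(1L, pmin(nchar(sa), fallback))))
      best <- NULL
      for (cands in list(sort(unique(primary)), fallback)) {
        for (cand in cands) {
          ni <- narrow_breakpoint_interval(sa, sb, cand)
          if (ni$length >= params$min_homology &&
              (is.null(best) || ni$length > best$length))
            best <- ni
        }
        if (!is.null(best)) break
      }
      seen <- c(seen, key)
      if (is.null(best)) next
      grA <- map_c2g(best$seqA_range, ga)
      grB <- map_c2g(best$seqB_range, gb)
      identical <- list(chromA = ga$chrom, startA = grA[1], endA = grA[2],
                        chromB = gb$chrom, startB = grB[1], endB = grB[2])
      hid <- length(out$homology) + 1L
      out$homology[[hid]] <- c(
        list(geneA = ga$name, geneB = gb$name, length = best$length,
             is_exact = best$is_exact, group = gi, group_kind = g$kind),
        identical)
      out$chimeras[[hid]] <- collect_chimera_support(
        aln, ga, gb, identical,
        insert_mean = params$insert_mean, insert_sd = params$insert_sd)
    }
  }
  out
}

#' Assemble the evidence bundle for classification
#'
#' Runs mappability -> unique regions -> windowed depth -> terminal CNV
#' -> soft-clip clusters (+ characterization) -> discordant groups ->
#' homology narrowing and chimera support, all against one reference.
#'
#' @param genome reference `gcr_genome` with features
#' @param alignments SAM/BAM path or [read_alignments()] result
#' @param params [gcr_params()]
#' @return an `evidence_bundle` list
#' @export
build_evidence <- function(genome, alignments, params = gcr_params()) {
  aln <- as_alignments(alignments)
  if (is.null(params$insert_mean) || is.null(params$insert_sd)) {
    proper <- bitwAnd(aln$reads$flag, 2L) > 0 & !is.na(aln$reads$isize) &
      aln$reads$isize > 0
    if (!any(proper)) stop("cannot estimate insert size: no proper pairs")
    if (is.null(params$insert_mean))
      params$insert_mean <- median(aln$reads$isize[proper])
    if (is.null(params$insert_sd))
      params$insert_sd <- mad(aln$reads$isize[proper])
  }
  message("mappability: k=", params$k, " m=", params$m)
  track <- compute_mappability(genome, params$k, params$m)
  regions <- extract_unique_regions(track, params$min_len)
  message("unique regions: ", nrow(regions))
  profile <- windowed_depth(aln, regions, bin = params$bin,
                            min_mapq = params$min_mapq)
  cnv <- call_terminal_cnv(profile, params$del_ratio_max,
                           params$dup_ratio_min, params$min_windows)
  message("terminal CNV calls: ", nrow(cnv))
  clusters <- cluster_soft_clips(aln, params$min_clip, params$min_support)
  message("soft-clip clusters: ", nrow(clusters))
  clip_char <- characterize_clips(clusters, genome, params)
  groups <- find_discordant_pairs(aln, params$insert_mean,
                                  params$insert_sd, params$min_pairs)
  message("discordant groups: ", nrow(groups))
  hom <- derive_homology_evidence(genome, aln, groups, cnv, clusters,
                                  params)
  structure(list(genome = genome, params = params, regions = regions,
                 profile = profile, cnv = cnv, clusters = clusters,
                 clip_char = clip_char, groups = groups,
                 homology = hom$homology, chimeras = hom$chimeras,
                 aln = aln),
            class = "evidence_bundle")
}

#' Classify terminal deletions into healing mechanisms
#'
#' Applies ordered decision rules to every terminal deletion call:
#' (1) a telomeric junction clip means de novo telomere addition —
#' upgraded to a complex inversion-plus-deletion when an inversion-kind
#' discordant group and a homology-narrowed inversion breakpoint lie
#' centromeric to the junction on the same arm; (2) a junction linked to
#' another chromosome's terminal region that carries a terminal
#' duplication, with chimeric read pairs through an identical interval,
#' is a homology-driven translocation (when the identical interval is
#' longer than a read no junction clip can exist, and the link comes
#' from the inter-chromosomal pair group; the junction is then the
#' telomere-side edge of the identical interval); (3) a clip realigning
#' elsewhere with at most `microhom_max` bases of junction microhomology
#' and no duplication at the partner is a homology-independent fusion;
#' (4) otherwise unresolved. Telomeric clips are tested first because
#' they can incidentally realign to telomeric tracts and masquerade as
#' fusions.
#'
#' @param bundle an [build_evidence()] result
#' @return data.frame of mechanism calls (one per terminal deletion):
#'   `chrom`, `side`, `mechanism`, `junction` (1-based first retained
#'   base), `partner_chrom`, `partner_coord`, `confidence`, `evidence`,
#'   `note`
#' @export
classify <- function(bundle) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  p <- bundle$params
  cnv <- bundle$cnv
  dels <- cnv[cnv$kind == "deletion", , drop = FALSE]
  if (!nrow(dels)) stop("bundle contains no terminal deletion call")
  dups <- cnv[cnv$kind == "duplication", , drop = FALSE]
  cls <- bundle$clusters
  calls <- list()
  for (i in seq_len(nrow(dels))) {
    d <- dels[i, ]
    # the junction must sit between the innermost depleted window and the
    # first normal one; the stretch in between can be wide where
    # homologous sequence breaks the unique-region mask
    lo <- min(d$inner_edge, d$boundary) - 2L * p$bin
    hi <- max(d$inner_edge, d$boundary) + 2L * p$bin
    near_edge <- function(j, slack = p$bin)
      j >= min(d$inner_edge, d$boundary) - slack &
      j <= max(d$inner_edge, d$boundary) + slack
    cand <- which(cls$chrom == d$chrom & cls$junction >= lo &
                  cls$junction <= hi)
    ci <- if (length(cand)) cand[order(-cls$support[cand],
                                       cls$junction[cand])][1] else NA
    cl <- if (!is.na(ci)) cls[ci, ] else NULL
    ch <- if (!is.na(ci)) bundle$clip_char[[ci]] else NULL

    mech <- "unresolved"; junction <- d$boundary
    partner_chrom <- NA_character_; partner_coord <- NA_integer_
    evid <- sprintf("cnv:%s:%s", d$chrom, d$side)
    note <- ""
    conf <- "low"

    inv <- bundle$groups[bundle$groups$chromA == d$chrom &
                         grepl("^inversion", bundle$groups$kind), ,
                         drop = FALSE]
    same_hom <- which(vapply(bundle$homology, function(h)
      h$chromA == d$chrom && h$chromB == d$chrom, TRUE))
    hom_edges <- function(h) c(h$startA + 1L, h$endA, h$startB + 1L,
                               h$endB)
    centromeric_of <- function(pos, j) if (d$side == "left") pos > j
      else pos < j

    if (!is.null(cl) && isTRUE(ch$is_telomeric)) {
      # boundary-adjacent telomeric clip: plain healed terminal deletion
      mech <- "de_novo_telomere_addition"
      junction <- cl$junction
      evid <- c(evid, sprintf("cluster:%s:%d", cl$chrom, cl$junction))
      hom_cent <- same_hom[vapply(same_hom, function(hi) {
        h <- bundle$homology[[hi]]
        centromeric_of(max(h$startA, h$startB) + 1L, junction)
      }, TRUE)]
      if (nrow(inv) && length(hom_cent)) {
        mech <- "complex_inversion_plus_deletion"
        h <- bundle$homology[[hom_cent[1]]]
        evid <- c(evid, sprintf("group:%s", inv$kind[1]),
                  sprintf("homology:%s-%s", h$geneA, h$geneB))
      }
      conf <- if (cl$support >= 2L * p$min_support &&
                  near_edge(junction)) "high" else "low"
    } else if (!is.null(cl) && nrow(inv) && length(same_hom) &&
               nrow(ch$partner_hits) &&
               any(ch$partner_hits$chrom == d$chrom) &&
               any(vapply(same_hom, function(hi)
                 min(abs(hom_edges(bundle$homology[[hi]]) -
                         cl$junction)) <= 3L, TRUE))) {
      # boundary-adjacent cluster is an inversion junction through an
      # identical window: the arm continues inverted, and the molecule's
      # real end is a telomeric cluster centromeric of it
      hi2 <- same_hom[vapply(same_hom, function(hi)
        min(abs(hom_edges(bundle$homology[[hi]]) - cl$junction)) <= 3L,
        TRUE)][1]
      h <- bundle$homology[[hi2]]
      far <- if (d$side == "left") max(hom_edges(h)) else
        min(hom_edges(h))
      tix <- which(cls$chrom == d$chrom &
                   vapply(seq_len(nrow(cls)), function(k)
                     isTRUE(bundle$clip_char[[k]]$is_telomeric), TRUE) &
                   centromeric_of(cls$junction, cl$junction) &
                   !centromeric_of(cls$junction, far))
      if (length(tix)) {
        tix <- tix[order(-cls$support[tix])][1]
        tcl <- cls[tix, ]
        mech <- "complex_inversion_plus_deletion"
        junction <- tcl$junction
        evid <- c(evid, sprintf("cluster:%s:%d", tcl$chrom, tcl$junction),
                  sprintf("inversion_junction:%s:%d", cl$chrom,
                          cl$junction),
                  sprintf("group:%s", inv$kind[1]),
                  sprintf("homology:%s-%s", h$geneA, h$geneB))
        conf <- if (tcl$support >= 2L * p$min_support &&
                    near_edge(cl$junction)) "high" else "low"
      }
    }

    if (mech == "unresolved") {
      # homology-driven translocation: identical interval linking this
      # arm to a duplicated terminal region on another chromosome
      tr <- NULL
      for (hi in seq_along(bundle$homology)) {
        h <- bundle$homology[[hi]]
        onA <- h$chromA == d$chrom
        onB <- h$chromB == d$chrom
        if (onA == onB) next               # need exactly one side here
        pchrom <- if (onA) h$chromB else h$chromA
        if (!any(dups$chrom == pchrom)) next
        chim <- bundle$chimeras[[hi]]
        # fully informative pairs (discriminating bases on both sides)
        # may be absent by sampling chance at 30x; a cluster of
        # one-sided supporting pairs through the interval still
        # identifies the chimera once the duplication and the
        # inter-chromosomal link are in hand
        if (is.null(chim) ||
            (chim$informative < 1L && chim$support < p$min_pairs)) next
        rs <- if (onA) c(h$startA, h$endA) else c(h$startB, h$endB)
        jh <- if (d$side == "left") rs[1] + 1L else rs[2]
        if (!near_edge(jh, 2L * p$bin)) next
        linked <- (!is.null(cl) && nrow(ch$partner_hits) &&
                   any(ch$partner_hits$chrom == pchrom)) ||
          h$group_kind == "inter_chromosomal"
        if (!linked) next
        ps <- if (onA) c(h$startB, h$endB) else c(h$startA, h$endA)
        tr <- list(h = h, hi = hi, junction = jh, pchrom = pchrom,
                   pcoord = ps[1] + 1L, chim = chim)
        break
      }
      if (!is.null(tr)) {
        mech <- "homology_driven_translocation"
        junction <- tr$junction
        partner_chrom <- tr$pchrom
        partner_coord <- tr$pcoord
        evid <- c(evid,
                  sprintf("homology:%s-%s", tr$h$geneA, tr$h$geneB),
                  sprintf("chimera:%d/%d", tr$chim$informative,
                          tr$chim$support),
                  sprintf("cnv:%s:duplication", tr$pchrom))
        conf <- if (tr$chim$informative >= p$min_pairs &&
                    near_edge(junction)) "high" else "low"
      } else if (!is.null(cl) && nrow(ch$partner_hits) &&
                 !is.na(ch$microhomology_len) &&
                 ch$microhomology_len <= p$microhom_max) {
        hit <- ch$partner_hits[1, ]
        if (!any(dups$chrom == hit$chrom)) {
          mech <- "homology_independent_fusion"
          junction <- cl$junction
          partner_chrom <- hit$chrom
          partner_coord <- hit$partner_coord
          evid <- c(evid, sprintf("cluster:%s:%d", cl$chrom, cl$junction),
                    sprintf("realign:%s:%d:%s", hit$chrom, hit$pos,
                            hit$strand),
                    sprintf("microhomology:%d", ch$microhomology_len))
          rd <- feature_rows(bundle$genome, kind = "rdna_array",
                             chrom = hit$chrom)
          if (nrow(rd) && any(rd$start < hit$end & rd$end > hit$pos - 1L))
            note <- "partner inside rDNA array; "
          note <- paste0(note, "dicentric fusion product presumed ",
                         "resolved by breakage or centromere inactivation")
          conf <- if (cl$support >= 2L * p$min_support &&
                      near_edge(junction)) "high" else "low"
        }
      }
    }

    if (mech %in% c("de_novo_telomere_addition",
                    "complex_inversion_plus_deletion")) {
      genes <- feature_rows(bundle$genome, kind = "gene", chrom = d$chrom)
      near <- if (d$side == "left")
        genes$name[genes$start + 1L >= junction &
                   genes$start + 1L - junction <= p$silencing_dist]
      else genes$name[genes$end <= junction &
                      junction - genes$end <= p$silencing_dist]
      if (length(near))
        note <- paste0(note, "near_new_telomere:",
                       paste(near, collapse = ","))
    }

    calls[[i]] <- data.frame(
      chrom = d$chrom, side = d$side, mechanism = mech,
      junction = as.integer(junction), partner_chrom = partner_chrom,
      partner_coord = partner_coord, confidence = conf,
      evidence = paste(evid, collapse = ";"), note = note,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, calls)
}
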