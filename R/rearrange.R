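#' Construct a rearrangement event record
#'
#' Describes one gross chromosomal rearrangement deleting the left
#' (telomere-proximal, low-coordinate) end of `chrom`. `first_retained`
#' is the 1-based coordinate of the first undeleted base, matching how
#' such junctions are reported from sequencing data. For homology-driven
#' events the first retained base is the telomere-side edge of the
#' identical interval (the junction itself is ambiguous across that
#' interval).
#'
#' @param event_type one of `homology_translocation`, `chromosome_fusion`,
#'   `telomere_addition`, `inversion_plus_deletion`
#' @param chrom chromosome receiving the terminal deletion
#' @param first_retained 1-based first undeleted base (may be `NA` for
#'   homology_translocation, where it is derived from the identical
#'   region)
#' @param partner optional list `(chrom, coord, strand)`; required
#'   concept for translocation/fusion, filled in by
#'   [apply_rearrangement()] when omitted
#' @param homology_interval optional list
#'   `(chromA, startA, endA, chromB, startB, endB)` (0-based half-open);
#'   filled in from the genome's `identical_region` features
#' @param telomere_seq optional appended telomeric repeat string
#' @return an object of class `gcr_event`
#' @export
rearrangement_event <- function(event_type, chrom, first_retained = NA,
                                partner = NULL, homology_interval = NULL,
                                telomere_seq = NULL) {
  event_type <- match.arg(event_type,
    c("homology_translocation", "chromosome_fusion", "telomere_addition",
      "inversion_plus_deletion"))
  structure(list(event_type = event_type, chrom = chrom,
                 first_retained = first_retained, partner = partner,
                 homology_interval = homology_interval,
                 telomere_seq = telomere_seq),
            class = "gcr_event")
}

validate_event <- function(ev, genome) {
  L <- nchar(genome$chroms[[ev$chrom]])
  stopifnot(!is.na(ev$first_retained),
            ev$first_retained >= 1, ev$first_retained <= L)
  needs_hom <- ev$event_type %in% c("homology_translocation",
                                    "inversion_plus_deletion")
  needs_par <- ev$event_type %in% c("homology_translocation",
                                    "chromosome_fusion")
  if (needs_hom != !is.null(ev$homology_interval))
    stop("homology_interval must be present iff the event is homology-driven")
  if (needs_par != !is.null(ev$partner))
    stop("partner must be present iff the event is a translocation or fusion")
  invisible(ev)
}

new_block <- function(ref_chrom = NA_character_, ref_start = NA_integer_,
                      ref_end = NA_integer_, strand = "+", novel_seq = NA) {
  data.frame(ref_chrom = ref_chrom, ref_start = as.integer(ref_start),
             ref_end = as.integer(ref_end), strand = strand,
             novel_seq = novel_seq, stringsAsFactors = FALSE)
}

identity_blocks <- function(genome) {
  lapply(setNames(names(genome$chroms), names(genome$chroms)), function(cn)
    finish_blocks(new_block(cn, 0L, nchar(genome$chroms[[cn]]), "+")))
}

# add mut_start/mut_end columns
finish_blocks <- function(b) {
  len <- ifelse(is.na(b$ref_chrom), nchar(b$novel_seq), b$ref_end - b$ref_start)
  b$mut_end <- cumsum(len)
  b$mut_start <- b$mut_end - len
  b
}

blocks_to_seq <- function(b, ref) {
  parts <- vapply(seq_len(nrow(b)), function(i) {
    if (is.na(b$ref_chrom[i])) return(b$novel_seq[i])
    s <- subseq0(ref$chroms[[b$ref_chrom[i]]], b$ref_start[i], b$ref_end[i])
    if (b$strand[i] == "-") s <- revcomp(s) else s
  }, "")
  paste(parts, collapse = "")
}

# Number of junction-adjacent appended/partner bases that the retained
# chromosome's reference could equally explain. Alignment extension
# shifts the observable junction outward by this many bases, so truth
# records store the coordinate soft-clip evidence can actually recover.
# strand is the anchored orientation of the retained side at the
# junction: "+" extends into lower reference coordinates, "-" (inverted
# retained segment) into higher ones, complemented.
junction_ext <- function(app, refseq, F1, strand) {
  L <- 0L
  la <- nchar(app)
  for (t in seq_len(min(20L, la))) {
    ab <- substring(app, la - t + 1L, la - t + 1L)
    rb <- if (strand == "+") {
      if (F1 - 1L - t < 0L) break
      subseq0(refseq, F1 - 1L - t, F1 - t)
    } else {
      if (F1 - 1L + t >= nchar(refseq)) break
      chartr("ACGT", "TGCA", subseq0(refseq, F1 - 1L + t, F1 + t))
    }
    if (ab != rb) break
    L <- t
  }
  L
}

check_essential_survives <- function(genome, chrom, deleted) {
  ess <- feature_rows(genome, kind = "essential_gene", chrom = chrom)
  for (i in seq_len(nrow(ess)))
    for (d in deleted)
      if (ess$start[i] < d[2] && ess$end[i] > d[1])
        stop("rearrangement would delete essential gene ", ess$name[i],
             "; such a cell is not viable")
}

id_pair <- function(genome, name) {
  rows <- feature_rows(genome, kind = "identical_region", name = name)
  if (nrow(rows) != 2)
    stop("expected exactly two identical_region features named ", name)
  rows
}

#' Apply a rearrangement to a genome, recording truth
#'
#' Builds the mutant genome as a list of sequence blocks copied from the
#' reference (or novel telomeric sequence), so that every simulated read
#' can later be given an exact truth alignment against the reference.
#'
#' Event semantics (all deleting the left end of `event$chrom`):
#' * `telomere_addition` — truncate at `first_retained`, prepend >= 4
#'   tandem GGTTAC-core repeats (stored reverse-complemented at the left
#'   end so the G-rich strand points off the chromosome).
#' * `chromosome_fusion` — truncate and join, telomere-proximal side
#'   facing the junction, to an rDNA-unit-internal position on the last
#'   chromosome; the partner coordinate is nudged (deterministically)
#'   until the junction carries zero microhomology.
#' * `homology_translocation` — replace the terminal segment through the
#'   `P1_id` identical region by a copy of the donor chromosome's
#'   terminal segment (the donor copy is retained, producing a terminal
#'   duplication there).
#' * `inversion_plus_deletion` — invert the segment between the `P2_id`
#'   windows through their shared identical window, then delete the
#'   (new) terminal segment into the middle gene and heal by telomere
#'   addition.
#'
#' @param genome the reference `gcr_genome` (features included)
#' @param event a [rearrangement_event()]; missing derivable fields
#'   (partner, homology interval, telomere sequence) are filled in
#' @return `list(genome = mutant, event = completed truth event)`; the
#'   mutant carries `blocks` and `reference` attributes consumed by
#'   [simulate_reads()]
#' @export
apply_rearrangement <- function(genome, event) {
  stopifnot(inherits(event, "gcr_event"))
  cn <- event$chrom
  if (!cn %in% names(genome$chroms)) stop("unknown chromosome ", cn)
  L <- nchar(genome$chroms[[cn]])
  ev <- event

  if (ev$event_type == "telomere_addition") {
    F1 <- ev$first_retained
    stopifnot(!is.na(F1))
    check_essential_survives(genome, cn, list(c(0L, F1 - 1L)))
    if (is.null(ev$telomere_seq))
      ev$telomere_seq <- make_telomere_tract(150L, 0.3)
    if (length(gregexpr("GGTTAC", ev$telomere_seq, fixed = TRUE)[[1]]) < 4)
      stop("telomere_seq must contain at least 4 core repeats")
    ev$first_retained <- F1 - junction_ext(revcomp(ev$telomere_seq),
                                           genome$chroms[[cn]], F1, "+")
    b <- rbind(new_block(novel_seq = revcomp(ev$telomere_seq)),
               new_block(cn, F1 - 1L, L))

  } else if (ev$event_type == "chromosome_fusion") {
    F1 <- ev$first_retained
    stopifnot(!is.na(F1))
    check_essential_survives(genome, cn, list(c(0L, F1 - 1L)))
    if (is.null(ev$partner)) {
      last <- names(genome$chroms)[length(genome$chroms)]
      arr <- feature_rows(genome, kind = "rdna_array", chrom = last)
      arr <- arr[which.min(arr$start), ]
      tc <- attr(genome, "toy_config")
      unit <- if (!is.null(tc)) tc$rdna_unit_len else 1500L
      ev$partner <- list(chrom = last,
                         coord = arr$start + unit + min(700L, unit %/% 2),
                         strand = "+")
    }
    # enforce a microhomology-free junction: shift the partner breakpoint
    # until no base is shared across the junction
    p <- as.integer(ev$partner$coord)
    pc <- ev$partner$chrom
    for (try in 1:100) {
      up <- subseq0(genome$chroms[[pc]], p - 20L, p)
      down <- subseq0(genome$chroms[[cn]], F1 - 1L, min(L, F1 + 19L))
      if (measure_microhomology(up, down) == 0L &&
          junction_ext(up, genome$chroms[[cn]], F1, "+") == 0L) break
      p <- p + 1L
      if (try == 100) stop("could not find microhomology-free junction")
    }
    ev$partner$coord <- p   # 1-based last partner base == 0-based end p
    b <- rbind(new_block(pc, 0L, p), new_block(cn, F1 - 1L, L))

  } else if (ev$event_type == "homology_translocation") {
    rows <- id_pair(genome, "P1_id")
    recip <- rows[rows$chrom == cn, ]
    donor <- rows[rows$chrom != cn, ]
    if (nrow(recip) != 1 || nrow(donor) != 1)
      stop("P1_id must pair ", cn, " with a donor chromosome")
    bs <- recip$start; be <- recip$end
    as_ <- donor$start; ae <- donor$end
    ev$first_retained <- bs + 1L
    ev$homology_interval <- list(chromA = donor$chrom, startA = as_,
                                 endA = ae, chromB = cn, startB = bs,
                                 endB = be)
    ev$partner <- list(chrom = donor$chrom, coord = as_, strand = "+")
    check_essential_survives(genome, cn, list(c(0L, bs)))
    b <- rbind(new_block(donor$chrom, 0L, as_), new_block(cn, bs, L))

  } else { # inversion_plus_deletion
    rows <- id_pair(genome, "P2_id")
    rows <- rows[rows$chrom == cn, ]
    if (nrow(rows) != 2) stop("P2_id windows must both lie on ", cn)
    wA <- rows[which.min(rows$start), ]
    wB <- rows[which.max(rows$start), ]
    F1 <- ev$first_retained
    stopifnot(!is.na(F1))
    if (!(F1 > wA$end && F1 <= wB$start))
      stop("first_retained must fall between the two inversion windows")
    if (is.null(ev$telomere_seq))
      ev$telomere_seq <- make_telomere_tract(150L, 0.3)
    ev$homology_interval <- list(chromA = cn, startA = wA$start,
                                 endA = wA$end, chromB = cn,
                                 startB = wB$start, endB = wB$end)
    check_essential_survives(genome, cn,
                             list(c(0L, wA$start), c(F1, wB$end)))
    ev$first_retained <- F1 + junction_ext(revcomp(ev$telomere_seq),
                                           genome$chroms[[cn]], F1, "-")
    b <- rbind(new_block(novel_seq = revcomp(ev$telomere_seq)),
               new_block(cn, wA$start, F1, "-"),
               new_block(cn, wB$end, L))
  }

  blocks <- identity_blocks(genome)
  blocks[[cn]] <- finish_blocks(b)
  chroms <- genome$chroms
  chroms[[cn]] <- blocks_to_seq(blocks[[cn]], genome)
  mut <- gcr_genome(chroms, empty_features())
  attr(mut, "blocks") <- blocks
  attr(mut, "reference") <- genome
  validate_event(ev, genome)
  list(genome = mut, event = ev)
}

#' Write truth events as JSON
#' @param events list of `gcr_event`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_truth_json <- function(events, path) {
  jsonlite::write_json(lapply(events, unclass), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
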