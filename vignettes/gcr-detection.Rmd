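---
title: "Detecting chromosome terminal deletions and their healing mechanisms"
author: "gcrscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosome terminal deletions and their healing mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcrscope)
```

## The problem

In haploid fungi such as fission yeast, a chromosome that loses its end
must be "healed" before it can be propagated: the broken end is either
re-capped by telomerase (de novo telomere addition), replaced by a copy
of another chromosome's end through recombination between dispersed
homologous genes (a nonreciprocal, homology-driven translocation),
joined to another chromosome — often through the rDNA arrays — without
any homology (a dicentric-forming fusion), or produced by a more complex
series of events such as an inversion between inverted homologous genes
followed by a terminal deletion and telomere addition. Short-read
whole-genome sequencing resolves all of these from four evidence layers:

1. **Read depth** over mappability-masked windows reveals the lost
   terminal segment (and, for translocations, the duplicated donor
   segment).
2. **Soft-clipped reads** at the junction give the first retained base
   at single-nucleotide resolution; the clipped sequence itself carries
   the partner: telomeric `GGTTAC` repeats, rDNA sequence, or the other
   homolog.
3. **Discordant read pairs** (same-orientation, inter-chromosomal, or
   long-insert) reveal inversions and translocations even where no
   single read can span the junction.
4. **Homology intervals**: when the junction falls inside sequence
   shared identically by two loci, no read evidence can place it more
   precisely than that interval; aligning the two homologs and taking
   the maximal run of identical columns around the switch quantifies
   exactly this ambiguity.

gcrscope implements the four layers, a rule-based classifier that
integrates them into one mechanism call per terminal deletion, and a
simulator that builds toy genomes carrying the relevant motifs so the
whole pipeline is verifiable without any external data.

## Mappability and unique regions

Depth is only interpretable where reads map uniquely. For every
position we compute the exact mappability value
$1 / |\{q : d_H(k_p, k_q) \le m\}|$ — the reciprocal of the number of
genome positions whose $k$-mer lies within Hamming distance $m$ of the
$k$-mer at $p$ (defaults $k = 100$, $m = 2$). The computation is exact,
not heuristic: candidate pairs are found by pigeonhole chunk seeding
($m+1$ chunks; a pair within distance $m$ must share one chunk exactly)
and verified by full Hamming comparison, in C++. Forward-strand k-mers
only are compared by default, matching the convention of index-based
mappability tools; `both_strands = TRUE` flips this. **Unique regions**
are maximal runs of mappability exactly 1 strictly longer than 1 kb.
Telomeric tracts, rDNA arrays and the identical regions of homologous
gene pairs fall out of the mask automatically — which is also why a
depth boundary can sit up to ~1 kb from the true junction when the
junction abuts such a region (see "terminal CNV" below).

## Windowed depth and terminal CNV calls

Depth windows tile each unique region in non-overlapping 200 bp bins
(the bin size is fixed by convention for these plots; the step is a
design choice here and exposed as a parameter), counting only aligned
(non-clipped) bases above a mapping-quality threshold (default 0: the
unique-region mask already removes ambiguity). The genome mean is the
average depth over all windowed bases, so the length-weighted mean of
normalized depth is exactly 1 — an invariant the tests assert to 1e-9.

A terminal deletion (duplication) is called when at least 10
consecutive windows with normalized depth below 0.25 (above 1.5) run
inward from a chromosome end. Two practical accommodations, both
visible in any real library:

* the outermost window of a chromosome always sags (fragments must fit
  inside the chromosome), so a run may skip up to `max_edge_skip = 2`
  tip windows;
* each call records both its `boundary` (first base at normal copy) and
  its `inner_edge` (the near edge of the last aberrant window), because
  the junction itself lives between the two — possibly far from the
  boundary when a mappability gap intervenes.

The thresholds are engineering choices for haploid data at 20x or more;
no published numeric threshold exists for these calls, and all are
exposed in `gcr_params()`. Depth resolves boundaries to ±1 bin only;
base resolution is delegated to soft clips.

## Junction analysis

Soft-clipped reads with clips of at least 10 bases are grouped by
(chromosome, clip coordinate, side); clusters with at least 3 reads are
kept. The junction is reported as the **first retained base** (1-based),
matching how such junctions are described from sequencing data. The
clip consensus (per-column majority; ties vote `N`, and `N`s are
excluded from telomere scoring and realignment seeds) is oriented
5'→3' *away* from the retained side — left-clip sequences are
reverse-complemented — so a telomeric clip reads `GGTTAC...` on either
chromosome arm.

Telomere scoring uses a small grammar: tandem chains of the core motif
`GGTTAC` with at most 2 non-core bases between consecutive cores, and a
telomeric verdict requires at least 2 cores covering at least half the
clip. Fission-yeast telomeric repeats are degenerate, but only the core
motif is documented; the spacer grammar is this package's decision,
configurable, and the simulator produces exactly the degeneracy the
detector must tolerate (0–2 nt A/C spacers with probability 0.3 per
core).

Clip realignment is seed-and-extend (15 bp exact seeds at half-seed
stride, ungapped extension allowing 2 mismatches, both strands), which
is ample for consensus clips of tens of bases against sub-megabase
genomes. The hit orientation is reported so "telomere-proximal side
facing the junction" is decidable: a minus-strand hit of an oriented
clip means the partner continues toward lower coordinates away from the
junction.

Microhomology at a non-homologous junction is measured on the
junction-forming strand: with `retained_flank` ending at the junction
and `partner_flank` starting at it, the value is the largest $L$ with
$\mathrm{suffix}_L(\text{retained}) = \mathrm{prefix}_L(\text{partner})$
— the number of bases over which the exact junction is ambiguous. The
measure is symmetric under swapping the flank roles together with
reverse complementation, and degenerates to $w$ for identical flanks of
length $w$ (such junctions are routed to the homology-driven logic
instead). Junctions with at most `microhom_max = 1` shared base count
as homology-independent.

## Discordant pairs, chimeras, and homology narrowing

Insert statistics default to the median and MAD of proper-pair template
lengths. Pairs are flagged as `inversion_FF`/`inversion_RR` (mates
share orientation), `inter_chromosomal`, or `long_insert` (span above
mean + 5 sd, a cut chosen here, not taken from any publication), then
clustered with a window of mean + 3 sd on both loci; groups need 3
pairs.

For a homology-mediated chimera of genes A and B, a read pair is
**informative** only if each mate carries at least one base of
gene-specific (outside-the-identical-interval) sequence and the implied
insert on the chimeric molecule is within 3 sd of the library mean. The
implied insert is evaluated over the four possible junction forms
(either side of A joined to either side of B through the interval,
which is counted once), so the same computation serves colinear and
inverted chimeras. Mates lying entirely inside the identical interval
are consistent with both parental loci and never count. A single read
soft-clipped at an interval edge with gene-specific aligned sequence
also counts as spanning the switch.

`narrow_breakpoint_interval()` aligns the two homologs globally (unit
scores: match +1, mismatch −1, gap −2, free end gaps) in chimera
orientation (one of an inverted pair is reverse-complemented first) and
returns the maximal run of identical columns containing the switch
column; if the switch column itself differs the interval has length 0.
Because diverged homologs contain many short identical runs, the choice
of switch column matters: the pipeline anchors it on soft-clip
junction coordinates when any exist (they are base-exact), and only
falls back to a deterministic 50 bp grid around the ±1-bin depth
boundary and the discordant-group locus otherwise, keeping the longest
interval within a tier. This two-tier rule is what lets a 12 bp
inversion window win over incidental longer runs elsewhere in the
homologs.

## Classification

For each terminal deletion, rules apply in order:

1. a telomeric junction clip ⇒ **de novo telomere addition**; if an
   inversion-kind group and a same-chromosome homology interval lie
   centromeric to the junction, the call is upgraded to **complex
   inversion plus deletion**. Telomeric clips are tested first because
   they can incidentally realign to telomeric tracts and masquerade as
   fusions.
2. a boundary-adjacent cluster whose clip realigns to the same
   chromosome at a homology-interval edge, with an inversion group, is
   itself an inversion junction: the molecule continues inverted and
   its real end is the telomeric cluster centromeric of it (this is
   the complex case seen from the depth boundary).
3. an identical interval linking the deleted arm to another chromosome
   that carries a terminal duplication, with chimeric-pair evidence
   (informative both-side pairs when fragment sampling provides them;
   otherwise a cluster of one-sided supporting pairs through the
   interval) ⇒ **homology-driven translocation**. When the identical
   interval is longer than a read, *no junction cluster can exist* —
   every junction-spanning read maps full-length to the donor — so the
   link comes from the inter-chromosomal pair group and the reported
   junction is the telomere-side edge of the interval on the recipient
   (which is also exactly how precise the data permit the junction to
   be).
4. a clip realigning elsewhere with microhomology ≤ 1 and no
   duplication at the partner ⇒ **homology-independent fusion** (the
   dicentric product's fate — breakage or centromere inactivation — is
   reported as a free-text note, never inferred).
5. otherwise **unresolved** (including, by design, translocations whose
   donor duplication is itself repetitive).

Confidence is `high` when junction support is at least twice the
cluster minimum (or chimeric support at least the pair minimum) and the
junction lies between the CNV call's inner edge and boundary (±1 bin).
Retained genes starting within 5 kb of a new telomere are flagged
`near_new_telomere` — possible telomeric silencing — with no claim
about expression.

## The simulator and what passing tests mean

`build_toy_genome()` constructs a ~440 kb three-chromosome genome:
degenerate telomeric tracts at every end (left ends store the reverse
complement of the G-rich tract so the G-rich strand points off the
end), rDNA-like arrays (3 tandem 1.5 kb units) at both ends of the last
chromosome, a colinear homologous gene pair on the chrA/chrB terminal
regions sharing a perfectly identical 240 bp region, an inverted pair
flanking a middle gene on the chrB arm sharing a 12 bp window, and an
essential gene ~35 kb centromeric of the inverted pair. Homolog pairs
are built by point substitution (8% / 10% divergence) with the
identical region copied exactly and its immediate flanks forced to
mismatch, so the longest shared exact run is exactly the configured
length. These defaults — sizes, divergences, identical-region lengths,
2×150 bp reads at 30× with 0.5% substitution error, Normal(300, 30)
inserts — are the package's study conditions and are not tuned per
test.

`apply_rearrangement()` records the mutant as blocks copied from the
reference, and `simulate_reads()` derives each read's truth alignment
by maximal exact extension against the reference from every
junction-adjacent block. Two consequences worth knowing:

* reads ending inside an identical region map full-length to the donor
  homolog — exactly what a real aligner does — so clips appear only
  beyond the discriminating base;
* when the appended sequence at a junction happens to match the next
  reference base(s), the observable junction shifts outward; truth
  records store that outward-most coordinate (and engineered fusions
  are nudged until no such ambiguity exists), so "exact junction
  recovery" is well defined.

Reads wholly inside novel telomeric sequence (best exact anchor under
20 bp) are emitted unmapped, as an aligner would leave them. Truth
CIGARs are exact because sequencing errors are substitutions only; PCR
duplicates, GC bias, quality models and indel errors are out of scope.
Passing the suite therefore demonstrates correct *inference logic*
under realistic coverage fluctuation and substitution noise — it says
nothing about aligner-specific clip placement, indel artifacts, or
repeat families absent from the toy genome.

## Numerical choices and problem sizes

* Coordinates are 0-based half-open internally; 1-based in SAM, VCF and
  every human-facing report.
* Consensus ties vote `N`; `N`s never seed realignment.
* Candidate-pair budget for mappability is capped (5×10⁷ verifications)
  with a hard error, and the brute-force guard rejects genomes over
  5 Mb.
* The unit-test genome is a ~200 kb version of the same layout; the
  benchmark of record (`truth_recovery_study()`) runs 25 replicates at
  the full ~440 kb, 30× conditions, one event per genome across the
  four types. Both sizes are the package's own choices, balancing
  statistical content against a test suite a maintainer will actually
  run.
* All randomness flows from a single integer seed per run; reruns are
  byte-identical, and the tests assert this on FASTA, FASTQ, SAM, TSV,
  JSON and VCF output.

## Worked example

```{r example, eval = FALSE}
library(gcrscope)
res <- run_pipeline(list(
  simulate = list(event_type = "chromosome_fusion"),
  outdir   = tempdir(),
  seed     = 7L))
res$calls
#   chrom side                   mechanism junction partner_chrom partner_coord
# 1  chrB left homology_independent_fusion    47975          chrC          1401
#   confidence
# 1       high
```

The deletion junction on the chrB analogue is recovered to the base;
the clipped sequence realigns inside the chrC rDNA array with zero
junction microhomology, so the call is a homology-independent fusion,
with the dicentric caveat in the `note` column.

## Known limitations

* Only left-arm (low-coordinate) terminal deletions are generated by
  the simulator — the geometry of the motivating events — though the
  detection side handles either end.
* The classifier deliberately returns `unresolved` when the donor of a
  putative translocation is itself repetitive (no unique duplication
  signal exists in that case).
* Interior CNV segmentation, diploid genotyping, gapped clip
  realignment, and genome-wide split-read SV calling are non-goals;
  the pipeline characterizes junctions near terminal-CNV boundaries
  and user-specified regions only.
* Accuracy figures come from simulated data; real libraries add
  aligner idiosyncrasies and repeat structure the toy genome does not
  model.
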