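---
title: "Methods: coverage-based sRNA discovery, differential expression and network inference"
author: "sRNAseeker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based sRNA discovery, differential expression and network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

sRNAseeker re-implements, as a tested and reusable package, a
genome-wide workflow for discovering bacterial small regulatory RNAs
(sRNAs) from deep-sequencing coverage, quantifying their expression
across stress conditions, testing differential expression, ordinating
the sRNA-by-sample matrix, and inferring an sRNA-pathway regulatory
network from ingested target predictions. The workflow was designed for
a cyanobacterial stress study with 18 libraries (six growth conditions
-- control, ethanol, butanol, hexane, salt, nitrogen starvation --
sampled at 24, 48 and 72 h), and every stage here keeps that design as
its default. Because raw sequencing data of that scale cannot ship with
a package, a synthetic-study generator with known ground truth stands
in for the original samples; it is first-class, tested code, and all
benchmarks in the test suite run against it.

# The discovery model

## Mapping by iterative trimming

Reads are aligned to the genome by exact full-length matching only.
Error tolerance comes from the trim loop, not from mismatches: a read
that fails to match loses the terminal base with the lower quality
score (ties go to the 3' end, where sequencer quality degrades first)
and is retried, for up to 50 cycles or until it falls below 50 nt,
whichever comes first. Reads that end below 50 nt are discarded. A read
matching several loci is placed at *every* locus rather than discarded;
the downstream repeat flag marks candidates whose sequence recurs in
the genome, which is where multi-mapping inflation would otherwise
mislead.

Internally the matcher hashes all genome k-mers of length 50 (the
minimum read length) and verifies each anchor hit by full-length string
comparison, on both strands. This is an implementation detail; the
mapper's contract -- identical placements to a naive full-scan exact
matcher -- is asserted in the test suite against an independent
per-read `matchPattern` oracle.

## Coverage, masking, normalization

Coverage depth `s_i` at nucleotide `i` is the number of read placements
spanning `i`, strands pooled (the library protocol is unstranded).
rRNA and tRNA regions are masked: their depths are kept, but excluded
from the sample's total mapped bases. Each sample is then rescaled so
its masked-excluded total equals a fixed target. At full study scale the
convention is 100,000,000 bases, which for a ~4 Mb genome corresponds to
roughly 25x mean depth; the synthetic demo keeps the same convention at
its own scale by normalizing to the analytically expected masked total
of one library (about 5.1e5 bases for the default study), so that the
50x calling threshold retains the same meaning relative to background.
Normalization to a fixed total is exact (relative error < 1e-6 is
asserted; in practice it is at machine precision) and idempotent.

## Multi-tier calling

1. **Segmentation.** On each normalized track, maximal runs of
   positions with depth strictly above 50x become raw candidate
   intervals. Runs shorter than 50 bp are kept at this stage -- they may
   merge with neighbors -- and filtered at the end.
2. **Rescue.** Low-expressed sRNAs that never cross 50x can be rescued
   at previously reported reference loci: a reference is retained when
   its inside mean depth is positive and at least 2-fold above the mean
   of each 50 bp flank. The 2-fold ratio operationalizes an "obvious
   coverage reduction" at the boundaries, which the original procedure
   left unquantified.
3. **Cross-sample support.** Detections from all samples are pooled and
   clustered by overlap; the cluster consensus is the position-wise
   median of member starts and ends. A sample "observes" the cluster
   when one of its detections reaches Jaccard overlap >= 0.5 with the
   consensus; clusters observed in at least 3 of the 18 samples
   survive. The Jaccard rule makes "repeatedly observed" explicit,
   which the source procedure left informal.
4. **Merging.** Adjacent candidates on the same replicon whose gap is
   shorter than 50 bp and whose per-sample expression vectors share a
   trend are merged, iteratively to a fixpoint. "Same trend" defaults
   to positive Pearson correlation (r > 0); a majority
   sign-concordance rule is available as a configuration alternative.
   We read the 50 bp bound as applying to the *gap* between candidates:
   bounding the candidate lengths instead would make the rule vacuous,
   since candidates shorter than 50 bp are discarded anyway.
5. **Boundary refinement.** Each boundary moves, within +/- 20 nt, to
   the position of the maximum single-step coverage decline (mirrored
   for the 5' side) on the across-sample mean track, standing in for
   the original manual correction. Ties break toward the unrefined
   boundary, so a flat plateau leaves boundaries untouched. The +/- 20
   nt window is a fixed choice: wide enough to recover ragged ends,
   narrow enough never to jump to a neighboring feature.
6. **Classification.** The library carries no strand information, so
   categories are assigned by location alone, with precedence: overlap
   with any gene body -> asRNA ("antisense" here means gene-body
   overlap on either strand; orientation resolution would need
   strand-specific follow-up experiments, which are out of scope);
   otherwise overlap with a gene's strand-aware 100 nt upstream or
   50 nt downstream window -> UTR; otherwise ncRNA (intergenic,
   trans-encoded). Ids are prefixed nc/as/U with serials in genomic
   order.
7. **Repeat flagging.** A candidate is flagged when its sequence has a
   second site elsewhere in the genome aligning over > 50 bp at > 80%
   identity, found by exact 20-mer seeding with ungapped X-drop
   extension. This replaces a BLAST E-value screen with a deterministic
   desk-scale contract that enforces the same length and identity
   thresholds.

External annotations (protein-database hits, RNA-family assignments,
ORF/RBS/terminator predictions) are ingested from tables rather than
recomputed; database hits with E-value >= 1e-10 are ignored.

# Quantification and statistics

**Expression** of an sRNA spanning nucleotides i..i+j-1 is the summed
normalized depth divided by its length j, i.e. mean normalized depth.
Raw read counts per interval (span overlap) feed the
differential-expression test, with between-sample library size handled
by median-of-ratios size factors computed over sRNAs with all-positive
counts.

**Differential expression** uses a negative-binomial conditional exact
test: conditional on the rounded normalized total s = kA + kB of the two
condition groups, every split (a, s-a) is scored under NB group-sum
distributions with a common method-of-moments dispersion (the across-
sRNA mean of per-sRNA pooled-moment estimates -- a deliberate
information-sharing step, since three replicates per group cannot
estimate a per-sRNA dispersion stably), and the two-sided p value is the
total probability of splits no more likely than the observed one. The
original analysis used the DESeq package; this stand-in keeps DESeq's
structure (median-of-ratios + NB exact test + Benjamini-Hochberg) behind
a small interface so a full DESeq port could be swapped in, because the
workflow's substance is its thresholds, not the internals of one DE
engine. The fold change is (mean_B + 0.5)/(mean_A + 0.5) on normalized
counts; the 0.5 pseudocount stabilizes ratios at zero counts.
Significance requires fold change strictly above 1.5 (or below 1/1.5)
and BH-adjusted p strictly below 0.05. The original study sequenced one
library per condition and time point; we treat the three time points of
a condition as replicates (n = 3 vs 3) for condition-level calls, and
expose a per-time-point mode for early-response comparisons. The test's
null calibration (type-I rate in [0.03, 0.07] at alpha = 0.05 under
dispersion 0.1) and power (>= 0.8 for 4-fold changes at mean 200 after
BH) are asserted by simulation in the acceptance tests.

**Correspondence analysis** is classical: scale the nonnegative
expression matrix to proportions, form standardized residuals from the
row/column masses, SVD, principal coordinates; inertia per dimension is
the squared singular value and total inertia equals chi-square over the
grand total. CA operates on the expression matrix directly -- it is
contingency-like and nonnegative by construction -- with no log
transform. The implementation is a direct SVD; tests cross-check it
against an independent reimplementation and against `MASS::corresp`.

# Network inference

Target predictions arrive as comparative-prediction tables (sRNA, gene,
hybridization free energy dG in kcal/mol, rank). Filtering keeps, per
sRNA, rank <= 100 and dG <= -10 kcal/mol. Surviving predictions pass an
expression-correlation filter over paired sRNA/transcriptome profiles:
Pearson r over shared samples, keeping |r| > 0.4 with p < 0.05, both
signs retained (sRNA regulation can be activating). The correlation
p value uses the two-sided Fisher z transform (z = atanh r, se =
1/sqrt(n-3)); the source text attributes these p values to a two-sided
Fisher *exact* test, which does not apply to a correlation coefficient,
so the z transform is our documented substitution.

Per sRNA, pathway enrichment is the upper-tail hypergeometric
probability P = 1 - sum_{i<m} C(M,i) C(N-M,n-i)/C(N,n), with N the
number of genes carrying any pathway annotation (not the whole genome),
n the sRNA's surviving targets inside that universe, and (M, m) the
pathway's size and overlap. It is computed via the log-space CDF
(`stats::phyper`); tests pin it to exhaustive enumeration for every
(N <= 30, M, n, m) to 1e-12. Pathways need m >= 2 target genes and
P < 0.05 to be reported. Passing (sRNA, pathway) pairs become edges of
a bipartite graph carrying P, m and the dominant correlation sign;
the graph exports to GraphML (lossless round-trip through the package
reader) and SIF for Cytoscape-style viewers.

# The synthetic study

The generator emulates what the analysis assumes about real data, not
the data's full texture:

* a two-replicon genome (100 kb "chromosome", 10 kb "plasmid") of
  i.i.d. nucleotides at GC 0.475, with ~60 non-overlapping CDS genes,
  two rRNA operons and five tRNAs placed with intergenic gaps wide
  enough to admit planted intergenic features;
* 40 planted sRNAs (20 ncRNA, 12 asRNA, 8 UTR) of 60-100 nt -- the
  size-selected regime the trimming strategy targets -- at 100-300x
  expressed depth, plus 5 decoys flat at 20x, below the 50x threshold;
  placement guarantees each category is re-derivable from coordinates
  (ncRNAs keep >= 101 nt gene clearance, UTR features sit inside the
  upstream window without touching the gene, asRNAs sit wholly inside
  gene bodies, all features >= 200 nt apart);
* expression profiles cycle through constitutive / stress-induced /
  stress-repressed response types so that, as in a real stress study,
  most sRNAs are not responsive to any one treatment -- this is also
  what makes median-of-ratios size factors valid on the resulting
  counts;
* reads are single-end transcript fragments: features shorter than the
  100 nt read length yield whole-transcript reads with small Poisson
  end-raggedness (emulating size selection), on top of uniform 1x
  Poisson noise, 3x mRNA-degradation background over CDS bodies and
  30x structural-RNA coverage that the masking step must remove.
  Single-end reads stand in for the original paired-end protocol
  deliberately: pairing adds no information to coverage-threshold
  calling. A configurable 10% of reads carry one flipped terminal base
  at quality Q2, giving the "low-quality base" trim rule a concrete
  operational meaning;
* per-sample library-size factors are drawn log-normally (sd 0.2) so
  normalization has real work to do;
* network-truth tables over-sample true targets from chosen pathways
  with favorable energies (<= -12) and profiles correlated with the
  sRNA (|r| ~ 0.75-0.95), while decoys carry either unfavorable
  energies (> -10) or profiles orthogonalized against the sRNA.

Everything regenerates bit-identically from (parameters, seed): each
stage and sample derives its own stream from the master seed. Ground
truth is written beside every generated study so recovery metrics never
reach into generator internals.

What the generator does **not** emulate -- and hence what passing tests
do not establish about real data: realistic base-error and quality
profiles, adapter contamination, rRNA-depletion chemistry, sequence
composition of a real genome (repeats arise only when planted),
transcriptional read-through, and operon structure. Recovery rates on
the synthetic study are a correctness check of the pipeline's logic
under its own assumptions, not an estimate of sensitivity on real
libraries.

# Numerical and degenerate-case choices

* Thresholds are strict inequalities exactly where the method states
  them: depth > 50, fold change > 1.5, adjusted p < 0.05, |r| > 0.4,
  correlation p < 0.05, identity > 80%, alignment length > 50 bp; the
  energy filter keeps dG <= -10.
* The NB exact test returns p = 1, fold change = 1 for all-zero pairs;
  p values are floored at the smallest positive double.
* Constant expression profiles make Pearson r undefined; such
  predictions are dropped with a warning rather than scored.
* All-zero rows or columns abort correspondence analysis with the
  offender's name; zero masked totals abort normalization ("no usable
  coverage").
* Boundary-refinement ties keep the original boundary; only strictly
  positive rises/drops move it.
* All coordinates are 1-based inclusive at every interface (GFF3
  convention); BedGraph's 0-based half-open intervals are converted at
  the I/O boundary.

# Problem sizes

The default study (110 kb genome, 18 samples, ~190,000 reads) runs end
to end in about a minute on one CPU; the test suite's simulations use
1000 null and 200 signal sRNAs for DE calibration, the complete
(N <= 30) grid for the hypergeometric oracle, and 100 seeds for the
network null. These sizes were chosen so the full statistical checks
stay desk-scale while keeping Monte-Carlo error well inside the
asserted bands.

# Known limitations

* Exact-match-plus-trimming mapping cannot place reads over true SNPs
  or indels; on real data a seed-and-extend aligner would be swapped in
  at the `mapReadsIterative` interface.
* Unstranded coverage cannot distinguish a genuine antisense RNA from
  sense-strand degradation of its host gene; the asRNA category is a
  location label, not an orientation call.
* With one library per condition and time point, treating time points
  as replicates conflates temporal change with biological variance;
  the per-time-point mode exists for that reason but has n = 1 per
  group and should be read as exploratory.
* The enrichment universe is the pathway-annotated gene set; sRNAs
  whose targets are mostly unannotated lose power by construction.
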