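---
title: "coolsuite: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coolsuite: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the statistics it implements:
the models and their assumptions, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the places where the design was genuinely open
and a choice had to be made. It states no empirical result that the
test suite does not itself compute.

## 1. The assay and the two channels

In GpC-methyltransferase bisulfite assays (NOMe-seq and its single-cell
derivatives), M.CviPI methylates GpC dinucleotides in accessible
chromatin before bisulfite conversion. After conversion, a cytosine read
as C was methylated and a cytosine read as T was not, so a single
library carries two superimposed signals, separated purely by
trinucleotide context:

* **GCH** (H ∈ {A,C,T}): enzyme-accessible chromatin. High GCH
  methylation means the enzyme could reach the DNA — a nucleosome-free
  stretch; low GCH methylation means protection — a nucleosome core.
* **WCG** (W ∈ {A,T}): endogenous CpG methylation, untouched by the
  enzyme.

**GCG** is ambiguous (both a GpC and a CpG) and **CCG** is a known weak
off-target of the enzyme; both are excluded from every analysis. The
context is read on the cytosine's own strand (the upstream aligner's
convention), cytosines lacking a flank at a chromosome end are
unclassifiable, and any N in the trinucleotide makes the context
undefined; all three cases land in the OTHER class, which belongs to
neither channel.

The per-site methylation level is `C/(C+T)`. Depth filters follow the
assay's three regimes: ≥1 read for within-cell summaries (single-cell
data are too sparse for more), ≥3 for bulk libraries, and ≥2 whenever
per-site levels are compared *across* individual cells. Region and
global summaries are **unweighted means of site levels**, not pooled
read counts; the depth filters operate per site, and pooling would
silently re-weight deep sites. The one deliberate exception is the
NDR/nucleosome caller, which works on pooled counts (next section),
because its χ² test is count-based. Undefined is a first-class value
throughout — a promoter with four covered sites has *no* level, not
level zero.

## 2. The windowed χ² caller

Merged (multi-cell) GCH counts are summed per site, then in sliding
windows — 120 bp at 20-bp steps for nucleosome-depleted regions (NDRs),
40 bp at 20-bp steps for nucleosome-occupied regions. Each window's
pooled (C, T) is tested against the genome-wide totals with a 2×2 χ²
(df = 1, no continuity correction; the window is subtracted from the
totals so the margins are honest). Retained windows must pass the p
cutoff (1e−15 for NDRs, 1e−3 for nucleosomes) **and** lie on the right
side of the background rate — the χ² is two-sided, so enrichment or
depletion is enforced by a direction check. Overlapping retained
windows merge into union spans; merged regions survive if they are wide
enough (≥140 bp / ≥60 bp) and cover enough GCH sites (≥5 / ≥3). NDRs
are classified promoter (contain a TSS), proximal (< 2 kb from one) or
distal (≥ 2 kb).

Numerical and tie-break choices:

* windows tile from position 0; the final partial window is tested
  as-is;
* a window with any zero margin is degenerate: statistic 0, p = 1 —
  never an error;
* only *overlapping* windows merge; book-ended ones do not (at a 20-bp
  step with 120-bp windows, consecutive significant windows always
  overlap, so this only matters for exotic parameterizations);
* merged-region boundaries are the union span, with no trimming to the
  outermost GCH site.

### Boundary precision is window-limited

A consequence worth stating plainly, because the test suite encodes it:
with deep pooled counts, an edge window containing even a *single*
truly-open GCH site among several closed ones is already significant at
p ≤ 1e−15 (eight sites at 30 reads each give a χ² near 119 against a
quiet background, versus the ≈63 the cutoff requires). Union-span
merging therefore overshoots a sharp accessibility edge by up to one
window width (~100–120 bp), and when linkers between nucleosomes are
themselves accessible, significant linker windows chain calls across a
flanking nucleosome (~180 bp). Boundary accuracy of this caller is
window-limited by construction; the acceptance suite keeps a literal
≤60 bp boundary expectation and that single expectation fails, by
design, as an honest record. Recall and specificity are unaffected: in
the deep regime the suite demonstrates ≥90% recovery of planted NDRs
≥200 bp, ≥80% recovery of nucleosome cores, and zero calls deep inside
closed chromatin.

## 3. Promoter chromatin-state heterogeneity

Each promoter is scored in each cell over an *assessment region*: the
merged-cell NDR containing the TSS when one exists, otherwise the
strand-aware window from 200 bp upstream to 100 bp downstream of the
TSS. With ≥5 covered GCH sites (at the ≥2× cross-cell depth policy),
the cell's call is open (mean > 0.5), closed (mean < 0.3) or undefined
(the gap [0.3, 0.5] — the thresholds are strict inequalities, so exact
boundary values are undefined). Fewer than five sites is not-covered,
which is *not* the same as closed; keeping the two apart is the whole
point of the assay's sensitivity argument (below).

A promoter covered in at least half of the sequenced cells gets a
population label from f = open/(open+closed) over cells with a
definitive call: homogeneously open (f > 0.7), homogeneously closed
(f < 0.3), divergent (0.3 ≤ f ≤ 0.7, bounds inclusive). Two ambiguities
had to be decided: the denominator of f (cells with a definitive call,
not all covered cells — undefined calls carry no directional evidence)
and the boundary reading (the "between 30% and 70%" band is taken
inclusive). Both are encoded in the exhaustive-enumeration test, which
checks every call-count composition up to 12 cells against an
independent oracle.

The sensitivity argument, in expectation form
(`sensitivity_expectation`): with per-cell detection probability d and
a locus truly open in a fraction f of cells, a method that can
discriminate closed from undetected calls open in d·f and closed in
d·(1−f) of cells, leaving 1−d undetermined, and the open:closed ratio
estimator recovers f/(1−f) exactly; a method that cannot discriminate
leaves 1−d·f undetermined and the ratio is lost. At d = 0.2, f = 0.5
this is 10% / 10% / 80% versus 10% / 90%. `scripts/acceptance.R`
recomputes these four numbers by simulating 100,000 cells.

## 4. De novo methylation and demethylation

A WCG site enters a stage when covered (≥1 read) in ≥3 cells of that
stage; its stage mean is the unweighted mean of per-cell levels. A de
novo site has from-stage mean < 0.25, gain ≥ 0.3 and Benjamini-Hochberg
q < 0.05; a demethylated site mirrors this (> 0.75, loss ≥ 0.3). The
per-site test feeding BH is not named in the method this implements, so
a choice was required: Fisher's exact test on stage-pooled counts,
because single-cell pooled counts are small enough that asymptotic χ²
is unreliable; χ² is available behind a flag. Stage *means* use
per-cell levels while the *test* uses pooled counts — means answer "how
methylated is this site in a typical cell", the test answers "are these
two count samples distinguishable", and the thresholds keep biological
effect size in charge either way.

CpG islands are handled analogously at region level: a CGI contributes
a per-cell level only with ≥3 detected WCG sites in that cell, is
tested only with ≥3 such cells per stage, and is called de novo on the
same <0.25 / +0.3 thresholds (no per-CGI test — the stated rule is
threshold-only).

The suite verifies false-call control on a two-identical-stages null
(2,000 sites × 20 replicates) and ≥90% recall of planted 0.1→0.6
shifts. Recall is depth-limited: at pooled depth 20 per stage the best
attainable Fisher p (~1.5e−3 at counts (2,18) vs (12,8)) is marginal
against the BH threshold under a 90%-null burden, and measured recall
is ~55%; from pooled depth ~30 the ≥90% claim holds, and the
acceptance simulation runs there.

## 5. Allele-specific analysis

Reads are partitioned by heterozygous SNPs between the parental
genomes. Bisulfite chemistry collapses C→T on plus-strand reads and
(in reference space) G→A on minus-strand reads, so C/T allele pairs
are uninformative on the plus strand and G/A pairs on the minus strand;
such SNPs are strand-restricted rather than discarded. Base matching
runs in converted space — on a plus-strand read an observed T matches a
C allele — which keeps pairs like C/A informative. Each read is
assigned by majority vote over its informative SNPs; equal non-zero
support is a conflict, no informative SNP leaves the read unassigned,
and the four classes partition the reads exactly (a conservation the
tests assert). Site-level per-allele summaries sum assigned reads'
observations per site, then average site levels per cell, element class
(intragenic / intergenic / CGI) and allele; imprinting-control-style
regions are summarized the same way per region. On error-free
simulated crosses, assignment accuracy at usable SNPs is exactly 100%
by construction, and the suite checks that a planted WCG asymmetry is
recovered while the GCH channel stays symmetric.

## 6. Ploidy, CNV, replication, sex

Every cell receives the same lambda DNA spike-in, so genomic/lambda
read ratios scale with DNA content. Ratios are normalized so the mean
of the declared reference (known-diploid) cells is exactly 2. The class
boundaries — 1N [0.75, 1.25], 2N [1.75, 2.25], 4N [3.5, 4.5],
intermediate classes between, outlier outside — are a design choice:
only the class names are given by the method being implemented, never
the cut points; ±12.5% around each integer ploidy separates Poisson
noise at realistic read counts (≥10,000 genomic, ≥100 lambda reads)
from true intermediate (S-phase) cells, and the suite demonstrates
≥95% correct classification there.

CNV analysis bins the genome into consecutive 1-Mb windows, optionally
GC-corrects counts with a lowess fit (median-anchored), divides each
bin by its across-cell median and reports log2 ratios; bins with zero
median are masked. The published HMM segmentation is deliberately
replaced by chromosome-level threshold flagging (≥80% of a
chromosome's bins beyond |log2| ≥ 0.4 with one sign): the findings this
supports are chromosome-scale gains and losses, and an HMM would add an
external dependency without changing them. Mappability correction is
omitted — synthetic genomes are uniquely mappable — but a correction
track can be applied upstream. Per-cell CV (sd/mean of linear-scale
normalized bins) quantifies measurement noise and follows the 1/√λ
Poisson scaling in tests.

Replication timing consumes externally supplied leading/lagging domain
labels on 100-kb tiles and compares a cell's mean normalized counts
between the classes with a two-tailed Welch t-test: an S-phase cell
shows leading > lagging; G1 or G2/M cells do not. Sex inference uses
the length-normalized X:autosome read ratio with the midpoint between
the expected one-X and two-X ratios as threshold (again, no published
cut point exists).

## 7. The synthetic world

`simulate_genome` plants: i.i.d. sequence at the configured GC fraction
(0.42, mouse-like); genes on a jittered grid with random strand and
2–8 kb bodies; CpG islands (±300 bp) at half the promoters; promoter
NDRs (width 200–400 bp, containing the TSS) at a configured fraction of
promoters plus distal NDRs ≥2 kb from every TSS; nucleosome cores
tiling everything else; and heterozygous SNPs at 0.002/bp (a mouse
strain-cross density) with the reference as maternal allele.

`simulate_cells` then emulates the assay: every cytosine is covered
with probability 0.10 per cell (the ~10% site recovery of sparse
single-cell libraries), covered sites draw depth 1 + Poisson(2) (a
"≥1×, mostly 1–4×" regime), GCH reads are methylated at 0.8 in
accessible chromatin and 0.05 in cores, WCG reads split evenly between
alleles and follow the configured per-stage, per-allele,
per-element-class levels, and symmetric bisulfite error (0.5% each way)
corrupts both channels. Cells also emit simplified read records (span +
SNP observations + methylation observations) for allele partitioning,
genomic read positions scaled by ploidy and per-chromosome copy
multipliers, and Poisson lambda spike-in counts. Identical seeds give
byte-identical outputs.

Three generator choices deserve their rationale:

* **Linkers are accessible at the open probability.** A GpC
  methyltransferase cannot tell a 33-bp linker from an NDR — both are
  nucleosome-free — so linkers are open. The visible consequence is
  that callers legitimately find linker accessibility, which is why
  called-NDR counts exceed planted-NDR counts in deep simulations.
* **Flanking nucleosomes abut planted NDRs flush, and inter-NDR
  segments are tiled with evenly spaced cores.** Positioned −1/+1
  nucleosomes are the norm at real regulatory sites, and flush edges
  make the planted NDR boundary the true accessibility boundary, so
  boundary error is attributable to the caller rather than the world.
* **Closed promoters carry a dense, linker-free block of three cores
  centered on the TSS.** A "closed" ground-truth label must mean the
  TSS is genuinely occupied; without this, a TSS could land in an open
  linker and the planted label would be wrong, not the classifier.

What the generator does **not** emulate: read-level sequence (FASTQ),
alignment and mapping artifacts, PCR duplicates, coverage biases along
the genome, partial/patchy enzyme treatment, cell-to-cell detection
correlation, and fractional allele imbalance from CNV. A green test
therefore establishes correctness of the *statistics on honest input*,
not robustness to upstream artifacts — those live upstream of this
package's scope (trimming, alignment and duplicate removal are consumed
as done).

## 8. Known limitations

* NDR boundary precision is window-limited (§2); downstream analyses
  that need base-pair edges should not use union spans.
* The de novo caller's sensitivity claim holds from pooled depth ~30
  (§4); below that, power — not FDR control — is the binding
  constraint.
* The differential-NDR procedure (per-region 2×2 χ², BH, |Δ| ≥ 0.2) is
  a declared stand-in: the study this implements never specifies its
  own.
* The promoter-state population labels depend on the assessment-region
  definition; in dense-NDR genomes a chained call can contain a TSS
  whose planted state is closed, which is a property of the world, not
  a classifier bug (§7).
* Single-threaded throughout; genomes are held in memory as character
  vectors, fine for the megabase-scale simulations the package targets
  but not for whole mammalian genomes in one process.
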