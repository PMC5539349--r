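# coolsuite

Analysis toolkit for joint single-cell chromatin accessibility and DNA
methylation profiling (single-cell NOMe-seq style assays). In these
assays an exogenous GpC methyltransferase (M.CviPI) methylates GpC
dinucleotides wherever chromatin is accessible before bisulfite
sequencing, so a single bisulfite library reads out two signals at
single-base resolution:

* **GCH sites** (G-C-H, H = A/C/T) — enzyme-deposited methylation,
  reporting chromatin accessibility and nucleosome positioning;
* **WCG sites** (W-C-G, W = A/T) — endogenous CpG methylation,
  uncontaminated by the enzyme.

GCG trinucleotides (ambiguous between the two channels) and CCG (a known
enzyme off-target) are excluded from all analyses. The package is aimed
at method developers and analysts who need a tested, scriptable
implementation of the downstream statistics of such assays, together
with a synthetic data generator that provides planted ground truth for
every stage.

## What it computes

| stage | function(s) | method |
|---|---|---|
| context classification | `classify_cytosines`, `annotate_calls` | per-strand trinucleotide lookup, GCG/CCG exclusion |
| quantification | `site_levels`, `global_level`, `region_level`, `tile_levels`, `meta_profile` | level = C/(C+T) per site; depth filters ≥1× (single cell), ≥3× (bulk), ≥2× (cross-cell); unweighted site means; ≥5-site region rule |
| NDR / nucleosome calling | `window_test`, `scan_and_call` | pooled C/T counts in 120-bp windows at 20-bp steps (NDR) or 40-bp windows (nucleosome), χ² vs genomic background (df = 1, no correction), direction-enforced, overlap-merged; NDR: p ≤ 1e−15, ≥140 bp, ≥5 GCH sites; nucleosome: p ≤ 1e−3, ≥60 bp, ≥3 sites |
| promoter heterogeneity | `assessment_region`, `call_cell_state`, `classify_population`, `promoter_state_matrix` | per cell: open if mean GCH > 0.5, closed if < 0.3 over ≥5 sites; per promoter: homogeneously open/closed if the open fraction f among definitive calls is > 0.7 / < 0.3, divergent between, requiring coverage in ≥ half of cells |
| de novo methylation | `call_transition_sites`, `call_de_novo_cgis` | stage means over ≥3 covered cells; de novo: mean < 0.25 then gain ≥ 0.3 with BH FDR < 0.05 (Fisher exact on pooled counts); demethylation mirrored at > 0.75 then −0.3 |
| allele partitioning | `filter_informative_snps`, `assign_reads`, `allelic_summary`, `icr_region_check` | C/T and G/A SNP pairs strand-restricted (bisulfite chemistry); majority vote per read; per-allele site-level summaries by element class |
| ploidy / CNV | `estimate_ploidy`, `bin_and_normalize`, `per_cell_cv`, `flag_chromosome_cnv`, `replication_lead_lag`, `infer_sex` | genomic/lambda spike-in ratio normalized to reference (2N) cells; 1-Mb bins, GC lowess + across-cell median normalization, per-cell CV; chromosome-scale gain/loss flags; leading/lagging t-test; X:autosome ratio |
| simulation | `simulation_config`, `simulate_genome`, `simulate_cells`, `write_simulation` | planted NDRs, nucleosome arrays, per-allele WCG levels, ~10% site recovery, bisulfite error, lambda spike-ins, heterozygous SNPs |

## Worked example

```r
library(coolsuite)

cfg   <- simulation_config(seed = 11, chrom_length = 150000L,
                           n_genes = 15L, site_detection_prob = 1.0,
                           cells_per_stage = c(ES = 12L),
                           n_allele_reads = 0L)
truth <- simulate_genome(cfg)
sim   <- simulate_cells(truth, cfg)

gch <- data.table::rbindlist(sim$reports)[
  context_class == "GCH",
  .(c_count = sum(meth), t_count = sum(unmeth)), by = .(chrom, pos)]
ndrs <- scan_and_call(gch, truth$chrom_lengths, window_params("ndr"),
                      truth$tss_table)
nrow(ndrs)                    # 156 regions called
table(ndrs$class)             # distal 87  promoter 8  proximal 61
mean(ndrs$level)              # 0.40 (background GCH level is ~0.19)

cell_sites <- lapply(sim$reports, function(r)
  site_levels(r[context_class == "GCH"], min_depth = 2))
psm <- promoter_state_matrix(truth$tss_table, cell_sites, ndrs)
table(psm$labels)
#> homogeneously_closed  homogeneously_open
#>                    7                   8
```

The 15 simulated promoters split 8 open / 7 closed, exactly matching the
planted `truth$true_promoter_state` (8 promoters were given an NDR over
the TSS at `ndr_fraction_of_promoters = 0.5`). The calls beyond the
planted NDRs are linker accessibility between nucleosome cores, which is
genuinely open chromatin in the simulated world.

The partial-detection sensitivity argument (why discriminating closed
from undetected matters at ~20% per-cell detection):

```r
sensitivity_expectation(detection = 0.2, f_open = 0.5)
#>                method open closed undetermined open_closed_ratio
#>        discriminating  0.1    0.1          0.8                 1
#>    non_discriminating  0.1    0.0          0.9                NA
```

## Command line

An installed `exec/coolsuite` script exposes the main steps:

```sh
coolsuite simulate --seed 7 --outdir sim/
coolsuite context --genome sim/genome.fa --calls sim/cells/ES_c01.tsv --out-prefix c01
coolsuite call-ndr --genome sim/genome.fa --cells sim/cells --tss sim/tss.tsv --out ndrs.bed
coolsuite classify-promoters --cells sim/cells --ndrs ndrs.bed --tss sim/tss.tsv --out states.tsv
```

## File formats

Cytosine reports are 7-column headerless TSV (chrom, 1-based position,
strand, C count, T count, context class, trinucleotide on the C's
strand), a Bismark-CX-style dialect with an explicit context column.
Intervals are BED (0-based half-open); gene annotation is a 4-column TSV
(gene, chrom, 1-based TSS, strand) or BED6; SNP tables are TSV with
maternal/paternal alleles. Internal coordinates are 0-based half-open
throughout, converted at the I/O boundary.
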