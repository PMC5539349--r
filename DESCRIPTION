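Package: coolsuite
Title: Joint Single-Cell Chromatin Accessibility and DNA Methylation Analysis
Version: 0.1.0
Authors@R:
    person("coolsuite", "developers", email = "coolsuite@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for single-cell NOMe-seq style assays in which
    an exogenous GpC methyltransferase marks accessible chromatin before
    bisulfite sequencing, so that GCH methylation reports chromatin
    accessibility and WCG methylation reports endogenous CpG methylation.
    Provides trinucleotide context classification with GCG/CCG exclusion,
    per-site and per-region methylation quantification under depth filters,
    nucleosome-depleted region and nucleosome-occupied region calling by
    windowed chi-square tests against genomic background, promoter
    open/closed/divergent heterogeneity classification across cells, stage
    transition de novo methylation and demethylation calling with FDR
    control, allele-specific partitioning of reads by heterozygous SNPs,
    lambda spike-in ploidy estimation, 1-Mb copy-number binning, replication
    lead/lag comparison and sex inference, plus a synthetic single-cell
    NOMe-seq data generator that provides planted ground truth for every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
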