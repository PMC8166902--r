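#!/usr/bin/env Rscript
# Generate the synthetic F2 bulked-segregant dataset used throughout the
# analysis: a two-chromosome toy genome carrying a reverse-strand gene
# with a recessive nonsense allele, 2000 background EMS SNPs, an F2 of
# 307 plants, and two 25-plant bulks sequenced at ~25x.

suppressPackageStartupMessages(library(mutmapr))

seed <- 2026L
out <- "results/fixture"

cfg <- simulation_config(seed = seed)
fx <- write_fixture(cfg, out)
ds <- fx$dataset

cat("Simulated F2 population:", cfg$n_f2, "plants;",
    sum(ds$population$phenotype == "mutant"), "mutant-phenotype\n")
cat("Markers:", nrow(ds$markers), "(", cfg$n_background_snps,
    "background EMS SNPs + causal", cfg$causal$chrom,
    cfg$causal$pos, paste0(cfg$causal$ref, ">", cfg$causal$alt), ")\n")
bg <- ds$truth[!ds$truth$causal, ]
cat(sprintf("EMS spectrum: %.1f%% G:C->A:T transitions\n",
            100 * mean((bg$ref == "G" & bg$alt == "A") |
                         (bg$ref == "C" & bg$alt == "T"))))
cat("Wrote:", paste(unlist(fx$paths), collapse = ", "), "\n")
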