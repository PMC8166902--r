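#!/usr/bin/env Rscript
# Map the causal locus from the simulated fixture files: read the
# two-pool VCF back, depth-filter, compute SNP indices, scan 1 Mb
# windows, draw the Monte-Carlo 95%/99% null band and call candidate
# regions. Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(mutmapr))

seed <- 2026L
fixture <- "results/fixture"
stopifnot(file.exists(file.path(fixture, "pools.vcf")))

cfg <- pipeline_config(
  vcf = file.path(fixture, "pools.vcf"),
  fasta = file.path(fixture, "reference.fa"),
  gff3 = file.path(fixture, "genes.gff3"),
  bulk_size = 25L, mean_depth = 25,
  seed = seed, out_dir = "results/mapping"
)
res <- run_pipeline(cfg)
print(res)

cat("\nCalled region(s):\n")
print(as.data.frame(res$regions))
cat("\nWrote", paste(unlist(res$paths), collapse = ", "), "\n")
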