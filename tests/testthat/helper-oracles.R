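# Independent brute-force oracles used to cross-check the implementation.

# per-window mean delta by direct recomputation
oracle_window_means <- function(rows, window_size = 1e6, step = window_size) {
  rows <- rows[order(rows$chrom, rows$pos), ]
  out <- list()
  for (chr in unique(rows$chrom)) {
    r <- rows[rows$chrom == chr, ]
    for (s in seq(1, max(r$pos), by = step)) {
      d <- r$delta[r$pos >= s & r$pos <= s + window_size - 1]
      if (length(d) == 0) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = s, end = s + window_size - 1,
        n_snps = length(d), mean_delta = mean(d)
      )
    }
  }
  do.call(rbind, out)
}

# interval-membership location oracle with CDS > UTR > intron precedence
oracle_location <- function(chrom, pos, models) {
  one <- function(cc, p) {
    best <- "intergenic"
    rank <- c(intergenic = 0, intron = 1, UTR = 2, CDS = 3)
    for (m in models) {
      if (m$chrom != cc || p < m$start || p > m$end) next
      loc <- "intron"
      if (any(p >= m$exons$start & p <= m$exons$end)) loc <- "UTR"
      if (any(p >= m$cds$start & p <= m$cds$end)) loc <- "CDS"
      if (rank[loc] > rank[best]) best <- loc
    }
    best
  }
  mapply(one, chrom, pos, USE.NAMES = FALSE)
}

# random single-exon toy gene embedded on both strands of the same locus:
# the minus-strand version is the reverse complement of the plus-strand one
make_strand_pair <- function(n_codons = 40, flank = 30) {
  codons <- mutmapr:::sense_codons()
  cds <- paste(c("ATG", sample(codons, n_codons - 2, replace = TRUE), "TAA"),
               collapse = "")
  chrom_plus <- paste0(mutmapr:::random_dna(flank), cds,
                       mutmapr:::random_dna(flank))
  n <- nchar(chrom_plus)
  chrom_minus <- mutmapr:::revcomp(chrom_plus)
  a <- flank + 1
  b <- flank + nchar(cds)
  list(
    genome_plus = Biostrings::DNAStringSet(c(chr = chrom_plus)),
    genome_minus = Biostrings::DNAStringSet(c(chr = chrom_minus)),
    model_plus = gene_model("g+", "chr", "+",
                            exons = data.frame(start = a, end = b),
                            cds = data.frame(start = a, end = b)),
    model_minus = gene_model("g-", "chr", "-",
                             exons = data.frame(start = n - b + 1, end = n - a + 1),
                             cds = data.frame(start = n - b + 1, end = n - a + 1)),
    cds_start = a, cds_end = b, n = n
  )
}

# small simulation config for fast end-to-end tests
small_sim_config <- function(seed = 1L, n_background_snps = 300L, ...) {
  simulation_config(seed = seed, n_background_snps = n_background_snps, ...)
}
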