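BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

random_dna <- function(n) {
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 61 sense codons of the standard genetic code (stops excluded), used to
# fill coding sequence without creating premature terminations.
sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Construct the causal gene locus
#'
#' Builds a three-exon, reverse-strand gene around the causal position,
#' mirroring the geometry of the mapped locus: the causal base falls in
#' the second exon (in transcription order) at the third position of a
#' Tyr codon (TAT on the coding strand), so the genomic A-to-T
#' substitution reads T-to-A on the coding strand and converts Tyr to a
#' premature stop (TAA). A single TGTCTC auxin-response cis-element is
#' embedded in the promoter with its 5'-most base 245 nt upstream of the
#' start codon.
#'
#' The locus layout on the coding strand is: 300 nt promoter, 100 nt
#' 5' UTR, then a 900 nt spliced CDS (300 codons, ATG ... TAA) split over
#' three exons of 300/450/150 coding nt separated by 200 nt introns, then
#' a 100 nt 3' UTR. On the genome the gene occupies
#' `[causal_pos - 648, causal_pos + 851]` on the minus strand with the
#' promoter immediately upstream (higher coordinates).
#'
#' @param chrom Chromosome name.
#' @param causal_pos 1-based genomic position of the causal SNP.
#' @param gene_id Feature identifier used in the GFF3 output.
#' @return List with `segment` (the genomic-strand sequence covering gene
#'   plus promoter), `segment_start` (its genomic start), `features`
#'   (tibble of gene/mRNA/exon/CDS intervals, 1-based inclusive),
#'   `promoter_txn` (promoter + 5' UTR on the coding strand, ending just
#'   before the ATG) and `causal` (ref/alt bases with codon bookkeeping).
#' @keywords internal
make_causal_gene <- function(chrom, causal_pos, gene_id = "gene08.1") {
  S <- causal_pos - 648L
  if (S - 1L < 0L) stop("causal position too close to chromosome start for the gene model")

  codons <- sense_codons()
  body <- sample(codons, 300, replace = TRUE)
  body[1] <- "ATG"
  body[184] <- "TAT"      # coding positions 550..552; 552 is the causal base
  body[300] <- "TAA"
  cds <- paste(body, collapse = "")

  promoter <- strsplit(random_dna(300), "")[[1]]
  utr5 <- strsplit(random_dna(100), "")[[1]]
  upstream <- c(promoter, utr5)
  # exactly one TGTCTC in the 400 nt upstream of ATG, 5'-most base at -245
  repeat {
    up_str <- paste(upstream, collapse = "")
    hit <- gregexpr("TGTCTC", up_str, fixed = TRUE)[[1]]
    hit <- hit[hit > 0]
    hit <- hit[hit != 156L]
    if (length(hit) == 0) break
    upstream[hit[1]] <- sample(setdiff(BASES, upstream[hit[1]]), 1)
  }
  upstream[156:161] <- c("T", "G", "T", "C", "T", "C")
  upstream_str <- paste(upstream, collapse = "")

  locus_txn <- paste0(
    upstream_str,                 # promoter (1..300) + 5' UTR (301..400)
    substr(cds, 1, 300),          # exon 1 CDS part      (401..700)
    random_dna(200),              # intron 1             (701..900)
    substr(cds, 301, 750),        # exon 2               (901..1350)
    random_dna(200),              # intron 2             (1351..1550)
    substr(cds, 751, 900),        # exon 3 CDS part      (1551..1700)
    random_dna(100)               # 3' UTR               (1701..1800)
  )
  stopifnot(nchar(locus_txn) == 1800)

  features <- tibble::tibble(
    chrom = chrom,
    type = c("gene", "mRNA", "exon", "exon", "exon", "CDS", "CDS", "CDS"),
    start = S + c(0L, 0L, 0L, 450L, 1100L, 100L, 450L, 1100L),
    end = S + c(1499L, 1499L, 249L, 899L, 1499L, 249L, 899L, 1399L),
    strand = "-",
    id = c(gene_id, paste0(gene_id, ".mRNA"), rep(NA_character_, 6)),
    parent = c(NA_character_, gene_id, rep(paste0(gene_id, ".mRNA"), 6))
  )

  list(
    segment = revcomp(locus_txn),
    segment_start = S,
    segment_end = S + 1799L,
    features = features,
    gene_id = gene_id,
    promoter_txn = upstream_str,
    causal = list(chrom = chrom, pos = causal_pos, ref = "A", alt = "T",
                  codon_index = 184L, ref_codon = "TAT", alt_codon = "TAA")
  )
}

# Simple single-exon plus-strand gene (100 nt UTRs around a 900 nt CDS),
# included on the second chromosome for strand contrast in annotation.
make_plus_gene <- function(chrom, start, gene_id = "gene02.1") {
  codons <- sense_codons()
  body <- sample(codons, 300, replace = TRUE)
  body[1] <- "ATG"
  body[300] <- "TGA"
  segment <- paste0(random_dna(100), paste(body, collapse = ""), random_dna(100))
  S <- start
  features <- tibble::tibble(
    chrom = chrom,
    type = c("gene", "mRNA", "exon", "CDS"),
    start = S + c(0L, 0L, 0L, 100L),
    end = S + c(1099L, 1099L, 1099L, 999L),
    strand = "+",
    id = c(gene_id, paste0(gene_id, ".mRNA"), NA, NA),
    parent = c(NA, gene_id, paste0(gene_id, ".mRNA"), paste0(gene_id, ".mRNA"))
  )
  list(segment = segment, segment_start = start, segment_end = start + 1099L,
       features = features, gene_id = gene_id)
}

#' Build the synthetic reference genome and its gene models
#'
#' Random chromosomes with the causal reverse-strand gene inserted at the
#' configured causal locus and, when a second chromosome is available, one
#' plus-strand gene for strand contrast.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (a [Biostrings::DNAStringSet]), `features`
#'   (tibble of all gene-model intervals), `causal_gene` and
#'   `promoter_txn` (coding-strand promoter + 5' UTR of the causal gene).
#' @keywords internal
build_reference <- function(config) {
  chroms <- config$chromosomes
  seqs <- lapply(chroms, random_dna)

  cg <- make_causal_gene(config$causal$chrom, config$causal$pos)
  stopifnot(cg$segment_end <= chroms[[config$causal$chrom]])
  substr(seqs[[config$causal$chrom]], cg$segment_start, cg$segment_end) <-
    cg$segment
  features <- cg$features

  other <- setdiff(names(chroms), config$causal$chrom)
  if (length(other) > 0 && chroms[[other[1]]] >= 51101) {
    pg <- make_plus_gene(other[1], 50001L)
    substr(seqs[[other[1]]], pg$segment_start, pg$segment_end) <- pg$segment
    features <- rbind(features, pg$features)
  }

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(chroms)
  list(genome = genome, genome_strings = seqs, features = features,
       causal_gene = cg, promoter_txn = cg$promoter_txn)
}
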