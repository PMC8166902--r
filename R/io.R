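#' Write a two-sample allele-depth VCF
#'
#' Emits a VCF 4.2 file with two samples (`WT_POOL`, `MUT_POOL`) carrying
#' per-pool allele depths (`AD`) and total depth (`DP`) for each
#' biallelic SNP record.
#'
#' @param records SNP record table (`chrom`, `pos`, `ref`, `alt`,
#'   `wt_ref`, `wt_alt`, `mut_ref`, `mut_alt`).
#' @param path Output file.
#' @param chrom_lengths Optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_two_pool_vcf <- function(records, path, chrom_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mutmapr",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "WT_POOL", "MUT_POOL", sep = "\t")
  )
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
    records$chrom, as.integer(records$pos), records$ref, records$alt,
    records$wt_ref, records$wt_alt, records$wt_ref + records$wt_alt,
    records$mut_ref, records$mut_alt, records$mut_ref + records$mut_alt
  )
  con <- file(path, "wb")  # fixed newline convention => seed-reproducible bytes
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read a two-pool allele-depth VCF into a SNP record table
#'
#' Parses a VCF with exactly the two pool samples, keeping biallelic SNPs
#' and skipping (with a message) indels and multi-allelic records.
#'
#' @param path VCF file.
#' @param wt_sample,mut_sample Sample names of the wild-type-phenotype
#'   and mutant-phenotype pools (defaults match [write_two_pool_vcf()]).
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `wt_ref`, `wt_alt`,
#'   `mut_ref`, `mut_alt`; attribute `n_skipped` counts dropped records.
#' @export
read_two_pool_vcf <- function(path, wt_sample = "WT_POOL",
                              mut_sample = "MUT_POOL") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(wt_sample, mut_sample)) {
    if (!s %in% samples) {
      stop("sample `", s, "` not found in ", path,
           " (has: ", paste(samples, collapse = ", "), ")")
    }
  }
  if (!any(grepl("\\bAD\\b", vcf@gt[, "FORMAT"]))) {
    stop("no AD (allele depth) FORMAT field in ", path)
  }
  fix <- vcfR::getFIX(vcf)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% BASES & alt %in% BASES
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped in ", path)
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  parse_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    list(ref = as.integer(vapply(parts, `[`, "", 1)),
         alt = as.integer(vapply(parts, function(p) {
           if (length(p) >= 2) p[2] else NA_character_
         }, "")))
  }
  wt <- parse_ad(ad[keep, wt_sample])
  mut <- parse_ad(ad[keep, mut_sample])
  out <- tibble::tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    wt_ref = wt$ref, wt_alt = wt$alt,
    mut_ref = mut$ref, mut_alt = mut$alt
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write gene-model features to GFF3
#'
#' @param features Tibble of intervals (`chrom`, `type`, `start`, `end`,
#'   `strand`, `id`, `parent`) as produced by the simulator.
#' @param path Output file.
#' @param chrom_lengths Optional named vector used for sequence lengths.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(features, path, chrom_lengths = NULL) {
  # CDS phase: bases to skip to reach the next codon start, accumulated
  # over the preceding CDS segments in translation order
  phase <- rep(NA_integer_, nrow(features))
  is_cds <- features$type == "CDS"
  for (parent in unique(features$parent[is_cds])) {
    sel <- which(is_cds & features$parent == parent)
    ord <- order(features$start[sel],
                 decreasing = features$strand[sel[1]] == "-")
    widths <- (features$end - features$start + 1)[sel][ord]
    phase[sel[ord]] <- (3L - cumsum(c(0L, widths[-length(widths)])) %% 3L) %% 3L
  }
  gr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start, features$end),
    strand = features$strand,
    type = features$type,
    ID = features$id,
    Parent = features$parent,
    phase = phase
  )
  if (!is.null(chrom_lengths)) {
    GenomeInfoDb::seqlengths(gr) <-
      as.integer(chrom_lengths[GenomeInfoDb::seqlevels(gr)])
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Expects the conventional gene / mRNA / exon / CDS hierarchy and
#' returns one [gene_model()] per gene. UTRs need not be annotated: they
#' are inferred downstream as exon-minus-CDS.
#'
#' @param path GFF3 file.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0) NA_character_ else p[1]
  }, "")
  genes <- which(type == "gene")
  if (length(genes) == 0) stop("no gene features in ", path)
  models <- lapply(genes, function(gi) {
    gid <- ids[gi]
    mrnas <- ids[type == "mRNA" & parents == gid]
    child <- which(parents %in% mrnas)
    iv <- function(sel) {
      tibble::tibble(start = BiocGenerics::start(gr)[sel],
                     end = BiocGenerics::end(gr)[sel])
    }
    gene_model(
      gene_id = gid,
      chrom = as.character(GenomeInfoDb::seqnames(gr))[gi],
      strand = as.character(BiocGenerics::strand(gr))[gi],
      exons = iv(child[type[child] == "exon"]),
      cds = iv(child[type[child] == "CDS"])
    )
  })
  names(models) <- ids[genes]
  models
}

#' Build gene models from a feature interval table
#'
#' Converts the simulator's in-memory feature tibble (`chrom`, `type`,
#' `start`, `end`, `strand`, `id`, `parent`, with the usual
#' gene / mRNA / exon / CDS hierarchy) into [gene_model()] objects.
#'
#' @param features Feature tibble, e.g. `simulate_dataset(...)$features`.
#' @return Named list of `gene_model` objects.
#' @export
features_to_models <- function(features) {
  genes <- features[features$type == "gene", ]
  models <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$id[i]
    mrnas <- features$id[features$type == "mRNA" &
                           !is.na(features$parent) & features$parent == gid]
    child <- features[!is.na(features$parent) & features$parent %in% mrnas, ]
    gene_model(gene_id = gid, chrom = genes$chrom[i], strand = genes$strand[i],
               exons = child[child$type == "exon", c("start", "end")],
               cds = child[child$type == "CDS", c("start", "end")])
  })
  names(models) <- genes$id
  models
}

#' Extract the promoter of a gene on its coding strand
#'
#' Returns `upstream` bases of genomic sequence ending immediately before
#' the start codon, 5'->3' on the coding strand (reverse-complemented for
#' minus-strand genes), ready for [scan_motif()] with its default anchor.
#'
#' @param model A [gene_model()].
#' @param genome Reference [Biostrings::DNAStringSet].
#' @param upstream Bases upstream of the ATG to return (default 400).
#' @return Character promoter sequence of length `upstream`.
#' @export
promoter_sequence <- function(model, genome, upstream = 400) {
  chr_len <- length(genome[[model$chrom]])
  if (model$strand == "+") {
    atg <- min(model$cds$start)
    if (atg - upstream < 1) stop("promoter extends past chromosome start")
    as.character(Biostrings::subseq(genome[[model$chrom]],
                                    atg - upstream, atg - 1))
  } else {
    atg <- max(model$cds$end)
    if (atg + upstream > chr_len) stop("promoter extends past chromosome end")
    revcomp(as.character(Biostrings::subseq(genome[[model$chrom]],
                                            atg + 1, atg + upstream)))
  }
}
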