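# three-letter amino-acid codes for reporting ("Tyr→Stop" style)
AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Stop")

#' Construct a strand-aware gene model
#'
#' @param gene_id Identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Two-column data frames (`start`, `end`; 1-based
#'   inclusive) of exon and CDS segments. CDS must lie within exons, be
#'   non-overlapping, and have total length divisible by 3.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- dplyr::arrange(tibble::as_tibble(exons), .data$start)
  cds <- dplyr::arrange(tibble::as_tibble(cds), .data$start)
  check_disjoint <- function(x, what) {
    if (any(x$end < x$start)) stop(what, " has end < start")
    if (nrow(x) > 1 && any(x$start[-1] <= x$end[-nrow(x)])) {
      stop(what, " intervals overlap")
    }
  }
  check_disjoint(exons, "exons")
  check_disjoint(cds, "CDS")
  in_exon <- vapply(seq_len(nrow(cds)), function(i) {
    any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
  }, TRUE)
  if (!all(in_exon)) stop("CDS segments must be contained in exons")
  if (sum(cds$end - cds$start + 1) %% 3 != 0) {
    stop("spliced CDS length must be divisible by 3")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds,
                 start = min(exons$start), end = max(exons$end)),
            class = "gene_model")
}

#' Classify genomic positions relative to gene models
#'
#' Assigns each position one of `"CDS"`, `"UTR"`, `"intron"` or
#' `"intergenic"`, with precedence CDS > UTR > intron > intergenic when
#' features overlap. UTR is exon-minus-CDS. Positions on chromosomes
#' with no gene model are intergenic (with a warning).
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param models List of [gene_model()] objects.
#' @return Character vector of location classes; attribute `gene_id`
#'   carries the matched gene (highest-precedence hit) or `NA`.
#' @export
classify_location <- function(chrom, pos, models) {
  stopifnot(length(chrom) == length(pos))
  if (length(models) == 0 || length(pos) == 0) {
    out <- rep("intergenic", length(pos))
    attr(out, "gene_id") <- rep(NA_character_, length(pos))
    return(out)
  }
  model_chroms <- vapply(models, `[[`, "", "chrom")
  missing_chr <- setdiff(unique(chrom), unique(model_chroms))
  if (length(missing_chr) > 0) {
    warning("no gene models on: ", paste(missing_chr, collapse = ", "),
            "; positions there classified intergenic")
  }
  gr_of <- function(get) {
    pieces <- lapply(models, get)
    GenomicRanges::GRanges(
      rep(model_chroms, vapply(pieces, nrow, 0L)),
      IRanges::IRanges(unlist(lapply(pieces, `[[`, "start")),
                       unlist(lapply(pieces, `[[`, "end"))),
      gene_id = rep(vapply(models, `[[`, "", "gene_id"),
                    vapply(pieces, nrow, 0L))
    )
  }
  cds_gr <- gr_of(function(m) m$cds)
  exon_gr <- gr_of(function(m) m$exons)
  gene_gr <- gr_of(function(m) tibble::tibble(start = m$start, end = m$end))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))

  out <- rep("intergenic", length(pos))
  gene_id <- rep(NA_character_, length(pos))
  assign_hits <- function(gr, label, mask) {
    # seqlevels legitimately differ when a chromosome carries no genes
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, gr))
    first <- !duplicated(S4Vectors::queryHits(hits))
    qh <- S4Vectors::queryHits(hits)[first]
    sh <- S4Vectors::subjectHits(hits)[first]
    use <- mask[qh]
    out[qh[use]] <<- label
    gene_id[qh[use]] <<- gr$gene_id[sh[use]]
    mask[qh] <- FALSE
    mask
  }
  todo <- rep(TRUE, length(pos))
  todo <- assign_hits(cds_gr, "CDS", todo)
  todo <- assign_hits(exon_gr, "UTR", todo)
  todo <- assign_hits(gene_gr, "intron", todo)
  attr(out, "gene_id") <- gene_id
  out
}

# genomic coordinates of the spliced CDS in coding (5'->3') order
cds_coding_coords <- function(model) {
  coords <- unlist(lapply(seq_len(nrow(model$cds)), function(i) {
    seq(model$cds$start[i], model$cds$end[i])
  }))
  if (model$strand == "-") rev(coords) else coords
}

# spliced CDS sequence on the coding strand
splice_cds <- function(model, genome) {
  chr <- genome[[model$chrom]]
  pieces <- vapply(seq_len(nrow(model$cds)), function(i) {
    as.character(Biostrings::subseq(chr, model$cds$start[i], model$cds$end[i]))
  }, "")
  genomic <- paste(pieces, collapse = "")
  if (model$strand == "-") revcomp(genomic) else genomic
}

#' Predict the coding consequence of a SNP in a gene model
#'
#' For minus-strand genes the genomic alleles are reverse-complemented
#' onto the coding strand before codon lookup; the affected codon is
#' found from spliced CDS coordinates and translated with the standard
#' genetic code.
#'
#' @param chrom,pos,ref,alt The SNP (genomic strand, 1-based).
#' @param model A [gene_model()].
#' @param genome Reference as a [Biostrings::DNAStringSet] named by
#'   chromosome.
#' @return Object of class `variant_effect`: list with `location`,
#'   `gene_id`, `strand`, and — for CDS hits — `codon_index`,
#'   `ref_codon`, `alt_codon`, `coding_ref`, `coding_alt`, `ref_aa`,
#'   `alt_aa`, `aa_change` (e.g. `"Tyr→Stop"`) and `effect` in
#'   `{"synonymous", "missense", "nonsense"}`; non-CDS positions get
#'   `effect = "noncoding"`.
#' @export
predict_effect <- function(chrom, pos, ref, alt, model, genome) {
  stopifnot(inherits(model, "gene_model"))
  if (ref == alt) stop("ref and alt alleles must differ")
  genome_base <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
  if (genome_base != ref) {
    stop("reference mismatch at ", chrom, ":", pos, " (genome has ",
         genome_base, ", record says ", ref, ")")
  }
  in_cds <- chrom == model$chrom &
    any(pos >= model$cds$start & pos <= model$cds$end)
  if (!in_cds) {
    loc <- classify_location(chrom, pos, list(model))
    return(structure(list(location = as.character(loc),
                          gene_id = attr(loc, "gene_id")[1],
                          strand = model$strand, effect = "noncoding"),
                     class = "variant_effect"))
  }

  coords <- cds_coding_coords(model)
  cds_seq <- splice_cds(model, genome)
  coding_pos <- match(pos, coords)
  coding_ref <- if (model$strand == "-") COMPLEMENT[[ref]] else ref
  coding_alt <- if (model$strand == "-") COMPLEMENT[[alt]] else alt
  codon_index <- (coding_pos - 1) %/% 3 + 1
  within <- (coding_pos - 1) %% 3 + 1
  ref_codon <- substr(cds_seq, 3 * codon_index - 2, 3 * codon_index)
  stopifnot(substr(ref_codon, within, within) == coding_ref)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- coding_alt
  ref_aa <- Biostrings::GENETIC_CODE[[ref_codon]]
  alt_aa <- Biostrings::GENETIC_CODE[[alt_codon]]
  effect <- if (ref_aa == alt_aa) {
    "synonymous"
  } else if (alt_aa == "*") {
    "nonsense"
  } else {
    "missense"
  }
  structure(
    list(location = "CDS", gene_id = model$gene_id, strand = model$strand,
         codon_index = codon_index, ref_codon = ref_codon,
         alt_codon = alt_codon, coding_ref = coding_ref,
         coding_alt = coding_alt, ref_aa = ref_aa, alt_aa = alt_aa,
         aa_change = paste0(AA_THREE[[ref_aa]], "→", AA_THREE[[alt_aa]]),
         effect = effect),
    class = "variant_effect"
  )
}

#' @export
print.variant_effect <- function(x, ...) {
  if (x$effect == "noncoding") {
    cat("Variant effect: noncoding (", x$location, ")\n", sep = "")
  } else {
    cat(sprintf("Variant effect: %s — codon %d %s>%s (%s), strand %s\n",
                x$effect, x$codon_index, x$ref_codon, x$alt_codon,
                x$aa_change, x$strand))
  }
  invisible(x)
}

#' Filter SNPs to causal candidates
#'
#' Applies the MutMap candidate rules: the site lies in a called
#' candidate region; the mutant-pool SNP index passes the index rule
#' (exactly 1 by default — the mutant bulk is fixed for a recessive
#' causal allele — with a tolerance knob for sequencing error at finite
#' depth); the alt allele differs from the reference base; and, for the
#' final call, the site falls in a coding region.
#'
#' @param rows SNP-index table with `chrom`, `pos`, `ref`, `alt`,
#'   `mut_index`, `delta` and a `location` column (from
#'   [classify_location()]) when `cds_only = TRUE`.
#' @param regions Candidate regions from [call_regions()], or `NULL` to
#'   skip the region rule.
#' @param index_threshold Required mutant-pool index (default 1.0).
#' @param index_tolerance Allowance below the threshold (default 0):
#'   rows pass when `mut_index >= index_threshold - index_tolerance`.
#' @param require_alt_ne_ref Require `alt != ref` (default `TRUE`).
#' @param cds_only Keep only `location == "CDS"` rows (default `TRUE`).
#' @return Tibble of surviving candidates ordered by `delta` descending.
#'   The full audit trail (all rows with logical columns `pass_region`,
#'   `pass_index`, `pass_alt`, `pass_location`, `candidate`) is attached
#'   as attribute `"audit"`.
#' @export
filter_candidates <- function(rows, regions = NULL, index_threshold = 1.0,
                              index_tolerance = 0,
                              require_alt_ne_ref = TRUE, cds_only = TRUE) {
  audit <- tibble::as_tibble(rows)
  if (is.null(regions)) {
    audit$pass_region <- TRUE
  } else {
    audit$pass_region <- vapply(seq_len(nrow(audit)), function(i) {
      any(regions$chrom == audit$chrom[i] &
            audit$pos[i] >= regions$start & audit$pos[i] <= regions$end)
    }, TRUE)
  }
  audit$pass_index <- !is.na(audit$mut_index) &
    audit$mut_index >= index_threshold - index_tolerance
  audit$pass_alt <- if (require_alt_ne_ref) audit$ref != audit$alt else TRUE
  audit$pass_location <- if (cds_only) {
    if (!"location" %in% names(audit)) {
      stop("`rows` needs a `location` column when `cds_only = TRUE`")
    }
    audit$location == "CDS"
  } else {
    TRUE
  }
  audit$candidate <- audit$pass_region & audit$pass_index &
    audit$pass_alt & audit$pass_location
  out <- dplyr::arrange(audit[audit$candidate, , drop = FALSE],
                        dplyr::desc(.data$delta))
  attr(out, "audit") <- audit
  out
}

#' Locate a cis-element motif in a promoter
#'
#' Exact-match scan for a short motif (default the TGTCTC auxin-response
#' element) on the coding strand of a promoter sequence, reporting
#' positions relative to the start codon: the A of the ATG is +1 and the
#' base immediately upstream is -1 (there is no position 0); a motif
#' whose 5'-most base is 245 nt upstream is reported at -245.
#'
#' @param promoter Promoter sequence, 5'->3' on the coding strand.
#' @param motif Motif to find (default `"TGTCTC"`).
#' @param anchor 1-based position of the start codon's A within
#'   `promoter`; default `nchar(promoter) + 1` (sequence ends just
#'   before the ATG).
#' @param search_revcomp Also search the reverse complement of the motif
#'   (default `FALSE`); such hits are reported with `strand = "-"`.
#' @return Tibble with `start` (position in `promoter`), `rel_start`
#'   (ATG-relative), `strand` and `motif`, in ascending `start` order.
#' @export
scan_motif <- function(promoter, motif = "TGTCTC", anchor = NULL,
                       search_revcomp = FALSE) {
  if (!nzchar(motif)) stop("`motif` must be non-empty")
  if (is.null(anchor)) anchor <- nchar(promoter) + 1L
  if (anchor < 1 || anchor > nchar(promoter) + 1) {
    stop("`anchor` must lie inside the sequence or just past its end")
  }
  find <- function(m, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(m),
                                     Biostrings::DNAString(promoter))
    s <- BiocGenerics::start(hits)
    if (length(s) == 0) return(NULL)
    tibble::tibble(start = s,
                   rel_start = ifelse(s < anchor, s - anchor, s - anchor + 1L),
                   strand = strand, motif = motif)
  }
  out <- find(motif, "+")
  if (search_revcomp) out <- dplyr::bind_rows(out, find(revcomp(motif), "-"))
  if (is.null(out)) {
    return(tibble::tibble(start = integer(), rel_start = integer(),
                          strand = character(), motif = character()))
  }
  dplyr::arrange(out, .data$start)
}

#' Format candidates as a publication-style report table
#'
#' Renders the surviving candidates with the conventional column layout
#' of a MutMap candidate table: Chr, Pos, Ref, Allele, Wild type index,
#' Mutant index, Delta SNP index, Location, Gene, Direction, Amino acid
#' change. Locations are printed as Exon (CDS), UTR, Intron or
#' Intergene; strand as Forward/Reverse; missing fields as "--".
#'
#' @param candidates Candidate tibble from [filter_candidates()], with
#'   the effect columns added by the pipeline (`gene_id`, `strand`,
#'   `aa_change`).
#' @return Tibble in report layout.
#' @export
candidate_report <- function(candidates) {
  loc_label <- c(CDS = "Exon", UTR = "UTR", intron = "Intron",
                 intergenic = "Intergene")
  dir_label <- c(`+` = "Forward", `-` = "Reverse")
  dash <- function(x) ifelse(is.na(x), "--", x)
  tibble::tibble(
    Chr = candidates$chrom,
    Pos = candidates$pos,
    Ref = candidates$ref,
    Allele = candidates$alt,
    `Wild type index` = round(candidates$wt_index, 2),
    `Mutant index` = round(candidates$mut_index, 2),
    `Delta SNP index` = round(candidates$delta, 2),
    Location = unname(loc_label[candidates$location]),
    Gene = dash(candidates$gene_id),
    Direction = dash(unname(dir_label[candidates$strand])),
    `Amino acid change` = dash(
      if ("aa_change" %in% names(candidates)) candidates$aa_change
      else rep(NA_character_, nrow(candidates)))
  )
}
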