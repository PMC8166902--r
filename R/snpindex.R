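#' Per-pool SNP index
#'
#' The SNP index of a pool at a site is the fraction of reads carrying the
#' alternate (mutant) allele. In a MutMap design the mutant-phenotype bulk
#' is expected to reach an index of 1 at the causal site, while the
#' wild-type-phenotype bulk tends to 1/3 there and both pools hover around
#' 1/2 at unlinked sites.
#'
#' @param ref_reads,alt_reads Non-negative read counts (vectorised).
#' @return `alt_reads / (ref_reads + alt_reads)`; `NA` where total depth
#'   is zero (such sites are removed upstream by [depth_filter()]).
#' @export
snp_index <- function(ref_reads, alt_reads) {
  if (any(ref_reads < 0, na.rm = TRUE) || any(alt_reads < 0, na.rm = TRUE)) {
    stop("read counts must be >= 0")
  }
  depth <- ref_reads + alt_reads
  ifelse(depth > 0, alt_reads / depth, NA_real_)
}

#' Delta SNP index
#'
#' Difference between the mutant-pool and wild-type-pool SNP indices.
#' Positive values indicate enrichment of the mutant allele in the
#' mutant-phenotype bulk; a recessive causal locus produces a positive
#' peak (mutant index 1, wild-type index about 1/3, delta about 2/3).
#'
#' @param wt_index,mut_index Per-pool SNP indices in \[0, 1\] (vectorised).
#' @return `mut_index - wt_index`, in \[-1, 1\].
#' @export
delta_snp_index <- function(wt_index, mut_index) {
  stopifnot(all(wt_index >= 0 & wt_index <= 1, na.rm = TRUE),
            all(mut_index >= 0 & mut_index <= 1, na.rm = TRUE))
  mut_index - wt_index
}

#' Compute SNP indices and the delta SNP index for a two-pool SNP table
#'
#' @param records Tibble of biallelic SNP records with columns `chrom`,
#'   `pos`, `ref`, `alt`, `wt_ref`, `wt_alt`, `mut_ref`, `mut_alt`
#'   (per-pool ref/alt allele depths), as produced by
#'   [sequence_bulks()] or [read_two_pool_vcf()].
#' @return The input with columns `wt_index`, `mut_index` and `delta`
#'   appended.
#' @export
compute_snp_indices <- function(records) {
  req <- c("chrom", "pos", "ref", "alt", "wt_ref", "wt_alt", "mut_ref", "mut_alt")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("records table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  records$wt_index <- snp_index(records$wt_ref, records$wt_alt)
  records$mut_index <- snp_index(records$mut_ref, records$mut_alt)
  records$delta <- records$mut_index - records$wt_index
  records
}

#' Filter SNP records on per-pool depth
#'
#' Removes sites where either pool has read depth below `min_depth`,
#' guarding the index against small-count noise (and against the undefined
#' index at depth zero).
#'
#' @param records SNP record table (see [compute_snp_indices()]).
#' @param min_depth Minimum depth required in each pool (default 7).
#' @return The retained rows; the number removed is reported via `message()`
#'   and attached as attribute `n_removed`.
#' @export
depth_filter <- function(records, min_depth = 7) {
  if (length(min_depth) != 1 || !is.finite(min_depth) || min_depth < 0) {
    stop("`min_depth` must be a single number >= 0")
  }
  keep <- (records$wt_ref + records$wt_alt) >= min_depth &
    (records$mut_ref + records$mut_alt) >= min_depth
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(n_removed, " of ", nrow(records),
            " sites removed by depth filter (min depth ", min_depth,
            " per pool)")
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- n_removed
  out
}
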