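toy_plus_model <- function() {
  # exon1 1..60 (UTR 1..20, CDS 21..60), intron 61..100, exon2 101..160
  # (CDS 101..138, UTR 139..160)
  gene_model("toy", "chrT", "+",
             exons = data.frame(start = c(1, 101), end = c(60, 160)),
             cds = data.frame(start = c(21, 101), end = c(60, 138)))
}

test_that("gene model invariants are enforced", {
  expect_error(gene_model("g", "c", "+",
                          exons = data.frame(start = 1, end = 50),
                          cds = data.frame(start = 40, end = 60)),
               "contained")
  expect_error(gene_model("g", "c", "+",
                          exons = data.frame(start = 1, end = 50),
                          cds = data.frame(start = 1, end = 50)),
               "divisible")
  expect_error(gene_model("g", "c", "+",
                          exons = data.frame(start = c(1, 30), end = c(40, 60)),
                          cds = data.frame(start = 1, end = 30)),
               "overlap")
})

test_that("positions are classified with CDS > UTR > intron precedence", {
  m <- toy_plus_model()
  got <- classify_location(rep("chrT", 5), c(30, 10, 80, 150, 500), list(m))
  expect_equal(as.character(got),
               c("CDS", "UTR", "intron", "UTR", "intergenic"))
  expect_equal(attr(got, "gene_id"), c("toy", "toy", "toy", "toy", NA))
  expect_warning(classify_location("chrZ", 5, list(m)), "chrZ")
})

test_that("classification agrees with the interval-membership oracle", {
  set.seed(17)
  models <- list(
    toy_plus_model(),
    gene_model("g2", "chrT", "-",
               exons = data.frame(start = c(300, 420), end = c(380, 520)),
               cds = data.frame(start = c(320, 420), end = c(380, 478))),
    gene_model("g3", "chrU", "+",
               exons = data.frame(start = 50, end = 250),
               cds = data.frame(start = 100, end = 201))
  )
  chrom <- sample(c("chrT", "chrU"), 500, replace = TRUE)
  pos <- sample.int(600, 500, replace = TRUE)
  expect_equal(as.character(classify_location(chrom, pos, models)),
               oracle_location(chrom, pos, models))
})

test_that("the causal substitution is a Tyr-to-stop nonsense on the minus strand", {
  ds <- simulate_dataset(small_sim_config(seed = 6))
  causal <- ds$truth[ds$truth$causal, ]
  model <- features_to_models(ds$features)[["gene08.1"]]
  eff <- predict_effect(causal$chrom, causal$pos, causal$ref, causal$alt,
                        model, ds$genome)
  expect_equal(causal$ref, "A")
  expect_equal(causal$alt, "T")
  expect_equal(eff$strand, "-")
  expect_equal(eff$coding_ref, "T")   # genomic A -> coding T on minus strand
  expect_equal(eff$coding_alt, "A")
  expect_equal(eff$ref_codon, "TAT")
  expect_equal(eff$alt_codon, "TAA")
  expect_equal(eff$aa_change, "Tyr→Stop")
  expect_equal(eff$effect, "nonsense")
})

test_that("plus-strand synonymous changes are recognised", {
  # GAT -> GAC at the codon's third base: Asp -> Asp
  chrom <- paste0("ATG", "GAT", "TAA")
  genome <- Biostrings::DNAStringSet(c(chrS = chrom))
  m <- gene_model("gs", "chrS", "+",
                  exons = data.frame(start = 1, end = 9),
                  cds = data.frame(start = 1, end = 9))
  eff <- predict_effect("chrS", 6, "T", "C", m, genome)
  expect_equal(eff$ref_codon, "GAT")
  expect_equal(eff$alt_codon, "GAC")
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$aa_change, "Asp→Asp")
})

test_that("effects are invariant under strand involution", {
  set.seed(23)
  for (rep in 1:20) {
    pair <- make_strand_pair()
    p <- sample(pair$cds_start:pair$cds_end, 1)
    ref <- as.character(Biostrings::subseq(pair$genome_plus[["chr"]], p, p))
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    e_plus <- predict_effect("chr", p, ref, alt, pair$model_plus,
                             pair$genome_plus)
    p2 <- pair$n - p + 1
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    e_minus <- predict_effect("chr", p2, comp[[ref]], comp[[alt]],
                              pair$model_minus, pair$genome_minus)
    expect_equal(e_minus$ref_codon, e_plus$ref_codon)
    expect_equal(e_minus$alt_codon, e_plus$alt_codon)
    expect_equal(e_minus$effect, e_plus$effect)
    expect_equal(e_minus$aa_change, e_plus$aa_change)
    expect_equal(e_minus$codon_index, e_plus$codon_index)
  }
})

test_that("effect prediction guards its inputs", {
  pair <- make_strand_pair()
  p <- pair$cds_start
  ref <- as.character(Biostrings::subseq(pair$genome_plus[["chr"]], p, p))
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(predict_effect("chr", p, wrong, ref, pair$model_plus,
                              pair$genome_plus), "mismatch")
  # outside the CDS -> noncoding
  out_pos <- pair$cds_end + 5
  out_ref <- as.character(Biostrings::subseq(pair$genome_plus[["chr"]],
                                             out_pos, out_pos))
  out_alt <- setdiff(c("A", "C", "G", "T"), out_ref)[1]
  eff <- predict_effect("chr", out_pos, out_ref, out_alt, pair$model_plus,
                        pair$genome_plus)
  expect_equal(eff$effect, "noncoding")
})

test_that("candidate filtering reproduces the two-row candidate table", {
  rows <- tibble::tibble(
    chrom = "chr08", pos = c(16268L, 394612L),
    ref = c("A", "G"), alt = c("T", "A"),
    wt_index = c(0.27, 0.42), mut_index = c(1, 1),
    delta = c(0.73, 0.58),
    location = c("CDS", "intergenic")
  )
  cand <- filter_candidates(rows, regions = NULL,
                            index_threshold = 1, index_tolerance = 0)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pos, 16268L)
  audit <- attr(cand, "audit")
  expect_true(all(c("pass_region", "pass_index", "pass_alt",
                    "pass_location", "candidate") %in% names(audit)))
  expect_equal(audit$candidate, c(TRUE, FALSE))
  expect_false(audit$pass_location[2])

  # no index rule, no location rule: everything in range survives
  all_rows <- filter_candidates(rows, regions = NULL, index_threshold = 0,
                                cds_only = FALSE)
  expect_equal(nrow(all_rows), 2L)
  expect_equal(all_rows$delta, c(0.73, 0.58))  # delta-descending order

  # rule boundary
  rows$mut_index <- c(0.96, 1)
  expect_equal(nrow(filter_candidates(rows, NULL, index_threshold = 1,
                                      cds_only = TRUE)), 0L)
  expect_equal(nrow(filter_candidates(rows, NULL, index_threshold = 0.95,
                                      cds_only = TRUE)), 1L)

  # region rule
  regions <- tibble::tibble(chrom = "chr08", start = 1, end = 1.01e6)
  rows$mut_index <- c(1, 1)
  in_region <- filter_candidates(rows, regions, cds_only = FALSE)
  expect_equal(nrow(in_region), 2L)
  regions$end <- 1e5
  expect_equal(nrow(filter_candidates(rows, regions, cds_only = FALSE)), 1L)
})

test_that("promoter motif scan reports ATG-relative coordinates", {
  set.seed(29)
  # 300 nt promoter ending just before the ATG; motif 5' base at -245
  prom <- strsplit(mutmapr:::random_dna(300), "")[[1]]
  repeat {
    s <- paste(prom, collapse = "")
    extra <- gregexpr("TGTCTC", s, fixed = TRUE)[[1]]
    extra <- extra[extra > 0 & extra != 56]
    if (length(extra) == 0) break
    prom[extra[1]] <- sample(setdiff(c("A", "C", "G", "T"), prom[extra[1]]), 1)
  }
  prom[56:61] <- c("T", "G", "T", "C", "T", "C")
  hits <- scan_motif(paste(prom, collapse = ""))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$rel_start, -245L)

  expect_equal(nrow(scan_motif("AAAAAAAA")), 0L)
  two <- scan_motif("TGTCTCAATGTCTCAA")
  expect_equal(two$start, c(1L, 9L))
  expect_error(scan_motif("ACGT", motif = ""), "non-empty")

  # reverse-complement search picks up GAGACA on the given strand
  rc <- scan_motif("AAGAGACAAA", search_revcomp = TRUE)
  expect_equal(rc$strand, "-")
})

test_that("the simulated promoter carries one element 245 nt upstream of ATG", {
  ds <- simulate_dataset(small_sim_config(seed = 12))
  model <- features_to_models(ds$features)[["gene08.1"]]
  prom <- promoter_sequence(model, ds$genome, upstream = 400)
  expect_identical(prom, ds$promoter_txn)
  hits <- scan_motif(prom)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$rel_start, -245L)
})
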