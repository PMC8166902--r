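#' Configuration of the synthetic F2 bulked-segregant experiment
#'
#' Parameterises the whole generator: an EMS mutant carrying a recessive
#' causal SNP plus a genome-wide load of background EMS mutations is
#' crossed to its (otherwise isogenic) wild-type parent; the F2 segregates
#' 3:1; two phenotype bulks are pooled and sequenced at ~25x each.
#'
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @param chromosomes Named numeric vector of chromosome lengths in bp
#'   (default: two 2 Mb toy chromosomes).
#' @param recombination_rate Recombination rate in cM per Mb (default 4).
#' @param n_f2 Number of F2 individuals (default 307).
#' @param bulk_size Plants pooled per phenotype bulk (default 25).
#' @param mean_depth Expected read depth per site per pool (default 25).
#' @param seq_error Per-read miscall probability (default 0.01).
#' @param causal List with `chrom`, `pos`, `ref`, `alt` of the causal SNP.
#'   The default (chr1:16268 A>T) sits in the second exon of a
#'   reverse-strand gene where it creates a Tyr-to-stop nonsense change.
#' @param n_background_snps Number of background EMS SNPs (default 2000).
#' @param ems_transition_fraction Fraction of background SNPs that are
#'   G:C->A:T transitions, the canonical EMS signature (default 0.98).
#' @param phenotype_model Only `"recessive"` is supported: mutant
#'   phenotype iff homozygous for the causal alt allele.
#' @param phenotyping_error Probability of misclassifying a phenotype
#'   (default 0; the study's classes were clean).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chromosomes = c(chr1 = 2e6, chr2 = 2e6),
                              recombination_rate = 4,
                              n_f2 = 307L,
                              bulk_size = 25L,
                              mean_depth = 25,
                              seq_error = 0.01,
                              causal = list(chrom = "chr1", pos = 16268L,
                                            ref = "A", alt = "T"),
                              n_background_snps = 2000L,
                              ems_transition_fraction = 0.98,
                              phenotype_model = "recessive",
                              phenotyping_error = 0) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes)))) {
    stop("`chromosomes` must be a named vector of lengths")
  }
  if (any(chromosomes <= 0)) stop("chromosome lengths must be positive")
  if (!causal$chrom %in% names(chromosomes)) {
    stop("causal chromosome not among `chromosomes`")
  }
  if (causal$pos < 1 || causal$pos > chromosomes[[causal$chrom]]) {
    stop("causal position outside its chromosome")
  }
  if (seq_error < 0 || seq_error >= 0.5) stop("`seq_error` must be in [0, 0.5)")
  if (ems_transition_fraction < 0 || ems_transition_fraction > 1) {
    stop("`ems_transition_fraction` must be in [0, 1]")
  }
  if (n_f2 < 1 || bulk_size < 1) stop("`n_f2` and `bulk_size` must be >= 1")
  phenotype_model <- match.arg(phenotype_model, "recessive")
  structure(
    list(seed = as.integer(seed), chromosomes = chromosomes,
         recombination_rate = recombination_rate, n_f2 = as.integer(n_f2),
         bulk_size = as.integer(bulk_size), mean_depth = mean_depth,
         seq_error = seq_error, causal = causal,
         n_background_snps = as.integer(n_background_snps),
         ems_transition_fraction = ems_transition_fraction,
         phenotype_model = phenotype_model,
         phenotyping_error = phenotyping_error),
    class = "simulation_config"
  )
}

# One meiosis per gamete on one chromosome: crossover count ~
# Poisson(genetic length in Morgans), uniform crossover positions, no
# interference (Haldane model). Returns a gametes x markers 0/1 matrix of
# mutant-strand alleles.
sim_gametes_chrom <- function(n_gam, marker_morgans, chrom_morgans) {
  m <- length(marker_morgans)
  out <- matrix(0L, n_gam, m)
  start <- sample(0:1, n_gam, replace = TRUE)
  nx <- stats::rpois(n_gam, chrom_morgans)
  none <- nx == 0L
  if (any(none)) out[none, ] <- matrix(start[none], sum(none), m)
  for (i in which(nx > 0L)) {
    xpos <- sort(stats::runif(nx[i], 0, chrom_morgans))
    out[i, ] <- (start[i] + findInterval(marker_morgans, xpos)) %% 2L
  }
  out
}

#' Simulate an F2 population by meiosis from a uniformly heterozygous F1
#'
#' Every marker (the mutant parent's EMS mutations, including the causal
#' SNP) is heterozygous in the F1; each F2 individual receives two
#' independent gametes produced with Haldane recombination (Poisson
#' crossover counts, uniform positions, no interference). Phenotypes
#' follow the recessive rule: mutant iff causal dosage 2.
#'
#' @param config A [simulation_config()].
#' @param markers Optional tibble with columns `chrom`, `pos` listing the
#'   segregating markers; must include the causal position. Default
#'   `NULL` draws `n_background_snps` uniform positions plus the causal
#'   site (base identities are irrelevant to segregation).
#' @return List of class `f2_population` with `genotypes` (n_f2 x markers
#'   integer matrix of alt-allele dosage 0/1/2), `phenotype`
#'   (`"normal"`/`"mutant"`), `markers` and `causal_index` (column of the
#'   causal marker).
#' @export
simulate_f2_population <- function(config, markers = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(markers)) {
    markers <- draw_marker_positions(config)
  }
  if (!all(c("chrom", "pos") %in% names(markers))) {
    stop("`markers` needs columns chrom, pos")
  }
  markers <- dplyr::arrange(markers, .data$chrom, .data$pos)
  causal_index <- which(markers$chrom == config$causal$chrom &
                          markers$pos == config$causal$pos)
  if (length(causal_index) != 1) {
    stop("markers must contain the causal position exactly once")
  }

  n <- config$n_f2
  m <- nrow(markers)
  g1 <- matrix(0L, n, m)
  g2 <- matrix(0L, n, m)
  morgans_per_bp <- config$recombination_rate / 100 / 1e6
  for (chr in unique(markers$chrom)) {
    cols <- which(markers$chrom == chr)
    chrom_m <- config$chromosomes[[chr]] * morgans_per_bp
    mk_m <- markers$pos[cols] * morgans_per_bp
    g1[, cols] <- sim_gametes_chrom(n, mk_m, chrom_m)
    g2[, cols] <- sim_gametes_chrom(n, mk_m, chrom_m)
  }
  genotypes <- g1 + g2

  phenotype <- ifelse(genotypes[, causal_index] == 2L, "mutant", "normal")
  if (config$phenotyping_error > 0) {
    flip <- stats::runif(n) < config$phenotyping_error
    phenotype[flip] <- ifelse(phenotype[flip] == "mutant", "normal", "mutant")
  }

  structure(list(genotypes = genotypes, phenotype = phenotype,
                 markers = markers, causal_index = causal_index),
            class = "f2_population")
}

# Uniform background marker positions (no allele assignment); used when
# simulate_f2_population() is run without a genome.
draw_marker_positions <- function(config) {
  lens <- config$chromosomes
  chr <- sample(names(lens), config$n_background_snps, replace = TRUE,
                prob = lens / sum(lens))
  pos <- vapply(chr, function(cc) sample.int(lens[[cc]], 1), 1L)
  mk <- tibble::tibble(chrom = c(chr, config$causal$chrom),
                       pos = c(pos, as.integer(config$causal$pos)))
  mk <- dplyr::distinct(mk)
  dplyr::arrange(mk, .data$chrom, .data$pos)
}

#' Select the two phenotype bulks
#'
#' Uniform random subsets without replacement: `bulk_size` plants with the
#' normal phenotype into the wild-type bulk, `bulk_size` with the mutant
#' phenotype into the mutant bulk.
#'
#' @param population An `f2_population`.
#' @param bulk_size Plants per bulk.
#' @return List with integer index vectors `wt` and `mut`.
#' @export
select_bulks <- function(population, bulk_size) {
  stopifnot(inherits(population, "f2_population"))
  normal <- which(population$phenotype == "normal")
  mutant <- which(population$phenotype == "mutant")
  if (length(normal) < bulk_size) {
    stop("not enough normal-phenotype plants for the wild-type bulk (",
         length(normal), " < ", bulk_size, ")")
  }
  if (length(mutant) < bulk_size) {
    stop("not enough mutant-phenotype plants for the mutant bulk (",
         length(mutant), " < ", bulk_size, ")")
  }
  list(wt = sample(normal, bulk_size), mut = sample(mutant, bulk_size))
}

#' Sequence the two bulks to pooled allele counts
#'
#' Per site and pool: read depth ~ Poisson(`mean_depth`); alternate-read
#' count ~ Binomial(depth, f(1-e) + (1-f)e) where f is the bulk's true
#' alt-allele frequency and e the per-read miscall probability.
#'
#' @param population An `f2_population`.
#' @param bulks Output of [select_bulks()].
#' @param config The [simulation_config()].
#' @return List with `records` (tibble: chrom, pos, ref, alt, wt_ref,
#'   wt_alt, mut_ref, mut_alt; ref/alt are `NA` unless the markers carry
#'   them) and `truth` (tibble: chrom, pos, true per-bulk alt frequencies
#'   `wt_freq`, `mut_freq`, and logical `causal`).
#' @export
sequence_bulks <- function(population, bulks, config) {
  stopifnot(inherits(population, "f2_population"))
  g <- population$genotypes
  n2 <- 2 * length(bulks$wt)
  wt_freq <- colSums(g[bulks$wt, , drop = FALSE]) / n2
  mut_freq <- colSums(g[bulks$mut, , drop = FALSE]) / (2 * length(bulks$mut))

  m <- ncol(g)
  e <- config$seq_error
  draw_pool <- function(f) {
    depth <- stats::rpois(m, config$mean_depth)
    p <- f * (1 - e) + (1 - f) * e
    alt <- stats::rbinom(m, depth, p)
    list(ref = depth - alt, alt = alt)
  }
  wt <- draw_pool(wt_freq)
  mut <- draw_pool(mut_freq)

  mk <- population$markers
  records <- tibble::tibble(
    chrom = mk$chrom, pos = mk$pos,
    ref = if ("ref" %in% names(mk)) mk$ref else NA_character_,
    alt = if ("alt" %in% names(mk)) mk$alt else NA_character_,
    wt_ref = wt$ref, wt_alt = wt$alt,
    mut_ref = mut$ref, mut_alt = mut$alt
  )
  truth <- tibble::tibble(
    chrom = mk$chrom, pos = mk$pos,
    ref = records$ref, alt = records$alt,
    wt_freq = wt_freq, mut_freq = mut_freq,
    causal = seq_len(m) == population$causal_index
  )
  list(records = records, truth = truth)
}

# Assign background marker positions and EMS-spectrum alleles against a
# concrete genome. The canonical fraction are G:C->A:T transitions (ref G
# gets alt A, ref C gets alt T); the remainder are any other substitution.
# The causal gene's CDS is kept free of background mutations so the truth
# table carries exactly one coding causal variant.
generate_markers <- function(config, reference) {
  lens <- config$chromosomes
  genome_strings <- reference$genome_strings

  cds <- reference$causal_gene$features
  cds <- cds[cds$type == "CDS", ]
  excluded <- function(chr, pos) {
    if (chr == config$causal$chrom && pos == config$causal$pos) return(TRUE)
    any(cds$chrom == chr & pos >= cds$start & pos <= cds$end)
  }

  n <- config$n_background_snps
  n_canon <- round(config$ems_transition_fraction * n)
  taken <- new.env(hash = TRUE)
  key <- function(chr, pos) paste0(chr, ":", pos)
  out_chr <- character(n); out_pos <- integer(n)
  out_ref <- character(n); out_alt <- character(n)
  filled <- 0L
  while (filled < n) {
    chr <- sample(names(lens), 1, prob = lens / sum(lens))
    pos <- sample.int(lens[[chr]], 1)
    if (!is.null(taken[[key(chr, pos)]]) || excluded(chr, pos)) next
    ref <- substr(genome_strings[[chr]], pos, pos)
    canonical_wanted <- filled < n_canon
    if (canonical_wanted) {
      if (!ref %in% c("G", "C")) next
      alt <- if (ref == "G") "A" else "T"
    } else {
      alt <- sample(setdiff(BASES, ref), 1)
      if ((ref == "G" && alt == "A") || (ref == "C" && alt == "T")) next
    }
    filled <- filled + 1L
    out_chr[filled] <- chr; out_pos[filled] <- pos
    out_ref[filled] <- ref; out_alt[filled] <- alt
    taken[[key(chr, pos)]] <- TRUE
  }

  mk <- tibble::tibble(
    chrom = c(out_chr, config$causal$chrom),
    pos = c(out_pos, as.integer(config$causal$pos)),
    ref = c(out_ref, config$causal$ref),
    alt = c(out_alt, config$causal$alt)
  )
  dplyr::arrange(mk, .data$chrom, .data$pos)
}

#' Simulate one full bulked-segregant dataset in memory
#'
#' Runs the whole generator under `config$seed`: reference genome with
#' gene models, EMS marker set, F2 population, bulk selection and pooled
#' sequencing.
#'
#' @param config A [simulation_config()].
#' @return List of class `bsa_dataset` with `config`, `genome`
#'   ([Biostrings::DNAStringSet]), `features` (gene-model tibble),
#'   `markers`, `population`, `bulks`, `records` (two-pool allele counts)
#'   and `truth`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  reference <- build_reference(config)
  markers <- generate_markers(config, reference)
  population <- simulate_f2_population(config, markers)
  bulks <- select_bulks(population, config$bulk_size)
  seqd <- sequence_bulks(population, bulks, config)
  structure(
    list(config = config, genome = reference$genome,
         features = reference$features, promoter_txn = reference$promoter_txn,
         causal_gene = reference$causal_gene, markers = markers,
         population = population, bulks = bulks,
         records = seqd$records, truth = seqd$truth),
    class = "bsa_dataset"
  )
}

#' Write a complete simulated fixture set to disk
#'
#' Emits reference FASTA, gene-model GFF3, two-sample allele-depth VCF
#' and a truth TSV; byte-identical files for identical configurations.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the four file `paths` and the in-memory
#'   `dataset`.
#' @export
write_fixture <- function(config, dir) {
  dataset <- simulate_dataset(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta = file.path(dir, "reference.fa"),
    gff3 = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "pools.vcf"),
    truth = file.path(dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(dataset$genome, paths$fasta)
  write_gene_models_gff3(dataset$features, paths$gff3,
                         chrom_lengths = config$chromosomes)
  write_two_pool_vcf(dataset$records, paths$vcf,
                     chrom_lengths = config$chromosomes)
  utils::write.table(dataset$truth, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(paths = paths, dataset = dataset))
}
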