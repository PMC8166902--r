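#' Configure an end-to-end MutMap pipeline run
#'
#' Exactly one input mode is active: either a [simulation_config()]
#' (synthetic data generated in memory) or the three file paths of a real
#' dataset (two-pool VCF, reference FASTA, gene-model GFF3).
#'
#' @param simulation A [simulation_config()], or `NULL` when files are
#'   given.
#' @param vcf,fasta,gff3 Input paths (all three required together).
#' @param window_size,step Genome-scan window geometry in bp (default
#'   tumbling 1 Mb).
#' @param min_depth Per-pool depth filter (default 7).
#' @param band_reps Monte-Carlo replicates for the null band (default
#'   10000).
#' @param band_levels Band quantile levels (default 0.95 and 0.99).
#' @param level Level used for region calling (default 0.95).
#' @param index_threshold,index_tolerance Candidate index rule: keep
#'   sites with `mut_index >= index_threshold - index_tolerance`.
#'   Defaults 1.0 and 0.1: the recessive causal site is fixed in the
#'   mutant bulk, but at ~25x with ~1% miscalls an exact index of 1 is
#'   lost whenever a single read errs, so the working rule admits up to
#'   two miscalled reads at 25x while unlinked sites (index about 0.5)
#'   remain far below it.
#' @param bulk_size Plants per bulk for the null model (taken from
#'   `simulation` when present; default 25).
#' @param mean_depth Depth for the null model; `NULL` (default when
#'   reading files) estimates the median per-pool depth from the data.
#' @param seed Seed for the pipeline's Monte-Carlo stages.
#' @param out_dir Directory for TSV reports, or `NULL` to skip writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, vcf = NULL, fasta = NULL,
                            gff3 = NULL, window_size = 1e6,
                            step = window_size, min_depth = 7,
                            band_reps = 10000, band_levels = c(0.95, 0.99),
                            level = 0.95, index_threshold = 1.0,
                            index_tolerance = 0.1, bulk_size = NULL,
                            mean_depth = NULL, seed = 1L, out_dir = NULL) {
  have_files <- !is.null(vcf) || !is.null(fasta) || !is.null(gff3)
  if (is.null(simulation) == !have_files) {
    stop("exactly one of `simulation` or the file inputs must be given")
  }
  if (have_files && (is.null(vcf) || is.null(fasta) || is.null(gff3))) {
    stop("file input mode needs all of `vcf`, `fasta` and `gff3`")
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "simulation_config"))
    if (is.null(bulk_size)) bulk_size <- simulation$bulk_size
    if (is.null(mean_depth)) mean_depth <- simulation$mean_depth
  }
  if (is.null(bulk_size)) bulk_size <- 25L
  if (!level %in% band_levels) stop("`level` must be one of `band_levels`")
  structure(
    list(simulation = simulation, vcf = vcf, fasta = fasta, gff3 = gff3,
         window_size = window_size, step = step, min_depth = min_depth,
         band_reps = band_reps, band_levels = band_levels, level = level,
         index_threshold = index_threshold,
         index_tolerance = index_tolerance, bulk_size = bulk_size,
         mean_depth = mean_depth, seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full bulked-segregant mapping pipeline
#'
#' Stages, in order: input (simulate or read files), per-pool depth
#' filter, SNP-index computation, windowed delta-SNP-index scan,
#' Monte-Carlo null band (at window scale: the per-replicate statistic
#' averages as many simulated sites as the observed median SNPs per
#' window), candidate-region calling, location/effect annotation, and
#' candidate filtering. Deterministic under `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with `records` (raw),
#'   `indices` (depth-filtered, annotated with indices, location and
#'   gene), `windows`, `band`, `regions`, `candidates` (with effect
#'   columns for CDS hits), `models`, `genome`, `truth` (simulation mode
#'   only), `log` (seed, config hash, per-stage counts) and `paths`
#'   (written reports, when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulation)) {
    dataset <- simulate_dataset(config$simulation)
    records <- dataset$records
    genome <- dataset$genome
    models <- features_to_models(dataset$features)
    truth <- dataset$truth
  } else {
    records <- read_two_pool_vcf(config$vcf)
    genome <- Biostrings::readDNAStringSet(config$fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    models <- read_gene_models(config$gff3)
    truth <- NULL
    dataset <- NULL
  }

  filtered <- depth_filter(records, config$min_depth)
  indices <- compute_snp_indices(filtered)
  windows <- window_scan(indices, config$window_size, config$step)

  mean_depth <- config$mean_depth
  if (is.null(mean_depth)) {
    mean_depth <- stats::median(c(filtered$wt_ref + filtered$wt_alt,
                                  filtered$mut_ref + filtered$mut_alt))
  }
  k <- max(1, round(stats::median(windows$n_snps)))
  band <- null_band(config$bulk_size, mean_depth, n_sites = k,
                    n_reps = config$band_reps, levels = config$band_levels,
                    min_depth = config$min_depth, seed = config$seed)
  regions <- call_regions(windows, band, config$level)

  loc <- classify_location(indices$chrom, indices$pos, models)
  indices$location <- as.character(loc)
  indices$gene_id <- attr(loc, "gene_id")

  candidates <- filter_candidates(
    indices, regions,
    index_threshold = config$index_threshold,
    index_tolerance = config$index_tolerance
  )
  candidates <- add_effects(candidates, models, genome)

  log <- list(
    seed = config$seed,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("mutmapr")),
    n_input = nrow(records),
    n_depth_filtered = nrow(filtered),
    n_windows = nrow(windows),
    band_sites_per_window = k,
    thresholds = band$thresholds,
    n_regions = nrow(regions),
    n_candidates = nrow(candidates)
  )

  result <- structure(
    list(records = records, indices = indices, windows = windows,
         band = band, regions = regions, candidates = candidates,
         models = models, genome = genome, truth = truth, log = log,
         paths = NULL),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    result$paths <- write_pipeline_reports(result, config$out_dir)
  }
  result
}

# effect columns for CDS candidates (noncoding rows get effect "noncoding")
add_effects <- function(candidates, models, genome) {
  n <- nrow(candidates)
  candidates$effect <- rep(NA_character_, n)
  candidates$aa_change <- rep(NA_character_, n)
  candidates$strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    gid <- candidates$gene_id[i]
    if (is.na(gid)) {
      candidates$effect[i] <- "noncoding"
      next
    }
    eff <- predict_effect(candidates$chrom[i], candidates$pos[i],
                          candidates$ref[i], candidates$alt[i],
                          models[[gid]], genome)
    candidates$effect[i] <- eff$effect
    candidates$strand[i] <- eff$strand
    if (eff$effect != "noncoding") candidates$aa_change[i] <- eff$aa_change
  }
  candidates
}

write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list(
    sites = tsv(result$indices, "snp_index.tsv"),
    windows = tsv(result$windows, "windows.tsv"),
    regions = tsv(result$regions, "regions.tsv"),
    candidates = tsv(result$candidates, "candidates.tsv")
  )
  log_lines <- c(
    paste0("seed\t", result$log$seed),
    paste0("config_hash\t", result$log$config_hash),
    paste0("package_version\t", result$log$package_version),
    paste0("r_version\t", R.version.string),
    paste0("n_input\t", result$log$n_input),
    paste0("n_depth_filtered\t", result$log$n_depth_filtered),
    paste0("n_windows\t", result$log$n_windows),
    paste0("band_sites_per_window\t", result$log$band_sites_per_window),
    paste0("threshold_", names(result$log$thresholds), "\t",
           format(result$log$thresholds, digits = 6)),
    paste0("n_regions\t", result$log$n_regions),
    paste0("n_candidates\t", result$log$n_candidates)
  )
  paths$log <- file.path(out_dir, "run_log.tsv")
  writeLines(log_lines, paths$log)
  paths
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("MutMap pipeline result\n")
  cat(sprintf("  %d sites in, %d after depth filter, %d windows\n",
              x$log$n_input, x$log$n_depth_filtered, x$log$n_windows))
  cat(sprintf("  thresholds: %s\n",
              paste(sprintf("%s%%=%.4f", names(x$band$thresholds),
                            x$band$thresholds), collapse = ", ")))
  cat(sprintf("  %d candidate region(s), %d surviving candidate SNP(s)\n",
              nrow(x$regions), nrow(x$candidates)))
  if (nrow(x$candidates) > 0) {
    print(x$candidates[, intersect(c("chrom", "pos", "ref", "alt",
                                     "wt_index", "mut_index", "delta",
                                     "location", "gene_id", "effect",
                                     "aa_change"), names(x$candidates))])
  }
  invisible(x)
}

#' Repeated end-to-end causal-SNP recovery experiment
#'
#' Simulates and maps `n_runs` independent datasets (one seed each) and
#' records, per run, whether the true causal SNP lies inside a called
#' candidate region, whether exactly one candidate survives the filters,
#' and whether the surviving candidate is the causal SNP with a nonsense
#' effect.
#'
#' @param n_runs Number of runs (default 100).
#' @param seed Base seed; run `i` uses `seed + i - 1` for both the
#'   generator and the pipeline.
#' @param simulation Template [simulation_config()] (defaults used when
#'   `NULL`).
#' @param band_reps Null-band replicates per run (default 2000; the
#'   band enters only through its 95% quantile, far from the causal
#'   signal, so a moderate replicate count per run suffices).
#' @param ... Further arguments passed to [pipeline_config()].
#' @return Tibble with one row per run: `run`, `seed`, `n_regions`,
#'   `n_candidates`, `causal_in_region`, `sole_candidate`,
#'   `causal_recovered` (sole candidate is the causal SNP) and
#'   `causal_effect` (predicted effect at the causal SNP when it
#'   survived).
#' @export
recovery_experiment <- function(n_runs = 100, seed = 1L, simulation = NULL,
                                band_reps = 2000, ...) {
  if (is.null(simulation)) simulation <- simulation_config()
  runs <- lapply(seq_len(n_runs), function(i) {
    s <- as.integer(seed + i - 1L)
    sim_i <- simulation
    sim_i$seed <- s
    res <- run_pipeline(pipeline_config(simulation = sim_i, seed = s,
                                        band_reps = band_reps, ...))
    causal <- res$truth[res$truth$causal, ]
    in_region <- nrow(res$regions) > 0 &&
      any(res$regions$chrom == causal$chrom &
            causal$pos >= res$regions$start & causal$pos <= res$regions$end)
    is_causal <- res$candidates$chrom == causal$chrom &
      res$candidates$pos == causal$pos
    tibble::tibble(
      run = i, seed = s,
      n_regions = nrow(res$regions),
      n_candidates = nrow(res$candidates),
      causal_in_region = in_region,
      sole_candidate = nrow(res$candidates) == 1,
      causal_recovered = nrow(res$candidates) == 1 && any(is_causal),
      causal_effect = if (any(is_causal)) {
        res$candidates$effect[which(is_causal)[1]]
      } else {
        NA_character_
      }
    )
  })
  dplyr::bind_rows(runs)
}
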