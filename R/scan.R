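#' Windowed delta-SNP-index genome scan
#'
#' Averages the per-site delta SNP index in fixed-width windows along each
#' chromosome (tumbling 1 Mb windows by default, mirroring the per-1-Mb
#' profile used to localise the causal region; a sliding mode is available
#' via `step`). Windows containing no SNPs are omitted.
#'
#' @param rows SNP-index table with columns `chrom`, `pos`, `delta`
#'   (see [compute_snp_indices()]).
#' @param window_size Window width in bp (default 1e6).
#' @param step Distance between window starts (default `window_size`,
#'   i.e. tumbling; smaller values give overlapping sliding windows).
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `n_snps` and `mean_delta` (unweighted mean of member-site deltas),
#'   sorted by chromosome and start.
#' @export
window_scan <- function(rows, window_size = 1e6, step = window_size) {
  if (window_size <= 0 || step <= 0) {
    stop("`window_size` and `step` must be positive")
  }
  rows <- dplyr::arrange(rows, .data$chrom, .data$pos)
  out <- lapply(split(rows, rows$chrom), function(chr_rows) {
    max_pos <- max(chr_rows$pos)
    starts <- seq(1, max_pos, by = step)
    res <- lapply(starts, function(s) {
      in_win <- chr_rows$pos >= s & chr_rows$pos <= s + window_size - 1
      if (!any(in_win)) return(NULL)
      tibble::tibble(chrom = chr_rows$chrom[1], start = s,
                     end = s + window_size - 1,
                     n_snps = sum(in_win),
                     mean_delta = mean(chr_rows$delta[in_win]))
    })
    dplyr::bind_rows(res)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Monte-Carlo null confidence band for the windowed delta SNP index
#'
#' Simulates the no-linkage null: each bulk's allele frequency at a site
#' is the alt-allele frequency among `bulk_size` F2 plants whose dosages
#' are drawn 1:2:1 (equivalently Binomial(2 x bulk_size, 1/2) alleles);
#' read depths are Poisson(`mean_depth`) conditioned on passing the same
#' per-pool depth filter as the observed data; alt reads are
#' Binomial(depth, f). The per-replicate statistic is the mean delta over
#' `n_sites` independent sites, so thresholds computed with `n_sites`
#' equal to the typical SNPs-per-window count are directly comparable to
#' window means. Thresholds are upper one-sided empirical quantiles.
#'
#' @param bulk_size Plants per bulk.
#' @param mean_depth Expected per-pool depth per site.
#' @param n_sites Sites averaged per replicate (1 = site-level band).
#' @param n_reps Monte-Carlo replicates (default 10000, minimum 100).
#' @param levels Quantile levels (default 0.95 and 0.99).
#' @param min_depth Per-pool depth filter mirrored from the pipeline.
#' @param seed Optional seed; identical seeds give identical thresholds.
#' @return Object of class `confidence_band`: list with `thresholds`
#'   (named by level), `levels`, `n_reps`, `n_sites`, `bulk_size`,
#'   `mean_depth`, `min_depth`, `seed`.
#' @export
null_band <- function(bulk_size, mean_depth, n_sites = 1, n_reps = 10000,
                      levels = c(0.95, 0.99), min_depth = 7, seed = NULL) {
  if (bulk_size < 1) stop("`bulk_size` must be >= 1")
  if (n_reps < 100) stop("`n_reps` must be >= 100")
  if (n_sites < 1) stop("`n_sites` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  stat <- null_window_deltas(bulk_size, mean_depth, n_sites, n_reps, min_depth)
  thresholds <- stats::quantile(stat, probs = levels, names = FALSE)
  names(thresholds) <- format(levels)
  structure(
    list(thresholds = thresholds, levels = levels, n_reps = n_reps,
         n_sites = n_sites, bulk_size = bulk_size, mean_depth = mean_depth,
         min_depth = min_depth, seed = seed),
    class = "confidence_band"
  )
}

# Draws n_reps null window statistics (mean delta over n_sites sites).
# Vectorised; consumes the current RNG stream.
null_window_deltas <- function(bulk_size, mean_depth, n_sites, n_reps,
                               min_depth) {
  n <- n_sites * n_reps
  n_al <- 2 * bulk_size
  f_wt <- stats::rbinom(n, n_al, 0.5) / n_al
  f_mut <- stats::rbinom(n, n_al, 0.5) / n_al
  draw_depth <- function(n) {
    # depth 0 never reaches the index (undefined), so truncate at >= 1;
    # rejection sampling: the truncated mass is tiny at realistic depths
    floor_d <- max(min_depth, 1)
    d <- stats::rpois(n, mean_depth)
    bad <- which(d < floor_d)
    while (length(bad) > 0) {
      d[bad] <- stats::rpois(length(bad), mean_depth)
      bad <- bad[d[bad] < floor_d]
    }
    d
  }
  d_wt <- draw_depth(n)
  d_mut <- draw_depth(n)
  idx_wt <- stats::rbinom(n, d_wt, f_wt) / d_wt
  idx_mut <- stats::rbinom(n, d_mut, f_mut) / d_mut
  colMeans(matrix(idx_mut - idx_wt, nrow = n_sites))
}

#' @export
print.confidence_band <- function(x, ...) {
  cat("Null confidence band (", x$n_reps, " Monte-Carlo replicates, ",
      x$n_sites, " site(s)/window)\n", sep = "")
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %g%% threshold: %.4f\n", 100 * x$levels[i], x$thresholds[i]))
  }
  invisible(x)
}

#' Call candidate regions from a window scan
#'
#' Maximal runs of consecutive windows whose mean delta SNP index exceeds
#' the null-band threshold, merged per chromosome.
#'
#' @param windows Output of [window_scan()].
#' @param band A [null_band()] object (or a single numeric threshold).
#' @param level Which band level to use (default 0.95).
#' @return Tibble with `chrom`, `start`, `end`, `n_windows`,
#'   `peak_start` (start of the window with the largest mean delta),
#'   `peak_delta`, `level` and `threshold`; zero rows when nothing
#'   exceeds the threshold.
#' @export
call_regions <- function(windows, band, level = 0.95) {
  if (inherits(band, "confidence_band")) {
    i <- match(level, band$levels)
    if (is.na(i)) stop("level ", level, " not present in the band")
    threshold <- unname(band$thresholds[i])
  } else {
    threshold <- as.numeric(band)
  }
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_windows = integer(),
                          peak_start = numeric(), peak_delta = numeric(),
                          level = numeric(), threshold = numeric())
  if (nrow(windows) == 0) return(empty)
  windows <- dplyr::arrange(windows, .data$chrom, .data$start)
  out <- lapply(split(windows, windows$chrom), function(w) {
    hot <- w$mean_delta > threshold
    if (!any(hot)) return(NULL)
    # windows are consecutive when adjacent in the sorted scan
    run_id <- cumsum(c(TRUE, diff(which(hot)) > 1))
    hot_w <- w[hot, ]
    dplyr::bind_rows(lapply(split(hot_w, run_id), function(r) {
      peak <- which.max(r$mean_delta)
      tibble::tibble(chrom = r$chrom[1], start = min(r$start),
                     end = max(r$end), n_windows = nrow(r),
                     peak_start = r$start[peak],
                     peak_delta = r$mean_delta[peak],
                     level = level, threshold = threshold)
    }))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$chrom, .data$start)
}
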