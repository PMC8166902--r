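test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(chromosomes = c(chr1 = 0)), "positive")
  expect_error(simulation_config(seq_error = 0.6), "seq_error")
  expect_error(simulation_config(ems_transition_fraction = 1.2),
               "ems_transition_fraction")
  expect_error(simulation_config(causal = list(chrom = "chrX", pos = 1,
                                               ref = "A", alt = "T")),
               "causal")
  expect_error(simulation_config(causal = list(chrom = "chr1", pos = 3e6,
                                               ref = "A", alt = "T")),
               "outside")
})

test_that("F2 genotypes segregate 1:2:1 and phenotypes 3:1", {
  cfg <- simulation_config(seed = 7, n_f2 = 1e4)
  markers <- tibble::tibble(chrom = c("chr1", "chr2"), pos = c(16268L, 1e6))
  set.seed(7)
  pop <- simulate_f2_population(cfg, markers)
  # unlinked marker on the other chromosome
  unlinked <- pop$genotypes[, pop$markers$chrom == "chr2"]
  counts <- tabulate(unlinked + 1, nbins = 3)
  expect_gt(stats::chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 0.001)
  # recessive 3:1 phenotype ratio, 3 sigma binomial band
  p_mut <- mean(pop$phenotype == "mutant")
  expect_lt(abs(p_mut - 0.25), 3 * sqrt(0.25 * 0.75 / 1e4))
  # phenotype is exactly the recessive rule on causal dosage
  expect_identical(pop$phenotype == "mutant",
                   pop$genotypes[, pop$causal_index] == 2L)
})

test_that("recombinant gamete fraction follows the Haldane map function", {
  # markers 10 cM apart: r = (1 - exp(-0.2)) / 2 ~ 0.0906
  set.seed(5)
  n_gam <- 4e4
  g <- mutmapr:::sim_gametes_chrom(n_gam, marker_morgans = c(0.01, 0.11),
                                   chrom_morgans = 0.12)
  r_hat <- mean(g[, 1] != g[, 2])
  r_exp <- (1 - exp(-0.2)) / 2
  expect_lt(abs(r_hat - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n_gam))
})

test_that("bulk allele frequencies have the Mendelian expectations", {
  cfg <- simulation_config(seed = 1)
  markers <- tibble::tibble(chrom = "chr1", pos = 16268L)
  set.seed(123)
  n_draws <- 300
  wt_f <- mut_f <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    pop <- simulate_f2_population(cfg, markers)
    b <- select_bulks(pop, cfg$bulk_size)
    wt_f[i] <- mean(pop$genotypes[b$wt, 1]) / 2
    mut_f[i] <- mean(pop$genotypes[b$mut, 1]) / 2
  }
  # mutant bulk is fixed for the causal allele in every draw
  expect_true(all(mut_f == 1))
  # wild-type bulk: 1/3 AA : 2/3 Aa among normals -> alt frequency 1/3
  se <- sd(wt_f) / sqrt(n_draws)
  expect_lt(abs(mean(wt_f) - 1 / 3), 3 * se)
})

test_that("unlinked loci show no bulk selection signal", {
  cfg <- simulation_config(seed = 1)
  markers <- tibble::tibble(chrom = c("chr1", "chr2"), pos = c(16268L, 1e6))
  set.seed(99)
  f <- replicate(300, {
    pop <- simulate_f2_population(cfg, markers)
    b <- select_bulks(pop, cfg$bulk_size)
    unl <- which(pop$markers$chrom == "chr2")
    c(mean(pop$genotypes[b$wt, unl]), mean(pop$genotypes[b$mut, unl])) / 2
  })
  for (row in 1:2) {
    se <- sd(f[row, ]) / sqrt(ncol(f))
    expect_lt(abs(mean(f[row, ]) - 0.5), 3 * se)
  }
})

test_that("bulk selection fails loudly when a phenotype class is too small", {
  cfg <- simulation_config(seed = 2, n_f2 = 100L)
  markers <- tibble::tibble(chrom = "chr1", pos = 16268L)
  set.seed(2)
  pop <- simulate_f2_population(cfg, markers)
  pop$phenotype[] <- "normal"
  expect_error(select_bulks(pop, 25), "mutant")
  pop$phenotype[] <- "mutant"
  expect_error(select_bulks(pop, 25), "wild-type")
})

test_that("pooled sequencing follows the binomial read model", {
  # fixed bulk of homozygous-alt plants across many replicate sites
  m <- 1e4
  pop <- structure(list(
    genotypes = matrix(2L, nrow = 25, ncol = m),
    phenotype = rep("mutant", 25),
    markers = tibble::tibble(chrom = "chr1", pos = seq_len(m)),
    causal_index = 1L
  ), class = "f2_population")
  bulks <- list(wt = 1:25, mut = 1:25)

  # no sequencing error: index exactly 1 at every site
  set.seed(3)
  cfg0 <- simulation_config(seed = 3, seq_error = 0)
  s0 <- sequence_bulks(pop, bulks, cfg0)
  d <- s0$records$mut_ref + s0$records$mut_alt
  expect_true(all(s0$records$mut_alt[d > 0] == d[d > 0]))

  # e = 0.01: mean observed alt fraction ~ f(1-e) + (1-f)e = 0.99
  cfg1 <- simulation_config(seed = 3, seq_error = 0.01)
  s1 <- sequence_bulks(pop, bulks, cfg1)
  d1 <- s1$records$mut_ref + s1$records$mut_alt
  frac <- s1$records$mut_alt[d1 > 0] / d1[d1 > 0]
  expect_lt(abs(mean(frac) - 0.99), 3 * sd(frac) / sqrt(length(frac)))
})

test_that("background SNPs carry the EMS spectrum and avoid the causal CDS", {
  ds <- simulate_dataset(small_sim_config(seed = 4,
                                          n_background_snps = 1000L))
  bg <- ds$truth[!ds$truth$causal, ]
  canonical <- (bg$ref == "G" & bg$alt == "A") |
    (bg$ref == "C" & bg$alt == "T")
  expect_equal(mean(canonical), 0.98, tolerance = 0.006)
  # genome base at every marker matches the recorded ref allele
  probe <- vapply(seq_len(nrow(bg)), function(i) {
    as.character(Biostrings::subseq(ds$genome[[bg$chrom[i]]],
                                    bg$pos[i], bg$pos[i]))
  }, "")
  expect_identical(probe, bg$ref)
  cds <- ds$features[ds$features$type == "CDS" & ds$features$strand == "-", ]
  in_cds <- vapply(seq_len(nrow(bg)), function(i) {
    any(bg$chrom[i] == cds$chrom & bg$pos[i] >= cds$start &
          bg$pos[i] <= cds$end)
  }, TRUE)
  expect_false(any(in_cds))
  expect_equal(sum(ds$truth$causal), 1L)
})

test_that("fixtures are bit-reproducible under the seed and differ across seeds", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  dir3 <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 10)
  write_fixture(cfg, dir1)
  write_fixture(cfg, dir2)
  write_fixture(small_sim_config(seed = 11), dir3)
  for (f in c("reference.fa", "genes.gff3", "pools.vcf", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
  # sequence-bearing outputs differ across seeds (the GFF3 does not:
  # the toy gene geometry is fixed by construction)
  for (f in c("reference.fa", "pools.vcf", "truth.tsv")) {
    expect_false(identical(unname(tools::md5sum(file.path(dir1, f))),
                           unname(tools::md5sum(file.path(dir3, f)))))
  }
})
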