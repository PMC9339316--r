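# The synthetic ZW genome generator and the depth / read / genotype
# simulators that feed every downstream stage.

test_that("built genomes satisfy their own construction properties", {
  g <- build_genomes(tiny_blueprint())
  tr <- g$truth
  W <- as.character(g$haplotypes[["W"]])
  Z <- as.character(g$haplotypes[["Z"]])

  # W = Z backbone + SDR insertion: removing the insertion recovers the
  # sequence shared with Z outside the Z-specific element
  ins <- substr(W, tr$sdr$W[1] + 1, tr$sdr$W[2])
  expect_identical(nchar(ins), 4000L)
  w_wo <- paste0(substr(W, 1, tr$sdr$W[1]), substr(W, tr$sdr$W[2] + 1, nchar(W)))
  z_wo <- paste0(substr(Z, 1, tr$z_element$Z[1]),
                 substr(Z, tr$z_element$Z[1] + tr$z_element$inserted_len + 1,
                        nchar(Z)))
  expect_identical(w_wo, z_wo)

  # SDR terminal inverted repeats are exact reverse complements
  irl <- tr$sdr$ir_len
  expect_identical(substr(ins, 1, irl),
                   revcomp(substr(ins, nchar(ins) - irl + 1, nchar(ins))))

  # Z element is flanked by the TSD motif on both sides (on Z and on mosaic)
  for (case in list(list(s = Z, iv = tr$z_element$Z),
                    list(s = as.character(g$reference[["chrZW"]]),
                         iv = tr$z_element$mosaic))) {
    expect_identical(substr(case$s, case$iv[1] - 2, case$iv[1]), "TTA")
    expect_identical(substr(case$s, case$iv[2] + 1, case$iv[2] + 3), "TTA")
  }

  # copy-number track covers every reference base exactly once
  cn <- tr$cn_track
  for (chrom in names(g$reference)) {
    seg <- cn[cn$chrom == chrom, ]
    seg <- seg[order(seg$start), ]
    expect_identical(seg$start[1], 0L)
    expect_identical(max(seg$end), nchar(as.character(g$reference[[chrom]])))
    if (nrow(seg) > 1)
      expect_identical(seg$start[-1], seg$end[-nrow(seg)])
  }
  expect_true(all(cn$cn_F %in% 0:2 & cn$cn_M %in% 0:2))

  # planted W-specific / Z-specific copy numbers
  sdr_seg <- cn[cn$start == tr$sdr$mosaic[1] & cn$chrom == "chrZW", ]
  expect_identical(c(sdr_seg$cn_F, sdr_seg$cn_M), c(1L, 0L))
  z_seg <- cn[cn$start == tr$z_element$mosaic[1] & cn$chrom == "chrZW", ]
  expect_identical(c(z_seg$cn_F, z_seg$cn_M), c(1L, 2L))
})

test_that("genome construction is deterministic and feature-complete at the default scale", {
  g1 <- build_genomes(zw_blueprint_default(seed = 11))
  g2 <- build_genomes(zw_blueprint_default(seed = 11))
  expect_identical(as.character(g1$reference), as.character(g2$reference))
  expect_identical(as.character(g1$haplotypes), as.character(g2$haplotypes))
  expect_identical(g1$truth$features, g2$truth$features)

  # every planted hallmark appears exactly once in the truth features
  kinds <- table(g1$truth$features$name)
  for (nm in c("SDR", "sdr_ir5", "sdr_ir3", "ltr_element", "Z_element",
               "z_tsd5", "z_tsd3", "retro_polyA", "palindrome"))
    expect_identical(unname(kinds[nm]), 1L)
})

test_that("an empty blueprint yields identical haplotypes and no features", {
  bp <- tiny_blueprint(sdr = NULL, zint = NULL)
  g <- build_genomes(bp)
  expect_identical(as.character(g$haplotypes[["W"]]),
                   as.character(g$haplotypes[["Z"]]))
  expect_identical(nrow(g$truth$features), 0L)
  expect_true(all(g$truth$cn_track$cn_F == 2 & g$truth$cn_track$cn_M == 2))
})

test_that("overlapping planted features are rejected with the pair named", {
  expect_error(
    zw_blueprint(chrom_lengths = c(chrZW = 60000L, chrA1 = 30000L),
                 sdr_interval = c(10000L, 45000L), sdr_ir_len = 29L,
                 z_specific_interval = NULL,
                 ltr_spec = list(offset = 1000L, length = 4923L,
                                 arm_len = 208L, n_sub = 1L, n_ins = 1L,
                                 flank = c("TA", "TA")),
                 retrogene_spec = list(offset = 3000L, cds_len = 960L,
                                       polyA_len = 16L, polyA_offset = 99L,
                                       dr_len = 13L, upstream_offset = 152L),
                 telomere_arrays = NULL, palindrome_spec = NULL),
    "ltr_spec and retrogene_spec")

  # overlaps only detectable at build time name the offending pair too
  bp <- tiny_blueprint(sdr = NULL, zint = NULL)
  bp$telomere_arrays <- data.frame(chrom = "chrA1", where = "5p",
                                   len = 2000L, offset = 0L)
  bp$palindrome_spec <- list(chrom = "chrA1", pos = 1500L, arm_len = 400L,
                             spacer = 10L)
  expect_error(build_genomes(bp), "overlapping planted features")
})

test_that("simulated depth follows the planted copy-number model", {
  g <- build_genomes(tiny_blueprint())
  samples <- zw_samples(2, 2, 10)
  d <- simulate_depth(g$truth, samples, seed = 3)
  tr <- g$truth
  male_cols <- samples$sample_id[samples$sex == "M"]

  # copy number 0: male depth identically zero over the SDR
  sdr_rows <- d$chrom == "chrZW" & d$pos > tr$sdr$mosaic[1] &
    d$pos <= tr$sdr$mosaic[2]
  expect_true(all(d[sdr_rows, male_cols, with = FALSE] == 0))

  # diploid autosome: mean ~ target_depth * 2 (Poisson mean 20)
  auto <- d[d$chrom == "chrA1", ]
  for (id in samples$sample_id)
    expect_equal(mean(auto[[id]]), 20, tolerance = 0.02)

  # hemizygous region in females: mean ~ 10
  f1 <- samples$sample_id[1]
  expect_equal(mean(d[[f1]][sdr_rows]), 10, tolerance = 0.05)

  # byte-identical under the same seed
  d2 <- simulate_depth(g$truth, samples, seed = 3)
  expect_identical(d, d2)
  f1 <- tempfile(); f2 <- tempfile()
  write_depth(d, f1); write_depth(d2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("read simulation respects carried haplotypes and is reproducible", {
  g <- build_genomes(tiny_blueprint())
  samples <- zw_samples(1, 1, 10)
  reads <- simulate_reads(g, samples, read_len = 50, coverage = 4,
                          error_rate = 0, seed = 7)

  # expected read count ~ coverage * total_bp / read_len
  tot_F <- sum(nchar(as.character(g$haplotypes))) +
    2 * nchar(as.character(g$reference[["chrA1"]]))
  expect_equal(length(reads$F01), 4 * tot_F / 50, tolerance = 0.01)

  # error-free male reads contain no W-specific k-mer
  tr <- g$truth
  W <- as.character(g$haplotypes[["W"]])
  sdr_kmers <- count_kmers(substr(W, tr$sdr$W[1] + 1, tr$sdr$W[2]), k = 31)
  male_kmers <- count_kmers(reads$M01, k = 31)
  expect_identical(length(intersect(sdr_kmers, male_kmers)), 0L)

  # same seed -> identical reads (and identical FASTQ bytes)
  reads2 <- simulate_reads(g, samples, read_len = 50, coverage = 4,
                           error_rate = 0, seed = 7)
  expect_identical(reads, reads2)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_fastq(reads$F01, f1, "F01"); write_fastq(reads2$F01, f2, "F01")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(simulate_reads(g, samples, read_len = 40000),
               "read_len longer")
})

test_that("simulated genotype panels have the planted sex-linkage structure", {
  g <- build_genomes(tiny_blueprint())
  samples <- zw_samples(2, 2, 10)
  sim <- simulate_variants(g, samples, n_neutral_sites = 50,
                           n_sexlinked_sites = 20, seed = 5)
  sl <- sim$sites$sexlinked
  # fully sex-linked: females het, males hom-ref
  expect_true(all(sim$gt[sl, samples$sex == "F"] == 1))
  expect_true(all(sim$gt[sl, samples$sex == "M"] == 0))
  # sex-linked sites stay inside the planted non-recombining region
  expect_true(all(sim$sites$chrom[sl] == g$truth$nonrec$chrom &
                    sim$sites$pos[sl] - 1 >= g$truth$nonrec$start &
                    sim$sites$pos[sl] - 1 < g$truth$nonrec$end))

  # requesting sex-linked sites outside the region errors
  bad <- data.frame(chrom = "chrA1", start = 0, end = 10000)
  expect_error(simulate_variants(g, samples, n_sexlinked_sites = 5,
                                 sexlinked_region = bad, seed = 5),
               "outside the planted non-recombining region")

  # header-only VCF when nothing is simulated
  sim0 <- simulate_variants(g, samples, n_neutral_sites = 0,
                            n_sexlinked_sites = 0, seed = 5)
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim0, f)
  lines <- readLines(f)
  expect_true(all(grepl("^#", lines)))
})

test_that("neutral allele frequencies are independent of sex", {
  g <- build_genomes(tiny_blueprint())
  samples <- zw_samples(10, 10, 10)
  sim <- simulate_variants(g, samples, n_neutral_sites = 1500,
                           n_sexlinked_sites = 0, seed = 2)
  f_freq <- rowMeans(sim$gt[, samples$sex == "F"]) / 2
  m_freq <- rowMeans(sim$gt[, samples$sex == "M"]) / 2
  # Monte-Carlo: mean |freq_F - freq_M| matches the binomial sampling
  # expectation and the mean signed difference is ~0
  expect_lt(abs(mean(f_freq - m_freq)), 0.01)
  expect_lt(mean(abs(f_freq - m_freq)), 0.15)
})
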