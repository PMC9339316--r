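# Structural-hallmark scanners: telomere variants/arrays, TIR, TSD, LTR
# direct repeats, retrogene signatures, palindromes, repeat fractions.

rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("telomere motif variants are the rotation + strand closure", {
  v <- telomere_variants("CCCTAAA")
  expect_identical(length(v), 14L)
  expect_true("CCCTAAA" %in% v && "TTTAGGG" %in% v)
  # self-reverse-complementary under rotation collapses the set
  expect_setequal(telomere_variants("AT"), c("AT", "TA"))
  expect_setequal(telomere_variants("A"), c("A", "T"))
  # brute-force closure oracle for assorted motifs
  for (m in c("CCCTAAA", "TTAGGG", "AT", "ACGT", "AAC", "GGCGCC"))
    expect_identical(length(telomere_variants(m)), rotation_closure_oracle(m))
  expect_error(telomere_variants("ACGX"), "ACGT")
  expect_error(telomere_variants(""), "ACGT|empty")
})

test_that("telomere arrays are found, measured and classified terminal/interstitial", {
  set.seed(12)
  motif <- "CCCTAAA"
  arr <- function(n) strrep(motif, n)
  bg <- rand_dna(5000, 13)
  # 800-bp run (~114 copies) at position 0: terminal
  s <- paste0(arr(115), substr(bg, 806, 5000))
  ta <- find_telomere_arrays(s, motif, min_array_len = 750)
  expect_identical(nrow(ta), 1L)
  expect_true(ta$terminal[1])
  expect_identical(ta$start[1], 0L)
  expect_gte(ta$length[1], 750L)

  # no occurrences: empty
  expect_identical(nrow(find_telomere_arrays(bg, motif, 750)), 0L)

  # ~120-bp internal run: interstitial at a lower threshold
  s2 <- paste0(substr(bg, 1, 2500), arr(17), substr(bg, 2501, 5000))
  ta2 <- find_telomere_arrays(s2, motif, min_array_len = 100,
                              terminal_dist = 1000)
  expect_identical(nrow(ta2), 1L)
  expect_false(ta2$terminal[1])
  expect_gte(ta2$length[1], 119L)
})

test_that("terminal inverted repeats: exact recovery, absence, strand symmetry", {
  ir <- rand_dna(29, 41)
  core <- rand_dna(1000, 42)
  ins <- paste0(ir, core, revcomp(ir))
  tir <- terminal_inverted_repeats(ins, min_len = 10)
  # arm can only exceed 29 if the next inner pair happens to complement
  expect_gte(tir$arm_len, 29L)
  expect_lte(tir$arm_len, 31L)
  expect_identical(tir$mismatches, 0L)

  # random sequence: no 10-bp exact terminal IR
  expect_null(terminal_inverted_repeats(rand_dna(2000, 43), min_len = 10))

  # detection is identical on the reverse complement
  tir_rc <- terminal_inverted_repeats(revcomp(ins), min_len = 10)
  expect_identical(tir_rc$arm_len, tir$arm_len)

  # mismatch budget
  ins2 <- ins
  substr(ins2, 5, 5) <- if (substr(ins2, 5, 5) == "A") "C" else "A"
  expect_null(terminal_inverted_repeats(ins2, min_len = 10, max_mismatch = 0))
  tir2 <- terminal_inverted_repeats(ins2, min_len = 10, max_mismatch = 1)
  expect_gte(tir2$arm_len, 29L)
  expect_identical(tir2$mismatches, 1L)
})

test_that("target-site duplications are read off the insertion flanks", {
  g <- build_genomes(tiny_blueprint(seed = 51))
  Z <- as.character(g$haplotypes[["Z"]])
  iv <- g$truth$z_element$Z
  tsd <- target_site_duplication(Z, iv[1], iv[2])
  expect_identical(tsd$motif, "TTA")
  expect_identical(tsd$length, 3L)

  # no duplication on a random flank
  s <- rand_dna(1000, 52)
  expect_null(target_site_duplication(s, 500, 600, min_len = 3))

  # the ancestral (un-inserted) sequence has a single copy of the site: none
  backbone <- paste0(substr(Z, 1, iv[1]),
                     substr(Z, iv[1] + g$truth$z_element$inserted_len + 1,
                            nchar(Z)))
  expect_null(target_site_duplication(backbone, iv[1], iv[1], min_len = 3))
})

test_that("LTR direct repeats report planted arms, edits and flank class", {
  g <- build_genomes(zw_blueprint_default(seed = 61))
  tr <- g$truth
  W <- as.character(g$haplotypes[["W"]])
  ins <- substr(W, tr$sdr$W[1] + 1, tr$sdr$W[2])
  el <- substr(ins, tr$ltr$offset + 1, tr$ltr$offset + tr$ltr$length)
  res <- ltr_direct_repeats(el)
  expect_identical(res$arm_lens, c(208L, 209L))
  expect_identical(res$edits, 2L)
  expect_identical(res$flank, "TA.TA")
  expect_false(res$canonical)
  expect_identical(res$arm1, c(0L, 208L))
  expect_identical(res$arm2, c(tr$ltr$length - 209L, tr$ltr$length))

  # canonical TG...CA element
  arm <- paste0("TG", rand_dna(200, 62), "CA")
  el2 <- paste0(arm, rand_dna(1000, 63), arm)
  res2 <- ltr_direct_repeats(el2)
  expect_identical(res2$arm_lens, c(204L, 204L))
  expect_identical(res2$edits, 0L)
  expect_true(res2$canonical)

  # no terminal repeat of the required length: none
  expect_null(ltr_direct_repeats(rand_dna(3000, 64), min_len = 100))
})

test_that("retrogene hallmarks are recovered at their planted offsets", {
  g <- build_genomes(zw_blueprint_default(seed = 71))
  tr <- g$truth
  W <- as.character(g$haplotypes[["W"]])
  ins <- substr(W, tr$sdr$W[1] + 1, tr$sdr$W[2])
  rg <- tr$retrogene
  res <- retrogene_scan(ins, rg$cds[1], rg$cds[2])
  expect_true(res$positive)
  expect_identical(res$polyA$length, 16L)
  expect_identical(res$polyA$offset, 99L)
  expect_identical(res$direct_repeat$length, 13L)
  expect_identical(res$direct_repeat$upstream_offset, 152L)
  expect_identical(res$direct_repeat$downstream_offset, 0L)

  # gene without a poly-A tract: negative
  s <- rand_dna(3000, 72)
  res2 <- retrogene_scan(s, 1000, 1999, polyA_min_len = 10)
  expect_false(res2$positive)

  # an A-run one base short of the threshold: negative
  s3 <- paste0(rand_dna(1000, 73), gsub("A", "C", rand_dna(200, 74)),
               strrep("A", 9), gsub("A", "C", rand_dna(500, 75)))
  res3 <- retrogene_scan(s3, 0, 999, polyA_min_len = 10)
  expect_false(res3$positive)

  expect_error(retrogene_scan(s, 2500, 3500), "outside")
})

test_that("palindrome search finds planted arms and nothing in random sequence", {
  arm <- rand_dna(1000, 81)
  spacer <- rand_dna(50, 82)
  bg1 <- rand_dna(20000, 83); bg2 <- rand_dna(20000, 84)
  s <- paste0(bg1, arm, spacer, revcomp(arm), bg2)
  res <- find_palindromes(s, min_arm = 1000, max_spacer = 2000)
  expect_identical(nrow(res), 1L)
  expect_gte(res$arm_len[1], 1000L)
  expect_lte(res$arm1_start[1], 20000L)
  expect_identical(res$arm2_end[1] - res$arm1_start[1],
                   2L * res$arm_len[1] + res$spacer[1])

  # random 100-kb sequence: no 1-kb palindrome
  expect_identical(nrow(find_palindromes(rand_dna(100000, 85),
                                         min_arm = 1000)), 0L)

  # symmetric on the reverse-complemented input (coordinates mapped)
  res_rc <- find_palindromes(revcomp(s), min_arm = 1000, max_spacer = 2000)
  expect_identical(nrow(res_rc), 1L)
  expect_identical(res_rc$arm_len, res$arm_len)
  expect_identical(res_rc$arm1_start, nchar(s) - res$arm2_end)
})

test_that("repeat fractions equal the per-base marking oracle", {
  expect_identical(repeat_fraction(1000, data.frame(start = integer(),
                                                    end = integer())), 0)
  expect_identical(repeat_fraction(1000, data.frame(start = 0, end = 1000)), 1)
  set.seed(91)
  for (i in 1:20) {
    n <- 30
    st <- sample(0:900, n, replace = TRUE)
    en <- pmin(st + sample(1:150, n, replace = TRUE), 1000)
    expect_equal(repeat_fraction(1000, data.frame(start = st, end = en)),
                 union_len_oracle(st, en, 1000) / 1000)
  }
  expect_error(repeat_fraction(100, data.frame(start = 50, end = 150)),
               "outside")
})
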