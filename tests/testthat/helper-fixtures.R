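# Small synthetic fixtures shared across test files. Everything is generated
# in code at test time; the canonical suite seed is 1.

tiny_blueprint <- function(seed = 1L, sdr = c(10000L, 14000L),
                           zint = c(20000L, 21703L),
                           chrom_lengths = c(chrZW = 30000L, chrA1 = 30000L),
                           ...) {
  zw_blueprint(chrom_lengths = chrom_lengths,
               sdr_interval = sdr, sdr_ir_len = 29L,
               z_specific_interval = zint, z_ir_len = 14L,
               ltr_spec = NULL, retrogene_spec = NULL,
               telomere_arrays = NULL, palindrome_spec = NULL,
               seed = seed, ...)
}

# genotype-dosage matrix for a single site given per-group vectors
one_site <- function(g_f, g_m) {
  list(gt = matrix(c(g_f, g_m), nrow = 1),
       sex = rep(c("F", "M"), c(length(g_f), length(g_m))))
}

# simple two-chromosome copy-number track: a sex-like chromosome with a
# hemizygous-in-F (cn 1/2) central region, plus a diploid autosome
hemi_cn_track <- function(chrom_len = 500000L, region = c(200000L, 300000L)) {
  data.frame(
    chrom = c(rep("sexchr", 3), "auto"),
    start = c(0L, region[1], region[2], 0L),
    end = c(region[1], region[2], chrom_len, chrom_len),
    cn_F = c(2L, 1L, 2L, 2L),
    cn_M = c(2L, 2L, 2L, 2L))
}
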