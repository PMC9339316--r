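#' Blueprint for a synthetic ZW genome
#'
#' Describes a miniature ZW genome pair: a set of backbone chromosomes, a
#' W-specific sex-determining-region (SDR) insertion with terminal inverted
#' repeats, a Z-specific insertion carrying DNA-transposon hallmarks (terminal
#' inverted repeats and a target-site duplication), an LTR retrotransposon and
#' a retrogene planted inside the SDR, telomere arrays, and a large palindrome.
#' [build_genomes()] turns a blueprint into sequences plus a machine-readable
#' planted truth.
#'
#' Coordinates are 0-based half-open. `chrom_lengths` are *backbone* lengths:
#' the shared proto-sequence before any haplotype-specific insertion is
#' applied, so the Z and W haplotypes (and the Z/W mosaic reference) can be
#' longer than the backbone.
#'
#' @param chrom_lengths named integer vector of backbone lengths; the first
#'   entry is the sex chromosome unless `sex_chrom` says otherwise.
#' @param sex_chrom name of the sex chromosome backbone.
#' @param rep_autosome name of the representative autosome used downstream for
#'   depth normalization and the resampling band.
#' @param sdr_interval W-haplotype interval (start, end) of the W-specific SDR
#'   insertion, or `NULL` for none. Since the SDR is the only W insertion,
#'   `start` is also the backbone insertion point.
#' @param sdr_ir_len length (bp) of the exact terminal inverted repeats
#'   flanking the SDR insertion.
#' @param z_specific_interval Z-haplotype interval of the Z-specific insertion
#'   (a TIR/TSD-bearing DNA-transposon-like element), or `NULL`.
#' @param z_ir_len length (bp) of the Z element's terminal inverted repeats.
#' @param tsd_motif target-site duplication motif planted on both sides of the
#'   Z element.
#' @param par_intervals list of W-haplotype intervals regarded as
#'   pseudoautosomal; defaults to everything outside the SDR insertion.
#' @param ltr_spec LTR retrotransposon planted inside the SDR: list with
#'   `offset` (bp from SDR insertion start), `length`, `arm_len` (planted arm
#'   length before edits), `n_sub`/`n_ins` edits applied to the second arm, and
#'   `flank` (first and last dinucleotide of the element). `NULL` for none.
#' @param retrogene_spec retrogene hallmarks planted inside the SDR: list with
#'   `offset` (bp from SDR start to the upstream direct-repeat copy),
#'   `cds_len`, `polyA_len`, `polyA_offset` (gap between stop codon and
#'   poly-A), `dr_len`, and `upstream_offset` (gap between the upstream
#'   direct-repeat copy and the start codon). `NULL` for none.
#' @param telomere_arrays data.frame with columns `chrom`, `where` (one of
#'   "5p", "3p", "interstitial"), `len` (bp), and `offset` (backbone bp; used
#'   for interstitial arrays only). `NULL` for none.
#' @param telomere_motif canonical telomere repeat motif.
#' @param palindrome_spec large palindrome planted on a backbone chromosome:
#'   list with `chrom`, `pos` (backbone bp of the first arm), `arm_len`,
#'   `spacer`. `NULL` for none.
#' @param nonrec_flank bp added on both sides of the SDR when defining the
#'   non-recombining region in which fully sex-linked variants may be placed.
#' @param gc GC fraction of the background sequence.
#' @param seed integer seed making the built genome reproducible.
#' @return an object of class `zw_blueprint`.
#' @export
#' @examples
#' bp <- zw_blueprint(chrom_lengths = c(chrZW = 5e4, chrA1 = 5e4),
#'                    sdr_interval = c(2e4, 2.4e4), z_specific_interval = NULL,
#'                    telomere_arrays = NULL, palindrome_spec = NULL,
#'                    ltr_spec = NULL, retrogene_spec = NULL)
zw_blueprint <- function(chrom_lengths = c(chrZW = 500000L, chrA1 = 500000L,
                                           chrA2 = 500000L),
                         sex_chrom = names(chrom_lengths)[1],
                         rep_autosome = setdiff(names(chrom_lengths), sex_chrom)[1],
                         sdr_interval = c(290000L, 321455L),
                         sdr_ir_len = 29L,
                         z_specific_interval = c(370000L, 430000L),
                         z_ir_len = 14L,
                         tsd_motif = "TTA",
                         par_intervals = NULL,
                         ltr_spec = list(offset = 5000L, length = 4923L,
                                         arm_len = 208L, n_sub = 1L, n_ins = 1L,
                                         flank = c("TA", "TA")),
                         retrogene_spec = list(offset = 15000L, cds_len = 960L,
                                               polyA_len = 16L, polyA_offset = 99L,
                                               dr_len = 13L, upstream_offset = 152L),
                         telomere_arrays = NULL,
                         telomere_motif = "CCCTAAA",
                         palindrome_spec = list(chrom = NULL, pos = 100000L,
                                                arm_len = 1000L, spacer = 50L),
                         nonrec_flank = 10000L,
                         gc = 0.5,
                         seed = 20220601L) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)))
    stop("chrom_lengths must be a named vector")
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (!sex_chrom %in% names(chrom_lengths))
    stop("sex_chrom not found in chrom_lengths")
  if (!is.na(rep_autosome) && !rep_autosome %in% names(chrom_lengths))
    stop("rep_autosome not found in chrom_lengths")

  if (is.null(telomere_arrays) && length(chrom_lengths) >= 1 && missing(telomere_arrays)) {
    # keep NULL: defaults are provided by zw_blueprint_default()
  }
  if (!is.null(palindrome_spec) && is.null(palindrome_spec$chrom)) {
    auto <- setdiff(names(chrom_lengths), c(sex_chrom, rep_autosome))
    palindrome_spec$chrom <- if (length(auto)) auto[1] else rep_autosome
    if (is.na(palindrome_spec$chrom)) palindrome_spec <- NULL
  }

  bp <- structure(list(
    chrom_lengths = chrom_lengths,
    sex_chrom = sex_chrom,
    rep_autosome = rep_autosome,
    sdr_interval = if (is.null(sdr_interval)) NULL else as.integer(sdr_interval),
    sdr_ir_len = as.integer(sdr_ir_len),
    z_specific_interval = if (is.null(z_specific_interval)) NULL else as.integer(z_specific_interval),
    z_ir_len = as.integer(z_ir_len),
    tsd_motif = toupper(tsd_motif),
    par_intervals = par_intervals,
    ltr_spec = ltr_spec,
    retrogene_spec = retrogene_spec,
    telomere_arrays = telomere_arrays,
    telomere_motif = toupper(telomere_motif),
    palindrome_spec = palindrome_spec,
    nonrec_flank = as.integer(nonrec_flank),
    gc = gc,
    seed = as.integer(seed)
  ), class = "zw_blueprint")
  validate_blueprint(bp)
  bp
}

#' Default full-featured blueprint at the package's miniature study scale
#'
#' Three 500-kb backbone chromosomes (a sex pair, a representative autosome and
#' a second autosome), a 31,455-bp W-specific SDR insertion with 29-bp terminal
#' inverted repeats containing a 4,923-bp LTR element (arms 208/209 bp after 1
#' substitution + 1 insertion, TA.TA flanks) and a retrogene (16-bp poly-A 99 bp
#' downstream of the stop codon, 13-bp direct repeats adjacent to the poly-A and
#' 152 bp upstream of the start codon); a 60-kb Z-specific insertion with 14-bp
#' TIRs and TTA target-site duplications; ~1.1-kb terminal telomere arrays plus
#' one 119-bp interstitial array; and a 1-kb-arm palindrome on the second
#' autosome.
#'
#' @inheritParams zw_blueprint
#' @return a `zw_blueprint`
#' @export
zw_blueprint_default <- function(seed = 20220601L) {
  zw_blueprint(
    telomere_arrays = data.frame(
      chrom = c("chrZW", "chrZW", "chrA1", "chrA1", "chrA2", "chrA2", "chrA1"),
      where = c("5p", "3p", "5p", "3p", "5p", "3p", "interstitial"),
      len = c(1099L, 1099L, 1099L, 1099L, 1099L, 1099L, 119L),
      offset = c(0L, 0L, 0L, 0L, 0L, 0L, 250000L)
    ),
    seed = seed
  )
}

validate_blueprint <- function(bp) {
  lens <- bp$chrom_lengths
  if (!is.null(bp$sdr_interval)) {
    if (length(bp$sdr_interval) != 2 || diff(bp$sdr_interval) < 1)
      stop("sdr_interval must be (start, end) with end > start")
    if (bp$sdr_interval[1] < 0 || bp$sdr_interval[1] > lens[bp$sex_chrom])
      stop("sdr_interval insertion point outside the sex chromosome backbone")
    if (bp$sdr_ir_len < 1) stop("sdr_ir_len must be >= 1")
    if (diff(bp$sdr_interval) < 2 * bp$sdr_ir_len + 2)
      stop("SDR insertion too short for its terminal inverted repeats")
  }
  if (!is.null(bp$z_specific_interval)) {
    if (length(bp$z_specific_interval) != 2 || diff(bp$z_specific_interval) < 1)
      stop("z_specific_interval must be (start, end) with end > start")
    zlen <- diff(bp$z_specific_interval)
    p <- bp$z_specific_interval[1]
    if (p < nchar(bp$tsd_motif) + 1 || p > lens[bp$sex_chrom])
      stop("z_specific_interval insertion point outside the sex chromosome backbone")
    if (zlen < 2 * bp$z_ir_len + 2)
      stop("Z-specific insertion too short for its terminal inverted repeats")
    if (!is.null(bp$sdr_interval) && p == bp$sdr_interval[1])
      stop("overlapping planted features: sdr_interval and z_specific_interval share an insertion point")
  }
  if (!grepl("^[ACGT]+$", bp$tsd_motif)) stop("tsd_motif must be ACGT only")
  if (!grepl("^[ACGT]+$", bp$telomere_motif)) stop("telomere_motif must be ACGT only")
  if (!is.null(bp$par_intervals) && !is.null(bp$sdr_interval)) {
    for (iv in bp$par_intervals) {
      if (iv[1] < bp$sdr_interval[2] && bp$sdr_interval[1] < iv[2])
        stop("sdr_interval must be disjoint from par_intervals")
    }
  }
  if (!is.null(bp$ltr_spec)) {
    ls <- bp$ltr_spec
    if (ls$arm_len < 4) stop("LTR arm_len must be >= 4")
    if (ls$length < 2 * ls$arm_len + 2) stop("LTR element too short for its arms")
    if (is.null(bp$sdr_interval))
      stop("ltr_spec requires an SDR insertion to live in")
    if (ls$offset + ls$length > diff(bp$sdr_interval))
      stop("LTR element extends beyond the SDR insertion")
  }
  if (!is.null(bp$retrogene_spec)) {
    rs <- bp$retrogene_spec
    if (is.null(bp$sdr_interval))
      stop("retrogene_spec requires an SDR insertion to live in")
    span <- retro_span(rs)
    if (rs$offset + span > diff(bp$sdr_interval))
      stop("retrogene region extends beyond the SDR insertion")
    if (rs$cds_len %% 3 != 0 || rs$cds_len < 9)
      stop("retrogene cds_len must be a positive multiple of 3")
  }
  if (!is.null(bp$ltr_spec) && !is.null(bp$retrogene_spec)) {
    a <- c(bp$ltr_spec$offset, bp$ltr_spec$offset + bp$ltr_spec$length)
    b <- c(bp$retrogene_spec$offset,
           bp$retrogene_spec$offset + retro_span(bp$retrogene_spec))
    if (a[1] < b[2] && b[1] < a[2])
      stop("overlapping planted features: ltr_spec and retrogene_spec")
  }
  if (!is.null(bp$telomere_arrays)) {
    ta <- bp$telomere_arrays
    if (!all(ta$chrom %in% names(lens))) stop("telomere array on unknown chromosome")
    if (!all(ta$where %in% c("5p", "3p", "interstitial")))
      stop("telomere array 'where' must be 5p, 3p or interstitial")
    if (any(ta$len < nchar(bp$telomere_motif))) stop("telomere array shorter than motif")
    if (any(ta$len > lens[ta$chrom])) stop("telomere array longer than chromosome")
  }
  if (!is.null(bp$palindrome_spec)) {
    ps <- bp$palindrome_spec
    if (ps$arm_len < 1 || ps$spacer < 0) stop("palindrome arm/spacer lengths invalid")
    if (!ps$chrom %in% names(lens)) stop("palindrome on unknown chromosome")
    if (ps$pos < 1 || ps$pos + 2 * ps$arm_len + ps$spacer + 1 > lens[ps$chrom])
      stop("palindrome extends beyond its chromosome")
  }
  invisible(bp)
}

# total bp of the planted retrogene layout (upstream DR .. downstream DR)
retro_span <- function(rs) {
  rs$dr_len + rs$upstream_offset + rs$cds_len + rs$polyA_offset +
    rs$polyA_len + rs$dr_len
}

#' @export
print.zw_blueprint <- function(x, ...) {
  cat("ZW genome blueprint\n")
  cat("  backbone chromosomes:",
      paste(sprintf("%s (%d bp)", names(x$chrom_lengths), x$chrom_lengths),
            collapse = ", "), "\n")
  cat("  sex chromosome:", x$sex_chrom,
      " representative autosome:", x$rep_autosome, "\n")
  if (!is.null(x$sdr_interval))
    cat(sprintf("  W-specific SDR insertion: %d bp at %d (IRs %d bp)\n",
                diff(x$sdr_interval), x$sdr_interval[1], x$sdr_ir_len))
  if (!is.null(x$z_specific_interval))
    cat(sprintf("  Z-specific insertion: %d bp at %d (TIRs %d bp, TSD %s)\n",
                diff(x$z_specific_interval), x$z_specific_interval[1],
                x$z_ir_len, x$tsd_motif))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Sample sheet for a simulated resequencing panel
#'
#' @param n_female,n_male numbers of individuals of each sex.
#' @param target_depth mean per-haploid-copy sequencing depth (x).
#' @return data.frame with columns `sample_id`, `sex` ("F"/"M"),
#'   `target_depth`, `norm_factor` (NA until filled by [normalize_samples()]).
#' @export
#' @examples
#' head(zw_samples(3, 3, 10))
zw_samples <- function(n_female = 12, n_male = 12, target_depth = 20) {
  if (n_female < 0 || n_male < 0) stop("sample counts must be >= 0")
  if (target_depth <= 0) stop("target_depth must be > 0")
  data.frame(
    sample_id = c(sprintf("F%02d", seq_len(n_female)),
                  sprintf("M%02d", seq_len(n_male))),
    sex = rep(c("F", "M"), c(n_female, n_male)),
    target_depth = target_depth,
    norm_factor = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Read / write a sample sheet (TSV: sample_id, sex[, target_depth])
#' @param path file path
#' @return data.frame like [zw_samples()]
#' @export
read_samples <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sex") %in% names(df)))
    stop("sample sheet needs columns sample_id and sex")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (is.null(df$target_depth)) df$target_depth <- NA_real_
  if (is.null(df$norm_factor)) df$norm_factor <- NA_real_
  df
}

#' @rdname read_samples
#' @param samples a sample sheet data.frame
#' @export
write_samples <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
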