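# Evidence integration: merge classified coverage windows into candidate
# regions, attach FST and k-mer support, rank, and drive the end-to-end run
# on synthetic data.

#' Merge classified windows into candidate sex-linked regions
#'
#' Consecutive windows of the same W-specific / Z-specific class within
#' `merge_gap` bp of each other are merged; region boundaries sit at the
#' outer window edges.
#'
#' @param windows classified window statistics ([classify_windows()])
#' @param merge_gap maximum gap (bp) bridged when merging (default two
#'   windows, 20 kb)
#' @return data.frame: `chrom`, `start`, `end`, `call`, `n_windows`,
#'   `max_abs_log2`
#' @export
merge_windows <- function(windows, merge_gap = 20000L) {
  out <- list()
  for (cls in c("W-specific", "Z-specific")) {
    w <- windows[windows$class %in% cls, , drop = FALSE]
    if (!nrow(w)) next
    w <- w[order(w$chrom, w$start), , drop = FALSE]
    for (cn in unique(w$chrom)) {
      d <- w[w$chrom == cn, , drop = FALSE]
      grp <- cumsum(c(1L, d$start[-1] - d$end[-nrow(d)] > merge_gap))
      for (g in split(d, grp)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = cn, start = min(g$start), end = max(g$end), call = cls,
          n_windows = nrow(g), max_abs_log2 = max(abs(g$log2_ratio)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), call = character(),
                      n_windows = integer(), max_abs_log2 = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Upper bound of the autosomal windowed-FST distribution
#'
#' @param fst_windows [window_weighted_fst()] output
#' @param autosomes chromosome names regarded as autosomal
#' @param prob percentile (default 0.975)
#' @return numeric upper bound
#' @export
autosomal_fst_upper <- function(fst_windows, autosomes, prob = 0.975) {
  x <- fst_windows$weighted_fst[fst_windows$chrom %in% autosomes &
                                  !is.na(fst_windows$weighted_fst)]
  if (!length(x)) stop("no autosomal FST windows")
  unname(quantile(x, prob))
}

#' Attach FST and k-mer evidence to candidate regions
#'
#' The `fst` flag is set iff an overlapping FST window exceeds the autosomal
#' FST upper bound; the `kmer` flag iff at least one sex-specific k-mer
#' interval overlaps. Calls are ranked by number of evidence types, then by
#' peak |log2 ratio|; single-evidence calls are tagged weak (mirroring the
#' judgment that a coverage-only spike without k-mer support is a likely
#' artifact).
#'
#' @param regions [merge_windows()] output
#' @param fst_windows [window_weighted_fst()] output (may be NULL)
#' @param kmer_intervals [cluster_hits()] output (may be NULL)
#' @param fst_upper autosomal FST band upper bound
#'   ([autosomal_fst_upper()]; may be NULL)
#' @return data.frame of ranked region calls with evidence columns
#'   `ev_coverage`, `ev_fst`, `ev_kmer`, `n_evidence`, `n_kmers`,
#'   `max_fst`, `weak`
#' @export
attach_evidence <- function(regions, fst_windows = NULL,
                            kmer_intervals = NULL, fst_upper = NULL) {
  if (!nrow(regions)) {
    regions$ev_coverage <- logical(); regions$ev_fst <- logical()
    regions$ev_kmer <- logical(); regions$n_evidence <- integer()
    regions$n_kmers <- integer(); regions$max_fst <- numeric()
    regions$weak <- logical()
    return(regions)
  }
  r <- regions
  r$ev_coverage <- TRUE
  r$ev_fst <- FALSE; r$max_fst <- NA_real_
  r$ev_kmer <- FALSE; r$n_kmers <- 0L
  for (i in seq_len(nrow(r))) {
    if (!is.null(fst_windows) && nrow(fst_windows)) {
      ov <- fst_windows$chrom == r$chrom[i] &
        fst_windows$start < r$end[i] & fst_windows$end > r$start[i] &
        !is.na(fst_windows$weighted_fst)
      if (any(ov)) {
        r$max_fst[i] <- max(fst_windows$weighted_fst[ov])
        if (!is.null(fst_upper))
          r$ev_fst[i] <- r$max_fst[i] > fst_upper
      }
    }
    if (!is.null(kmer_intervals) && nrow(kmer_intervals)) {
      ov <- kmer_intervals$chrom == r$chrom[i] &
        kmer_intervals$start < r$end[i] & kmer_intervals$end > r$start[i]
      if (any(ov)) {
        r$ev_kmer[i] <- TRUE
        r$n_kmers[i] <- sum(kmer_intervals$n_kmers[ov])
      }
    }
  }
  r$n_evidence <- r$ev_coverage + r$ev_fst + r$ev_kmer
  r$weak <- r$n_evidence == 1L
  r[order(-r$n_evidence, -r$max_abs_log2), , drop = FALSE]
}

#' Run the whole sex-linked-region scan on a synthetic genome
#'
#' Builds (or takes) a synthetic ZW genome, simulates depth, genotype and
#' read panels, and runs every line of evidence end to end: windowed
#' normalized coverage log2 ratios with the autosome-resampling band,
#' windowed intersexual Weir-Cockerham FST, sex-specific k-mer detection and
#' localization, Z/W haplotype comparison, hallmark annotation of the called
#' insertions, and integrated region calls.
#'
#' @param blueprint a [zw_blueprint()] (default [zw_blueprint_default()])
#' @param samples sample sheet (default 12 F + 12 M at 20x per haploid copy)
#' @param seed master seed for every stochastic stage
#' @param window window size (bp)
#' @param n_boot bootstrap replicates for the coverage band
#' @param eps,floor,z_threshold,w_threshold see [fm_log2_ratio()] /
#'   [classify_windows()]
#' @param k k-mer length
#' @param read_coverage per-haploid-copy coverage of the simulated read
#'   panels feeding the k-mer stage
#' @param read_len read length (bp)
#' @param error_rate per-base read error rate
#' @param min_count per-sample k-mer presence threshold
#' @param min_female_frac fraction of females required to carry a
#'   female-specific k-mer
#' @param max_gap k-mer hit clustering gap (bp)
#' @param n_neutral_sites,n_sexlinked_sites,theta see [simulate_variants()]
#' @param merge_gap region merge gap (bp)
#' @param fst_prob autosomal FST percentile used as the evidence bound
#' @param genome optionally a pre-built [build_genomes()] result (its
#'   blueprint overrides `blueprint`)
#' @return object of class `zw_scan`
#' @export
zw_run <- function(blueprint = zw_blueprint_default(),
                   samples = zw_samples(12, 12, 20),
                   seed = 1L,
                   window = 10000L, n_boot = 1000L,
                   eps = 0.001, floor = 0.1, z_threshold = -0.5, w_threshold = 0.5,
                   k = 31L, read_coverage = 15, read_len = 100L,
                   error_rate = 0, min_count = 2L, min_female_frac = 0.9,
                   max_gap = 5000L,
                   n_neutral_sites = 3000L, n_sexlinked_sites = 300L,
                   theta = 0.05,
                   merge_gap = 20000L, fst_prob = 0.975,
                   genome = NULL) {
  genome <- genome %||% build_genomes(blueprint)
  bp <- genome$truth$blueprint
  ref_lens <- setNames(Biostrings::width(genome$reference),
                       names(genome$reference))
  autosomes <- setdiff(names(genome$reference), bp$sex_chrom)

  # --- coverage line of evidence ---
  depth <- simulate_depth(genome$truth, samples, seed = derive_seed(seed, 11L))
  wm <- window_means(depth, w = window, chrom_lengths = ref_lens,
                     samples = samples)
  norm <- normalize_samples(wm, samples, autosome = bp$rep_autosome)
  windows <- fm_log2_ratio(norm$wm, norm$samples, eps = eps, floor = floor)
  band <- autosome_band(windows, autosome = bp$rep_autosome, n_boot = n_boot,
                        seed = derive_seed(seed, 12L))
  windows <- classify_windows(windows, band, z_threshold = z_threshold,
                              w_threshold = w_threshold)

  # --- FST line of evidence ---
  vcf_sim <- simulate_variants(genome, samples, theta = theta,
                               n_neutral_sites = n_neutral_sites,
                               n_sexlinked_sites = n_sexlinked_sites,
                               seed = derive_seed(seed, 13L))
  comp <- site_components(vcf_sim$gt, samples$sex)
  fst_windows <- window_weighted_fst(cbind(vcf_sim$sites, comp), w = window,
                                     chrom_lengths = ref_lens)
  fst_upper <- autosomal_fst_upper(fst_windows, autosomes, prob = fst_prob)

  # --- k-mer line of evidence ---
  reads <- simulate_reads(genome, samples, read_len = read_len,
                          coverage = read_coverage, error_rate = error_rate,
                          seed = derive_seed(seed, 14L))
  fem <- samples$sex == "F"
  kmers <- sex_specific_scan(reads[fem], reads[!fem], k = k,
                             min_count = min_count,
                             min_female_frac = min_female_frac)
  hits <- map_kmers(genome$reference, kmers)
  kmer_intervals <- cluster_hits(hits, k = k, max_gap = max_gap)

  # --- haplotype comparison + hallmark annotation ---
  hapdiff <- diff_haplotypes(genome$haplotypes[["Z"]],
                             genome$haplotypes[["W"]],
                             names = c("Z", "W"))
  annotations <- annotate_calls(hapdiff, genome)

  # --- integration ---
  regions <- merge_windows(windows, merge_gap = merge_gap)
  calls <- attach_evidence(regions, fst_windows, kmer_intervals, fst_upper)

  structure(list(
    windows = windows, band = band,
    fst_windows = fst_windows, fst_upper = fst_upper,
    kmers = kmers, kmer_intervals = kmer_intervals,
    hapdiff = hapdiff, annotations = annotations,
    calls = calls, genome = genome, samples = norm$samples,
    params = list(seed = seed, window = window, n_boot = n_boot, eps = eps,
                  floor = floor, z_threshold = z_threshold,
                  w_threshold = w_threshold, k = k,
                  read_coverage = read_coverage, read_len = read_len,
                  error_rate = error_rate, min_count = min_count,
                  min_female_frac = min_female_frac, max_gap = max_gap,
                  n_neutral_sites = n_neutral_sites,
                  n_sexlinked_sites = n_sexlinked_sites, theta = theta,
                  merge_gap = merge_gap, fst_prob = fst_prob)
  ), class = "zw_scan")
}

# annotate the structural calls of a haplotype comparison with hallmark scans
annotate_calls <- function(hapdiff, genome) {
  anns <- list()
  calls <- hapdiff$calls
  for (i in seq_len(nrow(calls))) {
    if (calls$kind[i] != "insertion") next
    carrier <- calls$carrier[i]
    seq <- as.character(genome$haplotypes[[carrier]])
    ins <- substr(seq, calls$start[i] + 1L, calls$end[i])
    tir <- terminal_inverted_repeats(ins, min_len = 10L)
    tsd <- tryCatch(
      target_site_duplication(seq, calls$start[i], calls$end[i]),
      error = function(e) NULL)
    anns[[length(anns) + 1]] <- list(
      carrier = carrier, start = calls$start[i], end = calls$end[i],
      length = calls$length[i], tir = tir, tsd = tsd)
  }
  anns
}

#' @export
print.zw_scan <- function(x, ...) {
  cat("ZW sex-linked region scan (synthetic panel)\n")
  cat(sprintf("  samples: %d F + %d M\n", sum(x$samples$sex == "F"),
              sum(x$samples$sex == "M")))
  cat(sprintf("  coverage band on %s: [%.4f, %.4f]\n",
              x$band$source_chrom, x$band$lower, x$band$upper))
  cat(sprintf("  autosomal FST upper bound: %.4f\n", x$fst_upper))
  cat(sprintf("  female-specific %d-mers: %d in %d interval(s)\n",
              x$params$k, length(x$kmers), nrow(x$kmer_intervals)))
  cat(sprintf("  region calls: %d\n", nrow(x$calls)))
  if (nrow(x$calls)) {
    for (i in seq_len(nrow(x$calls))) {
      ev <- c("coverage", "fst", "kmer")[c(x$calls$ev_coverage[i],
                                           x$calls$ev_fst[i],
                                           x$calls$ev_kmer[i])]
      cat(sprintf("    %s %s:%d-%d (%d windows, peak |log2| %.2f, evidence: %s%s)\n",
                  x$calls$call[i], x$calls$chrom[i], x$calls$start[i],
                  x$calls$end[i], x$calls$n_windows[i],
                  x$calls$max_abs_log2[i], paste(ev, collapse = "+"),
                  if (x$calls$weak[i]) ", weak" else ""))
    }
  }
  invisible(x)
}

#' @export
summary.zw_scan <- function(object, ...) print(object, ...)

#' Write the report files of a scan
#'
#' Writes `windows.tsv`, `fst_windows.tsv`, `kmer_intervals.bed`,
#' `calls.tsv`, `calls.bed` and `run_metadata.json` (parameters, seed, band).
#'
#' @param scan a [zw_run()] result
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_zw_report <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
  wtsv(scan$windows, "windows.tsv")
  wtsv(scan$fst_windows, "fst_windows.tsv")
  ki <- scan$kmer_intervals
  if (nrow(ki)) {
    ki$name <- sprintf("kmers_%d", ki$n_kmers)
    write_bed(ki, file.path(dir, "kmer_intervals.bed"))
  } else file.create(file.path(dir, "kmer_intervals.bed"))
  wtsv(scan$calls, "calls.tsv")
  if (nrow(scan$calls)) {
    cb <- scan$calls
    cb$name <- cb$call
    write_bed(cb, file.path(dir, "calls.bed"))
  } else file.create(file.path(dir, "calls.bed"))
  jsonlite::write_json(list(params = scan$params,
                            band = scan$band[c("lower", "upper", "n_boot",
                                               "source_chrom", "stat")],
                            fst_upper = scan$fst_upper),
                       file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
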