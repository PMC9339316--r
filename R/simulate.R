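# Simulators for the study's input data: per-base depth tracks, read panels,
# and genotype panels, all driven by the planted truth.

#' Simulate per-base read depth from planted copy numbers
#'
#' Emulates mapped-read depth directly: for each sample and base, depth is
#' Poisson with mean `target_depth * copy_number(sex)`, where copy numbers come
#' from the truth's `cn_track` (or any data.frame with columns `chrom`,
#' `start`, `end`, `cn_F`, `cn_M` in 0-based half-open coordinates).
#'
#' @param truth a `zw_truth` (from [build_genomes()]) or a copy-number track
#'   data.frame as above.
#' @param samples sample sheet from [zw_samples()]
#' @param seed integer seed
#' @return a [data.table::data.table] in samtools-depth layout: `chrom`, `pos`
#'   (1-based), then one integer depth column per sample.
#' @export
#' @examples
#' cn <- data.frame(chrom = "c1", start = 0, end = 100, cn_F = 2, cn_M = 2)
#' d <- simulate_depth(cn, zw_samples(2, 2, 5), seed = 1)
#' dim(d)
simulate_depth <- function(truth, samples, seed = 1L) {
  cn <- if (inherits(truth, "zw_truth")) truth$cn_track else truth
  if (!all(c("chrom", "start", "end", "cn_F", "cn_M") %in% names(cn)))
    stop("truth must provide a cn_track with chrom/start/end/cn_F/cn_M")
  if (nrow(samples) == 0) stop("samples must be non-empty")
  if (any(!samples$sex %in% c("F", "M"))) stop("sample sex must be F or M")
  set.seed(derive_seed(seed, 1L))
  out <- vector("list", length(unique(cn$chrom)))
  chroms <- unique(cn$chrom)
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    seg <- cn[cn$chrom == chrom, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    L <- max(seg$end)
    cnF <- rep(rep(seg$cn_F, seg$end - seg$start), 1)
    cnM <- rep(rep(seg$cn_M, seg$end - seg$start), 1)
    dt <- data.table::data.table(chrom = chrom, pos = seq_len(L))
    for (si in seq_len(nrow(samples))) {
      cnv <- if (samples$sex[si] == "F") cnF else cnM
      dt[[samples$sample_id[si]]] <- rpois(L, samples$target_depth[si] * cnv)
    }
    out[[ci]] <- dt
  }
  data.table::rbindlist(out)
}

#' Write / read a samtools-depth-style TSV (chrom, 1-based pos, depth columns)
#' @param depth depth table from [simulate_depth()]
#' @param path output file
#' @export
write_depth <- function(depth, path) {
  data.table::fwrite(depth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_depth
#' @param sample_ids column names to use when the file has no header
#' @export
read_depth <- function(path, sample_ids = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  if (!identical(names(dt)[1:2], c("chrom", "pos"))) {
    nm <- c("chrom", "pos",
            sample_ids %||% paste0("S", seq_len(ncol(dt) - 2)))
    data.table::setnames(dt, nm)
  }
  dt
}

#' Simulate sequencing reads from the haplotypes an individual carries
#'
#' Females draw reads from Z + W + one copy of each autosome pair (two
#' identical copies); males from 2x Z + autosomes. Read start positions are
#' uniform per haplotype copy, strands random, and a per-base error rate
#' substitutes random bases. Quality strings are constant (error modelling
#' beyond uniform substitution is out of scope).
#'
#' @param genome a [build_genomes()] result
#' @param samples sample sheet
#' @param read_len read length (bp)
#' @param coverage mean depth per haploid copy (x)
#' @param error_rate per-base substitution error probability in `[0, 1)`
#' @param seed integer seed
#' @return named list (one element per sample) of character vectors of read
#'   sequences; write with [write_fastq()].
#' @export
simulate_reads <- function(genome, samples, read_len = 100L, coverage = 15,
                           error_rate = 0, seed = 1L) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  auto <- setdiff(names(genome$reference), genome$truth$blueprint$sex_chrom)
  hap <- genome$haplotypes
  pool_F <- c(as.character(hap[c("Z", "W")]),
              rep(as.character(genome$reference[auto]), each = 2))
  pool_M <- c(rep(as.character(hap["Z"]), 2),
              rep(as.character(genome$reference[auto]), each = 2))
  min_len <- min(nchar(c(pool_F, pool_M)))
  if (read_len > min_len)
    stop("read_len longer than the shortest chromosome")
  set.seed(derive_seed(seed, 2L))
  reads <- setNames(vector("list", nrow(samples)), samples$sample_id)
  for (si in seq_len(nrow(samples))) {
    pool <- if (samples$sex[si] == "F") pool_F else pool_M
    rd <- lapply(pool, function(s) {
      L <- nchar(s)
      n <- round(coverage * L / read_len)
      starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
      r <- substring(s, starts, starts + read_len - 1L)
      rc <- runif(n) < 0.5
      if (any(rc)) r[rc] <- revcomp(r[rc])
      r
    })
    rd <- unlist(rd, use.names = FALSE)
    if (error_rate > 0) {
      n_err <- rbinom(length(rd), read_len, error_rate)
      idx <- which(n_err > 0)
      for (i in idx) {
        p <- sample.int(read_len, n_err[i])
        for (p0 in p) substr(rd[i], p0, p0) <- sample(c("A", "C", "G", "T"), 1)
      }
    }
    reads[[si]] <- rd
  }
  reads
}

#' Write reads to FASTQ
#' @param reads character vector of read sequences
#' @param path output FASTQ path
#' @param sample_id read-name prefix
#' @param qual constant phred quality character
#' @export
write_fastq <- function(reads, path, sample_id = "S", qual = "I") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s_read%06d", sample_id, seq_along(reads))
  q <- Biostrings::BStringSet(strrep(qual, nchar(reads)))
  xq <- Biostrings::QualityScaledDNAStringSet(
    x, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}

#' Simulate an intersexual genotype panel and write/represent it as VCF
#'
#' Neutral biallelic sites get an ALT frequency drawn uniformly on
#' `[theta, 1 - theta]` and Hardy-Weinberg genotypes independent of sex;
#' fully sex-linked sites (inside the planted non-recombining region) make
#' every female heterozygous (Z allele / W allele, W allele = ALT) and every
#' male homozygous reference.
#'
#' @param genome a [build_genomes()] result
#' @param samples sample sheet
#' @param theta minor-allele-frequency floor for neutral sites, in (0, 0.5]
#' @param n_neutral_sites number of neutral sites (placed uniformly over
#'   regions where both sexes carry two copies)
#' @param n_sexlinked_sites number of fully sex-linked sites (placed uniformly
#'   over the non-recombining region)
#' @param sexlinked_region optional data.frame(chrom, start, end) overriding
#'   the truth's non-recombining region; requesting sex-linked sites outside
#'   the planted non-recombining region is an error
#' @param seed integer seed
#' @return object of class `zw_vcf_sim`: data.frame of sites (`chrom`, `pos`
#'   1-based, `ref`, `alt`, `sexlinked`) plus a genotype matrix (`$gt`, coded
#'   0/1/2 ALT-allele dosage). Write with [write_vcf()].
#' @export
simulate_variants <- function(genome, samples, theta = 0.05,
                              n_neutral_sites = 2000L,
                              n_sexlinked_sites = 200L,
                              sexlinked_region = NULL, seed = 1L) {
  if (theta <= 0 || theta > 0.5) stop("theta must be in (0, 0.5]")
  if (n_neutral_sites < 0) stop("n_neutral_sites must be >= 0")
  truth <- genome$truth
  cn <- truth$cn_track
  set.seed(derive_seed(seed, 3L))

  if (n_sexlinked_sites > 0) {
    reg <- sexlinked_region %||% truth$nonrec
    if (is.null(reg))
      stop("sex-linked sites requested but no non-recombining region is planted")
    if (!is.null(truth$nonrec)) {
      inside <- reg$chrom %in% truth$nonrec$chrom &
        reg$start >= truth$nonrec$start & reg$end <= truth$nonrec$end
      if (!all(inside))
        stop("sex-linked sites requested outside the planted non-recombining region")
    }
  }

  neutral_seg <- cn[cn$cn_F == 2 & cn$cn_M == 2, , drop = FALSE]
  sites <- list()
  n_F <- sum(samples$sex == "F"); n_M <- sum(samples$sex == "M")

  if (n_neutral_sites > 0) {
    wseg <- sample.int(nrow(neutral_seg), n_neutral_sites, replace = TRUE,
                       prob = neutral_seg$end - neutral_seg$start)
    pos0 <- neutral_seg$start[wseg] +
      floor(runif(n_neutral_sites) * (neutral_seg$end - neutral_seg$start)[wseg])
    p <- runif(n_neutral_sites, theta, 1 - theta)
    gt <- matrix(rbinom(n_neutral_sites * nrow(samples), 2, rep(p, nrow(samples))),
                 nrow = n_neutral_sites)
    sites$neutral <- list(chrom = neutral_seg$chrom[wseg], pos0 = pos0,
                          gt = gt, sexlinked = FALSE)
  }
  if (n_sexlinked_sites > 0) {
    reg <- sexlinked_region %||% truth$nonrec
    wseg <- sample.int(nrow(reg), n_sexlinked_sites, replace = TRUE,
                       prob = reg$end - reg$start)
    pos0 <- reg$start[wseg] +
      floor(runif(n_sexlinked_sites) * (reg$end - reg$start)[wseg])
    gt <- matrix(rep(ifelse(samples$sex == "F", 1L, 0L),
                     each = n_sexlinked_sites),
                 nrow = n_sexlinked_sites)
    sites$sexlinked <- list(chrom = reg$chrom[wseg], pos0 = pos0,
                            gt = gt, sexlinked = TRUE)
  }

  chrom <- unlist(lapply(sites, `[[`, "chrom"))
  pos0 <- unlist(lapply(sites, `[[`, "pos0"))
  sexl <- unlist(lapply(sites, function(s) rep(s$sexlinked, length(s$pos0))))
  gt <- do.call(rbind, lapply(sites, `[[`, "gt"))
  if (is.null(chrom)) {
    chrom <- character(); pos0 <- integer(); sexl <- logical()
    gt <- matrix(integer(), 0, nrow(samples))
  }
  # de-duplicate positions, sort
  key <- paste(chrom, pos0)
  keep <- !duplicated(key)
  chrom <- chrom[keep]; pos0 <- pos0[keep]; sexl <- sexl[keep]
  gt <- gt[keep, , drop = FALSE]
  ord <- order(match(chrom, names(genome$reference)), pos0)
  chrom <- chrom[ord]; pos0 <- pos0[ord]; sexl <- sexl[ord]
  gt <- gt[ord, , drop = FALSE]
  colnames(gt) <- samples$sample_id

  ref <- if (length(pos0)) {
    mapply(function(ch, p) as.character(Biostrings::subseq(
      genome$reference[[ch]], p + 1, p + 1)), chrom, pos0, USE.NAMES = FALSE)
  } else character()
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "", USE.NAMES = FALSE)

  structure(list(
    sites = data.frame(chrom = chrom, pos = pos0 + 1L, ref = ref, alt = alt,
                       sexlinked = sexl, stringsAsFactors = FALSE),
    gt = gt,
    contigs = setNames(Biostrings::width(genome$reference),
                       names(genome$reference))
  ), class = "zw_vcf_sim")
}

#' Write a simulated genotype panel as VCF v4.2 (GT only)
#' @param sim a [simulate_variants()] result
#' @param path output path
#' @export
write_vcf <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=zwscan_simulate_variants",
    sprintf("##contig=<ID=%s,length=%d>", names(sim$contigs), sim$contigs),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(sim$gt)), collapse = "\t")
  ), con)
  if (nrow(sim$sites)) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[sim$gt + 1L], nrow = nrow(sim$gt))
    gt_str[is.na(sim$gt)] <- "./."
    body <- paste(sim$sites$chrom, sim$sites$pos, ".", sim$sites$ref,
                  sim$sites$alt, ".", "PASS", ".", "GT",
                  apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
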