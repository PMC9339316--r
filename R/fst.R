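# Windowed intersexual Weir-Cockerham FST, implemented from the estimator's
# definition (two populations = the sexes; full a/b/c variance-component
# decomposition with observed heterozygosity and unequal sample sizes).

#' Per-site Weir-Cockerham variance components between two groups
#'
#' Computes the among-population (`a`), among-individuals-within-population
#' (`b`) and within-individual (`c`) variance components of the
#' Weir & Cockerham (1984) FST estimator for biallelic sites with diploid
#' genotypes, two populations, allowing missing genotypes (they reduce the
#' per-group sample size). Sites where either group has fewer than two called
#' genotypes get `NA` components (skipped, counted in attributes); sites
#' monomorphic across all samples get `(0, 0, 0)` and are flagged unusable.
#'
#' @param gt integer matrix of ALT-allele dosages (0/1/2, NA = missing),
#'   sites in rows, samples in columns
#' @param sex character vector ("F"/"M") or factor with two levels, one per
#'   sample column
#' @return data.frame with columns `a`, `b`, `c`, `usable` (polymorphic and
#'   both groups have >= 2 called genotypes); attribute `n_skipped` counts
#'   sites dropped for insufficient calls
#' @export
#' @examples
#' gt <- rbind(c(1, 1, 0, 0), c(2, 1, 0, 1))
#' site_components(gt, c("F", "F", "M", "M"))
site_components <- function(gt, sex) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  sex <- as.character(sex)
  groups <- unique(sex)
  if (length(groups) != 2) stop("need exactly two groups")
  g1 <- sex == groups[1]
  g2 <- sex == groups[2]
  r <- 2

  called1 <- !is.na(gt[, g1, drop = FALSE])
  called2 <- !is.na(gt[, g2, drop = FALSE])
  n1 <- rowSums(called1)
  n2 <- rowSums(called2)
  p1 <- rowSums(gt[, g1, drop = FALSE], na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gt[, g2, drop = FALSE], na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(gt[, g1, drop = FALSE] == 1, na.rm = TRUE) / n1
  h2 <- rowSums(gt[, g2, drop = FALSE] == 1, na.rm = TRUE) / n2

  ok <- n1 >= 2 & n2 >= 2
  nbar <- (n1 + n2) / r
  nC <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nC) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  mono <- pbar %in% c(0, 1) & hbar == 0
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  out <- data.frame(a = a, b = b, c = cc, usable = ok & !mono)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Windowed weighted FST (ratio of sums)
#'
#' Per nonoverlapping window, `weighted_fst = sum(a) / sum(a + b + c)` over
#' the usable polymorphic sites in the window; windows without usable sites
#' are missing.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based) and the component
#'   columns from [site_components()] (`a`, `b`, `c`, `usable`)
#' @param w window size (bp)
#' @param chrom_lengths optional named vector for a full tiling; defaults to
#'   windows that contain at least one site
#' @return data.table: `chrom`, `start`, `end`, `n_sites`, `sum_a`,
#'   `sum_abc`, `weighted_fst`
#' @export
window_weighted_fst <- function(sites, w = 10000L, chrom_lengths = NULL) {
  dt <- data.table::as.data.table(sites)
  dt <- dt[dt$usable %in% TRUE, ]
  dt[, start := (pos - 1L) %/% as.integer(w) * as.integer(w)]
  agg <- dt[, .(n_sites = .N, sum_a = sum(a), sum_abc = sum(a + b + c)),
            by = .(chrom, start)]
  if (!is.null(chrom_lengths)) {
    tile <- data.table::rbindlist(lapply(names(chrom_lengths), function(cn) {
      st <- seq(0L, max(0L, as.integer(chrom_lengths[[cn]]) - 1L),
                by = as.integer(w))
      data.table::data.table(chrom = cn, start = st)
    }))
    agg <- merge(tile, agg, by = c("chrom", "start"), all.x = TRUE)
    agg[is.na(n_sites), n_sites := 0L]
  }
  agg[, end := start + as.integer(w)]
  if (!is.null(chrom_lengths))
    agg[, end := pmin(end, as.integer(chrom_lengths[chrom]))]
  agg[, weighted_fst := ifelse(!is.na(sum_abc) & sum_abc > 0,
                               sum_a / sum_abc, NA_real_)]
  data.table::setcolorder(agg, c("chrom", "start", "end", "n_sites",
                                 "sum_a", "sum_abc", "weighted_fst"))
  ord <- if (!is.null(chrom_lengths)) match(agg$chrom, names(chrom_lengths))
         else agg$chrom
  agg[order(ord, start)]
}

#' Read and filter a VCF into a genotype-dosage site table
#'
#' Retains biallelic SNPs with per-site call rate at or above
#' `min_call_rate` in each sex group. Genotype calling itself is upstream and
#' out of scope; this applies post-call site filters.
#'
#' @param vcf path to a VCF (v4.2, GT required) or a `vcfR` object
#' @param samples sample sheet (`sample_id`, `sex`); must match VCF samples
#' @param min_call_rate minimum per-group fraction of called genotypes
#' @param biallelic_only drop multi-allelic records (default TRUE)
#' @return list with `sites` (data.frame chrom/pos/ref/alt), `gt` (dosage
#'   matrix, sites x samples), `sex`, and `n_input`/`n_retained` counts
#' @export
vcf_filter <- function(vcf, samples, min_call_rate = 0.8,
                       biallelic_only = TRUE) {
  v <- if (inherits(vcf, "vcfR")) vcf else
    vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(v@gt) > 0 && !"GT" %in% unlist(strsplit(v@gt[, "FORMAT"], ":")))
    stop("VCF has no GT field")
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  miss_ids <- setdiff(samples$sample_id, colnames(gt_chr))
  if (length(miss_ids))
    stop("samples absent from VCF: ", paste(miss_ids, collapse = ", "))
  gt_chr <- gt_chr[, samples$sample_id, drop = FALSE]
  n_input <- nrow(fix)

  keep <- rep(TRUE, n_input)
  if (biallelic_only)
    keep <- keep & !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
      nchar(fix$ALT) == 1
  dose <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr),
                 dimnames = dimnames(gt_chr))
  clean <- gsub("\\|", "/", gt_chr)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L

  f_cols <- samples$sex == "F"
  m_cols <- samples$sex == "M"
  call_f <- rowMeans(!is.na(dose[, f_cols, drop = FALSE]))
  call_m <- rowMeans(!is.na(dose[, m_cols, drop = FALSE]))
  keep <- keep & call_f >= min_call_rate & call_m >= min_call_rate

  list(sites = data.frame(chrom = fix$CHROM[keep],
                          pos = as.integer(fix$POS[keep]),
                          ref = fix$REF[keep], alt = fix$ALT[keep],
                          stringsAsFactors = FALSE),
       gt = dose[keep, , drop = FALSE],
       sex = samples$sex,
       n_input = n_input, n_retained = sum(keep))
}

#' Windowed intersexual FST from a VCF in one call
#'
#' Convenience wrapper: [vcf_filter()] then [site_components()] then
#' [window_weighted_fst()].
#' @inheritParams vcf_filter
#' @inheritParams window_weighted_fst
#' @return see [window_weighted_fst()]
#' @export
fst_scan <- function(vcf, samples, w = 10000L, min_call_rate = 0.8,
                     chrom_lengths = NULL) {
  flt <- vcf_filter(vcf, samples, min_call_rate = min_call_rate)
  comp <- site_components(flt$gt, flt$sex)
  window_weighted_fst(cbind(flt$sites, comp), w = w,
                      chrom_lengths = chrom_lengths)
}
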