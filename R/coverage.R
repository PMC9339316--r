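# Windowed female/male normalized-coverage analysis: per-sample window means,
# representative-autosome normalization, log2(F/M) ratios, the
# autosome-resampling confidence band, and window classification.

#' Per-sample mean depth in nonoverlapping windows
#'
#' Tiles each chromosome with nonoverlapping windows of `w` bp starting at
#' position 0 (0-based half-open). Positions absent from the depth table count
#' as depth 0; the final partial window is retained and flagged (`partial`)
#' when shorter than `w / 2`.
#'
#' @param depth depth table (`chrom`, `pos` 1-based, one column per sample),
#'   sorted by chrom then pos
#' @param w window size in bp
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the largest observed position per chromosome
#' @param samples optional sample sheet; if given, its `sample_id`s must all
#'   be depth-table columns
#' @return data.table: `chrom`, `start`, `end`, `partial`, `n_pos` (positions
#'   present in the table), then one mean-depth column per sample
#' @export
window_means <- function(depth, w = 10000L, chrom_lengths = NULL,
                         samples = NULL) {
  if (w <= 0) stop("window size must be > 0")
  depth <- data.table::as.data.table(depth)
  sample_cols <- setdiff(names(depth), c("chrom", "pos"))
  if (!is.null(samples)) {
    missing_s <- setdiff(samples$sample_id, sample_cols)
    if (length(missing_s))
      stop("unknown sample(s) not in depth table: ",
           paste(missing_s, collapse = ", "))
    sample_cols <- samples$sample_id
  }
  # sortedness check: chromosomes in contiguous blocks, positions nondecreasing
  ch <- depth$chrom
  if (anyDuplicated(rle(ch)$values))
    stop("depth table not sorted: chromosome rows are not contiguous")
  if (any(depth[, any(diff(pos) < 0), by = chrom]$V1))
    stop("depth table not sorted by position")

  lens <- chrom_lengths %||% vapply(split(depth$pos, depth$chrom), max, 0)
  pos <- NULL; chrom <- NULL  # NSE notes
  depth_w <- depth[, c("chrom", "pos", sample_cols), with = FALSE]
  depth_w[, start := (pos - 1L) %/% as.integer(w) * as.integer(w)]
  agg <- depth_w[, c(list(n_pos = .N),
                     lapply(.SD, function(x) sum(as.numeric(x)))),
                 by = .(chrom, start), .SDcols = sample_cols]

  # full tiling incl. empty windows
  tile <- data.table::rbindlist(lapply(names(lens), function(cn) {
    st <- seq(0L, max(0L, as.integer(lens[[cn]]) - 1L), by = as.integer(w))
    data.table::data.table(chrom = cn, start = st,
                           end = pmin(st + as.integer(w),
                                      as.integer(lens[[cn]])))
  }))
  out <- merge(tile, agg, by = c("chrom", "start"), all.x = TRUE)
  out[is.na(n_pos), n_pos := 0L]
  for (sc in sample_cols) {
    data.table::set(out, j = sc,
                    value = ifelse(is.na(out[[sc]]), 0, out[[sc]]) /
                      (out$end - out$start))
  }
  data.table::set(out, j = "partial", value = (out$end - out$start) < w / 2)
  data.table::setcolorder(out, c("chrom", "start", "end", "partial", "n_pos",
                                 sample_cols))
  out[order(match(chrom, names(lens)), start)]
}

#' Normalize per-sample window means by a representative autosome
#'
#' Divides every sample's window means by that sample's mean depth over the
#' representative autosome (window means weighted by window width, i.e. the
#' per-base mean), so each sample's normalized mean over that autosome is 1.
#'
#' @param wm window means from [window_means()]
#' @param samples sample sheet; `norm_factor` is filled in the returned copy
#' @param autosome representative autosome name
#' @return list with `wm` (normalized window means) and `samples` (sheet with
#'   `norm_factor` filled)
#' @export
normalize_samples <- function(wm, samples, autosome) {
  if (!autosome %in% wm$chrom)
    stop("representative autosome ", autosome, " not present in windows")
  wm <- data.table::copy(data.table::as.data.table(wm))
  a <- wm[wm$chrom == autosome, ]
  width <- a$end - a$start
  for (si in seq_len(nrow(samples))) {
    id <- samples$sample_id[si]
    nf <- sum(a[[id]] * width) / sum(width)
    if (nf <= 0)
      stop("zero depth on representative autosome for sample ", id)
    samples$norm_factor[si] <- nf
    wm[[id]] <- wm[[id]] / nf
  }
  list(wm = wm, samples = samples)
}

#' Windowed log2(female/male) normalized depth ratio
#'
#' @param wm normalized window means ([normalize_samples()] output `$wm`)
#' @param samples sample sheet with `sex`
#' @param eps symmetric pseudo-count added to both group means before the
#'   ratio, in normalized-depth units (keeps hemizygous spikes finite)
#' @param floor minimum-depth floor: windows where both group means fall
#'   below it are classed `missing`
#' @return data.table of window statistics: `chrom`, `start`, `end`,
#'   `partial`, `mean_F`, `mean_M`, `log2_ratio`, `class` (NA until
#'   [classify_windows()]; "missing" for floored windows)
#' @export
fm_log2_ratio <- function(wm, samples, eps = 0.001, floor = 0.1) {
  f_ids <- samples$sample_id[samples$sex == "F"]
  m_ids <- samples$sample_id[samples$sex == "M"]
  if (!length(f_ids) || !length(m_ids))
    stop("need at least one sample of each sex")
  wm <- data.table::as.data.table(wm)
  mean_F <- rowMeans(as.matrix(wm[, f_ids, with = FALSE]))
  mean_M <- rowMeans(as.matrix(wm[, m_ids, with = FALSE]))
  out <- wm[, .(chrom, start, end, partial)]
  out[, mean_F := mean_F]
  out[, mean_M := mean_M]
  # difference of logs, so exchanging the sex labels negates the statistic
  # exactly (bit-for-bit), not just approximately
  out[, log2_ratio := log2(mean_F + eps) - log2(mean_M + eps)]
  out[, class := NA_character_]
  miss <- mean_F < floor & mean_M < floor
  out[miss, `:=`(log2_ratio = NA_real_, class = "missing")]
  out[]
}

#' Autosome-resampling confidence band for the log2 ratio
#'
#' Bootstrap-resamples the representative autosome's nonmissing window log2
#' values with replacement `n_boot` times (resample size = number of windows).
#' With `stat = "windows"` (default) the band is the mean over replicates of
#' each replicate's 2.5th/97.5th percentiles; with `stat = "mean"` it is the
#' 2.5th/97.5th percentile of the replicate means.
#'
#' @param windows window statistics from [fm_log2_ratio()]
#' @param autosome representative autosome name
#' @param n_boot number of bootstrap replicates
#' @param seed integer seed
#' @param stat resampling summary, `"windows"` or `"mean"`
#' @param level confidence level (default 0.95)
#' @return object of class `zw_band`: list(lower, upper, n_boot, source_chrom,
#'   seed, stat, level)
#' @export
autosome_band <- function(windows, autosome, n_boot = 1000L, seed = 1L,
                          stat = c("windows", "mean"), level = 0.95) {
  stat <- match.arg(stat)
  x <- windows$log2_ratio[windows$chrom == autosome &
                            !is.na(windows$log2_ratio) & !windows$partial]
  if (length(x) < 10)
    stop("need at least 10 nonmissing windows on the representative autosome")
  if (n_boot < 1) stop("n_boot must be >= 1")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  set.seed(derive_seed(seed, 4L))
  n <- length(x)
  qs <- matrix(NA_real_, n_boot, 2)
  mu <- numeric(n_boot)
  # type-6 quantiles (plotting position (n+1)p) keep the band at its nominal
  # level for modest window counts; the default type places the 2.5th/97.5th
  # percentiles inside the extreme order statistics and over-covers the tails
  for (b in seq_len(n_boot)) {
    xb <- x[sample.int(n, n, replace = TRUE)]
    qs[b, ] <- quantile(xb, probs, names = FALSE, type = 6)
    mu[b] <- mean(xb)
  }
  band <- if (stat == "windows") colMeans(qs) else
    quantile(mu, probs, names = FALSE, type = 6)
  structure(list(lower = band[1], upper = band[2], n_boot = as.integer(n_boot),
                 source_chrom = autosome, seed = as.integer(seed),
                 stat = stat, level = level),
            class = "zw_band")
}

#' @export
print.zw_band <- function(x, ...) {
  cat(sprintf("log2-ratio %g%% band from %d-fold resampling of %s: [%.4f, %.4f]\n",
              100 * x$level, x$n_boot, x$source_chrom, x$lower, x$upper))
  invisible(x)
}

#' Classify windows as W-specific / Z-specific / PAR-autosomal / ambiguous
#'
#' W-specific: log2 above the band *and* at or above the hard W-call
#' threshold (hemizygous W windows sit far above 0, so band exceedance alone
#' would over-call diploid noise); Z-specific: log2 below the band *and* at
#' or below the hard Z-call threshold (hemizygous expectation is -1, so
#' mildly low windows are not over-called); PAR/autosomal: within the band;
#' ambiguous: beyond the band but inside the hard thresholds. Windows already
#' classed `missing` are untouched.
#'
#' @param windows window statistics from [fm_log2_ratio()]
#' @param band a [autosome_band()] result
#' @param z_threshold hard log2 threshold for a Z-specific call
#' @param w_threshold hard log2 threshold for a W-specific call
#' @return `windows` with `class` filled
#' @export
classify_windows <- function(windows, band, z_threshold = -0.5,
                             w_threshold = 0.5) {
  w <- data.table::copy(data.table::as.data.table(windows))
  x <- w$log2_ratio
  cls <- ifelse(is.na(x), "missing",
         ifelse(x > band$upper & x >= w_threshold, "W-specific",
         ifelse(x < band$lower & x <= z_threshold, "Z-specific",
         ifelse(x >= band$lower & x <= band$upper, "PAR/autosomal",
                "ambiguous"))))
  w[, class := cls]
  w[]
}

#' Fraction of repeat-covered bases per window
#'
#' @param repeats repeat intervals: data.frame(chrom, start, end) 0-based
#'   half-open, or a GRanges, or a BED path (read via [read_bed()])
#' @param windows window table (chrom, start, end)
#' @return numeric vector, one value in `[0, 1]` per window row
#' @export
repeat_density <- function(repeats, windows) {
  if (is.character(repeats)) repeats <- read_bed(repeats)
  if (methods::is(repeats, "GRanges")) {
    repeats <- data.frame(chrom = as.character(GenomicRanges::seqnames(repeats)),
                          start = GenomicRanges::start(repeats) - 1L,
                          end = GenomicRanges::end(repeats))
  }
  dens <- numeric(nrow(windows))
  for (cn in unique(windows$chrom)) {
    wi <- which(windows$chrom == cn)
    r <- repeats[repeats$chrom == cn, , drop = FALSE]
    if (!nrow(r)) next
    rr <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
    wr <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    ov <- IRanges::findOverlaps(wr, rr)
    if (!length(ov)) next
    inter <- IRanges::pintersect(wr[S4Vectors::queryHits(ov)],
                                 rr[S4Vectors::subjectHits(ov)])
    cov <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    dens[wi[as.integer(names(cov))]] <-
      cov / IRanges::width(wr)[as.integer(names(cov))]
  }
  dens
}
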