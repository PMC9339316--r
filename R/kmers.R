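# Sex-specific canonical k-mer detection and localization. Counting is done
# in compiled code on 2-bit-encoded canonical k-mers (k <= 31); localization
# uses Biostrings dictionary matching.

as_read_seqs <- function(x) {
  # treat as FASTQ paths only if the first element cannot be a DNA sequence
  if (is.character(x) && length(x) && !grepl("^[ACGTNacgtn]*$", x[1]) &&
      all(file.exists(x))) {
    x <- unlist(lapply(x, function(p)
      as.character(Biostrings::readDNAStringSet(p, format = "fastq"))),
      use.names = FALSE)
  } else if (methods::is(x, "XStringSet")) {
    x <- as.character(x)
  }
  unname(x)
}

check_k <- function(k) {
  if (k %% 2 == 0) stop("k must be odd (so no k-mer is its own reverse complement)")
  if (k < 1 || k > 31) stop("k must be between 1 and 31")
  as.integer(k)
}

#' Canonical k-mer presence set of a read set
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) in a set of reads and returns those seen at least `min_count`
#' times. K-mers containing non-ACGT characters are skipped.
#'
#' @param reads character vector of read sequences, a DNAStringSet, or one or
#'   more FASTQ paths
#' @param k k-mer length (odd, <= 31)
#' @param min_count minimum count for a k-mer to be called present
#' @return sorted character vector of canonical k-mers
#' @export
#' @examples
#' count_kmers("ACGTA", k = 3)
count_kmers <- function(reads, k = 31L, min_count = 1L) {
  k <- check_k(k)
  .cpp_count_kmers(as_read_seqs(reads), k, as.integer(min_count))
}

#' Female-specific k-mers from per-sample presence panels
#'
#' Retains k-mers present in at least `min_female_presence` female panels and
#' in at most `max_male_presence` male panels (default 0: absent from every
#' male).
#'
#' @param panels_f,panels_m lists of per-sample canonical k-mer presence sets
#'   (character vectors, e.g. from [count_kmers()])
#' @param min_female_presence minimum number of female panels containing the
#'   k-mer
#' @param max_male_presence maximum number of male panels containing it
#' @return sorted character vector of sex-specific canonical k-mers
#' @export
sex_specific <- function(panels_f, panels_m, min_female_presence,
                         max_male_presence = 0L) {
  if (!length(panels_f) || !length(panels_m))
    stop("need at least one panel per sex")
  if (min_female_presence > length(panels_f))
    stop("min_female_presence exceeds the number of female panels")
  univ <- unique(unlist(panels_f, use.names = FALSE))
  nf <- rowSums(vapply(panels_f, function(p) univ %in% p,
                       logical(length(univ))))
  nm <- rowSums(vapply(panels_m, function(p) univ %in% p,
                       logical(length(univ))))
  sort(univ[nf >= min_female_presence & nm <= max_male_presence])
}

#' Stream per-sample read sets into a sex-specific k-mer scan
#'
#' Memory-light equivalent of [count_kmers()] + [sex_specific()]: samples are
#' processed one at a time through a compiled presence accumulator.
#'
#' @param reads_f,reads_m lists of per-sample read sets (each element accepted
#'   by [count_kmers()]: character vector, DNAStringSet, or FASTQ path(s))
#' @param k k-mer length (odd, <= 31)
#' @param min_count per-sample minimum count to call a k-mer present
#' @param min_female_frac minimum fraction of females that must carry a k-mer
#'   (converted to a count with `ceiling`)
#' @param max_male_presence maximum number of male panels carrying it
#' @return sorted character vector of female-specific canonical k-mers
#' @export
sex_specific_scan <- function(reads_f, reads_m, k = 31L, min_count = 2L,
                              min_female_frac = 0.9, max_male_presence = 0L) {
  k <- check_k(k)
  if (!length(reads_f) || !length(reads_m))
    stop("need at least one read set per sex")
  min_female <- as.integer(ceiling(min_female_frac * length(reads_f)))
  acc <- .cpp_kmer_acc_new(k)
  for (r in reads_f)
    .cpp_kmer_acc_add(acc, as_read_seqs(r), as.integer(min_count), TRUE)
  for (r in reads_m)
    .cpp_kmer_acc_add(acc, as_read_seqs(r), as.integer(min_count), FALSE)
  .cpp_kmer_acc_select(acc, min_female, as.integer(max_male_presence))
}

#' Localize a k-mer set on an assembly (strandless exact matching)
#'
#' Reports every exact occurrence of each k-mer or of its reverse complement
#' (canonical matching) on the assembly.
#'
#' @param assembly a DNAStringSet or FASTA path
#' @param kmers character vector of k-mers (equal length)
#' @return data.frame: `kmer`, `chrom`, `pos` (0-based occurrence start),
#'   `n_hits` (total occurrences of that k-mer genome-wide; > 1 flags
#'   multi-hit k-mers)
#' @export
map_kmers <- function(assembly, kmers) {
  if (is.character(assembly) && length(assembly) == 1 && file.exists(assembly))
    assembly <- Biostrings::readDNAStringSet(assembly)
  if (!length(kmers))
    return(data.frame(kmer = character(), chrom = character(),
                      pos = integer(), n_hits = integer()))
  if (length(unique(nchar(kmers))) != 1)
    stop("k-mers must have equal length")
  ks <- Biostrings::DNAStringSet(kmers)
  pd_f <- Biostrings::PDict(ks)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(ks))
  hits <- list()
  for (ci in seq_along(assembly)) {
    subj <- assembly[[ci]]
    for (pd in list(pd_f, pd_r)) {
      m <- Biostrings::matchPDict(pd, subj)
      n_per <- S4Vectors::elementNROWS(m)
      if (!sum(n_per)) next
      idx <- rep(seq_along(n_per), n_per)
      hits[[length(hits) + 1]] <- data.frame(
        kmer = kmers[idx], chrom = names(assembly)[ci],
        pos = BiocGenerics::start(unlist(m)) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(kmer = character(), chrom = character(),
                      pos = integer(), n_hits = integer()))
  out <- do.call(rbind, hits)
  # a k-mer matching both strands at one site is impossible for odd k, but
  # collapse any duplicate (kmer, chrom, pos) defensively
  out <- out[!duplicated(out[c("kmer", "chrom", "pos")]), ]
  tab <- table(out$kmer)
  out$n_hits <- as.integer(tab[out$kmer])
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Cluster k-mer hit positions into maximal intervals
#'
#' Maximal runs of sorted hit positions where consecutive hits are at most
#' `max_gap` apart; each run becomes the strandless interval
#' `[first hit, last hit + k)`.
#'
#' @param hits data.frame from [map_kmers()] (needs `chrom`, `pos`, `kmer`)
#' @param k k-mer length
#' @param max_gap maximum distance (bp) between consecutive hits in a cluster
#' @return data.frame: `chrom`, `start`, `end`, `n_kmers` (distinct k-mers
#'   supporting the interval)
#' @export
cluster_hits <- function(hits, k, max_gap = 5000L) {
  if (!nrow(hits))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_kmers = integer()))
  out <- list()
  for (cn in unique(hits$chrom)) {
    h <- hits[hits$chrom == cn, , drop = FALSE]
    h <- h[order(h$pos), , drop = FALSE]
    grp <- cumsum(c(1L, diff(h$pos) > max_gap))
    for (g in split(h, grp)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = cn, start = min(g$pos), end = max(g$pos) + as.integer(k),
        n_kmers = length(unique(g$kmer)), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
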