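# Structural-hallmark scanners: telomere arrays, terminal inverted repeats,
# target-site duplications, LTR direct repeats, retrogene poly-A signatures,
# large palindromes, and repeat-content summaries. Coordinates 0-based
# half-open throughout.

seq_chars <- function(x) strsplit(as.character(x), "")[[1]]

#' All strand/rotation variants of a telomere repeat motif
#'
#' Returns every circular rotation of the motif and of its reverse
#' complement, deduplicated. For the canonical plant telomere repeat
#' `CCCTAAA` this yields 14 variants.
#'
#' @param motif repeat motif (ACGT only)
#' @return character vector of variant motifs
#' @export
#' @examples
#' length(telomere_variants("CCCTAAA"))  # 14
telomere_variants <- function(motif) {
  motif <- toupper(motif)
  if (!nzchar(motif) || !grepl("^[ACGT]+$", motif))
    stop("motif must be non-empty and ACGT only")
  n <- nchar(motif)
  rot <- function(s) vapply(seq_len(n) - 1L, function(i)
    paste0(substr(s, i + 1, n), substr(s, 1, i)), "")
  unique(c(rot(motif), rot(revcomp(motif))))
}

#' Find telomere repeat arrays in a sequence
#'
#' Scans for maximal runs of (possibly phase-shifted) telomere motif-variant
#' matches: bases covered by any variant occurrence are merged into maximal
#' intervals, and intervals at least `min_array_len` long are reported.
#' Arrays whose edge lies within `terminal_dist` of a sequence end are
#' classified terminal, the rest interstitial.
#'
#' @param seq sequence (character or DNAString)
#' @param motif telomere motif (variants generated internally)
#' @param min_array_len minimum array length (bp); the default reports
#'   arrays longer than 750 bp, the usual threshold for assembled telomeres
#' @param terminal_dist distance (bp) from a sequence end within which an
#'   array counts as terminal
#' @return data.frame: `kind`, `start`, `end`, `length`, `terminal`
#' @export
find_telomere_arrays <- function(seq, motif = "CCCTAAA", min_array_len = 750L,
                                 terminal_dist = 1000L) {
  if (min_array_len < nchar(motif))
    stop("min_array_len must be >= motif length")
  subj <- if (methods::is(seq, "DNAString")) seq else
    Biostrings::DNAString(as.character(seq))
  vars <- telomere_variants(motif)
  cov <- IRanges::IRanges()
  for (v in vars) {
    m <- Biostrings::matchPattern(v, subj)
    if (length(m))
      cov <- c(cov, IRanges::IRanges(BiocGenerics::start(m),
                                     BiocGenerics::end(m)))
  }
  cov <- IRanges::reduce(cov)
  cov <- cov[IRanges::width(cov) >= min_array_len]
  if (!length(cov))
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      length = integer(), terminal = logical()))
  st <- BiocGenerics::start(cov) - 1L
  en <- BiocGenerics::end(cov)
  L <- length(subj)
  data.frame(kind = "telomere", start = st, end = en, length = en - st,
             terminal = st <= terminal_dist | (L - en) <= terminal_dist)
}

#' Terminal inverted repeats of an insertion sequence
#'
#' Longest prefix whose reverse complement matches the sequence's suffix
#' within `max_mismatch` mismatches (arms do not overlap).
#'
#' @param seq insertion sequence
#' @param min_len minimum arm length to report
#' @param max_mismatch mismatch budget (default 0: exact)
#' @return list(arm_len, mismatches, arm1 = c(start, end),
#'   arm2 = c(start, end)) or `NULL` if no arm of at least `min_len`
#' @export
terminal_inverted_repeats <- function(seq, min_len = 10L, max_mismatch = 0L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n <= 2 * min_len) stop("insertion shorter than twice min_len")
  x <- seq_chars(seq)
  y <- seq_chars(revcomp(seq))
  lmax <- n %/% 2L
  mism <- cumsum(x[1:lmax] != y[1:lmax])
  ok <- which(mism <= max_mismatch)
  if (!length(ok)) return(NULL)
  l <- max(ok)
  if (l < min_len) return(NULL)
  list(arm_len = l, mismatches = unname(mism[l]),
       arm1 = c(0L, l), arm2 = c(n - l, n))
}

#' Target-site duplication flanking an insertion
#'
#' On the carrier sequence (insertion present), finds the longest exact
#' direct repeat with `min_len <= length <= max_len` whose copies immediately
#' abut the insertion's outer 5' and outer 3' sides.
#'
#' @param seq carrier sequence
#' @param ins_start,ins_end insertion interval (0-based half-open); equal
#'   values probe an insertion point on an un-inserted sequence
#' @param min_len,max_len length bounds for the duplication
#' @return list(motif, length, left = c(start, end), right = c(start, end))
#'   or `NULL`
#' @export
target_site_duplication <- function(seq, ins_start, ins_end, min_len = 2L,
                                    max_len = 20L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (ins_start < max_len || ins_end + max_len > n)
    stop("need at least max_len of flank on both sides of the insertion")
  best <- NULL
  for (l in seq(min_len, max_len)) {
    left <- substr(seq, ins_start - l + 1L, ins_start)
    right <- substr(seq, ins_end + 1L, ins_end + l)
    if (identical(left, right)) best <- l
  }
  if (is.null(best)) return(NULL)
  list(motif = substr(seq, ins_start - best + 1L, ins_start), length = best,
       left = c(ins_start - best, ins_start),
       right = c(ins_end, ins_end + best))
}

#' Long terminal repeat (LTR) pair of a retroelement
#'
#' Finds the highest-scoring near-identical same-strand repeat pair with one
#' arm at each element terminus, by local alignment of the element's terminal
#' windows, and classifies the element's flanking dinucleotides
#' (first two / last two bases) as canonical (`TG.CA`) or not.
#'
#' @param element element sequence
#' @param min_len minimum arm length (bp)
#' @param window terminal window searched at each end (default
#'   `min(floor(len/2), 2000)`)
#' @return list(arm_lens = c(5' arm, 3' arm), edits (mismatches + inserted /
#'   deleted bases), arm1, arm2 (0-based intervals), flank ("XX.YY"),
#'   canonical) or `NULL`
#' @export
ltr_direct_repeats <- function(element, min_len = 100L, window = NULL) {
  element <- toupper(as.character(element))
  n <- nchar(element)
  if (n <= 2 * min_len) stop("element shorter than twice min_len")
  wl <- window %||% min(n %/% 2L, 2000L)
  pre <- Biostrings::DNAString(substr(element, 1, wl))
  suf <- Biostrings::DNAString(substr(element, n - wl + 1L, n))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(pre, suf, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  pr <- pa@pattern@range
  sr <- pa@subject@range
  arm1_len <- BiocGenerics::width(pr)
  arm2_len <- BiocGenerics::width(sr)
  if (arm1_len < min_len || arm2_len < min_len) return(NULL)
  edits <- Biostrings::nmismatch(pa) +
    sum(unlist(Biostrings::nindel(pa)@insertion[, "WidthSum"]),
        unlist(Biostrings::nindel(pa)@deletion[, "WidthSum"]))
  flank <- paste0(substr(element, 1, 2), ".", substr(element, n - 1L, n))
  list(arm_lens = c(arm1_len, arm2_len), edits = edits,
       arm1 = c(BiocGenerics::start(pr) - 1L, BiocGenerics::end(pr)),
       arm2 = c(n - wl + BiocGenerics::start(sr) - 1L,
                n - wl + BiocGenerics::end(sr)),
       flank = flank, canonical = identical(flank, "TG.CA"))
}

#' Retrotransposition hallmarks around a candidate retrogene
#'
#' Reports (i) the longest A-run of at least `polyA_min_len` within
#' `polyA_window` bp downstream of the CDS stop codon, with its offset from
#' the stop, and (ii) the longest exact direct-repeat pair of at least
#' `dr_min_len` with one copy within `dr_search_window` downstream of the
#' poly-A and one within `dr_search_window` upstream of the start codon.
#' The region is "retro-hallmark positive" iff both are found.
#'
#' @param seq sequence containing the gene
#' @param cds_start,cds_end CDS interval (0-based half-open)
#' @param polyA_min_len minimum A-run length
#' @param polyA_window search window downstream of the stop codon (bp)
#' @param dr_min_len minimum direct-repeat length
#' @param dr_search_window search window on each side (bp)
#' @return list(polyA = list(start, end, length, offset) or NULL,
#'   direct_repeat = list(motif, length, upstream, downstream,
#'   upstream_offset, downstream_offset) or NULL, positive)
#' @export
retrogene_scan <- function(seq, cds_start, cds_end, polyA_min_len = 10L,
                           polyA_window = 500L, dr_min_len = 8L,
                           dr_search_window = 500L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (cds_start < 0 || cds_end > n || cds_start >= cds_end)
    stop("cds interval outside the sequence")
  res <- list(polyA = NULL, direct_repeat = NULL, positive = FALSE)

  win_end <- min(n, cds_end + polyA_window)
  down <- substr(seq, cds_end + 1L, win_end)
  r <- rle(seq_chars(down))
  if (length(r$lengths)) {
    a_runs <- which(r$values == "A" & r$lengths >= polyA_min_len)
    if (length(a_runs)) {
      best <- a_runs[which.max(r$lengths[a_runs])]
      off <- if (best > 1) sum(r$lengths[1:(best - 1)]) else 0L
      res$polyA <- list(start = cds_end + off,
                        end = cds_end + off + r$lengths[best],
                        length = unname(r$lengths[best]), offset = off)
    }
  }
  if (!is.null(res$polyA)) {
    up_start <- max(0L, cds_start - dr_search_window)
    up <- substr(seq, up_start + 1L, cds_start)
    dn_start <- res$polyA$end
    dn <- substr(seq, dn_start + 1L, min(n, dn_start + dr_search_window))
    lcs <- longest_common_substring(up, dn)
    if (!is.null(lcs) && lcs$length >= dr_min_len) {
      us <- up_start + lcs$start1
      ds <- dn_start + lcs$start2
      res$direct_repeat <- list(
        motif = lcs$string, length = lcs$length,
        upstream = c(us, us + lcs$length),
        downstream = c(ds, ds + lcs$length),
        upstream_offset = cds_start - (us + lcs$length),
        downstream_offset = ds - dn_start)
    }
  }
  res$positive <- !is.null(res$polyA) && !is.null(res$direct_repeat)
  res
}

# longest exact common substring of two strings (0-based starts), via local
# alignment with prohibitive mismatch/gap penalties
longest_common_substring <- function(s1, s2) {
  if (!nzchar(s1) || !nzchar(s2)) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1e6,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(s1),
                                      Biostrings::DNAString(s2),
                                      type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 1e6, gapExtension = 1e6)
  w <- BiocGenerics::width(pa@pattern@range)
  if (w < 1) return(NULL)
  list(string = as.character(pa@pattern),
       length = w,
       start1 = BiocGenerics::start(pa@pattern@range) - 1L,
       start2 = BiocGenerics::start(pa@subject@range) - 1L)
}

#' Find large palindromes (inverted repeat pairs) in a sequence
#'
#' Matches seed k-mers of the sequence against its reverse complement,
#' merges seeds along anti-diagonals into maximal exact inverted-repeat
#' runs, and reports arm pairs with arm length at least `min_arm` and
#' spacer at most `max_spacer`.
#'
#' @param seq sequence
#' @param min_arm minimum arm length (bp, >= 20)
#' @param max_spacer maximum separation between arms (bp)
#' @param seed_k seed length (odd; default 19)
#' @return data.frame: `arm1_start`, `arm1_end`, `arm2_start`, `arm2_end`,
#'   `arm_len`, `spacer`
#' @export
find_palindromes <- function(seq, min_arm = 1000L, max_spacer = 2000L,
                             seed_k = 19L) {
  if (min_arm < 20) stop("min_arm must be >= 20 (seeded search)")
  if (max_spacer < 0) stop("max_spacer must be >= 0")
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  empty <- data.frame(arm1_start = integer(), arm1_end = integer(),
                      arm2_start = integer(), arm2_end = integer(),
                      arm_len = integer(), spacer = integer())
  if (n < 2 * min_arm) return(empty)
  k <- as.integer(seed_k)
  ks <- kmer_starts(seq, k)
  kr <- kmer_starts(revcomp(seq), k)
  # position j on the forward strand of the k-mer at revcomp position j'
  jmap <- (n - k):0
  u1 <- !(duplicated(ks) | duplicated(ks, fromLast = TRUE))
  u2 <- !(duplicated(kr) | duplicated(kr, fromLast = TRUE))
  i_idx <- which(u1)
  m <- match(ks[i_idx], kr)
  keep <- !is.na(m) & u2[m]
  i <- i_idx[keep] - 1L
  j <- jmap[m[keep]]
  keep2 <- j > i
  i <- i[keep2]; j <- j[keep2]
  if (!length(i)) return(empty)
  d <- i + j
  out <- list()
  for (dv in unique(d)) {
    ii <- sort(i[d == dv])
    run <- cumsum(c(1L, diff(ii) != 1L))
    for (g in split(ii, run)) {
      i0 <- min(g); i1 <- max(g)
      arm_len <- i1 - i0 + k
      arm2_start <- dv - i1
      spacer <- arm2_start - (i0 + arm_len)
      if (arm_len >= min_arm && spacer >= 0 && spacer <= max_spacer) {
        out[[length(out) + 1]] <- data.frame(
          arm1_start = i0, arm1_end = i0 + arm_len,
          arm2_start = arm2_start, arm2_end = arm2_start + arm_len,
          arm_len = arm_len, spacer = spacer)
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$arm1_start), , drop = FALSE]
}

#' Fraction of a sequence covered by repeat intervals
#'
#' @param seq_len sequence length (bp)
#' @param repeats data.frame(start, end) 0-based half-open (a `chrom` column
#'   is ignored), or a BED path
#' @return fraction in `[0, 1]` (overlapping intervals counted once)
#' @export
repeat_fraction <- function(seq_len, repeats) {
  if (is.character(repeats)) repeats <- read_bed(repeats)
  if (methods::is(repeats, "GRanges"))
    repeats <- data.frame(start = GenomicRanges::start(repeats) - 1L,
                          end = GenomicRanges::end(repeats))
  if (!nrow(repeats)) return(0)
  if (any(repeats$start < 0 | repeats$end > seq_len))
    stop("repeat interval outside the sequence")
  rr <- IRanges::reduce(IRanges::IRanges(repeats$start + 1L, repeats$end))
  sum(IRanges::width(rr)) / seq_len
}
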