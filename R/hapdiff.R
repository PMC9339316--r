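# Z/W haplotype structural comparison by unique-anchor chaining: exact
# k-mers unique in both sequences are merged into maximal runs, chained into
# the best collinear set, and the gaps between consecutive anchors are
# interpreted as haplotype-specific insertions or divergent regions.

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

#' Maximal unique exact anchors between two sequences
#'
#' Finds k-mers occurring exactly once in each sequence and matching across
#' them (same strand), and merges runs of consecutive k-mers into maximal
#' exact anchors.
#'
#' @param seqA,seqB sequences (character or DNAString)
#' @param anchor_k anchor seed length (>= 15)
#' @return data.frame: `posA`, `posB` (0-based starts), `length` (bp)
#' @export
unique_anchors <- function(seqA, seqB, anchor_k = 21L) {
  if (anchor_k < 15) stop("anchor_k must be >= 15")
  seqA <- as.character(seqA); seqB <- as.character(seqB)
  ka <- kmer_starts(seqA, anchor_k)
  kb <- kmer_starts(seqB, anchor_k)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  posA <- which(ua)
  m <- match(ka[posA], kb)
  keep <- !is.na(m) & ub[m]
  posA <- posA[keep] - 1L           # to 0-based
  posB <- m[keep] - 1L
  if (!length(posA))
    return(data.frame(posA = integer(), posB = integer(), length = integer()))
  ord <- order(posA)
  posA <- posA[ord]; posB <- posB[ord]
  # merge runs where both coordinates advance by 1
  run <- cumsum(c(1L, (diff(posA) != 1L) | (diff(posB) != 1L)))
  starts <- !duplicated(run)
  lens <- as.integer(table(run)) + anchor_k - 1L
  data.frame(posA = posA[starts], posB = posB[starts], length = lens)
}

#' Best collinear anchor chain (weighted longest increasing subsequence)
#'
#' Selects the subset of anchors with the highest total anchor length that is
#' strictly increasing and nonoverlapping in both coordinates; ties broken
#' toward the chain whose anchors start earlier on the first sequence.
#'
#' @param anchors data.frame from [unique_anchors()]
#' @param max_overlap small anchor overlap tolerated when chaining (bp);
#'   chance single-base extensions at insertion junctions can make adjacent
#'   anchors overlap slightly
#' @return list of class `zw_chain`: `anchors` (the chained subset) and
#'   `collinear` (TRUE if no anchor was dropped)
#' @export
chain_anchors <- function(anchors, max_overlap = 10L) {
  n <- nrow(anchors)
  if (n == 0)
    return(structure(list(anchors = anchors, collinear = TRUE),
                     class = "zw_chain"))
  a <- anchors[order(anchors$posA, anchors$posB), , drop = FALSE]
  best <- as.numeric(a$length)   # best chain weight ending at i
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- a$posA[j] < a$posA[i] && a$posB[j] < a$posB[i] &&
        a$posA[j] + a$length[j] - max_overlap <= a$posA[i] &&
        a$posB[j] + a$length[j] - max_overlap <= a$posB[i]
      if (ok && best[j] + a$length[i] > best[i]) {
        best[i] <- best[j] + a$length[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)   # ties: earliest index = smallest posA
  sel <- integer(0)
  while (!is.na(i)) { sel <- c(i, sel); i <- prev[i] }
  structure(list(anchors = a[sel, , drop = FALSE],
                 collinear = length(sel) == n),
            class = "zw_chain")
}

#' Call haplotype-specific insertions from an anchor chain
#'
#' Between consecutive chained anchors, a near-zero gap on one sequence with a
#' gap of at least `min_len` on the other is an insertion on the latter
#' (carrier); when both gaps are at least `min_len` the gap is reported as a
#' divergent region, not an insertion.
#'
#' @param chain a [chain_anchors()] result
#' @param min_len minimum insertion length (bp)
#' @param gap_eps gap size still treated as "approximately zero" (bp);
#'   defaults to the anchor seed length's order, 25 bp
#' @param names length-2 character: names of sequences A and B (used as
#'   carrier labels)
#' @return data.frame: `kind` ("insertion"/"divergent"), `carrier`,
#'   `start`, `end` (0-based half-open on the carrier), `length`,
#'   `pos_other` (insertion point on the other sequence)
#' @export
call_indels <- function(chain, min_len = 50L, gap_eps = 25L,
                        names = c("A", "B")) {
  a <- chain$anchors
  out <- data.frame(kind = character(), carrier = character(),
                    start = integer(), end = integer(), length = integer(),
                    pos_other = integer(), stringsAsFactors = FALSE)
  if (nrow(a) < 2) return(out)
  for (i in seq_len(nrow(a) - 1L)) {
    endA <- a$posA[i] + a$length[i]; endB <- a$posB[i] + a$length[i]
    gapA <- a$posA[i + 1L] - endA
    gapB <- a$posB[i + 1L] - endB
    if (gapA <= gap_eps && gapB >= min_len) {
      out <- rbind(out, data.frame(kind = "insertion", carrier = names[2],
                                   start = endB, end = a$posB[i + 1L],
                                   length = gapB, pos_other = endA))
    } else if (gapB <= gap_eps && gapA >= min_len) {
      out <- rbind(out, data.frame(kind = "insertion", carrier = names[1],
                                   start = endA, end = a$posA[i + 1L],
                                   length = gapA, pos_other = endB))
    } else if (gapA >= min_len && gapB >= min_len) {
      out <- rbind(out, data.frame(kind = "divergent", carrier = NA_character_,
                                   start = endA, end = a$posA[i + 1L],
                                   length = max(gapA, gapB), pos_other = endB))
    }
  }
  out
}

#' Compare two haplotype sequences end to end
#'
#' [unique_anchors()] + [chain_anchors()] + [call_indels()] in one call.
#'
#' @inheritParams unique_anchors
#' @inheritParams call_indels
#' @return list of class `zw_hapdiff`: `calls` (see [call_indels()]),
#'   `chain`, and `anchors`
#' @export
#' @examples
#' a <- strrep("ACGTTGCA", 40)
#' diff_haplotypes(a, paste0(substr(a, 1, 100), "T", substr(a, 101, 320)))
diff_haplotypes <- function(seqA, seqB, anchor_k = 21L, min_len = 50L,
                            gap_eps = 25L, names = c("A", "B")) {
  anchors <- unique_anchors(seqA, seqB, anchor_k)
  chain <- chain_anchors(anchors)
  calls <- call_indels(chain, min_len = min_len, gap_eps = gap_eps,
                       names = names)
  structure(list(calls = calls, chain = chain, anchors = anchors,
                 names = names), class = "zw_hapdiff")
}

#' @export
print.zw_hapdiff <- function(x, ...) {
  cat(sprintf("Haplotype comparison %s vs %s: %d anchors, %d chained, %s\n",
              x$names[1], x$names[2], nrow(x$anchors),
              nrow(x$chain$anchors),
              if (x$chain$collinear) "collinear" else "non-collinear"))
  if (nrow(x$calls)) {
    for (i in seq_len(nrow(x$calls)))
      cat(sprintf("  %s on %s: %d bp at %d-%d\n", x$calls$kind[i],
                  ifelse(is.na(x$calls$carrier[i]), "-", x$calls$carrier[i]),
                  x$calls$length[i],
                  x$calls$start[i], x$calls$end[i]))
  } else cat("  no structural differences >= min_len\n")
  invisible(x)
}
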