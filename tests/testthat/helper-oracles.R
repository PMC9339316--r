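# Independent oracles used by the tests. Each is a direct, unoptimized
# transcription of the published definition, computed from raw data, and is
# deliberately kept separate from the package's vectorized implementations.

# Weir & Cockerham (1984) variance components via the ANOVA mean-squares
# route: sums of squares computed from per-gene-copy allele indicators, two
# populations, diploids. g1/g2 are ALT-dosage vectors (0/1/2, NA = missing).
wc_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  r <- 2
  n <- c(length(g1), length(g2))
  ntot <- sum(n)
  nc <- (ntot - sum(n^2) / ntot) / (r - 1)
  ym <- c(g1, g2) / 2                 # per-individual allele-frequency mean
  pop <- rep(1:2, n)
  p <- tapply(ym, pop, mean)
  pbar <- sum(n * p) / ntot
  SSG <- sum(ifelse(c(g1, g2) == 1, 0.5, 0))   # within-individual SS
  SSI <- 2 * sum((ym - p[pop])^2)              # individuals within pops
  SSP <- 2 * sum(n * (p - pbar)^2)             # among populations
  MSG <- SSG / ntot
  MSI <- SSI / (ntot - r)
  MSP <- SSP / (r - 1)
  c(a = (MSP - MSI) / (2 * nc), b = (MSI - MSG) / 2, c = MSG)
}

# ratio-of-sums weighted FST over a set of sites, via the oracle
wc_oracle_weighted <- function(gt, sex) {
  comps <- t(apply(gt, 1, function(g) wc_oracle(g[sex == "F"], g[sex == "M"])))
  poly <- apply(gt, 1, function(g) length(unique(na.omit(g))) > 1 ||
                  any(g == 1, na.rm = TRUE))
  comps <- comps[poly, , drop = FALSE]
  sum(comps[, "a"]) / sum(comps)
}

# brute-force best collinear anchor chain: enumerate all subsets (<= 12
# anchors), keep strictly increasing nonoverlapping ones, maximize total
# anchor length
chain_oracle <- function(anchors, max_overlap = 0L) {
  n <- nrow(anchors)
  best <- NULL; best_w <- -1
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(idx)) next
    a <- anchors[idx, , drop = FALSE]
    a <- a[order(a$posA), , drop = FALSE]
    ok <- TRUE
    if (nrow(a) > 1) {
      for (i in seq_len(nrow(a) - 1)) {
        if (!(a$posA[i] < a$posA[i + 1] && a$posB[i] < a$posB[i + 1] &&
              a$posA[i] + a$length[i] - max_overlap <= a$posA[i + 1] &&
              a$posB[i] + a$length[i] - max_overlap <= a$posB[i + 1])) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) {
      w <- sum(a$length)
      if (w > best_w) { best_w <- w; best <- a }
    }
  }
  list(anchors = best, weight = best_w)
}

# rotation + strand closure of a motif by brute-force enumeration
rotation_closure_oracle <- function(motif) {
  n <- nchar(motif)
  rots <- function(s) vapply(seq_len(n), function(i)
    paste0(substr(s, i, n), substr(s, 1, i - 1)), "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  length(unique(c(rots(motif), rots(rc))))
}

# per-base boolean-marking union length of intervals (0-based half-open)
union_len_oracle <- function(starts, ends, len) {
  covered <- logical(len)
  for (i in seq_along(starts))
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  sum(covered)
}
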