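# Synthetic ZW genome construction from a blueprint.
# All coordinates 0-based half-open; sequences handled as plain strings here
# and exported as Biostrings objects at the edges.

plant <- function(seq, at0, s) {
  substr(seq, at0 + 1, at0 + nchar(s)) <- s
  seq
}

char_at <- function(seq, at0) substr(seq, at0 + 1, at0 + 1)

set_base_not <- function(seq, at0, forbidden) {
  if (char_at(seq, at0) %in% forbidden)
    seq <- plant(seq, at0, setdiff(c("A", "C", "G", "T"), forbidden)[1])
  seq
}

splice_in <- function(seq, at0, ins) {
  paste0(substr(seq, 1, at0), ins, substr(seq, at0 + 1, nchar(seq)))
}

comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Build a synthetic ZW genome pair with planted truth
#'
#' Materializes a [zw_blueprint()]: a reference assembly whose sex chromosome
#' is a Z/W *mosaic* carrying both the W-specific SDR insertion and the
#' Z-specific insertion (so every planted feature appears exactly once on the
#' reference), the two phased haplotype sequences (Z = backbone + Z-specific
#' element, W = backbone + SDR insertion), and a machine-readable truth set
#' with per-base expected copy numbers per sex (W-specific: F=1/M=0,
#' Z-specific: F=1/M=2, elsewhere F=M=2).
#'
#' Planted exact repeats (terminal inverted repeats, target-site duplications,
#' direct repeats, poly-A run, palindrome arms) are constructed so that they
#' cannot be extended by chance-matching flanking bases, making recovery of
#' the exact planted lengths well defined.
#'
#' @param blueprint a [zw_blueprint()]
#' @return an object of class `zw_genome`: list with `reference` and
#'   `haplotypes` ([Biostrings::DNAStringSet]s) and `truth` (class `zw_truth`).
#' @export
#' @examples
#' bp <- zw_blueprint(chrom_lengths = c(chrZW = 2e4, chrA1 = 2e4),
#'                    sdr_interval = c(8000, 11000), sdr_ir_len = 29,
#'                    z_specific_interval = c(14000, 15000), z_ir_len = 14,
#'                    ltr_spec = NULL, retrogene_spec = NULL,
#'                    telomere_arrays = NULL, palindrome_spec = NULL)
#' g <- build_genomes(bp)
#' g$truth$sdr
build_genomes <- function(blueprint) {
  bp <- validate_blueprint(blueprint)
  set.seed(bp$seed)
  lens <- bp$chrom_lengths
  seqs <- lapply(lens, random_dna, gc = bp$gc)
  sex <- bp$sex_chrom
  tsd <- bp$tsd_motif
  t_len <- nchar(tsd)

  feats <- list()   # reference-space (filled later, backbone-space first)
  bb_iv <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE)
  add_bb <- function(chrom, start, end, name) {
    bb_iv <<- rbind(bb_iv, data.frame(chrom = chrom, start = as.integer(start),
                                      end = as.integer(end), name = name,
                                      stringsAsFactors = FALSE))
  }

  # --- telomere arrays on backbones ---
  telo <- NULL
  if (!is.null(bp$telomere_arrays)) {
    ta <- bp$telomere_arrays
    telo <- data.frame(chrom = ta$chrom, where = ta$where,
                       start = NA_integer_, end = NA_integer_, len = ta$len,
                       stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ta))) {
      L <- lens[[ta$chrom[i]]]
      st <- switch(ta$where[i],
                   "5p" = 0L,
                   "3p" = as.integer(L - ta$len[i]),
                   "interstitial" = as.integer(ta$offset[i]))
      en <- st + ta$len[i]
      array <- substr(strrep(bp$telomere_motif,
                             ceiling(ta$len[i] / nchar(bp$telomere_motif))),
                      1, ta$len[i])
      seqs[[ta$chrom[i]]] <- plant(seqs[[ta$chrom[i]]], st, array)
      telo$start[i] <- st; telo$end[i] <- en
      add_bb(ta$chrom[i], st, en, sprintf("telomere_%s_%s", ta$chrom[i], ta$where[i]))
    }
  }

  # --- palindrome ---
  pal <- NULL
  if (!is.null(bp$palindrome_spec)) {
    ps <- bp$palindrome_spec
    arm <- random_dna(ps$arm_len, bp$gc)
    spc <- if (ps$spacer > 0) random_dna(ps$spacer, bp$gc) else ""
    s0 <- as.integer(ps$pos)
    tot <- 2L * ps$arm_len + ps$spacer
    sq <- plant(seqs[[ps$chrom]], s0, paste0(arm, spc, revcomp(arm)))
    # block chance extension of the inverted-repeat arms, outward and inward
    sq <- set_base_not(sq, s0 - 1L, comp1(char_at(sq, s0 + tot)))
    if (ps$spacer >= 2)
      sq <- set_base_not(sq, s0 + ps$arm_len,
                         comp1(char_at(sq, s0 + ps$arm_len + ps$spacer - 1L)))
    seqs[[ps$chrom]] <- sq
    pal <- list(chrom = ps$chrom, arm1 = c(s0, s0 + ps$arm_len),
                arm2 = c(s0 + ps$arm_len + ps$spacer, s0 + tot),
                arm_len = ps$arm_len, spacer = ps$spacer)
    add_bb(ps$chrom, s0 - 1L, s0 + tot + 1L, "palindrome")
  }

  # --- Z-specific element (TIRs + TSD) ---
  z_ins <- NULL; p_z <- NULL; z_elen <- NULL
  if (!is.null(bp$z_specific_interval)) {
    p_z <- bp$z_specific_interval[1]
    z_elen <- diff(bp$z_specific_interval)
    k <- bp$z_ir_len
    n_cg <- min(6L, k)
    tir <- paste0("G", if (n_cg > 1) paste(sample(c("C", "G"), n_cg - 1, TRUE), collapse = "") else "",
                  if (k > n_cg) random_dna(k - n_cg, bp$gc) else "")
    el <- random_dna(z_elen, bp$gc)
    el <- plant(el, 0L, tir)
    el <- plant(el, z_elen - k, revcomp(tir))
    el <- set_base_not(el, k, comp1(char_at(el, z_elen - k - 1L)))
    # target site: backbone carries one TSD copy ending at the cut; the
    # inserted segment is element + the duplicated copy
    seqs[[sex]] <- plant(seqs[[sex]], p_z - t_len, tsd)
    seqs[[sex]] <- plant(seqs[[sex]], p_z - t_len - 1L, "C")  # block extension
    # base after the cut must differ from the element start so alignment
    # anchors cannot extend past the (intrinsically ambiguous) TSD junction
    seqs[[sex]] <- set_base_not(seqs[[sex]], p_z, char_at(el, 0L))
    z_ins <- paste0(el, tsd)
    add_bb(sex, p_z - t_len - 1L, p_z + 1L, "z_specific_insertion_site")
  }

  # --- SDR insertion (terminal IRs; LTR + retrogene inside) ---
  sdr_ins <- NULL; p_s <- NULL; s_len <- NULL
  ltr <- NULL; retro <- NULL
  if (!is.null(bp$sdr_interval)) {
    p_s <- bp$sdr_interval[1]
    s_len <- diff(bp$sdr_interval)
    irl <- bp$sdr_ir_len
    ins <- random_dna(s_len, bp$gc)
    ir <- random_dna(irl, bp$gc)
    ins <- plant(ins, 0L, ir)
    ins <- plant(ins, s_len - irl, revcomp(ir))

    sdr_sub <- data.frame(start = c(0L, s_len - irl),
                          end = c(irl, s_len), name = c("sdr_ir5", "sdr_ir3"),
                          stringsAsFactors = FALSE)

    if (!is.null(bp$ltr_spec)) {
      ls <- bp$ltr_spec
      arm <- paste0(ls$flank[1],
                    random_dna(ls$arm_len - nchar(ls$flank[1]) - nchar(ls$flank[2]), bp$gc),
                    ls$flank[2])
      arm2 <- arm
      edit_pos <- sample(3:(ls$arm_len - 3), ls$n_sub + ls$n_ins)
      ptr <- 1L
      if (ls$n_sub > 0) for (i in seq_len(ls$n_sub)) {
        p0 <- edit_pos[ptr]; ptr <- ptr + 1L
        old <- substr(arm2, p0, p0)
        substr(arm2, p0, p0) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
      if (ls$n_ins > 0) for (i in seq_len(ls$n_ins)) {
        p0 <- edit_pos[ptr]; ptr <- ptr + 1L
        arm2 <- paste0(substr(arm2, 1, p0), sample(c("A", "C", "G", "T"), 1),
                       substr(arm2, p0 + 1, nchar(arm2)))
      }
      mid_len <- ls$length - nchar(arm) - nchar(arm2)
      element <- paste0(arm, random_dna(mid_len, bp$gc), arm2)
      ins <- plant(ins, ls$offset, element)
      ltr <- list(offset = ls$offset, length = ls$length,
                  arm_lens = c(nchar(arm), nchar(arm2)),
                  edits = ls$n_sub + ls$n_ins,
                  flank = paste0(ls$flank[1], ".", ls$flank[2]),
                  canonical = identical(toupper(paste0(ls$flank[1], ".", ls$flank[2])), "TG.CA"))
      sdr_sub <- rbind(sdr_sub, data.frame(start = ls$offset,
                                           end = ls$offset + ls$length,
                                           name = "ltr_element"))
    }

    if (!is.null(bp$retrogene_spec)) {
      rs <- bp$retrogene_spec
      dr <- random_dna(rs$dr_len, bp$gc)
      dr <- set_base_not(plant(dr, 0L, if (char_at(dr, 0L) == "A") "C" else char_at(dr, 0L)),
                         rs$dr_len - 1L, "A")
      up_gap <- random_dna(rs$upstream_offset, bp$gc)
      up_gap <- plant(up_gap, 0L, "C")
      cds <- paste0("ATG", random_dna(rs$cds_len - 6, bp$gc), "TAA")
      pa_gap <- random_dna(rs$polyA_offset, bp$gc)
      pa_gap <- set_base_not(pa_gap, rs$polyA_offset - 1L, "A")
      region <- paste0(dr, up_gap, cds, pa_gap,
                       strrep("A", rs$polyA_len), dr)
      ins <- plant(ins, rs$offset, region)
      # block leftward/rightward extension of the direct-repeat pair
      ins <- plant(ins, rs$offset - 1L, "G")
      ins <- plant(ins, rs$offset + nchar(region), "G")
      o <- rs$offset
      cds_start <- o + rs$dr_len + rs$upstream_offset
      polyA_start <- cds_start + rs$cds_len + rs$polyA_offset
      retro <- list(offset = o,
                    dr1 = c(o, o + rs$dr_len),
                    cds = c(cds_start, cds_start + rs$cds_len),
                    polyA = c(polyA_start, polyA_start + rs$polyA_len),
                    dr2 = c(polyA_start + rs$polyA_len,
                            polyA_start + rs$polyA_len + rs$dr_len),
                    dr_len = rs$dr_len, polyA_len = rs$polyA_len,
                    polyA_offset = rs$polyA_offset,
                    upstream_offset = rs$upstream_offset)
      sdr_sub <- rbind(sdr_sub, data.frame(start = o - 1L,
                                           end = o + nchar(region) + 1L,
                                           name = "retrogene_region"))
    }

    ov <- which(outer(sdr_sub$start, sdr_sub$end, `<`) &
                outer(sdr_sub$end, sdr_sub$start, `>`) &
                !diag(nrow(sdr_sub)), arr.ind = TRUE)
    if (nrow(ov))
      stop(sprintf("overlapping planted features: %s and %s",
                   sdr_sub$name[ov[1, 1]], sdr_sub$name[ov[1, 2]]))

    # block chance extension of the SDR terminal IRs
    ins <- set_base_not(ins, irl, comp1(char_at(ins, s_len - irl - 1L)))
    # junction guards: backbone bases flanking the cut must differ from the
    # insertion's terminal bases so anchors abut the insertion exactly
    seqs[[sex]] <- set_base_not(seqs[[sex]], p_s, char_at(ins, 0L))
    seqs[[sex]] <- set_base_not(seqs[[sex]], p_s - 1L, char_at(ins, s_len - 1L))
    sdr_ins <- ins
    add_bb(sex, p_s - 1L, p_s + 1L, "sdr_insertion_site")
  }

  # --- backbone overlap validation (error naming the offending pair) ---
  if (nrow(bb_iv) > 1) {
    for (chrom in unique(bb_iv$chrom)) {
      d <- bb_iv[bb_iv$chrom == chrom, , drop = FALSE]
      if (nrow(d) < 2) next
      ov <- which(outer(d$start, d$end, `<`) & outer(d$end, d$start, `>`) &
                  !diag(nrow(d)), arr.ind = TRUE)
      if (nrow(ov))
        stop(sprintf("overlapping planted features: %s and %s",
                     d$name[ov[1, 1]], d$name[ov[1, 2]]))
    }
  }

  # --- assemble haplotypes and the Z/W mosaic reference ---
  S <- seqs[[sex]]
  z_ilen <- if (is.null(z_ins)) 0L else nchar(z_ins)
  s_ilen <- if (is.null(sdr_ins)) 0L else nchar(sdr_ins)
  Zseq <- if (is.null(z_ins)) S else splice_in(S, p_z, z_ins)
  Wseq <- if (is.null(sdr_ins)) S else splice_in(S, p_s, sdr_ins)
  mosaic <- S
  pts <- list()
  if (!is.null(sdr_ins)) pts[[length(pts) + 1L]] <- list(at = p_s, ins = sdr_ins, what = "sdr")
  if (!is.null(z_ins)) pts[[length(pts) + 1L]] <- list(at = p_z, ins = z_ins, what = "z")
  if (length(pts)) {
    ord <- order(vapply(pts, `[[`, 0L, "at"), decreasing = TRUE)
    for (i in ord) mosaic <- splice_in(mosaic, pts[[i]]$at, pts[[i]]$ins)
  }

  # backbone position -> mosaic position
  to_mosaic <- function(pos) {
    pos + (if (!is.null(p_s)) s_ilen * (pos >= p_s) else 0L) +
      (if (!is.null(p_z)) z_ilen * (pos >= p_z) else 0L)
  }
  m_sdr <- if (is.null(p_s)) NULL else {
    st <- p_s + (if (!is.null(p_z) && p_z <= p_s) z_ilen else 0L)
    c(st, st + s_len)
  }
  m_z <- if (is.null(p_z)) NULL else {
    st <- p_z + (if (!is.null(p_s) && p_s <= p_z) s_ilen else 0L)
    c(st, st + z_elen)
  }

  ref_seqs <- seqs
  ref_seqs[[sex]] <- mosaic
  reference <- Biostrings::DNAStringSet(unlist(ref_seqs))
  haplotypes <- Biostrings::DNAStringSet(c(Z = Zseq, W = Wseq))

  # --- truth: reference-space features ---
  fr <- function(kind, seqname, start, end, name = kind)
    data.frame(kind = kind, seqname = seqname, start = as.integer(start),
               end = as.integer(end), name = name, stringsAsFactors = FALSE)
  feat_l <- list()
  if (!is.null(m_sdr)) {
    irl <- bp$sdr_ir_len
    feat_l[[length(feat_l) + 1]] <- fr("sdr_insertion", sex, m_sdr[1], m_sdr[2], "SDR")
    feat_l[[length(feat_l) + 1]] <- fr("tir", sex, m_sdr[1], m_sdr[1] + irl, "sdr_ir5")
    feat_l[[length(feat_l) + 1]] <- fr("tir", sex, m_sdr[2] - irl, m_sdr[2], "sdr_ir3")
    if (!is.null(ltr)) {
      a <- m_sdr[1] + ltr$offset
      feat_l[[length(feat_l) + 1]] <- fr("ltr", sex, a, a + ltr$length, "ltr_element")
      feat_l[[length(feat_l) + 1]] <- fr("direct_repeat", sex, a, a + ltr$arm_lens[1], "ltr_arm5")
      feat_l[[length(feat_l) + 1]] <- fr("direct_repeat", sex, a + ltr$length - ltr$arm_lens[2],
                               a + ltr$length, "ltr_arm3")
    }
    if (!is.null(retro)) {
      a <- m_sdr[1]
      feat_l[[length(feat_l) + 1]] <- fr("retro_cds", sex, a + retro$cds[1], a + retro$cds[2], "retro_cds")
      feat_l[[length(feat_l) + 1]] <- fr("polyA", sex, a + retro$polyA[1], a + retro$polyA[2], "retro_polyA")
      feat_l[[length(feat_l) + 1]] <- fr("direct_repeat", sex, a + retro$dr1[1], a + retro$dr1[2], "retro_dr_up")
      feat_l[[length(feat_l) + 1]] <- fr("direct_repeat", sex, a + retro$dr2[1], a + retro$dr2[2], "retro_dr_down")
    }
  }
  if (!is.null(m_z)) {
    k <- bp$z_ir_len
    feat_l[[length(feat_l) + 1]] <- fr("z_insertion", sex, m_z[1], m_z[2], "Z_element")
    feat_l[[length(feat_l) + 1]] <- fr("tir", sex, m_z[1], m_z[1] + k, "z_ir5")
    feat_l[[length(feat_l) + 1]] <- fr("tir", sex, m_z[2] - k, m_z[2], "z_ir3")
    feat_l[[length(feat_l) + 1]] <- fr("tsd", sex, m_z[1] - t_len, m_z[1], "z_tsd5")
    feat_l[[length(feat_l) + 1]] <- fr("tsd", sex, m_z[2], m_z[2] + t_len, "z_tsd3")
  }
  if (!is.null(telo)) {
    for (i in seq_len(nrow(telo))) {
      st <- telo$start[i]; en <- telo$end[i]
      if (telo$chrom[i] == sex) { st <- to_mosaic(st); en <- to_mosaic(en) }
      feat_l[[length(feat_l) + 1]] <- fr("telomere", telo$chrom[i], st, en,
                               paste0("telomere_", telo$where[i]))
    }
  }
  if (!is.null(pal)) {
    a1 <- pal$arm1; a2 <- pal$arm2
    if (pal$chrom == sex) {
      a1 <- to_mosaic(a1); a2 <- to_mosaic(a2)
    }
    feat_l[[length(feat_l) + 1]] <- fr("palindrome", pal$chrom, a1[1], a2[2], "palindrome")
  }
  features <- if (length(feat_l)) do.call(rbind, feat_l) else
    fr(character(), character(), integer(), integer(), character())[0, ]

  # --- per-base copy number per sex on the reference ---
  cn <- list()
  for (chrom in names(ref_seqs)) {
    L <- nchar(ref_seqs[[chrom]])
    if (chrom != sex) {
      cn[[length(cn) + 1]] <- data.frame(chrom = chrom, start = 0L, end = L,
                                         cn_F = 2L, cn_M = 2L)
    } else {
      cuts <- c(0L, L)
      if (!is.null(m_sdr)) cuts <- c(cuts, m_sdr)
      if (!is.null(m_z)) cuts <- c(cuts, m_z[1], m_z[2] + t_len)
      cuts <- sort(unique(cuts))
      seg <- data.frame(chrom = chrom, start = head(cuts, -1), end = tail(cuts, -1),
                        cn_F = 2L, cn_M = 2L)
      if (!is.null(m_sdr)) {
        i <- seg$start >= m_sdr[1] & seg$end <= m_sdr[2]
        seg$cn_F[i] <- 1L; seg$cn_M[i] <- 0L
      }
      if (!is.null(m_z)) {
        i <- seg$start >= m_z[1] & seg$end <= m_z[2] + t_len
        seg$cn_F[i] <- 1L; seg$cn_M[i] <- 2L
      }
      cn[[length(cn) + 1]] <- seg
    }
  }
  cn_track <- do.call(rbind, cn)
  rownames(cn_track) <- NULL

  nonrec <- if (is.null(m_sdr)) NULL else data.frame(
    chrom = sex,
    start = max(0L, m_sdr[1] - bp$nonrec_flank),
    end = min(nchar(mosaic), m_sdr[2] + bp$nonrec_flank))

  truth <- structure(list(
    features = features,
    cn_track = cn_track,
    nonrec = nonrec,
    sdr = if (is.null(p_s)) NULL else list(
      W = c(p_s, p_s + s_len), mosaic = m_sdr, ir_len = bp$sdr_ir_len,
      insertion_point = p_s),
    z_element = if (is.null(p_z)) NULL else list(
      Z = c(p_z, p_z + z_elen), mosaic = m_z, ir_len = bp$z_ir_len,
      tsd = tsd, insertion_point = p_z, inserted_len = z_ilen),
    ltr = ltr, retrogene = retro, telomeres = telo, palindrome = pal,
    blueprint = bp
  ), class = "zw_truth")

  structure(list(reference = reference, haplotypes = haplotypes, truth = truth),
            class = "zw_genome")
}

#' @export
print.zw_genome <- function(x, ...) {
  cat("Synthetic ZW genome\n")
  cat("  reference:", paste(sprintf("%s (%d bp)", names(x$reference),
                                    Biostrings::width(x$reference)),
                            collapse = ", "), "\n")
  cat("  haplotypes:", paste(sprintf("%s (%d bp)", names(x$haplotypes),
                                     Biostrings::width(x$haplotypes)),
                             collapse = ", "), "\n")
  cat("  planted features:", nrow(x$truth$features), "\n")
  invisible(x)
}

#' Write a synthetic genome and its truth to disk
#'
#' Writes `reference.fa`, `haplotypes.fa`, `truth_features.bed` (0-based
#' half-open) and `truth.json`.
#' @param genome a [build_genomes()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome$reference, file.path(dir, "reference.fa"))
  Biostrings::writeXStringSet(genome$haplotypes, file.path(dir, "haplotypes.fa"))
  tf <- genome$truth$features
  if (nrow(tf)) {
    bed <- data.frame(tf$seqname, tf$start, tf$end, tf$name)
    write.table(bed, file.path(dir, "truth_features.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  tr <- genome$truth
  jsonlite::write_json(
    list(features = tr$features, cn_track = tr$cn_track, nonrec = tr$nonrec,
         sdr = tr$sdr, z_element = tr$z_element, ltr = tr$ltr,
         retrogene = tr$retrogene),
    file.path(dir, "truth.json"), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
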