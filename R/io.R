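# Small format helpers shared across modules.

#' Read a BED file (0-based half-open) into a data.frame
#'
#' Parsing is delegated to rtracklayer; a light pre-check reports the first
#' malformed line by number.
#'
#' @param path BED path
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open), `name`
#'   when present
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(body)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3 || anyNA(suppressWarnings(as.numeric(f[2:3]))) ||
        as.numeric(f[2]) > as.numeric(f[3]))
      stop(sprintf("malformed BED line %d in %s", i, path))
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write intervals as BED (0-based half-open)
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`
#' @param path output path
#' @export
write_bed <- function(df, path) {
  cols <- df[c("chrom", "start", "end")]
  if (!is.null(df$name)) cols$name <- df$name
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
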