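#' Write alignment records as SAM
#'
#' Emits valid SAM 1.6 with an `@SQ` header line per contig, one primary
#' record per read, sequences in aligned orientation (reverse-complemented
#' for minus-strand records, as the format requires), all-Q40 qualities, an
#' `NM` mismatch tag, and CIGAR `<len>M` (alignment is gapless). Round-trips
#' through [read_sam()].
#'
#' @param records An `alignment_set`.
#' @param refset The `reference_set` the records were aligned against.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, refset, path) {
  paired <- "proper_pair" %in% names(records) &&
    any(records$mate == 2L, na.rm = TRUE)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    vapply(refset$genomes, function(g) {
      sprintf("@SQ\tSN:%s\tLN:%d", g$name, genome_length(g))
    }, character(1)),
    "@PG\tID:numtaudit\tPN:numtaudit")
  flag <- integer(nrow(records))
  if (paired) {
    flag <- flag + 1L +                                # paired
      ifelse(records$mate == 1L, 64L, 128L)
    mate_of <- ifelse(records$mate == 1L, 2L, 1L)
    key <- paste(records$read_id, records$mate)
    mkey <- paste(records$read_id, mate_of)
    midx <- match(mkey, key)
    mate_mapped <- records$mapped[midx]
    mate_strand <- records$strand[midx]
    flag <- flag +
      ifelse(records$proper_pair, 2L, 0L) +
      ifelse(!mate_mapped, 8L, 0L) +
      ifelse(mate_mapped & mate_strand == "-", 32L, 0L)
  }
  flag <- flag + ifelse(!records$mapped, 4L, 0L) +
    ifelse(records$mapped & records$strand == "-", 16L, 0L)
  seq_out <- ifelse(records$mapped & records$strand == "-",
                    revcomp(records$seq), records$seq)
  mapq <- ifelse(!records$mapped, 0L, ifelse(records$ambiguous, 0L, 60L))
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
    records$read_id, flag,
    ifelse(records$mapped, records$contig, "*"),
    ifelse(records$mapped, records$pos, 0L),
    mapq,
    ifelse(records$mapped, sprintf("%dM", nchar(records$seq)), "*"),
    seq_out, strrep("I", nchar(records$seq)),
    ifelse(records$mapped, sprintf("\tNM:i:%d", records$mismatches), ""))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read primary alignments from SAM/BAM
#'
#' The bridge for auditing external aligners: secondary and supplementary
#' records are dropped, the unmapped flag is honored, and the `NM` tag
#' supplies the mismatch count (recomputed against `refset` with a warning
#' when absent). MAPQ 0 is taken as the external analog of this package's
#' ambiguity flag. Stored sequences of minus-strand records are converted
#' back to original read orientation.
#'
#' @param path SAM or BAM path.
#' @param refset The `reference_set` the file was aligned against; unknown
#'   contigs are an error.
#' @return An `alignment_set`.
#' @export
read_sam <- function(path, refset) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "strand", "seq"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(x$qname)
  contig <- as.character(x$rname)
  known <- c(ref_contigs(refset), NA_character_)
  if (!all(contig %in% known)) {
    abort(sprintf("SAM contains unknown contig(s): %s",
                  paste(setdiff(unique(contig), known), collapse = ", ")))
  }
  mapped <- !bitwAnd(x$flag, 4L)
  paired <- bitwAnd(x$flag, 1L) > 0L
  mate <- ifelse(paired & bitwAnd(x$flag, 128L) > 0L, 2L, 1L)
  strand <- ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+")
  seq <- as.character(x$seq)
  seq <- ifelse(mapped & strand == "-", revcomp(seq), seq)
  nm <- x$tag$NM %||% rep(NA_integer_, n)
  need_nm <- mapped & is.na(nm)
  if (any(need_nm)) {
    warn(sprintf("NM tag missing on %d mapped record(s); recomputing",
                 sum(need_nm)))
    for (i in which(need_nm)) {
      g <- ref_genome(refset, contig[i])
      aln_seq <- if (strand[i] == "-") revcomp(seq[i]) else seq[i]
      nm[i] <- hamming(aln_seq,
                       genome_subseq(g, x$pos[i], x$pos[i] + nchar(seq[i]) - 1L))
    }
  }
  out <- tibble::tibble(
    read_id = x$qname, mate = mate, seq = seq,
    contig = ifelse(mapped, contig, NA_character_),
    pos = ifelse(mapped, x$pos, NA_integer_),
    strand = ifelse(mapped, strand, NA_character_),
    mismatches = ifelse(mapped, as.integer(nm), NA_integer_),
    mapped = mapped,
    ambiguous = mapped & !is.na(x$mapq) & x$mapq == 0L)
  if (any(paired)) {
    out$proper_pair <- bitwAnd(x$flag, 2L) > 0L
  }
  new_alignment_set(out)
}
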