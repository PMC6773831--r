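#' Enumerate every possible single-nucleotide variant of a genome
#'
#' Each of the L positions contributes its three non-reference alleles, for
#' 3L SNVs in total (49,707 for the canonical 16,569 bp mitochondrial
#' genome). Ordered by position, then alt allele (A < C < G < T).
#'
#' @param genome A `genome` with an A/C/G/T-only sequence.
#' @return A tibble of SNVs with columns `contig`, `pos`, `ref`, `alt`.
#' @export
enumerate_snvs <- function(genome) {
  stopifnot(inherits(genome, "genome"))
  assert_dna(genome$sequence, sprintf("contig '%s'", genome$name))
  L <- genome_length(genome)
  refs <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  # per position the three non-reference bases, in A<C<G<T order
  out <- tibble::tibble(
    contig = genome$name,
    pos = rep(seq_len(L), each = 4L),
    ref = rep(refs, each = 4L),
    alt = rep(BASES, times = L))
  out <- out[out$ref != out$alt, ]
  rownames(out) <- NULL
  out
}

#' Parse and format SNV shorthand like "chrM:6023G>A"
#'
#' @param x Character vector of `contig:posREF>ALT` strings.
#' @return For `parse_snv()`, an SNV tibble; for `format_snv()`, a character
#'   vector.
#' @export
parse_snv <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)([ACGT])>([ACGT])$", x))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) abort(sprintf("cannot parse SNV notation: %s", x[bad][1]))
  tibble::tibble(
    contig = vapply(m, `[[`, character(1), 2),
    pos = as.integer(vapply(m, `[[`, character(1), 3)),
    ref = vapply(m, `[[`, character(1), 4),
    alt = vapply(m, `[[`, character(1), 5))
}

#' @rdname parse_snv
#' @param snvs An SNV tibble (`contig`, `pos`, `ref`, `alt`).
#' @export
format_snv <- function(snvs) {
  sprintf("%s:%d%s>%s", snvs$contig, snvs$pos, snvs$ref, snvs$alt)
}

check_snv <- function(genome, snv) {
  if (!identical(snv$contig, genome$name)) {
    abort(sprintf("SNV contig '%s' does not match genome '%s'",
                  snv$contig, genome$name))
  }
  if (snv$pos < 1L || snv$pos > genome_length(genome)) {
    abort(sprintf("SNV position %d outside contig '%s'", snv$pos, genome$name))
  }
  have <- genome_subseq(genome, snv$pos, snv$pos)
  if (!identical(have, snv$ref)) {
    abort(sprintf(
      "SNV ref allele mismatch at %s:%d: expected '%s', sequence has '%s'",
      genome$name, snv$pos, snv$ref, have))
  }
  if (identical(snv$ref, snv$alt)) abort("SNV ref and alt alleles are equal")
  invisible(TRUE)
}

#' Apply a single-nucleotide variant to a genome
#'
#' The ref allele is checked against the sequence, guarding against
#' coordinate bugs; the input genome is untouched.
#'
#' @param genome A `genome`.
#' @param snv A one-row SNV tibble (`contig`, `pos`, `ref`, `alt`).
#' @return A new `genome` differing from the input at exactly `snv$pos`.
#' @export
apply_snv <- function(genome, snv) {
  snv <- as.list(tibble::as_tibble(snv)[1, c("contig", "pos", "ref", "alt")])
  snv$pos <- as.integer(snv$pos)
  check_snv(genome, snv)
  seq <- genome$sequence
  substr(seq, snv$pos, snv$pos) <- snv$alt
  genome(genome$name, seq, circular = genome$circular)
}

#' Heteroplasmy mixture of two fragment sets
#'
#' Models heteroplasmy by exact copy-count concatenation: `ref_copies` copies
#' of the reference fragment set followed by `mut_copies` copies of the
#' mutant set, with read ids re-serialised to stay unique. At any position
#' untouched by nuMT confounding, the alt-allele fraction among covering
#' reads is exactly `mut_copies / (ref_copies + mut_copies)` — e.g. 1:1 gives
#' 50% heteroplasmy and 95:5 gives 5%.
#'
#' @param ref_frags,mut_frags `fragment_set`s generated under the identical
#'   [read_config()].
#' @param ref_copies,mut_copies Non-negative copy counts (at least one > 0).
#' @return A `fragment_set` with an added `haplotype` column (`"ref"` or
#'   `"mut"`) and attribute `nominal_het = mut_copies / (ref_copies +
#'   mut_copies)`.
#' @export
mix_fragments <- function(ref_frags, mut_frags, ref_copies = 1L, mut_copies = 1L) {
  ref_copies <- as.integer(ref_copies)
  mut_copies <- as.integer(mut_copies)
  stopifnot(ref_copies >= 0L, mut_copies >= 0L, ref_copies + mut_copies >= 1L)
  cfg <- attr(ref_frags, "read_config")
  if (!same_config(cfg, attr(mut_frags, "read_config"))) {
    abort("ref and mut fragment sets were generated under different read configs")
  }
  pieces <- c(
    rep(list(tibble::as_tibble(ref_frags)[names(ref_frags) != "haplotype"]),
        ref_copies),
    rep(list(tibble::as_tibble(mut_frags)[names(mut_frags) != "haplotype"]),
        mut_copies))
  hap <- rep(c("ref", "mut"), c(ref_copies, mut_copies))
  out <- dplyr::bind_rows(lapply(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    p$haplotype <- hap[i]
    p$read_id <- paste0(p$read_id, "|c", i)
    p
  }))
  mixed <- new_fragment_set(out, cfg, attr(ref_frags, "genome_name"))
  attr(mixed, "nominal_het") <- mut_copies / (ref_copies + mut_copies)
  mixed
}

#' Read/write SNV tables as TSV or sites-only VCF
#'
#' The TSV is the package's native 4-column format (`contig`, `pos`, `ref`,
#' `alt`); the VCF writer emits a minimal sites-only VCF 4.2 for
#' interoperability with external tooling.
#'
#' @param snvs An SNV tibble.
#' @param path Output path.
#' @return `path`, invisibly (writers); an SNV tibble (readers).
#' @export
write_snv_tsv <- function(snvs, path) {
  readr::write_tsv(snvs[, c("contig", "pos", "ref", "alt")], path)
  invisible(path)
}

#' @rdname write_snv_tsv
#' @export
read_snv_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    contig = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character()))
}

#' @rdname write_snv_tsv
#' @param refset Optional `reference_set` supplying contig lengths for the
#'   VCF header.
#' @export
write_snv_vcf <- function(snvs, path, refset = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=numtaudit"), con)
  if (!is.null(refset)) {
    for (g in refset$genomes) {
      writeLines(sprintf("##contig=<ID=%s,length=%d>", g$name,
                         genome_length(g)), con)
    }
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(snvs) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       snvs$contig, snvs$pos, snvs$ref, snvs$alt), con)
  }
  invisible(path)
}
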