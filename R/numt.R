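empty_numt_table <- function() {
  tibble::tibble(
    host = character(), insert_pos = integer(), mito_start = integer(),
    length = integer(), mismatch_offsets = character(), mismatch_bases = character()
  )
}

#' Specify a nuMT to plant in a nuclear contig
#'
#' Describes a copied mitochondrial segment plus the point mismatches that
#' make the nuclear copy diverge from its mitochondrial source. Offsets are
#' 1-based within the copied segment.
#'
#' @param mito_start 1-based start of the copied mitochondrial segment.
#' @param length Segment length in bp.
#' @param mismatches A data frame with columns `offset` (1-based within the
#'   segment) and `base` (the substituted nuclear base), or `NULL` for a
#'   perfect copy.
#' @param host_contig Name of the nuclear host contig.
#' @param host_insert_pos 1-based position on the host at which the segment
#'   is painted over the random background.
#' @return An object of class `numt_spec`.
#' @export
numt_spec <- function(mito_start, length, mismatches = NULL,
                      host_contig = "nuc1", host_insert_pos = 1L) {
  mismatches <- if (is.null(mismatches)) {
    tibble::tibble(offset = integer(), base = character())
  } else {
    tibble::as_tibble(mismatches)
  }
  stopifnot(all(c("offset", "base") %in% names(mismatches)))
  if (anyDuplicated(mismatches$offset)) abort("mismatch offsets must be unique")
  if (nrow(mismatches) > 0 &&
      (any(mismatches$offset < 1L) || any(mismatches$offset > length))) {
    abort("mismatch offsets must lie within [1, length]")
  }
  structure(
    list(mito_start = as.integer(mito_start), length = as.integer(length),
         mismatches = mismatches, host_contig = host_contig,
         host_insert_pos = as.integer(host_insert_pos)),
    class = "numt_spec"
  )
}

#' Plant a nuMT copy into a nuclear contig
#'
#' Copies a segment of the mitochondrial contig, applies the specified point
#' mismatches, and paints it onto a nuclear host contig at the given position.
#' The host is created as i.i.d. uniform A/C/G/T background of
#' `background_length` bp if it does not yet exist; only homology to the
#' mitochondrial genome matters for the audit, so the background carries no
#' structure. Two nuMTs may not overlap on the same host.
#'
#' @param refset A `reference_set`.
#' @param spec A [numt_spec()].
#' @param background_length Length of a newly created host contig.
#' @param seed Integer seed for the background sequence.
#' @return A new `reference_set` with the nuMT planted and its `numt_table`
#'   sidecar updated.
#' @export
plant_numt <- function(refset, spec, background_length = 5000L, seed = 1L) {
  stopifnot(inherits(refset, "reference_set"), inherits(spec, "numt_spec"))
  mito <- mito_genome(refset)
  L <- genome_length(mito)
  if (spec$mito_start < 1L || spec$mito_start + spec$length - 1L > L) {
    abort("nuMT source segment out of mitochondrial genome bounds")
  }
  segment <- genome_subseq(mito, spec$mito_start, spec$mito_start + spec$length - 1L)
  for (i in seq_len(nrow(spec$mismatches))) {
    off <- spec$mismatches$offset[i]
    base <- toupper(spec$mismatches$base[i])
    if (!base %in% BASES) abort(sprintf("invalid mismatch base '%s'", base))
    if (substr(segment, off, off) == base) {
      abort(sprintf(
        "mismatch base at offset %d equals the mitochondrial base '%s'",
        off, base))
    }
    substr(segment, off, off) <- base
  }

  host_name <- spec$host_contig
  ins_start <- spec$host_insert_pos
  ins_end <- ins_start + spec$length - 1L
  prior <- refset$numt_table[refset$numt_table$host == host_name, , drop = FALSE]
  if (nrow(prior) > 0 &&
      any(ins_start <= prior$insert_pos + prior$length - 1L &
          ins_end >= prior$insert_pos)) {
    abort(sprintf("nuMT at %s:%d-%d overlaps a previously planted nuMT",
                  host_name, ins_start, ins_end))
  }

  if (host_name %in% ref_contigs(refset)) {
    host <- ref_genome(refset, host_name)
  } else {
    background_length <- max(as.integer(background_length), ins_end)
    host <- genome(host_name,
                   with_seed(stage_seed(seed, paste0("bg::", host_name)),
                             random_dna(background_length)))
  }
  if (ins_start < 1L || ins_end > genome_length(host)) {
    abort("nuMT insert position out of host contig bounds")
  }
  seq <- host$sequence
  substr(seq, ins_start, ins_end) <- segment
  host <- genome(host_name, seq)

  genomes <- refset$genomes
  genomes[[host_name]] <- host
  refset$genomes <- genomes
  refset$numt_table <- dplyr::bind_rows(
    refset$numt_table,
    tibble::tibble(
      host = host_name, insert_pos = ins_start, mito_start = spec$mito_start,
      length = spec$length,
      mismatch_offsets = paste(spec$mismatches$offset, collapse = ","),
      mismatch_bases = paste(spec$mismatches$base, collapse = ","))
  )
  refset
}

# Transition partner of a base (A<->G, C<->T), the most common substitution
# class in mtDNA and the relationship in the chrM:6023G>A exemplar.
transition <- function(base) {
  chartr("ACGT", "GTAC", base)
}

#' One-mismatch nuMT fixture
#'
#' Builds the minimal scenario in which a single alternative allele flips the
#' best-hit locus of every short read covering it: a synthetic mitochondrial
#' genome plus one nuclear contig carrying a copied mitochondrial segment
#' whose single mismatch sits at the focal position. The returned SNV's alt
#' allele equals the nuclear base, so applying it makes the focal window 100%
#' identical to the nuclear copy. This is a synthetic analog of a documented
#' real case where fragments covering a mitochondrial position match a chr1
#' nuMT with exactly one mismatch, and the alternative allele makes them
#' identical to chr1.
#'
#' @param seed Integer seed.
#' @param mito_length Mitochondrial genome length (default 16569).
#' @param flank Number of copied bases on each side of the focal position
#'   (default 150): every read up to `flank` bp covering the focal position
#'   lies entirely within the copy, while 300 bp reads always overhang it.
#' @param focal Focal mitochondrial position (default 6023 when it fits).
#' @return A list with elements `refset` (the `reference_set`), `snv` (the
#'   focal SNV as a one-row tibble), `focal`, `flank`, and `numt_host_pos`
#'   (host coordinate of the mismatched base).
#' @export
one_mismatch_fixture <- function(seed = 1L, mito_length = 16569L, flank = 150L,
                                 focal = NULL) {
  mito <- make_mito_genome(mito_length, seed = seed)
  L <- genome_length(mito)
  focal <- as.integer(focal %||% if (L >= 6023L + flank) 6023L else (L %/% 2L))
  stopifnot(focal - flank >= 1L, focal + flank <= L)
  ref_base <- genome_subseq(mito, focal, focal)
  alt_base <- transition(ref_base)
  pad <- 350L
  spec <- numt_spec(
    mito_start = focal - flank, length = 2L * flank + 1L,
    mismatches = tibble::tibble(offset = flank + 1L, base = alt_base),
    host_contig = "nuc1", host_insert_pos = pad + 1L)
  refset <- plant_numt(reference_set(mito), spec,
                       background_length = 2L * pad + 2L * flank + 1L,
                       seed = seed)
  list(
    refset = refset,
    snv = tibble::tibble(contig = mito$name, pos = focal,
                         ref = ref_base, alt = alt_base),
    focal = focal, flank = flank,
    numt_host_pos = pad + flank + 1L
  )
}

#' Two-mismatch nuMT fixture for the haplotype background scan
#'
#' Builds a nuclear copy that differs from its mitochondrial source at two
#' sites, both within one read length: a "background" site (analogous to a
#' haplogroup-defining SNP whose alt allele equals the nuclear base) and a
#' second divergence site. Reads covering both sites are retained on the
#' mitochondrial contig as long as at most one of their bases matches the
#' nuclear copy (ties break toward the mitochondrial contig), but once the
#' background SNP is present, adding the focal variant that matches the
#' nuclear base at the second site leaves such reads with zero mismatches to
#' the nuclear copy and they are captured — the mechanism by which select
#' haplogroup-defining SNPs exacerbate the coverage loss of surrounding
#' variants.
#'
#' @param seed Integer seed.
#' @param mito_length Mitochondrial genome length (default 6000; the scan
#'   realigns every SNV in a +/-100 bp window, so a compact genome keeps it
#'   fast without changing the mechanism).
#' @param read_length Read length the fixture is engineered for (default 100).
#' @param second_offset Distance from the background site to the second
#'   mismatch (default 60, within one read length so reads can cover both).
#' @return A list with `refset`, `background` (one-row SNV tibble whose alt
#'   equals the nuclear base), `inert_background` (an SNV in a region with no
#'   nuclear homology), `background_pos`, and `second_pos` (position of the
#'   second divergence site on the mitochondrial contig).
#' @export
two_mismatch_fixture <- function(seed = 2L, mito_length = 6000L,
                                 read_length = 100L,
                                 second_offset = 60L) {
  mito <- make_mito_genome(mito_length, seed = seed)
  L <- genome_length(mito)
  bpos <- L %/% 3L
  flank <- read_length + 100L
  seg_start <- bpos - flank
  seg_len <- flank + second_offset + flank + 1L
  stopifnot(seg_start >= 1L, seg_start + seg_len - 1L <= L)
  b_off <- flank + 1L
  s_off <- b_off + second_offset
  b_ref <- genome_subseq(mito, bpos, bpos)
  b_alt <- transition(b_ref)
  s_ref <- genome_subseq(mito, seg_start + s_off - 1L, seg_start + s_off - 1L)
  pad <- 350L
  spec <- numt_spec(
    mito_start = seg_start, length = seg_len,
    mismatches = tibble::tibble(offset = c(b_off, s_off),
                                base = c(b_alt, transition(s_ref))),
    host_contig = "nuc1", host_insert_pos = pad + 1L)
  refset <- plant_numt(reference_set(mito), spec,
                       background_length = 2L * pad + seg_len, seed = seed)

  # An inert background: far from any nuclear homology, on the opposite side
  # of the genome.
  ipos <- min(L - 150L, bpos + L %/% 2L)
  i_ref <- genome_subseq(mito, ipos, ipos)
  list(
    refset = refset,
    background = tibble::tibble(contig = mito$name, pos = bpos,
                                ref = b_ref, alt = b_alt),
    inert_background = tibble::tibble(contig = mito$name, pos = ipos,
                                      ref = i_ref, alt = transition(i_ref)),
    background_pos = bpos,
    second_pos = bpos + second_offset
  )
}
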