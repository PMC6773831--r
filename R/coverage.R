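#' Per-position depth profile of one contig
#'
#' Every mapped primary record adds 1 to each position of its aligned span
#' `[pos, pos + read_length - 1]`; unmapped records contribute nothing.
#' Ambiguous records are counted at their tie-break winner (the package's
#' explicit multi-mapping policy; drop them beforehand with
#' `dplyr::filter(!ambiguous)` for the stricter convention). Paired-end
#' records are counted per mate over each mate's own span.
#'
#' @param records An `alignment_set`.
#' @param contig Contig to profile.
#' @param contig_length Length of that contig (taken from `refset` if given).
#' @param refset Optional `reference_set` supplying the contig length.
#' @param drop_ambiguous Exclude ambiguous records? Default `FALSE`.
#' @return A `coverage_profile` tibble with columns `pos`, `depth`.
#' @export
depth_profile <- function(records, contig, contig_length = NULL, refset = NULL,
                          drop_ambiguous = FALSE) {
  if (is.null(contig_length)) {
    if (is.null(refset)) abort("supply contig_length or refset")
    contig_length <- genome_length(ref_genome(refset, contig))
  }
  r <- records[records$mapped & records$contig == contig, , drop = FALSE]
  if (drop_ambiguous) r <- r[!r$ambiguous, , drop = FALSE]
  lens <- nchar(r$seq)
  ends <- r$pos + lens - 1L
  if (any(r$pos < 1L) || any(ends > contig_length)) {
    abort(sprintf("alignment record extends past end of contig '%s'", contig))
  }
  # difference-array accumulation
  d <- integer(contig_length + 1L)
  if (nrow(r) > 0) {
    add <- tabulate(r$pos, nbins = contig_length + 1L)
    sub <- tabulate(ends + 1L, nbins = contig_length + 1L)
    d <- add - sub
  }
  structure(
    tibble::tibble(pos = seq_len(contig_length),
                   depth = cumsum(d)[seq_len(contig_length)]),
    class = c("coverage_profile", class(tibble::tibble())),
    contig = contig
  )
}

#' Depth at selected positions
#' @param profile A `coverage_profile`.
#' @param pos Positions to query.
#' @return Integer depths.
#' @export
depth_at <- function(profile, pos) profile$depth[pos]

#' Percent coverage loss at a mutated position
#'
#' Defined as `100 * (1 - mut_depth / ref_depth)`: the percent reduction of
#' depth at the mutated position relative to depth at the same position under
#' the unaltered reference fragments. A variant whose alternative-allele
#' fragments all realign to nuclear loci therefore scores 100%. The value is
#' not clamped — it is negative if coverage increased — and a zero reference
#' depth is an error (the position cannot be audited).
#'
#' @param ref_depth Depth under the reference alignment (> 0).
#' @param mut_depth Depth under the mutated-genome alignment.
#' @return Percent loss (vectorised).
#' @export
coverage_loss <- function(ref_depth, mut_depth) {
  if (any(ref_depth <= 0)) {
    abort("coverage_loss() requires ref_depth > 0 at every audited position")
  }
  100 * (1 - mut_depth / ref_depth)
}

align_for_config <- function(frags, index, max_mismatch) {
  cfg <- attr(frags, "read_config")
  if (cfg$layout == "paired") {
    align_paired(frags, index, max_mismatch = max_mismatch)
  } else {
    align_fragments(frags, index, max_mismatch = max_mismatch)
  }
}

# Number of mapped records on `contig` whose span covers `pos`.
span_count_at <- function(records, contig, pos) {
  r <- records[records$mapped & records$contig == contig, , drop = FALSE]
  sum(r$pos <= pos & r$pos + nchar(r$seq) - 1L >= pos)
}

# Templates whose reads can carry a base at `pos` (and whose fragments
# therefore differ between reference and mutated genome).
overlapping_templates <- function(frags, pos) {
  cfg <- attr(frags, "read_config")
  rl <- cfg$read_length
  if (cfg$layout == "single") {
    frags$template_start <= pos & frags$template_start + rl - 1L >= pos
  } else {
    m1 <- frags$template_start
    m2 <- frags$template_start + frags$template_length - rl
    (m1 <= pos & m1 + rl - 1L >= pos) | (m2 <= pos & m2 + rl - 1L >= pos)
  }
}

# Rebuild the fragments of the given template rows from a mutated genome,
# reusing the reference run's template starts and lengths so range-insert
# sampling is reproduced exactly.
rebuild_fragments <- function(ref_frags, genome, rows) {
  cfg <- attr(ref_frags, "read_config")
  rl <- cfg$read_length
  sub <- ref_frags[rows, , drop = FALSE]
  seq <- genome$sequence
  s <- sub$read_start
  out <- sub
  is_m2 <- sub$mate == 2L
  fwd <- substring(seq, s, s + rl - 1L)
  out$seq <- ifelse(is_m2, revcomp(fwd), fwd)
  new_fragment_set(out, cfg, genome$name)
}

#' Exhaustive per-variant coverage-loss sweep
#'
#' For each SNV, applies it to the source genome, re-simulates the fragments
#' that can carry the mutated base, realigns only those against the full
#' reference set, and records the depth at the mutated position relative to
#' the reference alignment. Only fragments overlapping the variant position
#' differ from the reference set, so the cached reference alignment is reused
#' everywhere else; results are identical to a from-scratch realignment of
#' every mutated genome (asserted against that oracle in the test suite) and
#' independent of sweep order. Run over [enumerate_snvs()] output, this is
#' the full 3L-variant saturation sweep.
#'
#' @param refset A `reference_set` to align against.
#' @param cfg A [read_config()].
#' @param snvs SNV tibble (`contig`, `pos`, `ref`, `alt`); positions must lie
#'   on the source genome.
#' @param source_genome Genome the fragments are simulated from; defaults to
#'   the reference set's mitochondrial contig. Supplying a genome that
#'   already carries a background SNP turns this into the haplotype scan's
#'   inner loop, with the loss denominator taken from that genome's own
#'   alignment.
#' @param index Optional prebuilt [build_index()]; built on demand.
#' @param max_mismatch Aligner mismatch cap (default 4).
#' @param k Seed length when `index` is not supplied.
#' @param ref_alignment Optional cached alignment of the source fragments.
#' @return A `loss_sweep` tibble: `contig`, `pos`, `ref`, `alt`,
#'   `read_length`, `layout`, `ref_depth`, `mut_depth`, `loss_pct`.
#' @export
variant_sweep <- function(refset, cfg, snvs, source_genome = NULL,
                          index = NULL, max_mismatch = 4L, k = 19L,
                          ref_alignment = NULL) {
  source_genome <- source_genome %||% mito_genome(refset)
  index <- index %||% build_index(refset, k = k)
  mito_name <- source_genome$name
  L <- genome_length(source_genome)
  if (any(snvs$pos < 1L | snvs$pos > L)) abort("SNV position outside source genome")

  ref_frags <- fragment_genome(source_genome, cfg)
  ref_aln <- ref_alignment %||% align_for_config(ref_frags, index, max_mismatch)
  ref_profile <- depth_profile(ref_aln, mito_name, contig_length = L)

  n <- nrow(snvs)
  ref_depth <- depth_at(ref_profile, snvs$pos)
  mut_depth <- integer(n)
  for (i in seq_len(n)) {
    snv <- snvs[i, ]
    mut <- apply_snv(source_genome, snv)
    rows <- which(overlapping_templates(ref_frags, snv$pos))
    if (cfg$layout == "paired" && length(rows) > 0) {
      # realign both mates of any template whose pair carries the variant:
      # the unchanged mate's placement can still move through joint pairing
      rows <- which(ref_frags$read_id %in% unique(ref_frags$read_id[rows]))
    }
    if (length(rows) == 0) {
      mut_depth[i] <- ref_depth[i]
      next
    }
    mut_frags <- rebuild_fragments(ref_frags, mut, rows)
    mut_aln <- align_for_config(mut_frags, index, max_mismatch)
    ref_contrib <- span_count_at(ref_aln[rows, , drop = FALSE], mito_name, snv$pos)
    mut_contrib <- span_count_at(mut_aln, mito_name, snv$pos)
    mut_depth[i] <- ref_depth[i] - ref_contrib + mut_contrib
  }
  new_loss_sweep(tibble::tibble(
    contig = snvs$contig, pos = snvs$pos, ref = snvs$ref, alt = snvs$alt,
    read_length = cfg$read_length, layout = cfg$layout,
    ref_depth = ref_depth, mut_depth = mut_depth,
    loss_pct = coverage_loss(ref_depth, mut_depth)), cfg)
}

new_loss_sweep <- function(tbl, cfg) {
  structure(tbl, class = c("loss_sweep", class(tibble::tibble())),
            read_config = cfg)
}

#' Full-realignment oracle for a single variant
#'
#' Computes one variant's coverage loss by fragmenting and realigning the
#' entire mutated genome from scratch, with no caching. Slow; exists to
#' verify [variant_sweep()]'s locality optimisation.
#'
#' @inheritParams variant_sweep
#' @param snv One-row SNV tibble.
#' @return A one-row `loss_sweep` tibble.
#' @export
full_realignment_loss <- function(refset, cfg, snv, source_genome = NULL,
                                  index = NULL, max_mismatch = 4L, k = 19L) {
  source_genome <- source_genome %||% mito_genome(refset)
  index <- index %||% build_index(refset, k = k)
  mito_name <- source_genome$name
  L <- genome_length(source_genome)
  ref_aln <- align_for_config(fragment_genome(source_genome, cfg), index, max_mismatch)
  mut <- apply_snv(source_genome, snv)
  mut_aln <- align_for_config(fragment_genome(mut, cfg), index, max_mismatch)
  rd <- depth_at(depth_profile(ref_aln, mito_name, contig_length = L), snv$pos)
  md <- depth_at(depth_profile(mut_aln, mito_name, contig_length = L), snv$pos)
  new_loss_sweep(tibble::tibble(
    contig = snv$contig, pos = snv$pos, ref = snv$ref, alt = snv$alt,
    read_length = cfg$read_length, layout = cfg$layout,
    ref_depth = rd, mut_depth = md, loss_pct = coverage_loss(rd, md)), cfg)
}

#' Bin coverage-loss records by threshold
#'
#' Counts records with loss strictly greater than each threshold, and the
#' number of distinct positions among them. Paired-end sweeps first apply a
#' `> 3%` floor to absorb insert-size jitter before binning.
#'
#' @param records A `loss_sweep`.
#' @param thresholds Percent thresholds (default `c(0, 10, 20, 50)`).
#' @param pe_floor Floor (percent) applied to paired-end records before
#'   binning (default 3).
#' @return A tibble with `threshold`, `n_variants`, `n_positions`.
#' @export
bin_losses <- function(records, thresholds = c(0, 10, 20, 50), pe_floor = 3) {
  loss <- records$loss_pct
  pos <- records$pos
  if (nrow(records) > 0 && any(records$layout == "paired")) {
    keep <- records$layout != "paired" | loss > pe_floor
    loss <- loss[keep]
    pos <- pos[keep]
  }
  tibble::tibble(
    threshold = thresholds,
    n_variants = vapply(thresholds, function(t) sum(loss > t), integer(1)),
    n_positions = vapply(thresholds, function(t) length(unique(pos[loss > t])),
                         integer(1)))
}

#' Coverage-loss scan across the circular breakpoint
#'
#' Variants near the join of a circular genome's linear representation cannot
#' be audited against the linear reference (reads there fall off the sequence
#' ends), so they are introduced into a rotated ("shifted") copy of the
#' genome and aligned against the shifted reference alone. Enumerates all
#' SNVs within `window` bp of the linear breakpoint, sweeps them on the
#' shifted genome, and reports losses in original coordinates.
#'
#' @param genome A circular `genome`.
#' @param cfg A [read_config()].
#' @param window Scan half-width in bp around the breakpoint (default 100).
#' @param shift_offset Rotation offset (default `L %/% 2`).
#' @inheritParams variant_sweep
#' @return A `loss_sweep` tibble with an extra `shifted_pos` column; `pos`
#'   is in original coordinates.
#' @export
breakpoint_scan <- function(genome, cfg, window = 100L,
                            shift_offset = NULL, max_mismatch = 4L, k = 19L) {
  if (!genome$circular) abort("breakpoint_scan() requires a circular genome")
  L <- genome_length(genome)
  window <- as.integer(window)
  shift_offset <- as.integer(shift_offset %||% (L %/% 2L))
  shifted <- shift_genome(genome, shift_offset)
  orig_pos <- if (window == 0L) integer(0) else {
    unique(c(seq.int(max(1L, L - window + 1L), L), seq_len(min(window, L))))
  }
  if (length(orig_pos) == 0) {
    return(new_loss_sweep(tibble::tibble(
      contig = character(), pos = integer(), ref = character(),
      alt = character(), read_length = integer(), layout = character(),
      ref_depth = integer(), mut_depth = integer(), loss_pct = numeric(),
      shifted_pos = integer()), cfg))
  }
  all_snvs <- enumerate_snvs(shifted)
  spos <- shifted_position(orig_pos, shift_offset, L)
  snvs <- all_snvs[all_snvs$pos %in% spos, ]
  res <- variant_sweep(reference_set(shifted), cfg, snvs,
                       max_mismatch = max_mismatch, k = k)
  res$shifted_pos <- res$pos
  res$pos <- unshifted_position(res$shifted_pos, shift_offset, L)
  res
}

#' Write a coverage-loss sweep as TSV
#' @param records A `loss_sweep`.
#' @param path Output path.
#' @param comment Optional header comment lines (prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(records, path, comment = NULL) {
  con <- file(path, "w")
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  close(con)
  readr::write_tsv(tibble::as_tibble(records), path, append = !is.null(comment),
                   col_names = TRUE)
  invisible(path)
}

#' Write a coverage profile as BedGraph
#' @param profile A `coverage_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  contig <- attr(profile, "contig")
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = profile$pos, width = 1L),
    score = profile$depth)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}
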