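#' Base pileup at one position
#'
#' Counts the base contributed at `pos` by every mapped primary record whose
#' aligned span covers it. Alignment is gapless, so a forward-strand record
#' contributes `read[pos - aln_pos + 1]` and a reverse-strand record the
#' complement of the corresponding base of the stored (original-orientation)
#' read. With error-free Q40 reads this counting pileup is an exact
#' allele-frequency estimator, so any deficit it reports is a property of
#' alignment, not of the caller.
#'
#' @param records An `alignment_set` (must carry read sequences).
#' @param contig Contig name.
#' @param pos 1-based position.
#' @param drop_ambiguous Exclude ambiguous records? Default `FALSE`.
#' @return A one-row `pileup` tibble: `contig`, `pos`, `A`, `C`, `G`, `T`,
#'   `depth`.
#' @export
pileup_at <- function(records, contig, pos, drop_ambiguous = FALSE) {
  r <- records[records$mapped & records$contig == contig, , drop = FALSE]
  if (drop_ambiguous) r <- r[!r$ambiguous, , drop = FALSE]
  lens <- nchar(r$seq)
  r <- r[r$pos <= pos & r$pos + lens - 1L >= pos, , drop = FALSE]
  if (nrow(r) > 0) {
    off <- pos - r$pos + 1L
    len <- nchar(r$seq)
    fwd_base <- substr(r$seq, off, off)
    rev_base <- complement_base(substr(r$seq, len - off + 1L, len - off + 1L))
    base <- ifelse(r$strand == "-", rev_base, fwd_base)
    counts <- table(factor(base, levels = BASES))
  } else {
    counts <- stats::setNames(rep(0L, 4L), BASES)
  }
  structure(
    tibble::tibble(contig = contig, pos = pos,
                   A = as.integer(counts[["A"]]), C = as.integer(counts[["C"]]),
                   G = as.integer(counts[["G"]]), T = as.integer(counts[["T"]]),
                   depth = as.integer(sum(counts))),
    class = c("pileup", class(tibble::tibble())))
}

#' Observed minor allele frequency at a heteroplasmic site
#'
#' The observed MAF is the alternative-allele fraction of the pileup,
#' `count(alt) / depth`. Under nuMT confounding it falls below the nominal
#' (true) heteroplasmy because alternative-allele reads preferentially align
#' to nuclear loci; a fully confounded variant has observed MAF 0 and is
#' undetectable. `detected` compares the observed MAF against a detection
#' threshold (default 1%), mirroring how low-frequency variants can be
#' screened out when the observed MAF falls below a pre-set cutoff.
#'
#' @param pileup A [pileup_at()] result at the variant position.
#' @param snv One-row SNV tibble.
#' @param nominal Nominal (true) heteroplasmy fraction in `[0, 1]`.
#' @param threshold Detection threshold on the observed MAF (default 0.01).
#' @return A one-row `maf_call` tibble: `contig`, `pos`, `ref`, `alt`,
#'   `nominal_maf`, `observed_maf`, `depth`, `detected`, `zero_depth`.
#' @export
observed_maf <- function(pileup, snv, nominal, threshold = 0.01) {
  snv <- tibble::as_tibble(snv)[1, ]
  stopifnot(identical(pileup$contig, snv$contig), identical(pileup$pos, snv$pos))
  depth <- pileup$depth
  zero <- depth == 0L
  if (zero) {
    warn(sprintf("zero depth at %s:%d: variant is undetectable",
                 snv$contig, snv$pos))
  }
  maf <- if (zero) 0 else pileup[[snv$alt]] / depth
  structure(
    tibble::tibble(
      contig = snv$contig, pos = snv$pos, ref = snv$ref, alt = snv$alt,
      nominal_maf = nominal, observed_maf = maf, depth = depth,
      detected = maf >= threshold, zero_depth = zero),
    class = c("maf_call", class(tibble::tibble())))
}

#' End-to-end heteroplasmy audit of one variant
#'
#' Simulates reference and mutated fragment sets, mixes them at exact copy
#' counts, aligns the mixture against the full reference set, and reports the
#' observed MAF at the variant position.
#'
#' @param refset A `reference_set`.
#' @param cfg A [read_config()].
#' @param snv One-row SNV tibble on the mitochondrial contig.
#' @param ref_copies,mut_copies Mixture copy counts (see [mix_fragments()]).
#' @param index Optional prebuilt [build_index()].
#' @param max_mismatch Aligner mismatch cap (default 4).
#' @param k Seed length when `index` is not supplied.
#' @param threshold Detection threshold (default 0.01).
#' @return A one-row `maf_call` tibble (see [observed_maf()]).
#' @export
heteroplasmy_audit <- function(refset, cfg, snv, ref_copies = 1L,
                               mut_copies = 1L, index = NULL,
                               max_mismatch = 4L, k = 19L, threshold = 0.01) {
  index <- index %||% build_index(refset, k = k)
  mito <- mito_genome(refset)
  snv <- tibble::as_tibble(snv)[1, ]
  ref_frags <- fragment_genome(mito, cfg)
  mut_frags <- fragment_genome(apply_snv(mito, snv), cfg)
  mixed <- mix_fragments(ref_frags, mut_frags, ref_copies, mut_copies)
  aln <- align_for_config(mixed, index, max_mismatch)
  p <- pileup_at(aln, mito$name, snv$pos)
  observed_maf(p, snv, nominal = attr(mixed, "nominal_het"),
               threshold = threshold)
}

#' Join coverage losses with heteroplasmy calls into a bias report
#'
#' One row per audited variant with its coverage loss, nominal and observed
#' MAF, and the reference-bias deficit `nominal - observed`. For fixtures in
#' which the nuMT matches the alternative allele, misalignment removes only
#' alt-carrying reads, so the deficit is non-negative up to counting
#' granularity.
#'
#' @param losses A `loss_sweep`.
#' @param calls A tibble of `maf_call` rows computed under the identical
#'   [read_config()].
#' @return A `bias_report` tibble with `deficit = nominal_maf - observed_maf`.
#' @export
bias_report <- function(losses, calls) {
  lcfg <- attr(losses, "read_config")
  if (!is.null(lcfg) && !is.null(attr(calls, "read_config")) &&
      !same_config(lcfg, attr(calls, "read_config"))) {
    abort("losses and calls were computed under different read configs")
  }
  out <- dplyr::inner_join(
    tibble::as_tibble(losses)[, c("contig", "pos", "ref", "alt",
                                  "read_length", "layout", "loss_pct")],
    tibble::as_tibble(calls)[, c("contig", "pos", "ref", "alt", "nominal_maf",
                                 "observed_maf", "depth", "detected")],
    by = c("contig", "pos", "ref", "alt"))
  out$deficit <- out$nominal_maf - out$observed_maf
  structure(out, class = c("bias_report", class(tibble::tibble())))
}

#' Write MAF calls as TSV (and optionally a sites-only VCF with AF)
#'
#' @param calls A tibble of `maf_call` rows.
#' @param path TSV output path.
#' @param vcf_path Optional VCF output path (AF in INFO).
#' @param refset Optional `reference_set` for VCF contig headers.
#' @return `path`, invisibly.
#' @export
write_maf_tsv <- function(calls, path, vcf_path = NULL, refset = NULL) {
  readr::write_tsv(tibble::as_tibble(calls), path)
  if (!is.null(vcf_path)) {
    con <- file(vcf_path, "w")
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##source=numtaudit",
      "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Observed allele frequency\">"),
      con)
    if (!is.null(refset)) {
      for (g in refset$genomes) {
        writeLines(sprintf("##contig=<ID=%s,length=%d>", g$name,
                           genome_length(g)), con)
      }
    }
    writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
    if (nrow(calls) > 0) {
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAF=%g",
                         calls$contig, calls$pos, calls$ref, calls$alt,
                         calls$observed_maf), con)
    }
    close(con)
  }
  invisible(path)
}
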