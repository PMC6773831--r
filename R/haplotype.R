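#' Coverage-loss scan around a background (haplogroup-defining) SNP
#'
#' Quantifies how a background SNP changes the coverage loss of every
#' possible SNV within a window around it. `loss_without` sweeps each focal
#' SNV on the plain genome; `loss_with` sweeps it on the genome already
#' carrying the background SNP, aligned against the same reference set, with
#' the loss denominator taken from the background genome's own reference
#' alignment so the background's solo loss does not contaminate the
#' comparison. Reads carrying both variants have two mismatches to the
#' reference mitochondrial contig, so a background allele that matches a
#' nuclear base can tip their best-hit locus to the nuMT — the mechanism by
#' which select haplogroup-defining SNPs exacerbate the loss of surrounding
#' variants, while SNPs in regions without nuclear homology leave it
#' unchanged.
#'
#' @param refset A `reference_set`.
#' @param cfg A [read_config()].
#' @param background One-row SNV tibble on the mitochondrial contig.
#' @param window Scan half-width in bp (default 100); the focal set is every
#'   SNV within `background$pos` +/- `window`, excluding the background
#'   position itself, truncated (with a message) at contig ends.
#' @param index Optional prebuilt [build_index()].
#' @param max_mismatch Aligner mismatch cap (default 4).
#' @param k Seed length when `index` is not supplied.
#' @return A `background_scan` tibble: focal `contig`, `pos`, `ref`, `alt`,
#'   `loss_without`, `loss_with`, `delta = loss_with - loss_without`, with
#'   the background SNV attached as an attribute.
#' @export
background_scan <- function(refset, cfg, background, window = 100L,
                            index = NULL, max_mismatch = 4L, k = 19L) {
  background <- tibble::as_tibble(background)[1, ]
  mito <- mito_genome(refset)
  check_snv(mito, as.list(background))
  index <- index %||% build_index(refset, k = k)
  L <- genome_length(mito)
  window <- as.integer(window)

  lo <- background$pos - window
  hi <- background$pos + window
  if (lo < 1L || hi > L) {
    message(sprintf(
      "focal window [%d, %d] truncated to contig bounds [1, %d]", lo, hi, L))
    lo <- max(1L, lo)
    hi <- min(L, hi)
  }
  all_snvs <- enumerate_snvs(mito)
  focal <- all_snvs[all_snvs$pos >= lo & all_snvs$pos <= hi &
                      all_snvs$pos != background$pos, ]
  if (nrow(focal) == 0) {
    return(structure(
      tibble::tibble(contig = character(), pos = integer(), ref = character(),
                     alt = character(), loss_without = numeric(),
                     loss_with = numeric(), delta = numeric()),
      class = c("background_scan", class(tibble::tibble())),
      background = background, read_config = cfg))
  }

  without <- variant_sweep(refset, cfg, focal, index = index,
                           max_mismatch = max_mismatch)
  bg_genome <- apply_snv(mito, background)
  with_bg <- variant_sweep(refset, cfg, focal, source_genome = bg_genome,
                           index = index, max_mismatch = max_mismatch)
  structure(
    tibble::tibble(
      contig = focal$contig, pos = focal$pos, ref = focal$ref, alt = focal$alt,
      loss_without = without$loss_pct, loss_with = with_bg$loss_pct,
      delta = with_bg$loss_pct - without$loss_pct),
    class = c("background_scan", class(tibble::tibble())),
    background = background, read_config = cfg)
}

#' Read a background-SNP catalog TSV
#'
#' Accepts a user-supplied table of haplogroup-defining SNPs with columns
#' `contig`, `pos`, `ref`, `alt` and optional `label`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_background_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols())
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(out))) {
    abort(sprintf("background TSV must have columns %s",
                  paste(need, collapse = ", ")))
  }
  out$pos <- as.integer(out$pos)
  out
}

#' Scan several background SNPs and summarise
#'
#' Runs [background_scan()] for each row of `backgrounds` and returns the
#' long-format scan plus a per-background summary (max and mean delta, number
#' of focal SNVs with a positive delta).
#'
#' @inheritParams background_scan
#' @param backgrounds SNV tibble with optional `label` column.
#' @return A list with `scan` (long tibble) and `summary` (one row per
#'   background).
#' @export
background_scan_many <- function(refset, cfg, backgrounds, window = 100L,
                                 index = NULL, max_mismatch = 4L, k = 19L) {
  backgrounds <- tibble::as_tibble(backgrounds)
  index <- index %||% build_index(refset, k = k)
  scans <- lapply(seq_len(nrow(backgrounds)), function(i) {
    b <- backgrounds[i, ]
    s <- background_scan(refset, cfg, b, window = window, index = index,
                         max_mismatch = max_mismatch)
    s$background <- format_snv(b)
    if ("label" %in% names(b)) s$background_label <- b$label
    tibble::as_tibble(s)
  })
  scan <- dplyr::bind_rows(scans)
  summary <- scan |>
    dplyr::group_by(.data$background) |>
    dplyr::summarise(
      n_focal = dplyr::n(),
      n_delta_pos = sum(.data$delta > 0),
      max_delta = max(.data$delta),
      mean_delta = mean(.data$delta),
      .groups = "drop")
  list(scan = scan, summary = summary)
}
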