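#' Create a genome (one reference contig)
#'
#' A genome is a single named contig with an uppercase A/C/G/T sequence and a
#' circularity flag. Coordinates throughout the package are 1-based inclusive,
#' matching mitochondrial variant notation such as `chrM:6023G>A`; conversion
#' to 0-based happens only inside file-format writers.
#'
#' @param name Contig identifier.
#' @param sequence DNA string (A/C/G/T only, upper-cased on input).
#' @param circular Is the contig circular (true for mitochondrial genomes)?
#' @return An object of class `genome`.
#' @export
genome <- function(name, sequence, circular = FALSE) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) abort("genome sequence must be non-empty")
  assert_dna(sequence, sprintf("contig '%s'", name))
  structure(
    list(name = name, sequence = sequence, circular = isTRUE(circular)),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp (%s)\n", x$name,
              format(genome_length(x), big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Length of a genome in base pairs
#' @param x A `genome`.
#' @return Integer length.
#' @export
genome_length <- function(x) nchar(x$sequence)

genome_subseq <- function(x, start, end) substr(x$sequence, start, end)

#' Bundle contigs into a reference set
#'
#' A reference set holds exactly one mitochondrial contig plus zero or more
#' nuclear contigs, standing in for a whole-genome reference in which nuMTs
#' (nuclear sequences of mitochondrial origin) compete with the mitochondrial
#' contig for read placements. Contig order matters: it is the deterministic
#' tie-break order of the aligner, with the mitochondrial contig first by
#' default (conservative: ambiguous reads stay on the mitochondrial contig).
#'
#' @param mito The mitochondrial `genome`.
#' @param nuclear A list of nuclear `genome` objects (may be empty).
#' @param mito_first Place the mitochondrial contig first in tie-break order?
#'   Set `FALSE` for sensitivity analysis (biases ties toward nuMTs).
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(mito, nuclear = list(), mito_first = TRUE) {
  stopifnot(inherits(mito, "genome"))
  if (inherits(nuclear, "genome")) nuclear <- list(nuclear)
  stopifnot(all(vapply(nuclear, inherits, logical(1), "genome")))
  nms <- c(mito$name, vapply(nuclear, `[[`, character(1), "name"))
  if (anyDuplicated(nms)) {
    abort(sprintf("contig names must be distinct; duplicated: %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  genomes <- c(list(mito), nuclear)
  names(genomes) <- nms
  if (!mito_first && length(nuclear) > 0) {
    genomes <- genomes[c(setdiff(nms, mito$name), mito$name)]
  }
  structure(
    list(genomes = genomes, mito = mito$name,
         numt_table = empty_numt_table()),
    class = "reference_set"
  )
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d contig(s); mitochondrial: %s\n",
              length(x$genomes), x$mito))
  for (g in x$genomes) {
    cat(sprintf("  %s%s: %s bp\n", g$name, if (g$name == x$mito) " [mito]" else "",
                format(genome_length(g), big.mark = ",")))
  }
  if (nrow(x$numt_table) > 0) {
    cat(sprintf("  %d planted nuMT(s)\n", nrow(x$numt_table)))
  }
  invisible(x)
}

#' Contig names in aligner tie-break order
#' @param refset A `reference_set`.
#' @return Character vector of contig names.
#' @export
ref_contigs <- function(refset) names(refset$genomes)

ref_genome <- function(refset, contig) {
  g <- refset$genomes[[contig]]
  if (is.null(g)) abort(sprintf("unknown contig '%s'", contig))
  g
}

#' @rdname ref_contigs
#' @export
mito_genome <- function(refset) refset$genomes[[refset$mito]]

#' Generate a synthetic mitochondrial genome
#'
#' Draws an i.i.d. uniform A/C/G/T circular sequence and screens it for
#' self-similarity: no k-mer (seed length `k`, matching the aligner's default
#' seed) may occur twice across both strands. This guarantees that, absent
#' nuMTs, every error-free fragment of length >= k maps back uniquely to its
#' origin, so any coverage loss observed downstream is nuMT-driven. The
#' canonical human mitochondrial reference is 16,569 bp, the default here.
#'
#' @param length Genome length in bp (default 16569). Must be at least
#'   `2 * max_read_length`.
#' @param seed Integer seed; generation is fully deterministic.
#' @param k Seed length used for the repeat screen (default 19, the aligner
#'   default).
#' @param max_read_length Largest read length the genome must support
#'   (default 300).
#' @param max_tries Number of regeneration attempts before giving up.
#' @return A circular `genome` named `"chrM"`.
#' @export
make_mito_genome <- function(length = 16569L, seed = 1L, k = 19L,
                             max_read_length = 300L, max_tries = 50L) {
  length <- as.integer(length)
  if (length < 2L * max_read_length) {
    abort(sprintf(
      "genome length %d too small: must be >= 2 x max read length (%d)",
      length, 2L * max_read_length))
  }
  for (try in seq_len(max_tries)) {
    seq <- with_seed(stage_seed(seed, paste0("mito", try)), random_dna(length))
    if (!has_repeat(seq, k)) {
      return(genome("chrM", seq, circular = TRUE))
    }
  }
  abort(sprintf("failed to generate a repeat-free genome in %d tries", max_tries))
}

# TRUE if any k-mer occurs more than once across both strands.
has_repeat <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(FALSE)
  starts <- seq_len(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  if (anyDuplicated(fwd)) return(TRUE)
  any(revcomp(fwd) %in% fwd)
}

#' Rotate a circular genome
#'
#' Returns the rotation whose first base is original position `offset + 1`.
#' Used to build a shifted reference so that variants near the linear
#' breakpoint of a circular genome can be audited away from sequence ends.
#'
#' @param genome A circular `genome`.
#' @param offset Rotation offset in bp, `0 <= offset < length`.
#' @return A `genome` of identical length. Position `p` on the original maps
#'   to `((p - 1 - offset) %% L) + 1` on the shifted genome.
#' @export
shift_genome <- function(genome, offset) {
  if (!genome$circular) abort("shift_genome() requires a circular genome")
  L <- genome_length(genome)
  offset <- as.integer(offset)
  if (offset < 0L || offset >= L) abort("offset must satisfy 0 <= offset < L")
  if (offset == 0L) return(genome)
  rotated <- paste0(substr(genome$sequence, offset + 1L, L),
                    substr(genome$sequence, 1L, offset))
  genome(genome$name, rotated, circular = TRUE)
}

#' Map positions between a genome and its shifted rotation
#'
#' @param pos 1-based positions on the original genome.
#' @param offset Rotation offset passed to [shift_genome()].
#' @param L Genome length.
#' @return Positions on the shifted genome.
#' @export
shifted_position <- function(pos, offset, L) {
  ((pos - 1L - offset) %% L) + 1L
}

#' @rdname shifted_position
#' @export
unshifted_position <- function(pos, offset, L) {
  ((pos - 1L + offset) %% L) + 1L
}

#' Write a reference set as multi-record FASTA
#'
#' Records are wrapped at 60 columns. If nuMTs were planted, a sidecar TSV
#' (`<path>.numts.tsv`) records each planted copy for test introspection.
#'
#' @param refset A `reference_set`.
#' @param path Output FASTA path.
#' @param sidecar Write the nuMT sidecar TSV? Default `TRUE` when any nuMT
#'   is present.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refset, path, sidecar = nrow(refset$numt_table) > 0) {
  seqs <- Biostrings::DNAStringSet(
    vapply(refset$genomes, `[[`, character(1), "sequence"))
  names(seqs) <- ref_contigs(refset)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60L)
  if (sidecar) {
    readr::write_tsv(refset$numt_table, paste0(path, ".numts.tsv"))
  }
  invisible(path)
}

#' Read a reference set from FASTA
#'
#' @param path FASTA path.
#' @param mito Name of the mitochondrial contig (default: first record).
#' @param circular_mito Flag the mitochondrial contig circular?
#' @return A `reference_set`.
#' @export
read_fasta <- function(path, mito = NULL, circular_mito = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*$", "", names(seqs))
  mito <- mito %||% nms[1]
  if (!mito %in% nms) abort(sprintf("mitochondrial contig '%s' not in %s", mito, path))
  gs <- lapply(seq_along(seqs), function(i) {
    genome(nms[i], as.character(seqs[[i]]),
           circular = identical(nms[i], mito) && circular_mito)
  })
  names(gs) <- nms
  reference_set(gs[[mito]], unname(gs[nms != mito]))
}
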