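#' Read-simulation configuration
#'
#' Describes one sliding-window fragmentation run. Fragmentation is
#' exhaustive and deterministic: templates start at every `step`-th position
#' from position 1, so with `step = 1` the maximum per-position depth equals
#' the read length for single-end runs (100x/150x/300x for 100/150/300 bp
#' reads) and twice the read length for paired-end runs with abutting mates
#' (insert = 2 x read length: 200x/300x/600x).
#'
#' @param read_length Read length in bp (canonical choices 100, 150, 300).
#' @param layout `"single"` or `"paired"`.
#' @param insert_size Paired-end template length: a single fixed value
#'   (e.g. 200) or an inclusive integer range `c(lo, hi)` (e.g. `c(200, 205)`,
#'   for aligners requiring a non-zero insert-size standard deviation).
#'   "Insert size" means total template length, so insert 200 with 2 x 100 bp
#'   reads gives abutting, non-overlapping mates.
#' @param step Window step in bp (default 1).
#' @param seed Integer seed used only for range insert sampling.
#' @return An object of class `read_config`.
#' @export
read_config <- function(read_length = 100L, layout = c("single", "paired"),
                        insert_size = NULL, step = 1L, seed = 1L) {
  layout <- match.arg(layout)
  read_length <- as.integer(read_length)
  step <- as.integer(step)
  stopifnot(read_length >= 1L, step >= 1L)
  if (layout == "paired") {
    if (is.null(insert_size)) insert_size <- 2L * read_length
    insert_size <- as.integer(insert_size)
    stopifnot(length(insert_size) %in% c(1L, 2L))
    if (length(insert_size) == 2L && insert_size[1] > insert_size[2]) {
      abort("insert_size range must satisfy lo <= hi")
    }
    if (min(insert_size) < read_length) {
      abort("insert_size must be >= read_length (template holds each mate)")
    }
  } else {
    insert_size <- NULL
  }
  structure(
    list(read_length = read_length, layout = layout,
         insert_size = insert_size, step = step, seed = as.integer(seed)),
    class = "read_config"
  )
}

#' @export
print.read_config <- function(x, ...) {
  ins <- if (is.null(x$insert_size)) "" else
    sprintf(", insert %s", paste(x$insert_size, collapse = "-"))
  cat(sprintf("<read_config> %d bp %s-end, step %d%s\n",
              x$read_length, x$layout, x$step, ins))
  invisible(x)
}

config_label <- function(cfg) {
  sprintf("%dbp_%s", cfg$read_length,
          if (cfg$layout == "single") "SE" else "PE")
}

same_config <- function(a, b) {
  identical(a[c("read_length", "layout", "insert_size", "step", "seed")],
            b[c("read_length", "layout", "insert_size", "step", "seed")])
}

# Deterministic per-start insert lengths for a range insert; regenerating a
# subset of templates reproduces the full run's inserts exactly.
sample_inserts <- function(cfg, n_starts) {
  ins <- cfg$insert_size
  if (length(ins) == 1L) return(rep(ins, n_starts))
  with_seed(stage_seed(cfg$seed, "insert"),
            sample(seq(ins[1], ins[2]), n_starts, replace = TRUE))
}

#' Fragment a genome into sliding-window reads
#'
#' Produces the exhaustive, error-free read set: one template per window
#' start, forward strand, all bases at quality Q40 when written to FASTQ.
#' Single-end fragments are the template itself; paired-end fragments take
#' read 1 as the template's first `read_length` bases (forward) and read 2 as
#' the reverse complement of its last `read_length` bases (standard FR
#' orientation). Circular genomes are fragmented in linear mode by default,
#' giving the familiar depth ramps at both sequence ends; `wrap = TRUE`
#' additionally emits templates spanning the breakpoint.
#'
#' @param genome A `genome`.
#' @param cfg A [read_config()].
#' @param wrap Emit windows across the circular breakpoint? Default `FALSE`.
#' @return A `fragment_set`: a tibble with one row per read (`read_id`,
#'   `mate`, `seq`, `origin_contig`, `template_start`, `template_length`,
#'   `read_start`) carrying the `read_config` as an attribute.
#' @export
fragment_genome <- function(genome, cfg, wrap = FALSE) {
  stopifnot(inherits(genome, "genome"), inherits(cfg, "read_config"))
  L <- genome_length(genome)
  rl <- cfg$read_length
  if (rl > L) abort(sprintf("read_length %d exceeds genome length %d", rl, L))
  if (wrap && !genome$circular) abort("wrap = TRUE requires a circular genome")
  seq <- genome$sequence
  if (wrap) seq <- paste0(seq, substr(seq, 1L, max(rl, max(cfg$insert_size %||% 0L)) - 1L))

  if (cfg$layout == "single") {
    last <- if (wrap) L else L - rl + 1L
    starts <- seq.int(1L, last, by = cfg$step)
    tlen <- rep(rl, length(starts))
  } else {
    lo <- min(cfg$insert_size)
    last <- if (wrap) L else L - lo + 1L
    if (last < 1L) abort("insert size exceeds genome length")
    starts <- seq.int(1L, last, by = cfg$step)
    tlen <- sample_inserts(cfg, length(starts))
    keep <- starts + tlen - 1L <= nchar(seq)
    starts <- starts[keep]
    tlen <- tlen[keep]
  }
  serial <- seq_along(starts)
  ids <- sprintf("%s|%d|%d|%d", genome$name, starts, tlen, serial)

  if (cfg$layout == "single") {
    frags <- tibble::tibble(
      read_id = ids, mate = 1L,
      seq = substring(seq, starts, starts + rl - 1L),
      origin_contig = genome$name, template_start = starts,
      template_length = tlen, read_start = starts)
  } else {
    r1 <- substring(seq, starts, starts + rl - 1L)
    r2 <- revcomp(substring(seq, starts + tlen - rl, starts + tlen - 1L))
    frags <- tibble::tibble(
      read_id = rep(ids, 2L), mate = rep(c(1L, 2L), each = length(ids)),
      seq = c(r1, r2),
      origin_contig = genome$name,
      template_start = rep(starts, 2L),
      template_length = rep(tlen, 2L),
      read_start = c(starts, starts + tlen - rl))
  }
  new_fragment_set(frags, cfg, genome$name)
}

new_fragment_set <- function(frags, cfg, genome_name) {
  structure(frags, class = c("fragment_set", class(tibble::tibble())),
            read_config = cfg, genome_name = genome_name)
}

#' @export
print.fragment_set <- function(x, ...) {
  cfg <- attr(x, "read_config")
  cat(sprintf("<fragment_set> %d reads (%d templates), %s\n",
              nrow(x), length(unique(x$read_id)), config_label(cfg)))
  NextMethod()
}

#' Ground-truth placements of simulated fragments
#'
#' Converts a `fragment_set` into the alignment records a perfect aligner
#' would emit: every read mapped at its origin with zero mismatches, mate 1
#' forward and mate 2 reverse. Used for truth-based depth profiles and for
#' checking aligner self-consistency.
#'
#' @param frags A `fragment_set`.
#' @return An alignment tibble (see [align_fragments()]).
#' @export
truth_alignments <- function(frags) {
  cfg <- attr(frags, "read_config")
  new_alignment_set(
    tibble::tibble(
      read_id = frags$read_id, mate = frags$mate, seq = frags$seq,
      contig = frags$origin_contig, pos = frags$read_start,
      strand = ifelse(frags$mate == 2L, "-", "+"),
      mismatches = 0L, mapped = TRUE, ambiguous = FALSE),
    read_length = cfg$read_length)
}

#' Write fragments as FASTQ (Phred+33, all bases Q40)
#'
#' Every base is written with quality character `"I"` (Q40). Paired-end sets
#' are written as synchronised `_R1`/`_R2` files with matching read ids.
#'
#' @param frags A `fragment_set`.
#' @param path Output path; for paired-end input, `_R1`/`_R2` are inserted
#'   before the extension.
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_fastq <- function(frags, path) {
  cfg <- attr(frags, "read_config")
  write_one <- function(rows, fp) {
    seqs <- Biostrings::DNAStringSet(rows$seq)
    names(seqs) <- rows$read_id
    quals <- Biostrings::BStringSet(strrep("I", nchar(rows$seq)))
    tryCatch(
      Biostrings::writeXStringSet(seqs, filepath = fp, format = "fastq",
                                  qualities = quals),
      error = function(e) abort(sprintf("failed writing FASTQ '%s': %s",
                                        fp, conditionMessage(e))))
    fp
  }
  if (cfg$layout == "single") {
    out <- write_one(frags, path)
  } else {
    has_ext <- grepl("\\.(fastq|fq)$", path)
    stem <- if (has_ext) sub("\\.(fastq|fq)$", "", path) else path
    ext <- if (has_ext) sub("^.*(\\.(fastq|fq))$", "\\1", path) else ".fastq"
    out <- c(
      write_one(frags[frags$mate == 1L, ], paste0(stem, "_R1", ext)),
      write_one(frags[frags$mate == 2L, ], paste0(stem, "_R2", ext)))
  }
  invisible(out)
}

#' Read a FASTQ file (or an R1/R2 pair) back into a tibble
#'
#' @param path One FASTQ path, or a length-2 vector `c(R1, R2)`.
#' @return A tibble with `read_id`, `mate`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  read_one <- function(fp, mate) {
    x <- Biostrings::readDNAStringSet(fp, format = "fastq", with.qualities = TRUE)
    tibble::tibble(read_id = names(x), mate = mate,
                   seq = unname(as.character(x)),
                   qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
  }
  if (length(path) == 1L) {
    read_one(path, 1L)
  } else {
    dplyr::bind_rows(read_one(path[1], 1L), read_one(path[2], 2L))
  }
}
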