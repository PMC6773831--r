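#' Build a k-mer seed index over a reference set
#'
#' Indexes every k-mer occurrence of every contig on both strands. Minus
#' strand entries store the reverse complement of the forward k-mer at the
#' same (leftmost) position. With non-overlapping query seeds at read offsets
#' 0, k, 2k, ..., a read with m mismatches retains at least
#' `floor(read_length / k) - m` exact seeds, so any `max_mismatch <
#' floor(read_length / k)` guarantees candidate recovery (default k = 19 and
#' max_mismatch = 4 for 100 bp reads).
#'
#' @param refset A `reference_set`.
#' @param k Seed length (>= 11; default 19). Must not exceed the shortest
#'   read to be aligned.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(refset, k = 19L) {
  stopifnot(inherits(refset, "reference_set"))
  k <- as.integer(k)
  if (k < 11L) abort("seed length k must be >= 11")
  tabs <- lapply(refset$genomes, function(g) {
    L <- genome_length(g)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    fwd <- substring(g$sequence, starts, starts + k - 1L)
    data.table::data.table(
      kmer = c(fwd, revcomp(fwd)),
      contig = g$name,
      pos = rep(starts, 2L),
      strand = rep(c("+", "-"), each = length(starts)))
  })
  dt <- data.table::rbindlist(tabs[!vapply(tabs, is.null, logical(1))])
  data.table::setkeyv(dt, "kmer")
  structure(
    list(dt = dt, k = k, refset = refset,
         contig_order = ref_contigs(refset),
         contig_length = vapply(refset$genomes, genome_length, integer(1))),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> k=%d, %d entries over %d contig(s)\n",
              x$k, nrow(x$dt), length(x$contig_order)))
  invisible(x)
}

# Non-overlapping seed offsets (1-based) for a read of length rl.
seed_offsets <- function(rl, k) {
  seq.int(1L, rl - k + 1L, by = k)
}

# Gather, score and rank candidate gapless placements for a batch of reads.
# Returns a data.table: idx (read index), contig, pos, strand, mismatches,
# sorted within read by (mismatches, contig rank, pos, strand + first).
candidate_table <- function(seqs, index, max_mismatch = Inf) {
  n <- length(seqs)
  rls <- nchar(seqs)
  if (any(rls < index$k)) abort("read shorter than seed length k")
  k <- index$k
  pieces <- lapply(unique(rls), function(rl) {
    idx <- which(rls == rl)
    offs <- seed_offsets(rl, k)
    data.table::rbindlist(lapply(offs, function(o) {
      data.table::data.table(idx = idx, off = o,
                             kmer = substring(seqs[idx], o, o + k - 1L))
    }))
  })
  seeds <- data.table::rbindlist(pieces)
  hits <- index$dt[seeds, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) == 0) {
    return(data.table::data.table(idx = integer(), contig = character(),
                                  pos = integer(), strand = character(),
                                  mismatches = integer()))
  }
  rl <- rls[hits$idx]
  # forward hit at genome pos for read offset off -> read start pos - off + 1;
  # minus hit: genome coord of read base off is pos + k - 1, so leftmost
  # start = pos + k - 1 + off - rl.
  hits[, start := data.table::fifelse(
    strand == "+", pos - off + 1L, pos + k - 1L + off - rl)]
  Lc <- index$contig_length[hits$contig]
  hits <- hits[start >= 1L & start + rl - 1L <= Lc]
  cand <- unique(hits[, list(idx, contig, start, strand)])
  if (nrow(cand) == 0) {
    return(data.table::data.table(idx = integer(), contig = character(),
                                  pos = integer(), strand = character(),
                                  mismatches = integer()))
  }
  # score: Hamming distance of the aligned-orientation read to the reference
  rc <- rep(NA_character_, n)
  need_rc <- unique(cand$idx[cand$strand == "-"])
  rc[need_rc] <- revcomp(seqs[need_rc])
  cand[, qseq := data.table::fifelse(strand == "+", seqs[idx], rc[idx])]
  cand[, mismatches := {
    g <- index$refset$genomes[[contig[1]]]$sequence
    refsub <- substring(g, start, start + nchar(qseq) - 1L)
    hamming_pairs(qseq, refsub)
  }, by = "contig"]
  cand <- cand[mismatches <= max_mismatch]
  cand[, qseq := NULL]
  crank <- match(cand$contig, index$contig_order)
  data.table::setorderv(
    cand[, crank := crank][, srank := data.table::fifelse(strand == "+", 1L, 2L)],
    c("idx", "mismatches", "crank", "start", "srank"))
  cand[, c("crank", "srank") := NULL]
  data.table::setnames(cand, "start", "pos")
  cand[]
}

new_alignment_set <- function(tbl, read_length = NA_integer_, cfg = NULL) {
  structure(tbl, class = c("alignment_set", class(tibble::tibble())),
            read_length = read_length, read_config = cfg)
}

#' Align reads by best hit (minimum mismatch count)
#'
#' The embedded aligner that stands in for production short-read aligners:
#' candidate loci are gathered from non-overlapping k-mer seed hits on both
#' strands and each candidate is scored by full-length gapless Hamming
#' distance. The reported primary alignment is the locus with the fewest
#' mismatches; ties set `ambiguous = TRUE` and are broken deterministically
#' by contig order in the reference set (mitochondrial contig first by
#' default), then position, then forward before reverse strand. A read whose
#' best candidate exceeds `max_mismatch` is unmapped. Gapless scoring is
#' exact here because simulated reads are substitution-only: the mechanism
#' under audit is the mismatch-count competition between the mitochondrial
#' contig and nuMTs, not gap handling.
#'
#' @param frags A `fragment_set`, or any tibble with `read_id`, `mate`,
#'   `seq` columns, or a bare character vector of read sequences.
#' @param index A [build_index()] result.
#' @param max_mismatch Maximum allowed mismatches for a mapped read
#'   (default 4).
#' @return An `alignment_set` tibble: `read_id`, `mate`, `seq` (original
#'   read orientation), `contig`, `pos` (1-based leftmost), `strand`,
#'   `mismatches`, `mapped`, `ambiguous`.
#' @export
align_fragments <- function(frags, index, max_mismatch = 4L) {
  if (is.character(frags)) {
    frags <- tibble::tibble(
      read_id = sprintf("read%d", seq_along(frags)), mate = 1L, seq = frags)
  }
  cfg <- attr(frags, "read_config")
  cand <- candidate_table(frags$seq, index, max_mismatch)
  best <- cand[, {
    m <- mismatches[1]
    list(contig = contig[1], pos = pos[1], strand = strand[1],
         mismatches = m, ambiguous = sum(mismatches == m) > 1L)
  }, by = "idx"]
  out <- tibble::tibble(
    read_id = frags$read_id, mate = frags$mate, seq = frags$seq,
    contig = NA_character_, pos = NA_integer_, strand = NA_character_,
    mismatches = NA_integer_, mapped = FALSE, ambiguous = FALSE)
  if (nrow(best) > 0) {
    out$contig[best$idx] <- best$contig
    out$pos[best$idx] <- best$pos
    out$strand[best$idx] <- best$strand
    out$mismatches[best$idx] <- best$mismatches
    out$mapped[best$idx] <- TRUE
    out$ambiguous[best$idx] <- best$ambiguous
  }
  new_alignment_set(out, read_length = cfg$read_length %||% NA_integer_,
                    cfg = cfg)
}

#' Align a single read
#'
#' Convenience wrapper around [align_fragments()] for one sequence.
#'
#' @param read A single DNA string.
#' @inheritParams align_fragments
#' @return A one-row `alignment_set`.
#' @export
align_read <- function(read, index, max_mismatch = 4L) {
  stopifnot(is.character(read), length(read) == 1)
  align_fragments(read, index, max_mismatch)
}

#' Align paired-end fragments with proper-pair rescue
#'
#' Scores properly paired placements jointly: mates on the same contig, on
#' opposite strands in FR orientation (forward mate leftmost), with template
#' length within `insert_range` plus/minus `insert_tol`. The joint mismatch
#' sum is minimised over proper pairings; the best combination of unpaired
#' placements replaces it only when it is better by at least `pair_bonus`
#' mismatches. Pairing is what rescues reads whose confounded mate alone
#' would be captured by a nuMT — the reason paired-end layouts lose less
#' coverage than single-end at every read length.
#'
#' @param frags A paired-end `fragment_set`.
#' @param index A [build_index()] result.
#' @param max_mismatch Per-mate mismatch cap (default 4).
#' @param insert_range Length-2 numeric `c(lo, hi)` of acceptable template
#'   lengths; defaults to the fragment set's own insert configuration.
#' @param insert_tol Slack added on both sides of `insert_range` (default 10).
#' @param pair_bonus Mismatch advantage an unpaired combination needs to beat
#'   a proper pair (default 2).
#' @return An `alignment_set` with an extra logical `proper_pair` column.
#' @export
align_paired <- function(frags, index, max_mismatch = 4L, insert_range = NULL,
                         insert_tol = 10L, pair_bonus = 2L) {
  cfg <- attr(frags, "read_config")
  if (is.null(cfg) || cfg$layout != "paired") {
    abort("align_paired() requires a paired-end fragment_set")
  }
  if (is.null(insert_range)) {
    ins <- cfg$insert_size
    insert_range <- c(min(ins), max(ins))
  }
  lo <- insert_range[1] - insert_tol
  hi <- insert_range[2] + insert_tol

  cand <- candidate_table(frags$seq, index, max_mismatch)
  cand[, read_id := frags$read_id[idx]]
  cand[, mate := frags$mate[idx]]
  c1 <- cand[mate == 1L]
  c2 <- cand[mate == 2L]
  pairs <- merge(c1, c2, by = c("read_id", "contig"),
                 allow.cartesian = TRUE, suffixes = c("_1", "_2"))
  rl1 <- nchar(frags$seq[pairs$idx_1])
  rl2 <- nchar(frags$seq[pairs$idx_2])
  fwd_pos <- data.table::fifelse(pairs$strand_1 == "+", pairs$pos_1, pairs$pos_2)
  rev_pos <- data.table::fifelse(pairs$strand_1 == "+", pairs$pos_2, pairs$pos_1)
  rev_rl <- data.table::fifelse(pairs$strand_1 == "+", rl2, rl1)
  tlen <- rev_pos + rev_rl - fwd_pos
  proper <- pairs$strand_1 != pairs$strand_2 & fwd_pos <= rev_pos &
    tlen >= lo & tlen <= hi
  pairs <- pairs[proper]
  pairs[, total := mismatches_1 + mismatches_2]
  crank <- match(pairs$contig, index$contig_order)
  data.table::setorderv(pairs[, crank := crank],
                        c("read_id", "total", "crank", "pos_1", "pos_2"))
  best_pair <- pairs[, c(list(n_tied = sum(total == total[1])), .SD[1]),
                     by = "read_id"]

  # per-mate individual bests (already sorted within idx)
  best_ind <- cand[, .SD[1], by = "idx"]
  data.table::setkeyv(best_pair, "read_id")

  ids <- unique(frags$read_id)
  out <- tibble::tibble(
    read_id = frags$read_id, mate = frags$mate, seq = frags$seq,
    contig = NA_character_, pos = NA_integer_, strand = NA_character_,
    mismatches = NA_integer_, mapped = FALSE, ambiguous = FALSE,
    proper_pair = FALSE)
  # unpaired fallback: each mate at its own best candidate
  if (nrow(best_ind) > 0) {
    out$contig[best_ind$idx] <- best_ind$contig
    out$pos[best_ind$idx] <- best_ind$pos
    out$strand[best_ind$idx] <- best_ind$strand
    out$mismatches[best_ind$idx] <- best_ind$mismatches
    out$mapped[best_ind$idx] <- TRUE
    amb <- cand[, list(a = sum(mismatches == mismatches[1]) > 1L), by = "idx"]
    out$ambiguous[amb$idx] <- amb$a
  }
  if (nrow(best_pair) > 0) {
    ind_total <- rep(Inf, length(ids))
    names(ind_total) <- ids
    bi <- best_ind[, list(t = sum(mismatches)), by = list(rid = frags$read_id[idx])]
    full <- bi$rid[tabulate(match(frags$read_id[best_ind$idx],
                                  bi$rid), nbins = nrow(bi)) == 2L]
    ind_total[bi$rid] <- ifelse(bi$rid %in% full, bi$t, Inf)
    for (r in seq_len(nrow(best_pair))) {
      bp <- best_pair[r]
      use_pair <- !(is.finite(ind_total[[bp$read_id]]) &&
                      bp$total - ind_total[[bp$read_id]] >= pair_bonus)
      if (!use_pair) next
      i1 <- bp$idx_1; i2 <- bp$idx_2
      out$contig[c(i1, i2)] <- bp$contig
      out$pos[i1] <- bp$pos_1; out$pos[i2] <- bp$pos_2
      out$strand[i1] <- bp$strand_1; out$strand[i2] <- bp$strand_2
      out$mismatches[i1] <- bp$mismatches_1; out$mismatches[i2] <- bp$mismatches_2
      out$mapped[c(i1, i2)] <- TRUE
      out$ambiguous[c(i1, i2)] <- bp$n_tied > 1L
      out$proper_pair[c(i1, i2)] <- TRUE
    }
  }
  new_alignment_set(out, read_length = cfg$read_length, cfg = cfg)
}

#' Brute-force alignment oracle
#'
#' Exhaustively scans every position and strand of every contig, scoring by
#' Hamming distance, with the identical tie-break rule as [align_read()].
#' Independent of the seed index; used to verify the seeded aligner.
#'
#' @param read A single DNA string.
#' @param refset A `reference_set`.
#' @param max_mismatch Maximum allowed mismatches (default 4).
#' @return A one-row `alignment_set`.
#' @export
brute_force_align <- function(read, refset, max_mismatch = 4L) {
  rl <- nchar(read)
  read_raw <- charToRaw(read)
  rc_raw <- charToRaw(revcomp(read))
  rows <- list()
  for (g in refset$genomes) {
    Lc <- genome_length(g)
    if (Lc < rl) next
    gr <- charToRaw(g$sequence)
    starts <- seq_len(Lc - rl + 1L)
    for (st in c("+", "-")) {
      q <- if (st == "+") read_raw else rc_raw
      mm <- vapply(starts, function(s) sum(gr[s:(s + rl - 1L)] != q), integer(1))
      keep <- which(mm <= max_mismatch)
      if (length(keep)) {
        rows[[length(rows) + 1L]] <- data.table::data.table(
          contig = g$name, pos = starts[keep], strand = st,
          mismatches = mm[keep])
      }
    }
  }
  out <- tibble::tibble(
    read_id = "read1", mate = 1L, seq = read, contig = NA_character_,
    pos = NA_integer_, strand = NA_character_, mismatches = NA_integer_,
    mapped = FALSE, ambiguous = FALSE)
  if (length(rows)) {
    cand <- data.table::rbindlist(rows)
    cand[, crank := match(contig, ref_contigs(refset))]
    cand[, srank := data.table::fifelse(strand == "+", 1L, 2L)]
    data.table::setorderv(cand, c("mismatches", "crank", "pos", "srank"))
    out$contig <- cand$contig[1]
    out$pos <- cand$pos[1]
    out$strand <- cand$strand[1]
    out$mismatches <- cand$mismatches[1]
    out$mapped <- TRUE
    out$ambiguous <- sum(cand$mismatches == cand$mismatches[1]) > 1L
  }
  new_alignment_set(out)
}
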