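test_that("seed index round-trips every indexed occurrence", {
  rs <- reference_set(make_mito_genome(1000, seed = 6, max_read_length = 300))
  idx <- build_index(rs, k = 19)
  g <- mito_genome(rs)$sequence
  expect_equal(nrow(idx$dt), 2L * (1000L - 19L + 1L))
  re <- substring(g, idx$dt$pos, idx$dt$pos + 18L)
  re[idx$dt$strand == "-"] <- revcomp(re[idx$dt$strand == "-"])
  expect_identical(re, idx$dt$kmer)
  expect_error(build_index(rs, k = 9), ">= 11")
})

test_that("exact, mutated and reverse-complement reads align as expected", {
  fx <- small_fixture()
  idx <- fx$index
  mito <- mito_genome(fx$refset)

  # unique exact hit away from the nuMT
  read <- substr(mito$sequence, 201, 300)
  rec <- align_read(read, idx)
  expect_true(rec$mapped)
  expect_identical(rec$contig, "chrM")
  expect_equal(rec$pos, 201L)
  expect_identical(rec$strand, "+")
  expect_equal(rec$mismatches, 0L)
  expect_false(rec$ambiguous)

  # strand symmetry: the reverse complement maps to the same locus on minus
  rc <- align_read(revcomp(read), idx)
  expect_equal(rc$pos, 201L)
  expect_identical(rc$strand, "-")
  expect_equal(rc$mismatches, 0L)

  # alternative allele flips the best hit to the nuclear copy
  mut <- apply_snv(mito, fx$snv)
  confounded <- substr(mut$sequence, fx$focal - 50, fx$focal + 49)
  rec2 <- align_read(confounded, idx)
  expect_identical(rec2$contig, "nuc1")
  expect_equal(rec2$mismatches, 0L)
  expect_false(rec2$ambiguous)
  # while the reference-allele read stays on the mitochondrial contig
  ref_read <- substr(mito$sequence, fx$focal - 50, fx$focal + 49)
  rec3 <- align_read(ref_read, idx)
  expect_identical(rec3$contig, "chrM")
  expect_equal(rec3$mismatches, 0L)

  # a read inside the copied segment but off the focal base ties 0:0 and is
  # broken deterministically toward the mitochondrial contig
  tie_read <- substr(mito$sequence, fx$focal + 1, fx$focal + 100)
  rec4 <- align_read(tie_read, idx)
  expect_true(rec4$ambiguous)
  expect_identical(rec4$contig, "chrM")

  # unrelated sequence is unmapped
  junk <- with_test_seed(1, random_read(100))
  expect_false(align_read(junk, idx)$mapped)

  expect_error(align_read(substr(mito$sequence, 1, 10), idx), "shorter than")
})

test_that("contig tie-break order is reversible for sensitivity analysis", {
  fx <- small_fixture()
  mito <- mito_genome(fx$refset)
  rs_rev <- reference_set(mito, fx$refset$genomes[-1], mito_first = FALSE)
  rs_rev$numt_table <- fx$refset$numt_table
  idx_rev <- build_index(rs_rev)
  tie_read <- substr(mito$sequence, fx$focal + 1, fx$focal + 100)
  rec <- align_read(tie_read, idx_rev)
  expect_true(rec$ambiguous)
  expect_identical(rec$contig, "nuc1")
})

test_that("seeded aligner is record-identical to the brute-force oracle", {
  fx <- small_fixture()
  mito <- mito_genome(fx$refset)
  nuc <- fx$refset$genomes$nuc1
  reads <- with_test_seed(99, {
    c(
      # clean windows from both contigs, both strands
      vapply(sample(genome_length(mito) - 99L, 30), function(s)
        substr(mito$sequence, s, s + 99L), character(1)),
      revcomp(vapply(sample(genome_length(mito) - 99L, 10), function(s)
        substr(mito$sequence, s, s + 99L), character(1))),
      vapply(sample(genome_length(nuc) - 99L, 10), function(s)
        substr(nuc$sequence, s, s + 99L), character(1)),
      # windows with 1-5 substitutions (spanning mapped and unmapped)
      vapply(1:40, function(i) {
        s <- sample(genome_length(mito) - 99L, 1)
        mutate_read(substr(mito$sequence, s, s + 99L), sample(5, 1))
      }, character(1)),
      # windows over the nuMT-homologous region
      vapply(1:20, function(i) {
        s <- sample((fx$focal - 200L):(fx$focal + 100L), 1)
        mutate_read(substr(mito$sequence, s, s + 99L), sample(0:2, 1))
      }, character(1)),
      # pure noise
      vapply(1:5, function(i) random_read(100), character(1)))
  })
  fast <- align_fragments(reads, fx$index)
  slow <- dplyr::bind_rows(
    lapply(reads, brute_force_align, refset = fx$refset))
  expect_same_alignment(fast, slow)
})

test_that("self-consistency: without nuMTs every fragment maps to its origin", {
  pr <- plain_refset()
  mito <- mito_genome(pr$refset)
  frags <- fragment_genome(mito, se100())
  aln <- align_fragments(frags, pr$index)
  expect_true(all(aln$mapped))
  expect_true(all(aln$contig == "chrM"))
  expect_true(all(aln$mismatches == 0L))
  expect_false(any(aln$ambiguous))
  expect_equal(aln$pos, frags$read_start)
})

test_that("mismatch monotonicity: extra substitutions never lower a contig's score", {
  fx <- small_fixture()
  mito <- mito_genome(fx$refset)
  with_test_seed(7, {
    for (i in 1:20) {
      s <- sample(genome_length(mito) - 99L, 1)
      read <- substr(mito$sequence, s, s + 99L)
      r0 <- align_read(read, fx$index, max_mismatch = 6)
      r1 <- align_read(mutate_read(read, 1), fx$index, max_mismatch = 6)
      if (r0$mapped && r1$mapped && identical(r0$contig, r1$contig) &&
          r0$pos == r1$pos) {
        expect_gte(r1$mismatches, r0$mismatches)
      }
    }
  })
})

test_that("proper pairing rescues a mate captured by a short nuMT", {
  # nuMT covers only mate 1's span: the pair stays on chrM even though the
  # confounded mate alone would prefer the nuclear copy
  mito <- make_mito_genome(3000, seed = 21)
  focal <- 1500L
  ref_base <- substr(mito$sequence, focal, focal)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  spec <- numt_spec(focal - 75L, 151L,
                    tibble::tibble(offset = 76L, base = alt),
                    host_insert_pos = 301L)
  rs <- plant_numt(reference_set(mito), spec, background_length = 800L, seed = 3)
  idx <- build_index(rs)
  cfg <- read_config(100, "paired", insert_size = 200)
  mut <- apply_snv(mito, tibble::tibble(contig = "chrM", pos = focal,
                                        ref = ref_base, alt = alt))
  frags <- fragment_genome(mut, cfg)
  # template whose mate 1 covers the focal base and mate 2 lies beyond the copy
  pick <- frags$template_start == focal - 50L
  sub <- frags[pick, ]
  attr(sub, "read_config") <- cfg
  aln <- align_paired(sub, idx)
  expect_true(all(aln$proper_pair))
  expect_true(all(aln$contig == "chrM"))
  expect_equal(sort(aln$mismatches), c(0L, 1L))

  # single-end, the same confounded mate goes to the nuclear copy
  m1 <- sub$seq[sub$mate == 1L]
  expect_identical(align_read(m1, idx)$contig, "nuc1")

  # both mates exactly matching only the nuclear copy pair onto it
  nuc <- rs$genomes$nuc1
  pair <- tibble::tibble(
    read_id = "p1", mate = 1:2,
    seq = c(substr(nuc$sequence, 101, 200),
            revcomp(substr(nuc$sequence, 201, 300))))
  attr(pair, "read_config") <- cfg
  aln2 <- align_paired(pair, idx)
  expect_true(all(aln2$contig == "nuc1"))
  expect_true(all(aln2$proper_pair))

  # mates from different loci with no proper pairing: reported unpaired
  far <- tibble::tibble(
    read_id = "p2", mate = 1:2,
    seq = c(substr(mito$sequence, 101, 200),
            revcomp(substr(mito$sequence, 2101, 2200))))
  attr(far, "read_config") <- cfg
  aln3 <- align_paired(far, idx)
  expect_false(any(aln3$proper_pair))
  expect_true(all(aln3$mapped))
  expect_equal(aln3$pos, c(101L, 2101L))

  expect_error(align_paired(fragment_genome(mito, se100()), idx),
               "paired-end")
})

test_that("paired alignment agrees with a joint brute-force over placements", {
  fx <- small_fixture()
  mito <- mito_genome(fx$refset)
  cfg <- read_config(100, "paired", insert_size = 200)
  frags <- fragment_genome(apply_snv(mito, fx$snv), cfg)
  keep <- frags$template_start %in%
    seq(fx$focal - 220L, fx$focal + 20L, by = 20L)
  sub <- frags[keep, ]
  attr(sub, "read_config") <- cfg
  aln <- align_paired(sub, fx$index)

  # joint oracle: brute-force each mate's candidate set, then apply the same
  # proper-pair rule
  for (id in unique(sub$read_id)) {
    rows <- which(sub$read_id == id)
    got <- aln[aln$read_id == id, ]
    b1 <- brute_force_align(sub$seq[rows[1]], fx$refset)
    b2 <- brute_force_align(sub$seq[rows[2]], fx$refset)
    if (all(got$proper_pair)) {
      # joint mismatch total never exceeds the unpaired optimum + pair bonus
      expect_lte(sum(got$mismatches), b1$mismatches + b2$mismatches + 2L)
      tl <- max(got$pos + 100L) - min(got$pos)
      expect_lte(abs(tl - 200L), 10L + 1L)
    }
  }
})

test_that("SAM records round-trip and secondary records are dropped", {
  fx <- small_fixture()
  mito <- mito_genome(fx$refset)
  frags <- fragment_genome(apply_snv(mito, fx$snv), se100())
  # include the nuMT-homologous region so some records land on nuc1
  keep <- seq(1000L, 2200L, by = 3L)
  sub <- frags[keep, ]
  attr(sub, "read_config") <- se100()
  aln <- align_fragments(sub, fx$index)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, fx$refset, sam)
  back <- read_sam(sam, fx$refset)
  expect_equal(nrow(back), nrow(aln))
  expect_same_alignment(back, aln)
  expect_identical(back$seq, aln$seq)

  # secondary alignments are excluded on read
  lines <- readLines(sam)
  first_body <- which(!startsWith(lines, "@"))[1]
  fields <- strsplit(lines[first_body], "\t")[[1]]
  fields[2] <- as.character(bitwOr(as.integer(fields[2]), 256L))
  writeLines(c(lines, paste(fields, collapse = "\t")), sam)
  back2 <- read_sam(sam, fx$refset)
  expect_equal(nrow(back2), nrow(aln))

  # missing NM is recomputed with a warning
  no_nm <- sub("\tNM:i:[0-9]+", "", lines)
  writeLines(no_nm, sam)
  expect_warning(back3 <- read_sam(sam, fx$refset), "recomputing")
  expect_equal(back3$mismatches, aln$mismatches)

  # unknown contigs are an error
  bad <- sub("SN:nuc1", "SN:weird", lines)
  bad <- sub("\tnuc1\t", "\tweird\t", bad)
  writeLines(bad, sam)
  expect_error(read_sam(sam, fx$refset), "unknown contig")
})
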