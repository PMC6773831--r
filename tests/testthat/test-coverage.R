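test_that("depth profiles count mapped primary spans and nothing else", {
  pr <- plain_refset()
  mito <- mito_genome(pr$refset)
  L <- genome_length(mito)
  frags <- fragment_genome(mito, se100())
  aln <- align_fragments(frags, pr$index)
  prof <- depth_profile(aln, "chrM", contig_length = L)
  expect_true(all(prof$depth[100:(L - 99)] == 100L))
  # read conservation: sum of depth = mapped reads x read length
  expect_equal(sum(prof$depth), sum(aln$mapped) * 100L)

  expect_equal(sum(depth_profile(aln[0, ], "chrM", contig_length = L)$depth), 0L)

  one <- aln[1, ]
  p1 <- depth_profile(one, "chrM", contig_length = L)
  expect_equal(p1$depth, c(rep(1L, 100L), rep(0L, L - 100L)))

  bad <- one
  bad$pos <- L - 10L
  expect_error(depth_profile(bad, "chrM", contig_length = L), "past end")
})

test_that("coverage loss is the percent depth reduction, unclamped", {
  expect_equal(coverage_loss(100, 0), 100)
  expect_equal(coverage_loss(100, 100), 0)
  expect_equal(coverage_loss(100, 33), 67)
  expect_equal(coverage_loss(100, 120), -20)
  expect_error(coverage_loss(0, 10), "ref_depth > 0")
})

test_that("sweep over an unconfounded genome reports zero loss everywhere", {
  pr <- plain_refset()
  snvs <- enumerate_snvs(mito_genome(pr$refset))
  pick <- snvs[seq(2, nrow(snvs), by = 120), ]
  sw <- variant_sweep(pr$refset, se100(), pick, index = pr$index)
  expect_true(all(sw$loss_pct == 0))
  expect_true(all(sw$ref_depth == sw$mut_depth))
})

test_that("sweep locality matches the full-realignment oracle", {
  # 2 kb fixture with a one-mismatch nuMT; compare cached-locality sweep
  # against from-scratch realignment of the whole mutated genome
  fx <- cached("locality_fixture", {
    f <- one_mismatch_fixture(seed = 13, mito_length = 2000, flank = 150,
                              focal = 1000)
    f$index <- build_index(f$refset)
    f
  })
  snvs <- dplyr::bind_rows(
    fx$snv,                                     # total loss at the focal SNV
    parse_snv(c("chrM:990A>C", "chrM:1120G>T",  # in/near the copied segment
                "chrM:300T>A")))                # far away, unconfounded
  snvs$ref <- substring(mito_genome(fx$refset)$sequence, snvs$pos, snvs$pos)
  ok <- snvs$ref != snvs$alt
  snvs$alt[!ok] <- vapply(snvs$ref[!ok], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))

  for (cfg in list(se100(), read_config(100, "paired", insert_size = 200))) {
    sw <- variant_sweep(fx$refset, cfg, snvs, index = fx$index)
    oracle <- dplyr::bind_rows(lapply(seq_len(nrow(snvs)), function(i) {
      full_realignment_loss(fx$refset, cfg, snvs[i, ], index = fx$index)
    }))
    expect_equal(tibble::as_tibble(sw), tibble::as_tibble(oracle))
  }
})

test_that("sweep results are independent of order and chunking", {
  fx <- small_fixture()
  snvs <- enumerate_snvs(mito_genome(fx$refset))
  pick <- snvs[c(4200, 4500, 4501, 9000), ]
  a <- variant_sweep(fx$refset, se100(), pick, index = fx$index)
  b <- variant_sweep(fx$refset, se100(), pick[4:1, ], index = fx$index)
  expect_equal(tibble::as_tibble(a),
               tibble::as_tibble(b)[4:1, ], ignore_attr = TRUE)
  chunks <- dplyr::bind_rows(
    tibble::as_tibble(variant_sweep(fx$refset, se100(), pick[1:2, ],
                                    index = fx$index)),
    tibble::as_tibble(variant_sweep(fx$refset, se100(), pick[3:4, ],
                                    index = fx$index)))
  expect_equal(tibble::as_tibble(a), chunks, ignore_attr = TRUE)
})

test_that("loss binning uses strict thresholds and the paired-end 3% floor", {
  rec <- tibble::tibble(
    contig = "chrM", pos = c(10L, 20L, 30L, 30L), ref = "A", alt = "C",
    read_length = 100L, layout = "single",
    ref_depth = 100L, mut_depth = c(100L, 95L, 85L, 40L),
    loss_pct = c(0, 5, 15, 60))
  b <- bin_losses(rec, thresholds = c(0, 10, 50))
  expect_equal(b$n_variants, c(3L, 2L, 1L))
  expect_equal(b$n_positions, c(2L, 1L, 1L))
  expect_true(all(b$n_positions <= b$n_variants))

  # strictness at the boundary: a loss exactly at a threshold is not counted
  expect_equal(bin_losses(rec, thresholds = 60)$n_variants, 0L)

  pe <- rec
  pe$layout <- "paired"
  pe$loss_pct <- c(2, 3.5, 15, 60)
  bpe <- bin_losses(pe, thresholds = c(0, 10))
  expect_equal(bpe$n_variants, c(3L, 2L))

  empty <- bin_losses(rec[0, ], thresholds = c(0, 10))
  expect_true(all(empty$n_variants == 0L))
})

test_that("breakpoint scan finds no losses on an unconfounded circular genome", {
  g <- make_mito_genome(2000, seed = 31)
  bs <- cached("breakpoint_scan_25", breakpoint_scan(g, se100(), window = 25))
  expect_equal(nrow(bs), 3L * 50L)
  expect_true(all(bs$loss_pct == 0))
  # reported in original coordinates around the linear breakpoint
  expect_setequal(unique(bs$pos), c(1976:2000, 1:25))

  expect_equal(nrow(breakpoint_scan(g, se100(), window = 0)), 0L)
  expect_error(breakpoint_scan(genome("m", strrep("ACGT", 100)), se100()),
               "circular")
})

test_that("breakpoint losses are invariant to the rotation offset", {
  g <- make_mito_genome(2000, seed = 31)
  L <- genome_length(g)
  a <- cached("breakpoint_scan_25", breakpoint_scan(g, se100(), window = 25))
  b <- breakpoint_scan(g, se100(), window = 25, shift_offset = L %/% 4L)
  expect_equal(a$pos, b$pos)
  expect_equal(a$loss_pct, b$loss_pct)
})

test_that("sweep TSV and BedGraph writers emit well-formed files", {
  fx <- small_fixture()
  sw <- variant_sweep(fx$refset, se100(), fx$snv, index = fx$index)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sweep_tsv(sw, tsv, comment = "seed=1")
  lines <- readLines(tsv)
  expect_true(startsWith(lines[1], "# "))
  back <- readr::read_tsv(tsv, comment = "#", show_col_types = FALSE)
  expect_equal(back$loss_pct, sw$loss_pct)

  frags <- fragment_genome(mito_genome(fx$refset), se100())
  prof <- depth_profile(align_fragments(frags, fx$index), "chrM",
                        refset = fx$refset)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(prof, bg)
  gr <- rtracklayer::import.bedGraph(bg)
  expect_equal(sum(gr$score * BiocGenerics::width(gr)), sum(prof$depth))
})
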