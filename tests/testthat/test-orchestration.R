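test_that("reference audit is clean without nuMTs and dips only near the copy", {
  pr <- plain_refset()
  audit <- run_reference_audit(pr$refset, run_config(list(se100())))
  expect_equal(nrow(audit$report), 0L)
  expect_equal(max(audit$profiles[["100bp_SE"]]$depth), 100L)

  # with a one-mismatch nuMT the unmutated reference still self-aligns fully:
  # ties break toward the mitochondrial contig, so no interior dips appear
  fx <- small_fixture()
  audit2 <- run_reference_audit(fx$refset, run_config(list(se100())))
  expect_equal(nrow(audit2$report), 0L)

  # with the nuclear copy favored in tie-break order, dips appear only within
  # a read length of the copied segment
  mito <- mito_genome(fx$refset)
  rs_rev <- reference_set(mito, fx$refset$genomes[-1], mito_first = FALSE)
  audit3 <- run_reference_audit(rs_rev, run_config(list(se100())))
  expect_gt(nrow(audit3$report), 0L)
  seg <- c(fx$focal - fx$flank, fx$focal + fx$flank)
  expect_true(all(audit3$report$pos >= seg[1] - 99L &
                    audit3$report$pos <= seg[2] + 99L))
})

test_that("full study runs end to end, deterministically, with consistent summaries", {
  fx <- small_fixture()
  cfg <- run_config(list(se100()), sweep_scope = fx$snv$pos,
                    mixtures = list(c(1L, 1L)), seed = 7)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressMessages({
    res1 <- run_full_study(fx$refset, cfg, out1)
    res2 <- run_full_study(fx$refset, cfg, out2)
  })
  # byte-identical reruns
  for (f in c("sweep.tsv", "sweep_summary.tsv", "heteroplasmy.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # header comment carries hash and seed
  expect_match(readLines(file.path(out1, "sweep.tsv"))[1],
               "config_hash=.* seed=7")
  # summary equals bin_losses recomputed on the sweep output
  sweep_back <- readr::read_tsv(file.path(out1, "sweep.tsv"), comment = "#",
                                show_col_types = FALSE)
  expect_equal(res1$bins$n_variants,
               bin_losses(sweep_back)$n_variants)
  # the focal SNV's full loss surfaces in sweep and heteroplasmy outputs
  expect_true(any(sweep_back$loss_pct == 100))
  expect_equal(res1$maf$observed_maf[res1$maf$pos == fx$snv$pos &
                                       res1$maf$alt == fx$snv$alt], 0)
  # manifest records stage counts
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 7L)
  expect_gt(man$stage_counts[[1]]$mapped, 0L)
})

test_that("a restricted sweep scope is a subset of the full sweep", {
  pr <- plain_refset()
  mito <- mito_genome(pr$refset)
  cfg_small <- run_config(list(se100()), sweep_scope = 150:160,
                          mixtures = list(), seed = 1)
  out <- withr::local_tempdir()
  suppressMessages(res <- run_full_study(pr$refset, cfg_small, out))
  expect_equal(nrow(res$sweep), 3L * 11L)
  expect_true(all(res$sweep$pos %in% 150:160))
  full_rows <- variant_sweep(pr$refset, se100(),
                             enumerate_snvs(mito)[448:480, ],
                             index = pr$index)
  sub <- tibble::as_tibble(full_rows)
  sub <- sub[sub$pos %in% 150:160, ]
  expect_equal(tibble::as_tibble(res$sweep)[, names(sub)], sub,
               ignore_attr = TRUE)
})

test_that("tidiers summarise sweeps and alignments", {
  fx <- small_fixture()
  sw <- variant_sweep(fx$refset, se100(), fx$snv, index = fx$index)
  g <- glance(sw)
  expect_equal(g$n_variants, 1L)
  expect_equal(g$n_total_loss, 1L)
  expect_identical(tidy(sw)$loss_pct, sw$loss_pct)

  frags <- fragment_genome(mito_genome(fx$refset), se100())
  aln <- align_fragments(frags, fx$index)
  ga <- glance(aln)
  expect_equal(ga$n_reads, nrow(frags))
  expect_equal(ga$n_mapped + ga$n_unmapped, ga$n_reads)
})

test_that("result plots build without error", {
  fx <- small_fixture()
  frags <- fragment_genome(mito_genome(fx$refset), se100())
  prof <- depth_profile(align_fragments(frags, fx$index), "chrM",
                        refset = fx$refset)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
  sw <- variant_sweep(fx$refset, se100(), fx$snv, index = fx$index)
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
  call <- heteroplasmy_audit(fx$refset, se100(), fx$snv, 1, 1, index = fx$index)
  rep <- bias_report(sw, call)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  bs <- cached("hap_scan",
               background_scan(hap_fixture()$refset, se100(),
                               hap_fixture()$background, window = 100,
                               index = hap_fixture()$index))
  expect_s3_class(ggplot2::autoplot(bs), "ggplot")
  mutprof <- depth_profile(
    align_fragments(fragment_genome(apply_snv(mito_genome(fx$refset), fx$snv),
                                    se100()), fx$index),
    "chrM", refset = fx$refset)
  expect_s3_class(plot_coverage_comparison(prof, mutprof,
                                           zoom = c(fx$focal - 500,
                                                    fx$focal + 500)),
                  "ggplot")
})
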