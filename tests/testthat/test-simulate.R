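test_that("gene models are placed without overlap, deterministically", {
  cfg <- small_sim_config()
  m1 <- simulate_gene_models(cfg)
  m2 <- simulate_gene_models(cfg)
  expect_equal(m1, m2)
  tx <- m1$transcripts
  expect_equal(nrow(tx), cfg$n_genes)
  setorder(tx, chrom, start)
  gapok <- tx[, .(ok = .N < 2 || all(head(end, -1) <= tail(start, -1))),
              by = chrom]
  expect_true(all(gapok$ok))
  # exons sorted, non-overlapping, inside the span
  ex <- merge(m1$exons, tx[, .(tx_id, gstart = start, gend = end)],
              by = "tx_id")
  expect_true(all(ex$start >= ex$gstart & ex$end <= ex$gend))
  # empty case
  m0 <- simulate_gene_models(sim_config(n_genes = 0L, n_enhancers = 0L,
                                        n_responsive_both = 0L,
                                        n_responsive_single = 0L))
  expect_equal(nrow(m0$transcripts), 0L)
})

test_that("planted enhancers honour the gap range and responsiveness plan", {
  cfg <- small_sim_config()
  models <- simulate_gene_models(cfg)
  truth <- plant_elements(cfg, models)
  enh <- truth[kind %like% "enhancer"]
  expect_equal(nrow(enh), cfg$n_enhancers)
  gaps <- enh$plus_tss - enh$minus_tss
  expect_true(all(gaps >= cfg$gap_range[1] & gaps <= cfg$gap_range[2]))
  expect_equal(sum(enh$responsive_minus & enh$responsive_plus),
               cfg$n_responsive_both)
  expect_equal(sum(xor(enh$responsive_minus, enh$responsive_plus)),
               cfg$n_responsive_single)
  expect_true(all(enh$fold_minus[enh$responsive_minus] == cfg$response_fold))
  # promoters sit at gene TSSs on the gene strand
  prom <- truth[kind == "promoter"]
  tx <- models$transcripts
  expect_equal(nrow(prom), nrow(tx))
  ptss <- ifelse(prom$strand == "+", prom$plus_tss, prom$minus_tss)
  expect_equal(sort(ptss), sort(tx$tss))
  # non-responsive configuration -> all true folds 1
  cfg0 <- small_sim_config()
  cfg0$n_responsive_both <- 0L; cfg0$n_responsive_single <- 0L
  cfg0$promoter_responsive_fraction <- 0
  t0 <- plant_elements(cfg0, models)
  expect_true(all(t0$fold_minus %in% c(1, NA)))
  expect_true(all(t0$fold_plus %in% c(1, NA)))
})

test_that("intronic enhancers fall inside gene spans but outside exons", {
  cfg <- small_sim_config()
  cfg$intronic_fraction <- 1
  models <- simulate_gene_models(cfg)
  truth <- plant_elements(cfg, models)
  enh <- truth[kind == "enhancer_intronic"]
  expect_equal(nrow(enh), cfg$n_enhancers)
  tx <- models$transcripts
  ex <- models$exons
  mids <- floor((enh$minus_tss + enh$plus_tss) / 2)
  in_gene <- vapply(seq_along(mids), function(i)
    any(tx$chrom == enh$chrom[i] & tx$start <= mids[i] & mids[i] < tx$end),
    TRUE)
  in_exon <- vapply(seq_along(mids), function(i)
    any(ex$start <= mids[i] & mids[i] < ex$end), TRUE)
  expect_true(all(in_gene))
  expect_false(any(in_exon))
})

test_that("simulated counts recover the planted moments", {
  # single enhancer, many replicates: stimulated/control mean ratio ~ fold
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e5), n_genes = 0L,
                    n_enhancers = 1L, n_responsive_both = 1L,
                    n_responsive_single = 0L, n_reps = 500L,
                    noise_per_chrom = 0L, lib_factor_range = c(1, 1),
                    seed = 77L)
  truth <- data.table(element_id = "enh_001", kind = "enhancer",
                      chrom = "chr1", minus_tss = 5000L, plus_tss = 5150L,
                      strand = ".", responsive_minus = TRUE,
                      responsive_plus = TRUE, fold_minus = 12,
                      fold_plus = 12, base_mean = 50)
  ctss <- simulate_counts(truth, cfg)
  conds <- attr(ctss, "conditions")
  totals <- vapply(ctss, function(x) sum(x$count), 0)
  ratio <- mean(totals[conds == "stimulated"]) / mean(totals[conds == "control"])
  expect_equal(ratio, 12, tolerance = 0.1)
  expect_equal(mean(totals[conds == "control"]), 2 * 50, tolerance = 0.1)
  # all positions stay near the planted TSSs (within the scatter window)
  pos <- unique(rbindlist(ctss)$pos)
  expect_true(all(pmin(abs(pos - 5000L), abs(pos - 5150L)) <= 5))
})

test_that("the same seed reproduces a byte-identical dataset", {
  cfg <- small_sim_config()
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1)); h2 <- tools::md5sum(file.path(d2, f2))
  expect_equal(unname(h1), unname(h2))
  expect_error(simulate_dataset(cfg, d1), "not empty")
  # truth round-trip
  t1 <- read_truth(file.path(d1, "truth.tsv"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_truth(t1, tmp)
  expect_equal(read_truth(tmp), t1)
})

test_that("recovery scoring matches hand-checked cases", {
  truth <- data.table(
    element_id = c("e1", "e2", "e3"), kind = "enhancer", chrom = "chr1",
    minus_tss = c(1000L, 5000L, 9000L), plus_tss = c(1200L, 5200L, 9200L),
    strand = ".",
    responsive_minus = c(TRUE, TRUE, FALSE),
    responsive_plus = c(TRUE, TRUE, TRUE),
    fold_minus = c(12, 12, 1), fold_plus = c(12, 12, 12), base_mean = 50)
  loci <- data.table(chrom = "chr1",
                     midpoint = c(1100L, 5120L, 9100L, 20000L),
                     strand_class = c("bidirectional", "bidirectional",
                                      "plus_only", "bidirectional"))
  s <- score_recovery(loci, truth, match_window = 100L)
  expect_equal(s$sensitivity, 1)          # both planted-both recovered
  expect_equal(s$precision, 2 / 3)        # one reported locus unmatched
  expect_equal(s$single_strand_accuracy, 1)
  # shifting reported midpoints beyond the window kills sensitivity
  shifted <- copy(loci)[, midpoint := midpoint + 500L]
  expect_equal(score_recovery(shifted, truth, 100L)$sensitivity, 0)
  # empty report: undefined precision flagged as NA
  s0 <- score_recovery(loci[0], truth, 100L)
  expect_equal(s0$sensitivity, 0)
  expect_true(is.na(s0$precision))
})
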