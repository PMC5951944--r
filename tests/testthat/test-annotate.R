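test_that("signed distances follow the gene-orientation convention", {
  models <- toy_gene_models()
  # minus-strand gene (tss 5000): anchor upstream-in-gene-orientation
  d <- distance_to_tss(data.table(chrom = "chrT", pos = 4630L), models)
  expect_equal(d$distance_to_tss, 370L)
  expect_equal(d$gene_strand, "-")
  # minus-strand gene (tss 205000): anchor beyond the TSS
  d2 <- distance_to_tss(data.table(chrom = "chrT", pos = 207769L), models)
  expect_equal(d2$distance_to_tss, -2769L)
  # anchor exactly at a plus-strand TSS
  d3 <- distance_to_tss(data.table(chrom = "chrT", pos = 400000L), models)
  expect_equal(d3$distance_to_tss, 0L)
  expect_error(distance_to_tss(data.table(chrom = "chrT", pos = 1L),
                               list(transcripts = data.table())),
               "empty gene model")
})

test_that("distance ties break toward the lexicographically smallest gene", {
  tx <- data.table(tx_id = c("z.t1", "a.t1"), gene_id = c("zzz", "aaa"),
                   gene_name = c("Z", "A"), chrom = "chr1",
                   strand = c("+", "+"), start = c(900L, 1100L),
                   end = c(1500L, 1800L), cds_start = NA_integer_,
                   cds_end = NA_integer_, tss = c(900L, 1100L))
  models <- list(transcripts = tx,
                 exons = data.table(tx_id = tx$tx_id, start = tx$start,
                                    end = tx$end))
  d <- distance_to_tss(data.table(chrom = "chr1", pos = 1000L), models)
  expect_equal(d$gene_id, "aaa")
})

test_that("feature categories follow the documented priority", {
  models <- toy_gene_models()
  anch <- function(p) data.table(chrom = "chrT", pos = p)
  # promoter sub-bins by |d|
  expect_equal(annotate_feature(anch(4630L), models), "Promoter (<=1 kb)")
  expect_equal(annotate_feature(anch(207769L), models), "Promoter (2-3 kb)")
  expect_equal(annotate_feature(anch(203500L), models), "Promoter (1-2 kb)")
  # distal anchor with no feature overlap
  expect_equal(annotate_feature(anch(388149L), models), "Distal Intergenic")
  # intron between exons 6 and 7 of geneD, |d| > 3000
  expect_equal(annotate_feature(anch(621000L), models), "Intron")
  # 5' UTR of geneC (+): exon 1 before cds_start at 400500, but within the
  # promoter window -> promoter wins by priority; use a far 3' UTR instead
  expect_equal(annotate_feature(anch(639500L), models), "3' UTR")
  # coding exon interior of geneD
  expect_equal(annotate_feature(anch(612000L), models), "Exon")
  # downstream window past geneA's 3' end (minus strand: left of start),
  # far enough from the TSS to escape the promoter window
  expect_equal(annotate_feature(anch(1500L), models), "Downstream (<=3 kb)")
})

test_that("5' UTR outranks exon when outside the promoter window", {
  # gene starting far from its own TSS cannot exist; instead shrink the
  # promoter window to expose the UTR layer
  models <- toy_gene_models()
  a <- data.table(chrom = "chrT", pos = 400200L)  # exon 1 of geneC, pre-CDS
  expect_equal(annotate_feature(a, models, promoter_window = 100L), "5' UTR")
  # promoter window 0 sends all former promoter anchors elsewhere
  expect_equal(annotate_feature(data.table(chrom = "chrT", pos = 207769L),
                                models, promoter_window = 0L),
               "Distal Intergenic")
  expect_equal(annotate_feature(data.table(chrom = "chrT", pos = 4630L),
                                models, promoter_window = 0L), "Exon")
})

test_that("enhancer overlap uses half-open semantics and matches a scan oracle", {
  regions <- data.table(chrom = "chr1", start = 100L, end = 200L)
  a <- function(p) data.table(chrom = "chr1", pos = p)
  expect_true(overlap_enhancers(a(150L), regions))
  expect_true(overlap_enhancers(a(100L), regions))
  expect_false(overlap_enhancers(a(200L), regions))
  set.seed(51)
  regions <- data.table(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                        start = sample.int(5000L, 200, TRUE))
  regions[, end := start + sample.int(50L, 200, TRUE)]
  anchors <- data.table(chrom = sample(c("chr1", "chr2"), 1000, TRUE),
                        pos = sample.int(5200L, 1000, TRUE))
  got <- overlap_enhancers(anchors, regions)
  oracle <- vapply(seq_len(nrow(anchors)), function(i)
    any(regions$chrom == anchors$chrom[i] &
          regions$start <= anchors$pos[i] & anchors$pos[i] < regions$end),
    TRUE)
  expect_equal(got, oracle)
})

test_that("annotation summaries are normalized fractions per direction", {
  inc <- c(rep("Promoter (<=1 kb)", 4), rep("Promoter (2-3 kb)", 3),
           rep("Intron", 3))
  dec <- c(rep("Distal Intergenic", 2), "Exon")
  s <- summarize_annotation(inc, dec)
  expect_equal(s[s$set == "increased" & s$category == "proximal promoter",
                 fraction], 0.7)
  expect_equal(s[s$set == "increased" & s$category == "Intron", fraction], 0.3)
  base <- s[s$category != "proximal promoter"]
  expect_equal(base[, .(tot = sum(fraction)), by = set]$tot, c(1, 1),
               tolerance = 1e-9)
  expect_error(summarize_annotation(inc, character(0)), "decreased")
})

test_that("planted anchors at known offsets annotate to their true category", {
  models <- toy_gene_models()
  planted <- data.table(
    pos = c(4800L, 203500L, 202500L, 388149L, 621000L, 612000L, 197500L),
    truth = c("Promoter (<=1 kb)", "Promoter (1-2 kb)", "Promoter (2-3 kb)",
              "Distal Intergenic", "Intron", "Exon", "Downstream (<=3 kb)"))
  got <- annotate_feature(data.table(chrom = "chrT", pos = planted$pos),
                          models)
  expect_equal(got, planted$truth)
})
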