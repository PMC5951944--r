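# Synthetic CAGE data generator with planted ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# 4+4 replicate libraries of NB-distributed single-nucleotide 5'-end tag
# counts, strong promoters at gene TSSs spanning several orders of
# magnitude, divergent enhancer TSS pairs spaced <= 300 bp (a fraction of
# them intronic), a planted subset responding > 10-fold to stimulation, and
# sparse low-count background noise.

#' Default simulation configuration
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n_genes Number of protein-coding gene models.
#' @param n_enhancers Number of planted divergent enhancers.
#' @param n_responsive_both Enhancers responding on both strands.
#' @param n_responsive_single Enhancers responding on one random strand.
#' @param response_fold Mean fold change of responsive strands.
#' @param gap_range Uniform range of divergent TSS gaps in bp.
#' @param enhancer_baseline_mean Baseline mean tag count per enhancer strand
#'   per sample.
#' @param promoter_mean_meanlog,promoter_mean_sdlog Lognormal parameters of
#'   promoter baseline means.
#' @param promoter_responsive_fraction Fraction of promoters with a modest
#'   condition response.
#' @param promoter_response_fold Fold of responsive promoters (half up, half
#'   down).
#' @param phi NB dispersion (var = mu + phi mu^2).
#' @param n_reps Replicates per condition.
#' @param lib_factor_range Per-sample library scaling factors (uniform).
#' @param noise_per_chrom Background noise CTSSs per chromosome.
#' @param intronic_fraction Fraction of enhancers placed inside introns.
#' @param scatter_max_positions Tag counts of an element strand are scattered
#'   over 1..this many adjacent positions.
#' @param seed RNG seed; the full dataset is a deterministic function of it.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_genes = 200L, n_enhancers = 60L,
                       n_responsive_both = 40L, n_responsive_single = 10L,
                       response_fold = 12, gap_range = c(20L, 280L),
                       enhancer_baseline_mean = 50,
                       promoter_mean_meanlog = log(800),
                       promoter_mean_sdlog = 1.5,
                       promoter_responsive_fraction = 0.2,
                       promoter_response_fold = 3,
                       phi = 0.05, n_reps = 4L,
                       lib_factor_range = c(0.85, 1.15),
                       noise_per_chrom = 500L,
                       intronic_fraction = 0.15,
                       scatter_max_positions = 5L,
                       seed = 20180514L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_responsive_both + cfg$n_responsive_single <= cfg$n_enhancers,
            all(cfg$gap_range >= 0), cfg$phi >= 0, cfg$n_reps >= 2)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate non-overlapping protein-coding gene models
#'
#' Genes are rejection-placed with a spacing buffer so that intergenic
#' enhancers can sit at least a promoter window away from any TSS. Each gene
#' gets 3-8 exons and a CDS leaving 5'/3' UTRs in the terminal exons.
#'
#' @param config A `sim_config`.
#' @param seed Optional seed override.
#' @return Gene model list (`transcripts`, `exons`) as from [read_gtf()].
#' @export
simulate_gene_models <- function(config, seed = config$seed) {
  set.seed(seed)
  chroms <- names(config$chrom_lengths)
  n <- config$n_genes
  tx_list <- list(); ex_list <- list()
  if (n > 0L) {
    per_chrom <- table(factor(sample(chroms, n, replace = TRUE),
                              levels = chroms))
    gi <- 0L
    for (ch in chroms) {
      len <- config$chrom_lengths[[ch]]
      k <- as.integer(per_chrom[[ch]])
      if (k == 0L) next
      placed <- data.table(start = integer(), end = integer())
      buffer <- 12000L
      tries <- 0L
      while (nrow(placed) < k) {
        tries <- tries + 1L
        if (tries > 50L * k) {
          stop("could not place ", k, " genes on ", ch,
               "; use longer chromosomes")
        }
        glen <- as.integer(round(runif(1, 5000, 30000)))
        gstart <- as.integer(floor(runif(1, buffer, len - glen - buffer)))
        gend <- gstart + glen
        if (nrow(placed) == 0L ||
            all(gend + buffer <= placed$start | gstart >= placed$end + buffer)) {
          placed <- rbind(placed, data.table(start = gstart, end = gend))
        }
      }
      setorder(placed, start)
      for (j in seq_len(nrow(placed))) {
        gi <- gi + 1L
        gene_id <- sprintf("gene%03d", gi)
        strand <- sample(c("+", "-"), 1L)
        gstart <- placed$start[j]; gend <- placed$end[j]
        n_ex <- sample(3:8, 1L)
        # 2*(n_ex - 1) interior breakpoints partition the span into
        # alternating exons and introns
        bp <- sort(sample(seq(gstart + 200L, gend - 200L, by = 50L),
                          2L * (n_ex - 1L)))
        edges <- c(gstart, bp, gend)
        ex_start <- edges[seq(1L, length(edges) - 1L, by = 2L)]
        ex_end <- edges[seq(2L, length(edges), by = 2L)]
        first_len <- ex_end[1L] - ex_start[1L]
        last_len <- ex_end[n_ex] - ex_start[n_ex]
        cds_start <- ex_start[1L] + max(10L, as.integer(first_len * 0.3))
        cds_end <- ex_end[n_ex] - max(10L, as.integer(last_len * 0.3))
        tx_list[[gi]] <- data.table(
          tx_id = paste0(gene_id, ".t1"), gene_id = gene_id,
          gene_name = toupper(gene_id), chrom = ch, strand = strand,
          start = gstart, end = gend, cds_start = cds_start,
          cds_end = cds_end,
          tss = if (strand == "+") gstart else gend - 1L)
        ex_list[[gi]] <- data.table(tx_id = paste0(gene_id, ".t1"),
                                    start = ex_start, end = ex_end)
      }
    }
  }
  transcripts <- if (length(tx_list)) rbindlist(tx_list) else
    data.table(tx_id = character(), gene_id = character(),
               gene_name = character(), chrom = character(),
               strand = character(), start = integer(), end = integer(),
               cds_start = integer(), cds_end = integer(), tss = integer())
  exons <- if (length(ex_list)) rbindlist(ex_list) else
    data.table(tx_id = character(), start = integer(), end = integer())
  setorder(transcripts, chrom, start, tx_id)
  list(transcripts = transcripts[], exons = exons[])
}

#' Plant promoters and divergent enhancers with ground-truth response
#'
#' Promoters sit at gene TSSs on the gene strand. Enhancers get divergent
#' minus/plus TSS pairs with gaps uniform over `gap_range`; an
#' `intronic_fraction` of them is placed inside introns (far from the host
#' TSS), the rest intergenic and at least a promoter window away from every
#' gene TSS. The first `n_responsive_both` enhancers respond on both
#' strands, the next `n_responsive_single` on one random strand.
#'
#' @param config A `sim_config`.
#' @param models Gene models from [simulate_gene_models()].
#' @param seed Optional seed override (offset from the config seed so the
#'   draws are independent of gene placement).
#' @return Truth `data.table`: `element_id`, `kind`, `chrom`, `minus_tss`,
#'   `plus_tss`, `strand`, `responsive_minus`, `responsive_plus`,
#'   `fold_minus`, `fold_plus`, `base_mean`.
#' @export
plant_elements <- function(config, models, seed = config$seed + 1L) {
  set.seed(seed)
  tx <- as.data.table(models$transcripts)
  ex <- as.data.table(models$exons)
  rows <- list()
  # promoters
  if (nrow(tx)) {
    n_resp <- round(config$promoter_responsive_fraction * nrow(tx))
    resp_idx <- if (n_resp > 0) sample(nrow(tx), n_resp) else integer(0)
    up <- resp_idx[seq_len(floor(length(resp_idx) / 2))]
    down <- setdiff(resp_idx, up)
    base <- exp(rnorm(nrow(tx), config$promoter_mean_meanlog,
                      config$promoter_mean_sdlog))
    for (i in seq_len(nrow(tx))) {
      fold <- if (i %in% up) config$promoter_response_fold
              else if (i %in% down) 1 / config$promoter_response_fold else 1
      rows[[length(rows) + 1L]] <- data.table(
        element_id = sprintf("prom_%s", tx$gene_id[i]), kind = "promoter",
        chrom = tx$chrom[i],
        minus_tss = if (tx$strand[i] == "-") tx$tss[i] else NA_integer_,
        plus_tss = if (tx$strand[i] == "+") tx$tss[i] else NA_integer_,
        strand = tx$strand[i],
        responsive_minus = tx$strand[i] == "-" && fold != 1,
        responsive_plus = tx$strand[i] == "+" && fold != 1,
        fold_minus = if (tx$strand[i] == "-") fold else NA_real_,
        fold_plus = if (tx$strand[i] == "+") fold else NA_real_,
        base_mean = base[i])
    }
  }
  # enhancer placement
  n_enh <- config$n_enhancers
  if (n_enh > 0L) {
    n_intronic <- round(config$intronic_fraction * n_enh)
    margin <- 3500L
    tss_all <- tx$tss
    tss_chrom <- tx$chrom
    ok_intergenic <- function(ch, mid) {
      near_tss <- any(tss_chrom == ch & abs(tss_all - mid) < margin)
      in_gene <- any(tx$chrom == ch & tx$start <= mid & mid < tx$end)
      !near_tss && !in_gene
    }
    introns <- if (nrow(ex)) {
      exi <- merge(ex, tx[, .(tx_id, chrom, tss)], by = "tx_id")
      setorder(exi, tx_id, start)
      ii <- exi[, .(chrom = chrom[-.N], istart = head(end, -1L),
                    iend = tail(start, -1L), tss = tss[-.N]), by = tx_id]
      ii[iend - istart > 800L & pmin(abs(istart - tss), abs(iend - tss)) > margin]
    } else data.table()
    kinds <- c(rep(TRUE, n_intronic), rep(FALSE, n_enh - n_intronic))
    placed_mids <- data.table(chrom = character(), mid = integer())
    for (e in seq_len(n_enh)) {
      gap <- as.integer(round(runif(1, config$gap_range[1L],
                                    config$gap_range[2L])))
      mid <- NA_integer_; ch <- NA_character_
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 2000L) stop("could not place enhancer ", e)
        if (kinds[e] && nrow(introns)) {
          r <- introns[sample(.N, 1L)]
          ch <- r$chrom
          cand <- as.integer(floor(runif(1, r$istart + 200L, r$iend - 200L)))
        } else {
          ch <- sample(names(config$chrom_lengths), 1L)
          cand <- as.integer(floor(runif(1, 5000,
                                         config$chrom_lengths[[ch]] - 5000)))
          if (!ok_intergenic(ch, cand)) next
        }
        clash <- placed_mids[chrom == ch][abs(mid - cand) < 2000L]
        if (nrow(clash) == 0L) { mid <- cand; break }
      }
      placed_mids <- rbind(placed_mids, data.table(chrom = ch, mid = mid))
      minus_tss <- mid - as.integer(floor(gap / 2))
      plus_tss <- minus_tss + gap
      resp_m <- resp_p <- FALSE
      if (e <= config$n_responsive_both) {
        resp_m <- resp_p <- TRUE
      } else if (e <= config$n_responsive_both + config$n_responsive_single) {
        if (runif(1) < 0.5) resp_m <- TRUE else resp_p <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.table(
        element_id = sprintf("enh_%03d", e),
        kind = if (kinds[e]) "enhancer_intronic" else "enhancer",
        chrom = ch, minus_tss = minus_tss, plus_tss = plus_tss,
        strand = ".",
        responsive_minus = resp_m, responsive_plus = resp_p,
        fold_minus = if (resp_m) config$response_fold else 1,
        fold_plus = if (resp_p) config$response_fold else 1,
        base_mean = config$enhancer_baseline_mean)
    }
  }
  truth <- rbindlist(rows)
  setorder(truth, chrom, element_id)
  truth[]
}

#' Simulate per-sample CTSS tables from planted truth
#'
#' For each element strand and sample a tag count is drawn from
#' `NB(mean = base * fold^[stimulated & responsive] * lib_factor, phi)` and
#' scattered multinomially over 1-5 adjacent positions around the TSS.
#' Background noise CTSSs (count 1-2, single random sample) are added
#' uniformly along each chromosome.
#'
#' @param truth Truth table from [plant_elements()].
#' @param config A `sim_config`.
#' @param seed Optional seed override.
#' @return Named list of per-sample CTSS `data.table`s (samples
#'   `ctrl_1..n`, `rankl_1..n`), plus attributes `conditions` and
#'   `lib_factors`.
#' @export
simulate_counts <- function(truth, config, seed = config$seed + 2L) {
  set.seed(seed)
  n_reps <- config$n_reps
  samples <- c(paste0("ctrl_", seq_len(n_reps)),
               paste0("rankl_", seq_len(n_reps)))
  conditions <- setNames(rep(c("control", "stimulated"), each = n_reps),
                         samples)
  lib_factors <- setNames(runif(length(samples), config$lib_factor_range[1L],
                                config$lib_factor_range[2L]), samples)
  recs <- vector("list", 2L * nrow(truth) + 1L)
  ri <- 0L
  draw_counts <- function(mu) {
    if (config$phi > 0) rnbinom(length(mu), mu = mu, size = 1 / config$phi)
    else rpois(length(mu), mu)
  }
  for (i in seq_len(nrow(truth))) {
    el <- truth[i]
    for (str in c("-", "+")) {
      tss <- if (str == "-") el$minus_tss else el$plus_tss
      if (is.na(tss)) next
      fold <- if (str == "-") el$fold_minus else el$fold_plus
      if (is.na(fold)) fold <- 1
      k <- sample(seq_len(config$scatter_max_positions), 1L)
      offs <- tss + seq(0L, k - 1L) - floor((k - 1L) / 2)
      w <- rgamma(k, shape = 2); w <- w / sum(w)
      mu <- el$base_mean * ifelse(conditions == "stimulated", fold, 1) *
        lib_factors
      cnt <- draw_counts(mu)
      mat <- vapply(cnt, function(cc) {
        if (cc == 0) integer(k) else as.integer(rmultinom(1L, cc, w))
      }, integer(k))  # k x samples
      long <- data.table(
        chrom = el$chrom,
        pos = rep(offs, times = length(samples)),
        strand = str,
        count = as.integer(mat),
        sample_id = rep(samples, each = k))
      ri <- ri + 1L
      recs[[ri]] <- long[count > 0L & pos >= 0L]
    }
  }
  # background noise
  noise <- rbindlist(lapply(names(config$chrom_lengths), function(ch) {
    nn <- config$noise_per_chrom
    if (nn == 0L) return(NULL)
    data.table(chrom = ch,
               pos = as.integer(floor(runif(nn, 0, config$chrom_lengths[[ch]]))),
               strand = sample(c("+", "-"), nn, replace = TRUE),
               count = sample(1:2, nn, replace = TRUE, prob = c(0.7, 0.3)),
               sample_id = sample(samples, nn, replace = TRUE))
  }))
  ri <- ri + 1L
  recs[[ri]] <- noise
  all <- rbindlist(recs[seq_len(ri)])
  # collapse duplicates (noise can land on an element position)
  all <- all[, .(count = sum(count)), by = .(chrom, pos, strand, sample_id)]
  out <- lapply(samples, function(s) {
    x <- all[sample_id == s, .(chrom, pos, strand, count, sample_id)]
    setorder(x, chrom, pos, strand)
    x[]
  })
  names(out) <- samples
  attr(out, "conditions") <- conditions
  attr(out, "lib_factors") <- lib_factors
  out
}

#' Write / read a truth table
#' @param truth Truth `data.table`.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  fwrite(truth, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  out <- fread(path, sep = "\t", header = TRUE,
               colClasses = list(character = c("element_id", "kind", "chrom",
                                               "strand"),
                                 logical = c("responsive_minus",
                                             "responsive_plus")))
  out[]
}

#' Score recovery of planted responsive enhancers
#'
#' A planted both-strand-responsive enhancer is recovered iff some reported
#' locus of class `bidirectional` has its midpoint within `match_window` bp
#' of the truth midpoint. Sensitivity is recovered/planted; precision is
#' matched/reported (NA when nothing is reported). Single-strand responsive
#' enhancers are scored by whether their matched locus (any class, same
#' window) carries the correct `plus_only`/`minus_only` class.
#'
#' @param loci Classified loci table from the pipeline.
#' @param truth Truth table.
#' @param match_window Midpoint matching window in bp (default 100).
#' @return List: `sensitivity`, `precision`, `n_planted`, `n_reported`,
#'   `n_recovered`, `single_strand_accuracy`.
#' @export
score_recovery <- function(loci, truth, match_window = 100L) {
  truth <- as.data.table(truth)
  loci <- as.data.table(loci)
  enh <- truth[kind %like% "enhancer"]
  enh[, mid := as.integer(floor((minus_tss + plus_tss) / 2))]
  planted <- enh[responsive_minus & responsive_plus]
  bid <- loci[strand_class == "bidirectional"]
  match_one <- function(ch, mid, set) {
    nrow(set[chrom == ch & abs(midpoint - mid) <= match_window]) > 0L
  }
  recovered <- if (nrow(planted)) vapply(seq_len(nrow(planted)), function(i)
    match_one(planted$chrom[i], planted$mid[i], bid), TRUE) else logical(0)
  matched_report <- if (nrow(bid)) vapply(seq_len(nrow(bid)), function(i)
    nrow(planted[chrom == bid$chrom[i] &
                   abs(mid - bid$midpoint[i]) <= match_window]) > 0L,
    TRUE) else logical(0)
  single <- enh[xor(responsive_minus, responsive_plus)]
  single_ok <- if (nrow(single)) vapply(seq_len(nrow(single)), function(i) {
    want <- if (single$responsive_plus[i]) "plus_only" else "minus_only"
    hit <- loci[chrom == single$chrom[i] &
                  abs(midpoint - single$mid[i]) <= match_window]
    nrow(hit) > 0L && any(hit$strand_class == want)
  }, TRUE) else logical(0)
  list(
    sensitivity = if (nrow(planted)) mean(recovered) else NA_real_,
    precision = if (nrow(bid)) mean(matched_report) else NA_real_,
    n_planted = nrow(planted), n_reported = nrow(bid),
    n_recovered = sum(recovered),
    single_strand_accuracy = if (nrow(single)) mean(single_ok) else NA_real_)
}

#' Simulate a full dataset directory
#'
#' Writes per-sample CTSS BED6 files, the gene-model GTF, an enhancer-region
#' BED (truth enhancer spans +/- 100 bp, a synthetic stand-in for a
#' permissive-enhancer atlas), the truth TSV, a sample sheet and a manifest
#' of file MD5 hashes.
#'
#' @param config A `sim_config`.
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory?
#' @return The directory path, invisibly.
#' @export
simulate_dataset <- function(config = sim_config(), dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop("output directory ", dir, " is not empty (use force = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- simulate_gene_models(config)
  truth <- plant_elements(config, models)
  ctss <- simulate_counts(truth, config)
  conditions <- attr(ctss, "conditions")
  write_gtf(models, file.path(dir, "genes.gtf"))
  write_truth(truth, file.path(dir, "truth.tsv"))
  enh <- truth[kind %like% "enhancer",
               .(chrom, start = pmax(0L, minus_tss - 100L),
                 end = plus_tss + 101L)]
  write_regions_bed(enh, file.path(dir, "enhancers.bed"))
  paths <- character(0)
  for (s in names(ctss)) {
    p <- file.path(dir, paste0(s, ".ctss.bed"))
    write_ctss_bed(ctss[[s]], p)
    paths[s] <- p
  }
  ss <- data.table(sample_id = names(ctss),
                   condition = unname(conditions[names(ctss)]),
                   path = basename(paths))
  fwrite(ss, file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE)
  files <- sort(setdiff(list.files(dir), "MANIFEST.tsv"))
  manifest <- data.table(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))))
  fwrite(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}
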