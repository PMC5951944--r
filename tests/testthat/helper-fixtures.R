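library(data.table)

# random per-sample CTSS tables over a small genome
random_ctss_table <- function(n = 50, chroms = c("chr1", "chr2"),
                              max_pos = 1e5, sample_id = "s1",
                              max_count = 30) {
  pos_pool <- CJ(chrom = chroms, pos = sample.int(max_pos, n),
                 strand = c("+", "-"))
  dt <- unique(pos_pool[sample.int(nrow(pos_pool), n)])
  dt[, count := sample.int(max_count, .N, replace = TRUE)]
  dt[, sample_id := sample_id]
  setorder(dt, chrom, pos, strand)
  dt[]
}

random_ctss_list <- function(n_samples = 3, n = 40) {
  out <- lapply(seq_len(n_samples), function(i)
    random_ctss_table(n = n, sample_id = paste0("s", i)))
  names(out) <- paste0("s", seq_len(n_samples))
  out
}

# build a ctss_table directly from position/count vectors for 2+ samples
ctss_table_from_counts <- function(pos, counts_by_sample,
                                   chrom = "chr1", strand = "+") {
  lst <- lapply(names(counts_by_sample), function(s) {
    data.table(chrom = chrom, pos = pos, strand = strand,
               count = counts_by_sample[[s]], sample_id = s)[count > 0]
  })
  names(lst) <- names(counts_by_sample)
  merge_samples(lst)
}

# constructed gene models exercising the candidate-table conventions:
# a close minus-strand promoter, a 2-3 kb minus-strand promoter, a distal
# anchor, and a deep intronic anchor between exons 6 and 7
toy_gene_models <- function() {
  tx <- data.table(
    tx_id = c("gA.t1", "gB.t1", "gC.t1", "gD.t1"),
    gene_id = c("gA", "gB", "gC", "gD"),
    gene_name = c("GeneA", "GeneB", "GeneC", "GeneD"),
    chrom = "chrT",
    strand = c("-", "-", "+", "+"),
    start = c(4000L, 200000L, 400000L, 600000L),
    end = c(5001L, 205001L, 420000L, 640000L),
    cds_start = c(4100L, 200500L, 400500L, 600500L),
    cds_end = c(4900L, 204500L, 419000L, 639000L))
  tx[, tss := ifelse(strand == "+", start, end - 1L)]
  ex <- rbind(
    data.table(tx_id = "gA.t1", start = c(4000L, 4600L),
               end = c(4400L, 5001L)),
    data.table(tx_id = "gB.t1", start = c(200000L, 203000L),
               end = c(202000L, 205001L)),
    data.table(tx_id = "gC.t1", start = c(400000L, 410000L),
               end = c(405000L, 420000L)),
    data.table(tx_id = "gD.t1",
               start = 600000L + c(0L, 3000L, 6000L, 9000L, 12000L, 15000L,
                                   22000L, 30000L),
               end = 600000L + c(2000L, 5000L, 8000L, 11000L, 14000L,
                                 20000L, 25000L, 40000L)))
  list(transcripts = tx[], exons = ex[])
}

small_sim_config <- function(seed = 20180514L) {
  sim_config(chrom_lengths = c(chr1 = 1.2e6), n_genes = 30L,
             n_enhancers = 10L, n_responsive_both = 6L,
             n_responsive_single = 2L, noise_per_chrom = 100L, seed = seed)
}

# --- independent oracles ------------------------------------------------------

# conditional split p-value by ratio-recursion enumeration (no lgamma)
oracle_split_pvalue <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  w <- numeric(t + 1)
  w[1] <- 1
  if (phi > 0) {
    r1 <- n1 / phi; r2 <- n2 / phi
    for (a in 0:(t - 1)) {
      w[a + 2] <- w[a + 1] * ((a + r1) / (a + 1)) * ((t - a) / (t - a - 1 + r2))
    }
  } else {
    for (a in 0:(t - 1)) {
      w[a + 2] <- w[a + 1] * ((t - a) / (a + 1)) * (n1 / n2)
    }
  }
  w <- w / max(w)
  p_obs <- w[s1 + 1]
  min(1, sum(w[w <= p_obs * (1 + 1e-10)]) / sum(w))
}

# connected-component clustering oracle over all pairs within max_gap
oracle_cluster_components <- function(pos, max_gap) {
  n <- length(pos)
  if (n == 1L) return(1L)
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# are two partitions (integer/character labelings) identical up to renaming?
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    !anyDuplicated(unique(data.table(a = a, b = b)))
}
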