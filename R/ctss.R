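# Pooling per-sample CTSSs, consensus clustering, count matrix construction.

#' Merge per-sample CTSS tables into one position x sample count table
#'
#' Takes the union of (chrom, pos, strand) positions across samples; a
#' position absent from a sample gets count 0. Library sizes are the column
#' sums of the merged table.
#'
#' @param ctss_list Named list of per-sample CTSS `data.table`s (as from
#'   [read_ctss_bed()]); names are sample ids (taken from the `sample_id`
#'   column when unnamed).
#' @return A list of class `ctss_table`: `index` (`chrom`, `pos`, `strand`),
#'   integer matrix `counts` (positions x samples), and `library_size`.
#' @export
merge_samples <- function(ctss_list) {
  stopifnot(length(ctss_list) >= 1L)
  if (is.null(names(ctss_list)) || any(!nzchar(names(ctss_list)))) {
    names(ctss_list) <- vapply(ctss_list, function(x) x$sample_id[1L], "")
  }
  samples <- names(ctss_list)
  for (s in samples) {
    x <- ctss_list[[s]]
    if (anyDuplicated(x, by = c("chrom", "pos", "strand"))) {
      stop("duplicate (chrom, pos, strand) within sample ", s)
    }
  }
  long <- rbindlist(lapply(samples, function(s) {
    x <- as.data.table(ctss_list[[s]])[, .(chrom, pos, strand, count)]
    x[, sample_id := s]
    x
  }))
  index <- unique(long[, .(chrom, pos, strand)])
  setorder(index, chrom, strand, pos)
  index[, row := .I]
  long <- merge(long, index, by = c("chrom", "pos", "strand"))
  counts <- matrix(0L, nrow = nrow(index), ncol = length(samples),
                   dimnames = list(NULL, samples))
  counts[cbind(long$row, match(long$sample_id, samples))] <- as.integer(long$count)
  index[, row := NULL]
  structure(list(index = index[], counts = counts,
                 library_size = colSums(counts)),
            class = "ctss_table")
}

#' Tags-per-million normalization of a CTSS (or cluster) count matrix
#'
#' `tpm[i, s] = count[i, s] / library_size[s] * 1e6`, so each column sums to
#' one million. `library_size` defaults to the table's own column sums.
#'
#' @param x A `ctss_table` or a numeric count matrix.
#' @param library_size Optional per-sample library sizes (e.g. effective
#'   TMM-scaled sizes).
#' @return Numeric matrix of TPM values.
#' @export
normalize_tpm <- function(x, library_size = NULL) {
  counts <- if (inherits(x, "ctss_table")) x$counts else x
  if (is.null(library_size)) {
    library_size <- if (inherits(x, "ctss_table")) x$library_size else colSums(counts)
  }
  if (any(library_size <= 0)) {
    stop("sample with empty library: ",
         paste(colnames(counts)[library_size <= 0], collapse = ", "))
  }
  sweep(counts, 2L, library_size, "/") * 1e6
}

#' Cluster pooled CTSSs into non-overlapping strand-specific consensus TSSs
#'
#' Positions are pooled across all samples, filtered by pooled expression,
#' and single-linkage clustered per (chrom, strand): two retained CTSSs join
#' the same cluster iff their positional gap is `<= max_gap`. Cluster counts
#' are element-wise sums over member positions; the dominant position is the
#' member with maximal pooled count (ties broken toward the 5'-most position
#' of the cluster's strand).
#'
#' Pooled TPM of a position is its pooled count over the total pooled
#' library, times 1e6.
#'
#' @param ctss A `ctss_table` from [merge_samples()].
#' @param max_gap Maximum joining gap in bp (default 20).
#' @param min_pooled_tpm Pooled-TPM floor applied before clustering
#'   (default 0.5).
#' @return A list of class `cluster_set`: `clusters` (`data.table` with
#'   `cluster_id`, `chrom`, `strand`, `start`, `end`, `dominant_pos`,
#'   `pooled_count`, `pooled_tpm`), `counts` (cluster x sample matrix) and
#'   `library_size` (the original full-library sizes).
#' @export
cluster_ctss <- function(ctss, max_gap = 20L, min_pooled_tpm = 0.5) {
  stopifnot(inherits(ctss, "ctss_table"), max_gap >= 0)
  pooled <- rowSums(ctss$counts)
  total <- sum(ctss$library_size)
  if (total <= 0) stop("empty CTSS table")
  pooled_tpm <- pooled / total * 1e6
  keep <- pooled_tpm >= min_pooled_tpm
  idx <- copy(ctss$index)[, `:=`(pooled = pooled, row = .I)][keep]
  if (nrow(idx) == 0L) {
    return(empty_cluster_set(colnames(ctss$counts), ctss$library_size))
  }
  setorder(idx, chrom, strand, pos)
  idx[, new_block := c(TRUE, diff(pos) > max_gap), by = .(chrom, strand)]
  idx[, block := cumsum(new_block)]
  cl <- idx[, {
    o <- .SD[order(pos)]
    dom_cand <- o[pooled == max(pooled)]
    dom <- if (strand[1L] == "+") dom_cand$pos[1L] else dom_cand$pos[nrow(dom_cand)]
    .(start = min(pos), end = max(pos) + 1L, dominant_pos = dom,
      pooled_count = sum(pooled), member_rows = list(row))
  }, by = .(chrom, strand, block)]
  setorder(cl, chrom, strand, start)
  cl[, cluster_id := sprintf("%s:%s:%d", chrom, strand, start)]
  counts <- vapply(cl$member_rows, function(r) {
    if (length(r) == 1L) as.numeric(ctss$counts[r, ])
    else colSums(ctss$counts[r, , drop = FALSE])
  }, numeric(ncol(ctss$counts)))
  counts <- if (is.matrix(counts)) t(counts) else
    matrix(counts, ncol = ncol(ctss$counts))
  colnames(counts) <- colnames(ctss$counts)
  rownames(counts) <- cl$cluster_id
  clusters <- cl[, .(cluster_id, chrom, strand, start, end, dominant_pos,
                     pooled_count, pooled_tpm = pooled_count / total * 1e6)]
  structure(list(clusters = clusters[], counts = counts,
                 library_size = ctss$library_size),
            class = "cluster_set")
}

empty_cluster_set <- function(sample_ids, library_size) {
  structure(list(
    clusters = data.table(cluster_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), dominant_pos = integer(),
                          pooled_count = numeric(), pooled_tpm = numeric()),
    counts = matrix(0, 0L, length(sample_ids),
                    dimnames = list(NULL, sample_ids)),
    library_size = library_size), class = "cluster_set")
}

#' Dominant position of each cluster
#' @param cluster_set A `cluster_set` from [cluster_ctss()].
#' @return Named integer vector of dominant positions keyed by cluster id.
#' @export
dominant_position <- function(cluster_set) {
  setNames(cluster_set$clusters$dominant_pos, cluster_set$clusters$cluster_id)
}

#' Cluster x sample count matrix with full-library sizes
#'
#' @param cluster_set A `cluster_set`.
#' @return List with `counts` (rows keyed by cluster id) and `library_size`
#'   (original full-library sizes, not post-filter sums).
#' @export
count_matrix <- function(cluster_set) {
  list(counts = cluster_set$counts, library_size = cluster_set$library_size)
}

#' Write consensus clusters as BED6 (score = pooled count)
#' @param cluster_set A `cluster_set`.
#' @param path Output path.
#' @export
write_clusters_bed <- function(cluster_set, path) {
  cl <- cluster_set$clusters
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", cl$chrom, cl$start, cl$end,
                     cl$cluster_id, as.integer(round(cl$pooled_count)),
                     cl$strand), path)
  invisible(path)
}
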