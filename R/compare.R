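# Organelle-genome comparison: chloroplast-like insertions in a mitochondrial
# genome, and gene-order (synteny) clusters shared between two genomes.

#' Find chloroplast-like regions in a mitochondrial genome
#'
#' Local alignments of the mitochondrial sequence against the plastid
#' sequence (both plastid strands) at or above the identity and length
#' thresholds; overlapping mitochondrial intervals are merged and the merged
#' length is reported as a percent fraction of the mitochondrial genome.
#'
#' @param mito,plastid DNA character scalars
#' @param min_identity minimum percent identity (default 90)
#' @param min_len minimum aligned length in bases (default 100)
#' @param word_size seed length for the local aligner (default 12)
#' @return list with `regions` (data frame: `mito_start`, `mito_end`,
#'   `plastid_start`, `plastid_end`, `strand`, `length`, `identity`),
#'   `merged` (data frame of merged mito intervals) and `fraction` (percent
#'   of the mitochondrial genome, to 0.01%)
#' @export
find_plastid_like_regions <- function(mito, plastid, min_identity = 90,
                                      min_len = 100L, word_size = 12L) {
  stopifnot(nzchar(mito), nzchar(plastid))
  Lp <- nchar(plastid)
  fwd <- local_align(mito, plastid, min_identity, min_len, word_size)
  if (nrow(fwd)) fwd$strand <- "+"
  rev <- local_align(mito, revcomp(plastid), min_identity, min_len, word_size)
  if (nrow(rev)) {
    tmp <- Lp - rev$b_end
    rev$b_end <- Lp - rev$b_start
    rev$b_start <- tmp
    rev$strand <- "-"
  }
  hits <- rbind(fwd, rev)
  if (!nrow(hits)) {
    return(list(regions = data.frame(mito_start = integer(0),
                                     mito_end = integer(0),
                                     plastid_start = integer(0),
                                     plastid_end = integer(0),
                                     strand = character(0),
                                     length = integer(0),
                                     identity = numeric(0)),
                merged = data.frame(start = integer(0), end = integer(0)),
                fraction = 0))
  }
  regions <- data.frame(mito_start = hits$a_start, mito_end = hits$a_end,
                        plastid_start = hits$b_start, plastid_end = hits$b_end,
                        strand = hits$strand, length = hits$length,
                        identity = hits$identity)
  regions <- regions[order(regions$mito_start, regions$mito_end), , drop = FALSE]
  rownames(regions) <- NULL
  merged <- merge_intervals(regions$mito_start, regions$mito_end)
  fraction <- round(100 * sum(merged$end - merged$start) / nchar(mito), 2)
  list(regions = regions, merged = merged, fraction = fraction)
}

merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Gene order of an annotated genome
#'
#' Helper producing the input expected by [shared_gene_clusters()]: genes of
#' the requested kinds in genomic order (by first segment start), with
#' strands and normalized names, trans-spliced genes excluded.
#'
#' @param genome an [annotated_genome()]
#' @param kinds feature kinds to keep (default protein-coding only, the
#'   convention for organelle gene-order comparisons; include `"tRNA"` to
#'   reproduce tRNA-anchored observations)
#' @param aliases gene-name alias table, see [shared_genes()]
#' @return data frame with `gene` and `strand` in genomic order
#' @export
gene_order <- function(genome, kinds = "protein_coding",
                       aliases = default_gene_aliases()) {
  feats <- Filter(function(f) f$kind %in% kinds && !f$trans_spliced,
                  genome$features)
  if (!length(feats)) return(data.frame(gene = character(0), strand = character(0)))
  starts <- vapply(feats, function(f) min(f$segments[, 1]), 0L)
  o <- order(starts)
  data.frame(gene = normalize_gene_name(vapply(feats, `[[`, "", "gene_name")[o],
                                        aliases),
             strand = vapply(feats, `[[`, "", "strand")[o])
}

#' Gene-order clusters shared between two genomes
#'
#' Maximal runs of genes, restricted to the shared gene set, that are
#' adjacent in both genomes in consistent relative order and orientation
#' (same order, or exactly reversed with flipped strands).  A gene absent
#' from the shared set that sits between two shared genes breaks adjacency in
#' that genome.  Singleton runs are not reported.  Output order is
#' deterministic by first occurrence in genome A.
#'
#' @param order_a,order_b data frames with `gene` and `strand` columns in
#'   genomic order (see [gene_order()]); gene names must be unique per genome
#' @return list of clusters, each a list with `genes` (ordered as in A),
#'   `orientation_consistent` (flag: strand relations agree along the run)
#' @export
shared_gene_clusters <- function(order_a, order_b) {
  if (anyDuplicated(order_a$gene) || anyDuplicated(order_b$gene))
    stop("duplicated gene names; disambiguate copies before clustering")
  n <- nrow(order_a)
  if (n < 2L) return(list())
  # position of each A gene in B's full order; NA = not shared.  Adjacency is
  # judged on the full orders, so an unshared gene between two shared genes
  # breaks the run in that genome.
  pos_b <- match(order_a$gene, order_b$gene)
  strand_rel <- ifelse(order_a$strand == order_b$strand[pos_b], 1L, -1L)
  clusters <- list()
  flush <- function(s, e) {
    if (e - s + 1L >= 2L)
      clusters[[length(clusters) + 1L]] <<- list(
        genes = order_a$gene[s:e],
        orientation_consistent = length(unique(strand_rel[s:e])) == 1L)
  }
  run_start <- NA_integer_
  run_dir <- 0L
  for (i in seq_len(n)) {
    if (is.na(pos_b[i])) {                      # unshared gene breaks A-side run
      if (!is.na(run_start)) flush(run_start, i - 1L)
      run_start <- NA_integer_; run_dir <- 0L
      next
    }
    if (is.na(run_start)) { run_start <- i; run_dir <- 0L; next }
    step <- pos_b[i] - pos_b[i - 1L]
    if (abs(step) == 1L && (run_dir == 0L || step == run_dir)) {
      run_dir <- step
    } else {
      flush(run_start, i - 1L)
      run_start <- i; run_dir <- 0L
    }
  }
  if (!is.na(run_start)) flush(run_start, n)
  clusters
}

#' Write a gene-order cluster report as TSV
#' @param clusters result of [shared_gene_clusters()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cluster_report <- function(clusters, path) {
  df <- if (length(clusters)) data.frame(
    cluster = seq_along(clusters),
    genes = vapply(clusters, function(cl) paste(cl$genes, collapse = "/"), ""),
    n_genes = vapply(clusters, function(cl) length(cl$genes), 0L),
    orientation_consistent = vapply(clusters, `[[`, NA, "orientation_consistent"))
  else data.frame(cluster = integer(0), genes = character(0),
                  n_genes = integer(0), orientation_consistent = logical(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write plastid-like regions as BED
#' @param result a result of [find_plastid_like_regions()]
#' @param chrom mitochondrial sequence name
#' @param path output file
#' @return `path`, invisibly
#' @export
write_region_bed <- function(result, chrom, path) {
  r <- result$regions
  if (!nrow(r)) { writeLines(character(0), path); return(invisible(path)) }
  bed <- data.frame(chrom = chrom, start = r$mito_start, end = r$mito_end,
                    name = sprintf("cp_region_%d", seq_len(nrow(r))),
                    score = round(r$identity * 10), strand = r$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
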