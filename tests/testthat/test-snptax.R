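# Taxon-diagnostic SNP calling and the conserved-flank filter.

toy_lineages <- function(ids, member_ids, taxon = "Fagales") {
  stats::setNames(lapply(ids, function(i)
    if (i %in% member_ids) c("Eukaryota", taxon, paste0("Genus_", i))
    else c("Eukaryota", "Elsewhere", paste0("Genus_", i))), ids)
}

test_that("taxon_query derives disjoint member sets from lineages", {
  lin <- toy_lineages(c("a", "b", "c", "d"), c("a", "b"))
  q <- taxon_query("Fagales", lin)
  expect_setequal(q$members, c("a", "b"))
  expect_setequal(q$non_members, c("c", "d"))
  expect_error(taxon_query("Nothing", lin), "no genome")
  expect_error(taxon_query("Eukaryota", lin), "outgroup")
  expect_warning(taxon_query("Genus_a", lin), "single member")
})

test_that("an all-identical alignment yields no SNPs", {
  rows <- stats::setNames(rep("ACGTACGTACGT", 4), c("a", "b", "c", "d"))
  lin <- toy_lineages(names(rows), c("a", "b"))
  aln <- gene_alignment("g", rows, lin)
  q <- taxon_query("Fagales", lin)
  expect_equal(nrow(find_taxon_specific_snps(aln, q)), 0L)
})

test_that("a planted member/non-member partition is called exactly once", {
  base <- rand_dna(41)
  mk <- function(allele) {
    cs <- strsplit(base, "")[[1]]; cs[11] <- allele
    paste(cs, collapse = "")
  }
  ids <- c("m1", "m2", "n1", "n2", "n3", "n4")
  rows <- stats::setNames(c(mk("T"), mk("T"), mk("C"), mk("C"), mk("C"),
                            mk("C")), ids)
  lin <- toy_lineages(ids, c("m1", "m2"))
  aln <- gene_alignment("g", rows, lin)
  q <- taxon_query("Fagales", lin)
  snps <- find_taxon_specific_snps(aln, q, flank_width = 5)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$column, 10L)
  expect_identical(snps$target_allele, "T")
  expect_identical(snps$alt_alleles, "C")
  expect_true(snps$conserved)
  # positions attached per genome (1-based, gap-free alignment)
  expect_equal(unname(attr(snps, "positions")[[1]]["m1"]), 11L)
  # agrees with the brute-force column scan
  want <- oracle_snp_scan(aln, q$members, q$non_members)
  expect_equal(snps$column, want$column)
})

test_that("columns with gaps or ambiguity codes are ineligible", {
  rows <- c(m1 = "AAtAAA", m2 = "AATAAA", n1 = "AACAAA", n2 = "AA-AAA")
  rows <- toupper(rows)
  rows["n2"] <- "AA-AAA"
  lin <- toy_lineages(names(rows), c("m1", "m2"))
  aln <- gene_alignment("g", rows, lin)
  q <- taxon_query("Fagales", lin)
  expect_equal(nrow(find_taxon_specific_snps(aln, q)), 0L)
  rows["n2"] <- "AANAAA"
  aln2 <- gene_alignment("g", rows, lin)
  expect_equal(nrow(find_taxon_specific_snps(aln2, q)), 0L)
})

test_that("scanner equals brute force on random planted fixtures", {
  set.seed(67)
  ids <- c("m1", "m2", "m3", "n1", "n2", "n3", "n4")
  lin <- toy_lineages(ids, c("m1", "m2", "m3"))
  q <- taxon_query("Fagales", lin)
  for (rep in 1:30) {
    ncol <- sample(40:90, 1)
    base <- strsplit(rand_dna(ncol), "")[[1]]
    rows <- lapply(ids, function(i) base)
    names(rows) <- ids
    # plant diagnostic columns
    for (k in sample(5:(ncol - 5), sample(1:3, 1))) {
      pair <- sample(c("A", "C", "G", "T"), 2)
      for (i in ids) rows[[i]][k] <- if (i %in% q$members) pair[1] else pair[2]
    }
    # random noise and occasional gaps
    for (j in sample(seq_len(ncol), 6)) {
      i <- sample(ids, 1)
      rows[[i]][j] <- sample(c("A", "C", "G", "T", "-"), 1,
                             prob = c(.2, .2, .2, .2, .2))
    }
    rows <- vapply(rows, paste, "", collapse = "")
    aln <- gene_alignment("g", rows, lin)
    got <- find_taxon_specific_snps(aln, q)
    want <- oracle_snp_scan(aln, q$members, q$non_members)
    expect_equal(got$column, want$column)
    expect_identical(got$target_allele, want$target_allele)
    expect_identical(got$alt_alleles, want$alt_alleles)
    # soundness: re-check every emitted SNP against the raw alignment
    m <- do.call(rbind, strsplit(aln$rows, ""))
    rownames(m) <- names(aln$rows)
    for (r in seq_len(nrow(got))) {
      bases <- m[, got$column[r] + 1L]
      expect_true(all(bases[q$members] == got$target_allele[r]))
      expect_false(got$target_allele[r] %in% bases[q$non_members])
    }
  }
})

test_that("conserved-flank filter enforces width, gaps and monomorphism", {
  ids <- c("m1", "n1", "n2")
  lin <- toy_lineages(ids, "m1")
  mono <- function(n) strrep("A", n)
  # fully monomorphic gap-free flanks pass
  rows <- stats::setNames(rep(paste0(mono(20), "C", mono(20)), 3), ids)
  aln <- gene_alignment("g", rows, lin)
  expect_true(conserved_flank_filter(aln, 20, flank_width = 20))
  # truncated flank is a failure, not a shorter flank
  expect_false(conserved_flank_filter(aln, 5, flank_width = 20))
  expect_false(conserved_flank_filter(aln, 35, flank_width = 20))
  # one gap column inside a flank fails
  gapped <- rows
  cs <- strsplit(gapped[["n2"]], "")[[1]]; cs[10] <- "-"
  gapped[["n2"]] <- paste(cs, collapse = "")
  aln2 <- gene_alignment("g", gapped, lin)
  expect_false(conserved_flank_filter(aln2, 20, flank_width = 20))
  expect_error(conserved_flank_filter(aln, 20, flank_width = 0),
               "flank_width")
})

test_that("17 of 20 monomorphic flank columns fails a 90% threshold", {
  ids <- c("m1", "n1", "n2")
  lin <- toy_lineages(ids, "m1")
  left <- vapply(ids, function(i) strrep("A", 20), "")
  # make 3 left-flank columns polymorphic -> 17/20 = 85% < 90%
  lc <- strsplit(left, "")
  for (k in c(2, 8, 14)) lc[["n1"]][k] <- "G"
  left <- vapply(lc, paste, "", collapse = "")
  rows <- stats::setNames(paste0(left, "C", strrep("T", 20)), ids)
  aln <- gene_alignment("g", rows, lin)
  expect_false(conserved_flank_filter(aln, 20, flank_width = 20,
                                      min_monomorphic = 90))
  expect_true(conserved_flank_filter(aln, 20, flank_width = 20,
                                     min_monomorphic = 85))
})

test_that("tightening the filter never increases conserved SNP counts", {
  run <- default_pipeline()
  for (taxon in names(run$snps)) {
    q <- suppressWarnings(taxon_query(taxon, run$lineages))
    loose <- find_taxon_specific_snps(run$alns, q, flank_width = 10,
                                      min_monomorphic = 80)
    mid <- find_taxon_specific_snps(run$alns, q, flank_width = 20,
                                    min_monomorphic = 90)
    tight <- find_taxon_specific_snps(run$alns, q, flank_width = 30,
                                      min_monomorphic = 98)
    expect_gte(sum(loose$conserved), sum(mid$conserved))
    expect_gte(sum(mid$conserved), sum(tight$conserved))
  }
})

test_that("snp summary counts SNPs and distinct genes per taxon", {
  run <- default_pipeline()
  st <- run$snps[["Fagus"]]
  s <- summary(st)
  expect_identical(s$target_taxon, "Fagus")
  expect_equal(s$n_snps, sum(st$conserved))
  expect_lte(s$n_genes, length(unique(st$gene)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_snp_report(st, tf)
  rep <- utils::read.delim(tf)
  expect_equal(nrow(rep), nrow(st))
})
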