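# Restriction enzymes, site finding, digestion, in-silico PCR and CAPS
# marker design.

enzyme_by_name <- function(name) {
  e <- Filter(function(x) x$name == name, default_enzymes())
  expect_length(e, 1)
  e[[1]]
}

test_that("enzyme table notations parse to the right cut geometry", {
  eco <- capstax:::parse_enzyme_pattern("EcoRI", "G^AATTC")
  expect_identical(eco$recognition, "GAATTC")
  expect_equal(eco$cut_top, 1L)
  expect_equal(eco$cut_bottom, 5L)
  expect_true(eco$palindromic)

  bsm <- capstax:::parse_enzyme_pattern("BsmBI", "CGTCTC(1/5)")
  expect_identical(bsm$recognition, "CGTCTC")
  expect_equal(bsm$cut_top, 7L)   # one base past the 3' end
  expect_equal(bsm$cut_bottom, 11L)
  expect_false(bsm$palindromic)

  expect_error(capstax:::parse_enzyme_pattern("Bad", "G^AATTC(1/5)"),
               "mutually exclusive")
  expect_error(capstax:::parse_enzyme_pattern("Bad", "G^AAXTC"), "IUPAC")
  expect_error(capstax:::parse_enzyme_pattern("Bad", "GAATTC"), "neither")
})

test_that("the bundled table includes the validated marker enzymes", {
  names <- vapply(default_enzymes(), `[[`, "", "name")
  expect_true(all(c("NciI", "BstXI", "SfcI", "BsmBI") %in% names))
  bst <- enzyme_by_name("BstXI")
  expect_identical(bst$recognition, "CCANNNNNNTGG")
  expect_equal(bst$cut_top, 8L)
})

test_that("find_sites matches IUPAC sites on both strands", {
  nci <- enzyme_by_name("NciI")
  expect_equal(nrow(find_sites("AAAATTTT", nci)), 0L)
  hits <- find_sites("AACCCGGTTCCGGGAA", nci)
  expect_equal(hits$position, c(2L, 9L))  # CCCGG and CCGGG

  bsm <- enzyme_by_name("BsmBI")
  h2 <- find_sites(paste0("AAAA", "GAGACG", "AAAA"), bsm)
  expect_equal(nrow(h2), 1L)
  expect_identical(h2$strand, "-")
  expect_equal(h2$position, 4L)
})

test_that("find_sites equals brute-force sliding-window matching", {
  set.seed(77)
  enzymes <- default_enzymes()
  for (rep in 1:10) {
    s <- rand_dna(sample(300:2000, 1))
    enz <- enzymes[[sample(length(enzymes), 1)]]
    expect_equal(find_sites(s, enz), oracle_find_sites(s, enz),
                 info = enz$name)
  }
})

test_that("digestion partitions the molecule with correct cut offsets", {
  bam <- enzyme_by_name("BamHI")
  expect_equal(digest_linear("AAAATTTTAAAATT", bam), 14L)  # no site
  expect_equal(digest_linear(paste0("AAAA", "GGATCC", "TTTT"), bam),
               c(9L, 5L))

  # Type IIS: BsmBI cuts 1/5 past its site; a site whose cut coordinate
  # falls beyond the molecule end does not cut
  bsm <- enzyme_by_name("BsmBI")
  expect_equal(digest_linear(paste0(strrep("A", 10), "CGTCTC", "TGGGGG"), bsm),
               c(17L, 5L))
  expect_equal(digest_linear(paste0(strrep("A", 10), "CGTCTC"), bsm), 16L)
  # minus-strand site: top cut 5 bases left of the GAGACG start
  expect_equal(digest_linear(paste0(strrep("T", 10), "GAGACG", "TT"), bsm),
               c(13L, 5L))
})

test_that("fragment lengths always sum to the sequence length", {
  set.seed(55)
  enzymes <- default_enzymes()
  for (rep in 1:200) {
    L <- sample(30:400, 1)
    s <- rand_dna(L)
    enz <- enzymes[[sample(length(enzymes), 1)]]
    fr <- digest_linear(s, enz)
    expect_equal(sum(fr), L)
    expect_true(all(fr > 0))
    expect_false(is.unsorted(rev(fr)))
  }
})

test_that("in-silico PCR amplifies between matching primers", {
  set.seed(3)
  tmpl <- rand_dna(120)
  amp <- insilico_pcr(tmpl, substr(tmpl, 1, 20),
                      revcomp(substr(tmpl, 101, 120)))
  expect_identical(amp, tmpl)
  amp2 <- insilico_pcr(tmpl, substr(tmpl, 11, 30),
                       revcomp(substr(tmpl, 81, 100)))
  expect_equal(nchar(amp2), 90L)
  expect_identical(amp2, substr(tmpl, 11, 100))

  expect_error(insilico_pcr(tmpl, strrep("G", 20), strrep("C", 20)),
               class = "pcr_no_product")
  tmpl2 <- paste0(tmpl, tmpl)  # two possible products
  expect_error(insilico_pcr(tmpl2, substr(tmpl, 11, 30),
                            revcomp(substr(tmpl, 81, 100))),
               class = "pcr_multiple_products")
  expect_error(insilico_pcr(tmpl, "ACGTACGT", revcomp(substr(tmpl, 81, 100))),
               "12 bases")
})

test_that("primer mismatches respect the budget and the exact 3' base", {
  set.seed(13)
  tmpl <- rand_dna(150)
  fwd <- strsplit(substr(tmpl, 21, 40), "")[[1]]
  fwd[5] <- setdiff(c("A", "C", "G", "T"), fwd[5])[1]
  fwd_mm <- paste(fwd, collapse = "")
  rev <- revcomp(substr(tmpl, 111, 130))
  expect_error(insilico_pcr(tmpl, fwd_mm, rev, max_mismatches = 0),
               class = "pcr_no_product")
  expect_equal(nchar(insilico_pcr(tmpl, fwd_mm, rev, max_mismatches = 1)),
               110L)
  # a 3'-terminal mismatch is never tolerated
  fwd3 <- strsplit(substr(tmpl, 21, 40), "")[[1]]
  fwd3[20] <- setdiff(c("A", "C", "G", "T"), fwd3[20])[1]
  expect_error(insilico_pcr(tmpl, paste(fwd3, collapse = ""), rev,
                            max_mismatches = 2),
               class = "pcr_no_product")
})

test_that("planted markers are recovered with manifest-exact chemistry", {
  run <- default_pipeline()
  manifest <- run$sim$manifest$snps
  markers <- do.call(c, unname(run$markers))
  expect_length(markers, nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    want <- manifest[i, ]
    got <- Filter(function(m)
      m$taxon == want$target_taxon &&
        m$gene == capstax:::normalize_gene_name(want$gene) &&
        m$snp$column == want$column, markers)
    expect_length(got, 1)
    mk <- got[[1]]
    expect_identical(mk$enzyme$name, want$enzyme)
    expect_identical(mk$snp$target_allele, want$target_allele)
    expect_identical(mk$snp$alt_alleles, want$alt_alleles)
    # fragment arithmetic from the planted site and cut geometry
    expect_equal(sum(mk$fragments_target), nchar(mk$amplicon))
    site_in_amp <- want$site_gene_offset - mk$amplicon_columns[1]
    cut <- site_in_amp + mk$enzyme$cut_top
    expect_setequal(mk$fragments_target, c(cut, nchar(mk$amplicon) - cut))
  }
})

test_that("accepted markers discriminate: alternative alleles stay uncut", {
  run <- default_pipeline()
  markers <- do.call(c, unname(run$markers))
  expect_gt(length(markers), 0)
  for (mk in markers) {
    expect_lte(nchar(mk$amplicon), 200L)
    expect_gte(length(mk$fragments_target), 2L)
    expect_true(all(mk$fragments_target >= 40L))
    snp_off <- mk$snp$column - mk$amplicon_columns[1] + 1L
    cs <- strsplit(mk$amplicon, "")[[1]]
    expect_identical(cs[snp_off], mk$snp$target_allele)
    for (alt in strsplit(mk$snp$alt_alleles, ",")[[1]]) {
      cs2 <- cs; cs2[snp_off] <- alt
      expect_equal(digest_linear(paste(cs2, collapse = ""), mk$enzyme),
                   nchar(mk$amplicon))
    }
  }
})

test_that("a SNP without a discriminative enzyme yields no marker", {
  ids <- c("m1", "m2", "n1", "n2")
  lin <- stats::setNames(lapply(ids, function(i)
    if (startsWith(i, "m")) c("Eukaryota", "Fagales") else
      c("Eukaryota", "Elsewhere")), ids)
  base <- strsplit(strrep("AT", 60), "")[[1]]
  rows <- vapply(ids, function(i) {
    cs <- base
    cs[60] <- if (startsWith(i, "m")) "G" else "C"
    paste(cs, collapse = "")
  }, "")
  aln <- gene_alignment("g", rows, lin)
  q <- taxon_query("Fagales", lin)
  snps <- find_taxon_specific_snps(aln, q, flank_width = 10)
  expect_equal(nrow(snps), 1L)
  expect_length(design_caps_markers(snps, list(aln), default_enzymes()), 0)
})

test_that("marker reports are written in the published table layout", {
  run <- default_pipeline()
  markers <- do.call(c, unname(run$markers))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_marker_report(markers, tf)
  rep <- utils::read.delim(tf)
  expect_equal(nrow(rep), length(markers))
  expect_true(all(c("marker", "taxon", "alleles", "enzyme", "fragments",
                    "fwd_primer", "rev_primer") %in% names(rep)))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_marker_amplicons(markers, fa)
  expect_equal(sum(grepl("^>", readLines(fa))), length(markers))
})
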