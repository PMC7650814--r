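# GenBank I/O, gene extraction, shared genes and the ORF scan.

make_genome <- function(id = "GX1", n = 1200, feats = list()) {
  annotated_genome(id, "Genus species", c("Eukaryota", "Ordo", "Familia",
                                          "Genus"), rand_dna(n), feats)
}

test_that("write/read round-trip preserves sequence and features", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(500:2000, 1)
    feats <- list(
      gene_feature("atp1", "protein_coding",
                   c(10L, 10L + sample(100:200, 1)), "+"),
      gene_feature("ccmFc", "protein_coding",
                   matrix(c(300L, 360L, 400L, 470L), 2, byrow = TRUE), "-"),
      gene_feature("trnK", "tRNA", c(480L, 490L), "+"))
    g <- make_genome(n = n, feats = feats)
    tf <- withr::local_tempfile(fileext = ".gb")
    write_genbank(g, tf)
    g2 <- read_genbank(tf)[[1]]
    expect_identical(g2$sequence, g$sequence)
    expect_identical(g2$length, g$length)
    expect_identical(g2$lineage, g$lineage)
    expect_identical(g2$organism, g$organism)
    expect_equal(length(g2$features), length(g$features))
    for (k in seq_along(feats)) {
      expect_identical(g2$features[[k]]$gene_name, g$features[[k]]$gene_name)
      expect_identical(g2$features[[k]]$segments, g$features[[k]]$segments)
      expect_identical(g2$features[[k]]$strand, g$features[[k]]$strand)
      expect_identical(g2$features[[k]]$kind, g$features[[k]]$kind)
    }
  }
})

test_that("minimal record without features parses", {
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       MINI1 10 bp DNA linear PLN 01-JAN-2026",
               "ORIGIN",
               "        1 acgtacgtac",
               "//"), tf)
  g <- read_genbank(tf)[[1]]
  expect_equal(g$length, 10L)
  expect_equal(length(g$features), 0L)
  expect_identical(g$sequence, "ACGTACGTAC")
})

test_that("minus-strand multi-exon genes serialize as complement(join(...))", {
  g <- make_genome(n = 500, feats = list(
    gene_feature("nad4", "protein_coding",
                 matrix(c(100L, 200L, 300L, 400L), 2, byrow = TRUE), "-")))
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, tf)
  txt <- readLines(tf)
  expect_true(any(grepl("complement(join(101..200,301..400))", txt,
                        fixed = TRUE)))
})

test_that("location strings parse with nesting and 1-based conversion", {
  loc <- capstax:::parse_location("complement(join(101..200,301..400))")
  expect_identical(loc$strand, "-")
  expect_equal(loc$segments, matrix(c(100L, 200L, 300L, 400L), 2,
                                    byrow = TRUE))
  loc2 <- capstax:::parse_location("join(complement(301..400),complement(101..200))")
  expect_identical(loc2$strand, "-")
  single <- capstax:::parse_location("42")
  expect_equal(single$segments[1, ], c(41L, 42L))
})

test_that("malformed records and out-of-range features are rejected", {
  tf <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("NOT_A_LOCUS line", "//"), tf)
  expect_error(read_genbank(tf), "LOCUS")
  writeLines(c("LOCUS       BAD1 10 bp DNA",
               "FEATURES             Location/Qualifiers",
               "     CDS             5..50",
               "                     /gene=\"x\"",
               "ORIGIN",
               "        1 acgtacgtac",
               "//"), tf)
  expect_error(read_genbank(tf), "beyond|outside")
  g <- make_genome(n = 100)
  g$features <- list(gene_feature("far", "protein_coding", c(50L, 400L), "+"))
  expect_error(write_genbank(g, tf), "refusing")
})

test_that("gene extraction honors segments, strand and splicing mode", {
  g <- annotated_genome("X", "x", "A", "ATGAAATTT",
                        list(gene_feature("fwd", "protein_coding",
                                          c(0L, 6L), "+")))
  expect_identical(unname(extract_gene_sequences(g)[["fwd"]]), "ATGAAA")

  # complement(join(1..3,7..9)) on ATGTTTCCC, exon-joined: GGGCAT
  g2 <- annotated_genome("Y", "y", "A", "ATGTTTCCC",
                         list(gene_feature("rev", "protein_coding",
                                           matrix(c(0L, 3L, 6L, 9L), 2,
                                                  byrow = TRUE), "-")))
  expect_identical(unname(extract_gene_sequences(g2, mode = "exons")[["rev"]]),
                   "GGGCAT")
  # default span mode keeps the intron
  expect_identical(unname(extract_gene_sequences(g2)[["rev"]]),
                   revcomp("ATGTTTCCC"))
})

test_that("minus-strand extraction equals revcomp of the mirrored annotation", {
  set.seed(7)
  for (rep in 1:5) {
    s <- rand_dna(300)
    st <- sample(1:100, 1); en <- st + sample(50:150, 1)
    gm <- annotated_genome("M", "m", "A", s,
                           list(gene_feature("g", "protein_coding",
                                             c(st, en), "-")))
    mirror <- annotated_genome("P", "p", "A", revcomp(s),
                               list(gene_feature("g", "protein_coding",
                                                 c(300L - en, 300L - st), "+")))
    expect_identical(extract_gene_sequences(gm)[["g"]],
                     extract_gene_sequences(mirror)[["g"]])
  }
})

test_that("trans-spliced genes are flagged and excluded from extraction", {
  feats <- list(
    gene_feature("nad1", "protein_coding", c(10L, 60L), "+"),
    gene_feature("nad1", "protein_coding", c(200L, 260L), "-"),
    gene_feature("cox1", "protein_coding", c(300L, 390L), "+"))
  g <- make_genome(n = 500, feats = feats)
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, tf)
  g2 <- read_genbank(tf)[[1]]
  expect_true(g2$features[[1]]$trans_spliced)
  expect_true(g2$features[[2]]$trans_spliced)
  expect_false(g2$features[[3]]$trans_spliced)
  ex <- extract_gene_sequences(g2)
  expect_false("nad1" %in% names(ex))
  expect_true("cox1" %in% names(ex))
  # parts retrievable when not excluding
  ex2 <- extract_gene_sequences(g2, exclude_trans_spliced = FALSE)
  expect_true(all(c("nad1.1", "nad1.2") %in% names(ex2)))
})

test_that("shared_genes intersects normalized name sets", {
  mk <- function(id, genes) make_genome(id = id, n = 800, feats = lapply(
    seq_along(genes), function(i)
      gene_feature(genes[i], "protein_coding",
                   c(i * 100L, i * 100L + 50L), "+")))
  g1 <- mk("A1", c("a", "b", "c"))
  g2 <- mk("A2", c("b", "c", "d"))
  expect_identical(shared_genes(list(g1, g2)), c("b", "c"))
  expect_identical(shared_genes(list(g1)), c("a", "b", "c"))
  # case and alias normalization
  g3 <- mk("A3", c("ccmFC", "COX1"))
  g4 <- mk("A4", c("ccmfc", "cox1"))
  expect_identical(shared_genes(list(g3, g4)), c("ccmfc", "cox1"))
  expect_error(shared_genes(list()), "at least one")
})

test_that("orf_scan finds the constructed single ORF and obeys arguments", {
  expect_equal(nrow(orf_scan("CCCCCCAATTCCGG", min_codons = 1)), 0L)
  set.seed(31)
  sense <- c("GCT", "GGT", "TCT", "ACT", "CCT", "GAT")
  body <- paste(sample(sense, 103, TRUE), collapse = "")
  s <- paste0("CCC", "ATG", body, "TAA", "CCC")
  o <- orf_scan(s, min_codons = 100)
  expect_equal(nrow(o), 1L)
  expect_equal(o$length_codons, 105)
  expect_equal(o$end - o$start, 315)
  expect_error(orf_scan(s, min_codons = 0), "min_codons")
})

test_that("orf_scan equals six-frame brute force on random sequences", {
  set.seed(17)
  for (rep in 1:12) {
    s <- rand_dna(sample(300:1200, 1))
    for (nested in c(TRUE, FALSE)) {
      got <- orf_scan(s, min_codons = 8, both_strands = TRUE,
                      exclude_nested = nested)
      want <- oracle_orf_scan(s, min_codons = 8, both_strands = TRUE,
                              exclude_nested = nested)
      expect_equal(got, want)
    }
  }
})
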