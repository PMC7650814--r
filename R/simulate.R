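# Seeded synthetic-data generator: annotated GenBank files for a toy
# taxonomy (order -> family -> genus -> species) with planted taxon-specific
# SNPs, planted discriminative restriction sites, planted interspersed
# repeats and a planted plastid-like insertion, plus a truth manifest, so the
# whole pipeline is testable offline.
#
# Branch substitutions are drawn uniformly over unprotected positions with an
# equal-rate (Jukes-Cantor-like) base choice and are required to be
# "CAPS-neutral": a substitution may not create or destroy a recognition site
# of any cataloged enzyme, so no accidental column can satisfy the marker
# design criteria and planted-truth recovery is exact.  No indels are
# introduced by default, so per-gene alignments are unambiguous and columns
# equal gene offsets.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

default_species_table <- function() {
  data.frame(
    id = c("FSY1", "QVA1", "BPE1", "PTR1", "PAL1", "EGR1", "LTU1", "GBI1"),
    organism = c("Fagus sylvatica", "Quercus variabilis", "Betula pendula",
                 "Populus tremula", "Populus alba", "Eucalyptus grandis",
                 "Liriodendron tulipifera", "Ginkgo biloba"),
    order = c("Fagales", "Fagales", "Fagales", "Malpighiales", "Malpighiales",
              "Myrtales", "Magnoliales", "Ginkgoales"),
    family = c("Fagaceae", "Fagaceae", "Betulaceae", "Salicaceae",
               "Salicaceae", "Myrtaceae", "Magnoliaceae", "Ginkgoaceae"),
    genus = c("Fagus", "Quercus", "Betula", "Populus", "Populus",
              "Eucalyptus", "Liriodendron", "Ginkgo"),
    stringsAsFactors = FALSE)
}

default_gene_roster <- function() {
  data.frame(
    name = c("matR", "ccmFc", "nad7", "cox1", "cox3", "atp1", "cob",
             "rps3", "ccmB", "rpl10", "sdh3", "nad4"),
    length = c(1800L, 1400L, 1500L, 1400L, 800L, 1200L, 1100L, 900L, 600L,
               500L, 350L, 1300L),
    strand = c("+", "-", "+", "+", "-", "+", "+", "+", "+", "+", "+", "+"),
    n_exons = c(1L, 2L, 3L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)
}

# Planted CAPS-compatible SNPs mirroring the validated marker chemistry:
# genus-, family- and order-level targets with BstXI, BsmBI, SfcI and NciI.
# snp_in_site is the 0-based offset of the SNP inside the recognition site.
default_caps_plantings <- function() {
  data.frame(
    gene = c("matR", "ccmFc", "nad7", "matR"),
    gene_offset = c(900L, 700L, 750L, 300L),
    target_taxon = c("Fagus", "Fagus", "Fagaceae", "Fagales"),
    enzyme = c("BstXI", "BsmBI", "SfcI", "NciI"),
    snp_in_site = c(11L, 2L, 4L, 2L),
    target_allele = c("G", "T", "A", "G"),
    alt_alleles = c("C,T,A", "C", "G", "A"),
    stringsAsFactors = FALSE)
}

#' Clade model for the synthetic-data generator
#'
#' Defines a toy taxonomy, a gene roster, planted CAPS-compatible SNPs,
#' planted repeats and a planted plastid-like insertion.  The defaults mirror
#' the real study setting at desk scale: eight species in five orders, with
#' the Fagales represented by two Fagaceae and one Betulaceae species, a
#' genus with a single sequenced member, and four planted genus-, family- and
#' order-level markers using the BstXI/BsmBI/SfcI/NciI chemistry.
#'
#' @param species data frame with `id`, `organism`, `order`, `family`,
#'   `genus`
#' @param genes gene roster: `name`, `length`, `strand`, `n_exons`
#' @param caps_snps planted CAPS-compatible SNPs, see
#'   `default_caps_plantings()` for the column layout
#' @param subs_per_branch substitutions drawn on every tree branch
#'   (default 25)
#' @param spacer_len intergenic spacer length (default 400)
#' @param filler_len extra intergenic tail used for repeat/insertion planting
#'   (default 7000)
#' @param context_flank bases of protected monomorphic context planted on
#'   each side of a CAPS recognition site (default 120; wide enough for any
#'   amplicon the designer can choose)
#' @param repeats data frame of repeats to plant into the first species:
#'   `length`, `orientation` (`direct`/`inverted`)
#' @param insertion_len,insertion_subs length of the plastid fragment copied
#'   into the first species' genome and the substitutions applied to it
#'   (defaults 668 and 8)
#' @param plastid_len length of the synthetic plastid genome (default 12000)
#' @param seed integer seed; the generator is byte-deterministic given the
#'   model (default 42)
#' @return object of class `clade_model`
#' @export
clade_model <- function(species = default_species_table(),
                        genes = default_gene_roster(),
                        caps_snps = default_caps_plantings(),
                        subs_per_branch = 25L,
                        spacer_len = 400L,
                        filler_len = 7000L,
                        context_flank = 120L,
                        repeats = data.frame(length = c(316L, 120L),
                                             orientation = c("direct",
                                                             "inverted")),
                        insertion_len = 668L, insertion_subs = 8L,
                        plastid_len = 12000L,
                        seed = 42L) {
  stopifnot(nrow(species) >= 2L, !anyDuplicated(species$id))
  for (i in seq_len(nrow(caps_snps))) {
    s <- caps_snps[i, ]
    g <- genes[genes$name == s$gene, ]
    if (!nrow(g)) stop("planted SNP in unknown gene '", s$gene, "'")
    if (s$gene_offset - context_flank < 0L ||
        s$gene_offset + context_flank + 12L > g$length)
      stop("planted SNP in '", s$gene, "' too close to a gene end for its ",
           "protected context")
  }
  structure(list(species = species, genes = genes, caps_snps = caps_snps,
                 subs_per_branch = as.integer(subs_per_branch),
                 spacer_len = as.integer(spacer_len),
                 filler_len = as.integer(filler_len),
                 context_flank = as.integer(context_flank),
                 repeats = repeats,
                 insertion_len = as.integer(insertion_len),
                 insertion_subs = as.integer(insertion_subs),
                 plastid_len = as.integer(plastid_len),
                 seed = as.integer(seed)),
            class = "clade_model")
}

# enzymes whose recognition (either strand) discriminates target from every
# alternative allele at snp_idx (1-based) of a character-vector context
discriminative_enzymes <- function(ctx, snp_idx, target, alts, enzymes) {
  hits <- character(0)
  for (enz in enzymes) {
    len <- nchar(enz$recognition)
    pats <- unique(c(enz$recognition, revcomp(enz$recognition)))
    match_at <- function(allele) {
      w <- ctx; w[snp_idx] <- allele
      for (o in max(1L, snp_idx - len + 1L):min(snp_idx, length(ctx) - len + 1L)) {
        ws <- paste(w[o:(o + len - 1L)], collapse = "")
        for (p in pats) if (iupac_matches(p, ws)) return(TRUE)
      }
      FALSE
    }
    if (match_at(target) && !any(vapply(alts, match_at, NA)))
      hits <- c(hits, enz$name)
  }
  hits
}

count_sites <- function(s, enz) nrow(find_sites(s, enz))

# Build a protected context string: flank + recognition-with-SNP + flank,
# redrawn until exactly the intended enzyme discriminates and the context
# carries no stray site of that enzyme.
make_caps_context <- function(enzyme, snp_in_site, target, alts, flank,
                              enzymes) {
  len <- nchar(enzyme$recognition)
  site <- vapply(chars(enzyme$recognition), function(cc) {
    set <- .iupac_sets[[cc]]
    set[1L]  # deterministic concrete base for ambiguous positions
  }, "")
  if (!target %in% .iupac_sets[[chars(enzyme$recognition)[snp_in_site + 1L]]])
    stop("target allele '", target, "' does not complete the ", enzyme$name,
         " site at offset ", snp_in_site)
  site[snp_in_site + 1L] <- target
  for (try in 1:200) {
    ctx <- c(chars(random_dna(flank)), site, chars(random_dna(flank)))
    snp_idx <- flank + snp_in_site + 1L
    s_target <- paste(ctx, collapse = "")
    if (count_sites(s_target, enzyme) != 1L) next
    alt_ok <- all(vapply(alts, function(a) {
      w <- ctx; w[snp_idx] <- a
      count_sites(paste(w, collapse = ""), enzyme) == 0L
    }, NA))
    if (!alt_ok) next
    disc <- discriminative_enzymes(ctx, snp_idx, target, alts, enzymes)
    if (identical(disc, enzyme$name)) return(ctx)
  }
  stop("could not construct a discriminative context for ", enzyme$name)
}

# would substituting new_base at pos (1-based) create or destroy a site of
# any cataloged enzyme?
caps_neutral <- function(seq_chars, pos, new_base, enzymes) {
  n <- length(seq_chars)
  for (enz in enzymes) {
    len <- nchar(enz$recognition)
    pats <- unique(c(enz$recognition, revcomp(enz$recognition)))
    for (o in max(1L, pos - len + 1L):min(pos, n - len + 1L)) {
      old_w <- paste(seq_chars[o:(o + len - 1L)], collapse = "")
      new_c <- seq_chars[o:(o + len - 1L)]
      new_c[pos - o + 1L] <- new_base
      new_w <- paste(new_c, collapse = "")
      for (p in pats)
        if (iupac_matches(p, old_w) != iupac_matches(p, new_w)) return(FALSE)
    }
  }
  TRUE
}

#' Simulate an annotated clade dataset with planted truth
#'
#' One annotated genome per species of the model: a random ancestral genome
#' with the gene roster annotated (including a trans-spliced gene split
#' across two loci), per-branch CAPS-neutral random substitutions, planted
#' taxon-diagnostic SNPs inside discriminative restriction-site contexts,
#' planted interspersed repeats and a planted plastid-like insertion in the
#' first species.  Identical seeds give byte-identical output.
#'
#' @param model a [clade_model()]
#' @param dir if non-NULL, write one GenBank file per species plus
#'   `manifest.jsonl` and `plastid.fasta` into this directory
#' @return list with `genomes` (list of [annotated_genome()]), `plastid`
#'   (synthetic plastid sequence) and `manifest` (list: `snps`, `repeats`,
#'   `insertion`, `species`)
#' @export
simulate_clade_dataset <- function(model, dir = NULL) {
  stopifnot(inherits(model, "clade_model"))
  enzymes <- default_enzymes()
  with_seed(model$seed, {
    sim <- build_simulation(model, enzymes)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (g in sim$genomes) write_genbank(g, file.path(dir, paste0(g$id, ".gb")))
    write_fasta(list(plastid = sim$plastid), file.path(dir, "plastid.fasta"))
    manifest_path <- file.path(dir, "manifest.jsonl")
    con <- file(manifest_path, "w")
    for (part in names(sim$manifest)) {
      writeLines(jsonlite::toJSON(c(list(record = part),
                                    list(data = sim$manifest[[part]])),
                                  auto_unbox = TRUE, digits = NA), con)
    }
    close(con)
  }
  sim
}

build_simulation <- function(model, enzymes) {
  sp <- model$species
  genes <- model$genes

  # ---- ancestral gene sequences (gene coordinate space, 5'->3') ----
  gene_seqs <- lapply(seq_len(nrow(genes)), function(i)
    chars(random_dna(genes$length[i])))
  names(gene_seqs) <- genes$name

  # plant CAPS contexts into gene space; record protected gene intervals
  caps <- model$caps_snps
  caps$site_gene_offset <- caps$gene_offset - caps$snp_in_site
  protected_gene <- list()
  enzyme_by_name <- stats::setNames(enzymes,
                                    vapply(enzymes, `[[`, "", "name"))
  for (i in seq_len(nrow(caps))) {
    s <- caps[i, ]
    enz <- enzyme_by_name[[s$enzyme]]
    if (is.null(enz)) stop("planted enzyme '", s$enzyme, "' not in the table")
    alts <- strsplit(s$alt_alleles, ",", fixed = TRUE)[[1L]]
    ctx <- make_caps_context(enz, s$snp_in_site, s$target_allele, alts,
                             model$context_flank, enzymes)
    start <- s$gene_offset - model$context_flank - s$snp_in_site
    end <- start + length(ctx)
    prev <- protected_gene[[s$gene]]
    if (!is.null(prev) && any(prev[, 1] < end & start < prev[, 2]))
      stop("planted features collide in gene '", s$gene, "'")
    protected_gene[[s$gene]] <- rbind(prev, c(start, end))
    gene_seqs[[s$gene]][(start + 1L):end] <- ctx
    # ancestor carries the first alternative allele at the SNP
    gene_seqs[[s$gene]][s$gene_offset + 1L] <- alts[1L]
  }

  # ---- assemble the ancestral genome ----
  # layout: spacer, gene1, spacer, gene2, ..., trans-spliced gene in two
  # parts, filler tail
  blocks <- list()
  feats_proto <- list()   # name, kind, segments(gene-space), strand, start
  pos <- 0L
  add_block <- function(seq_chars) {
    blocks[[length(blocks) + 1L]] <<- seq_chars
    start <- pos
    pos <<- pos + length(seq_chars)
    start
  }
  gene_start <- integer(0)
  for (i in seq_len(nrow(genes))) {
    add_block(chars(random_dna(model$spacer_len)))
    gseq <- gene_seqs[[genes$name[i]]]
    emb <- if (genes$strand[i] == "-") chars(revcomp(paste(gseq, collapse = ""))) else gseq
    gstart <- add_block(emb)
    gene_start[genes$name[i]] <- gstart
    L <- genes$length[i]
    nex <- genes$n_exons[i]
    segs <- exon_segments(L, nex)
    feats_proto[[length(feats_proto) + 1L]] <-
      list(name = genes$name[i], kind = "protein_coding",
           segments = segs + gstart, strand = genes$strand[i])
  }
  # trans-spliced gene: two disjoint parts sharing one name
  for (part in 1:2) {
    add_block(chars(random_dna(model$spacer_len)))
    pseq <- chars(random_dna(600L))
    pstart <- add_block(pseq)
    feats_proto[[length(feats_proto) + 1L]] <-
      list(name = "nad1", kind = "protein_coding",
           segments = exon_segments(600L, 2L) + pstart,
           strand = if (part == 1L) "+" else "-")
  }
  # a couple of tRNAs so feature kinds vary
  for (tn in c("trnK", "trnM")) {
    add_block(chars(random_dna(150L)))
    tstart <- add_block(chars(random_dna(72L)))
    feats_proto[[length(feats_proto) + 1L]] <-
      list(name = tn, kind = "tRNA",
           segments = matrix(c(0L, 72L), ncol = 2) + tstart, strand = "+")
  }
  filler_start <- add_block(chars(random_dna(model$filler_len)))
  ancestor <- unlist(blocks)
  G <- length(ancestor)

  # protected genome intervals (0-based half-open)
  protected <- matrix(integer(0), ncol = 2)
  for (gname in names(protected_gene)) {
    gi <- which(genes$name == gname)
    for (r in seq_len(nrow(protected_gene[[gname]]))) {
      iv <- protected_gene[[gname]][r, ]
      protected <- rbind(protected,
                         gene_interval_to_genome(iv, gene_start[gname],
                                                 genes$length[gi],
                                                 genes$strand[gi]))
    }
  }

  # ---- phylogeny: root -> order -> family -> genus -> species ----
  edges <- list()
  for (o in unique(sp$order)) {
    edges[[length(edges) + 1L]] <- list(level = "order", value = o)
    fams <- unique(sp$family[sp$order == o])
    for (f in fams) {
      edges[[length(edges) + 1L]] <- list(level = "family", value = f)
      gens <- unique(sp$genus[sp$family == f])
      for (g in gens) {
        edges[[length(edges) + 1L]] <- list(level = "genus", value = g)
        ids <- sp$id[sp$genus == g]
        for (id in ids)
          edges[[length(edges) + 1L]] <- list(level = "species", value = id)
      }
    }
  }
  is_protected <- function(p) any(protected[, 1] <= p & p < protected[, 2])
  edge_subs <- lapply(edges, function(e) {
    out <- matrix(integer(0), ncol = 0)
    picked <- list()
    n_try <- 0L
    while (length(picked) < model$subs_per_branch && n_try < 50L * model$subs_per_branch) {
      n_try <- n_try + 1L
      p <- sample.int(G, 1L) - 1L          # 0-based
      if (is_protected(p)) next
      old <- ancestor[p + 1L]
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      if (!caps_neutral(ancestor, p + 1L, new, enzymes)) next
      picked[[length(picked) + 1L]] <- c(p, match(new, c("A", "C", "G", "T")))
    }
    do.call(rbind, picked)
  })

  base_letters <- c("A", "C", "G", "T")
  member_of <- function(i, level, value) sp[[level]][i] == value ||
    (level == "species" && sp$id[i] == value)

  # per-species sequences
  seqs <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    s <- ancestor
    for (k in seq_along(edges)) {
      e <- edges[[k]]
      on_path <- switch(e$level,
                        order = sp$order[i] == e$value,
                        family = sp$family[i] == e$value,
                        genus = sp$genus[i] == e$value,
                        species = sp$id[i] == e$value)
      if (!on_path || is.null(edge_subs[[k]])) next
      m <- edge_subs[[k]]
      s[m[, 1] + 1L] <- base_letters[m[, 2]]
    }
    seqs[[i]] <- s
  }

  # ---- apply planted SNP alleles per clade ----
  snp_rows <- list()
  for (r in seq_len(nrow(caps))) {
    s <- caps[r, ]
    gi <- which(genes$name == s$gene)
    alts <- strsplit(s$alt_alleles, ",", fixed = TRUE)[[1L]]
    gpos <- gene_pos_to_genome(s$gene_offset, gene_start[s$gene],
                               genes$length[gi], genes$strand[gi])
    level <- c(Fagales = "order", Fagaceae = "family", Fagus = "genus",
               Quercus = "genus", Betula = "genus")[s$target_taxon]
    if (is.na(level))
      level <- if (s$target_taxon %in% sp$order) "order"
               else if (s$target_taxon %in% sp$family) "family"
               else "genus"
    members <- sp$id[sp[[level]] == s$target_taxon]
    non_members <- setdiff(sp$id, members)
    allele_by_species <- stats::setNames(character(nrow(sp)), sp$id)
    allele_by_species[members] <- s$target_allele
    allele_by_species[non_members] <-
      rep(alts, length.out = length(non_members))
    for (i in seq_len(nrow(sp))) {
      a <- allele_by_species[sp$id[i]]
      base <- if (genes$strand[gi] == "-") revcomp(a) else a
      seqs[[i]][gpos + 1L] <- base
    }
    snp_rows[[r]] <- data.frame(
      gene = s$gene, gene_offset = s$gene_offset,
      gene_pos = s$gene_offset + 1L, column = s$gene_offset,
      target_taxon = s$target_taxon, target_allele = s$target_allele,
      alt_alleles = paste(sort(unique(alts)), collapse = ","),
      enzyme = s$enzyme, site_gene_offset = s$site_gene_offset,
      snp_in_site = s$snp_in_site, stringsAsFactors = FALSE)
  }

  # ---- planted repeats and plastid-like insertion in species 1 ----
  s1 <- seqs[[1L]]
  cursor <- filler_start + 50L
  rep_rows <- list()
  if (nrow(model$repeats)) {
    for (r in seq_len(nrow(model$repeats))) {
      len <- model$repeats$length[r]
      orient <- model$repeats$orientation[r]
      src <- cursor
      dst <- cursor + len + 200L
      if (dst + len > filler_start + model$filler_len)
        stop("filler too short for the planted repeats")
      block <- s1[(src + 1L):(src + len)]
      copy <- if (orient == "inverted")
        chars(revcomp(paste(block, collapse = ""))) else block
      s1[(dst + 1L):(dst + len)] <- copy
      # pin the copy's boundaries: the bases flanking the destination must
      # not extend the match, or the recovered repeat would exceed `len`
      other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
      if (orient == "direct") {
        s1[dst] <- other(c(s1[src], s1[dst]))
        s1[dst + len + 1L] <- other(c(s1[src + len + 1L], s1[dst + len + 1L]))
      } else {
        comp <- function(b) chartr("ACGT", "TGCA", b)
        s1[dst] <- other(c(comp(s1[src + len + 1L]), s1[dst]))
        s1[dst + len + 1L] <- other(c(comp(s1[src]), s1[dst + len + 1L]))
      }
      rep_rows[[r]] <- data.frame(a_start = src, a_end = src + len,
                                  b_start = dst, b_end = dst + len,
                                  orientation = orient, length = len,
                                  identity = 100)
      cursor <- dst + len + 100L
    }
  }
  plastid <- random_dna(model$plastid_len)
  ins <- NULL
  if (model$insertion_len > 0L) {
    frag_start <- 1000L
    frag <- chars(substr0(plastid, frag_start,
                          frag_start + model$insertion_len))
    # keep substitutions away from the fragment ends so the recovered hit
    # spans the full planted interval
    sub_at <- sort(sample(seq(21L, model$insertion_len - 20L),
                          model$insertion_subs))
    for (p in sub_at)
      frag[p] <- sample(setdiff(c("A", "C", "G", "T"), frag[p]), 1L)
    dst <- cursor + 100L
    if (dst + model$insertion_len > filler_start + model$filler_len)
      stop("filler too short for the planted insertion")
    s1[(dst + 1L):(dst + model$insertion_len)] <- frag
    # pin insertion boundaries against chance extension into the plastid
    pl <- chars(plastid)
    other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
    s1[dst] <- other(c(pl[frag_start], s1[dst]))
    s1[dst + model$insertion_len + 1L] <-
      other(c(pl[frag_start + model$insertion_len + 1L],
              s1[dst + model$insertion_len + 1L]))
    ins <- list(mito_start = dst, mito_end = dst + model$insertion_len,
                plastid_start = frag_start,
                plastid_end = frag_start + model$insertion_len,
                identity = round(100 * (model$insertion_len -
                                          model$insertion_subs) /
                                   model$insertion_len, 1))
  }
  seqs[[1L]] <- s1

  # ---- package genomes ----
  genomes <- lapply(seq_len(nrow(sp)), function(i) {
    feats <- lapply(feats_proto, function(f)
      gene_feature(f$name, f$kind, f$segments, f$strand))
    flag_trans_spliced(annotated_genome(sp$id[i], sp$organism[i],
                     lineage = c("Eukaryota", "Viridiplantae", "Streptophyta",
                                 sp$order[i], sp$family[i], sp$genus[i]),
                     sequence = paste(seqs[[i]], collapse = ""),
                     features = feats))
  })
  list(genomes = genomes, plastid = plastid,
       manifest = list(
         snps = do.call(rbind, snp_rows),
         repeats = if (length(rep_rows)) do.call(rbind, rep_rows) else NULL,
         insertion = ins,
         species = sp))
}

exon_segments <- function(L, n_exons) {
  if (n_exons == 1L) return(matrix(c(0L, L), ncol = 2))
  # equal exons separated by short introns inside the span
  intron <- max(20L, L %/% (6L * n_exons))
  exon <- (L - intron * (n_exons - 1L)) %/% n_exons
  starts <- cumsum(c(0L, rep(exon + intron, n_exons - 1L)))
  ends <- starts + exon
  ends[n_exons] <- L
  matrix(c(starts, ends), ncol = 2)
}

gene_pos_to_genome <- function(offset, gstart, glen, strand) {
  if (strand == "+") gstart + offset else gstart + glen - 1L - offset
}

gene_interval_to_genome <- function(iv, gstart, glen, strand) {
  if (strand == "+") matrix(gstart + iv, ncol = 2)
  else matrix(c(gstart + glen - iv[2], gstart + glen - iv[1]), ncol = 2)
}
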