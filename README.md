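# capstax

Taxon-diagnostic SNP discovery and CAPS marker design from annotated
organelle genomes.

## The problem

Wood and wood composite products often cannot be assigned to a tree genus by
morphology, and the DNA they yield is highly degraded.  Mitochondrial genomes
evolve slowly in plants, so genic SNPs that are fixed within a genus, family
or order — and absent outside it — make robust "golden" markers for taxon
assignment.  A practical assay is the CAPS (cleaved amplified polymorphic
site) marker: a short PCR amplicon whose restriction digestion pattern
differs between the target-taxon allele and every alternative allele, read
out as band sizes on an agarose gel.

`capstax` implements the full marker-development stack for researchers in
forest genetics and molecular taxonomy:

* **GenBank I/O** — read/write annotated organelle genomes, extract gene
  sequences with multi-exon and strand semantics (trans-spliced genes such
  as *nad1*/*nad2*/*nad5* are flagged and excluded), compute shared gene
  sets, scan ORFs.
* **Alignment** — a deterministic built-in progressive aligner (k-mer
  distances, UPGMA guide tree, affine-gap profile–profile alignment), an
  adapter for external aligned FASTA, and column↔position maps.
* **SNP calling** (`find_taxon_specific_snps`) — at every alignment column,
  the taxon is determined for which a base is characteristic: all members of
  the queried taxon share one base `X` and no non-member carries `X`.
  Columns with gaps or ambiguity codes in any row are ineligible, and a
  conserved-flank filter keeps only SNPs whose neighbourhoods are gap-free
  and near-monomorphic — the precondition for primers that amplify across a
  broad taxonomic range.
* **CAPS design** (`design_caps_markers`) — screens restriction enzymes
  (IUPAC-ambiguous recognition sites, Type IIS cut offsets in REBASE
  notation) for a site that the target allele completes and every
  alternative allele breaks, then selects an amplicon of at most 200 bp with
  conserved primer windows (0 mismatches inside the target clade, at most 2
  elsewhere) and predicts digestion fragments for every allele.
* **Genome characterization** — interspersed direct/inverted repeat
  detection by seeded self-comparison, chloroplast-like insertion (MTPT)
  detection, shared gene-order (synteny) clusters, in-silico PCR and linear
  digestion.
* **Simulation** (`simulate_clade_dataset`) — a seeded generator of
  annotated GenBank files for a toy order→family→genus→species taxonomy
  with planted diagnostic SNPs, discriminative enzyme sites, repeats and a
  plastid-like insertion, plus a truth manifest, so the entire pipeline is
  testable offline.

## Worked example

Simulate the default eight-species clade (three Fagales, five outgroup
species), align the shared genes, call SNPs diagnostic for the genus
*Fagus*, and design CAPS markers:

```r
library(capstax)

sim     <- simulate_clade_dataset(clade_model())     # seeded, default 42
genomes <- sim$genomes
lineages <- setNames(lapply(genomes, function(g) c(g$lineage, g$organism)),
                     vapply(genomes, `[[`, "", "id"))
gene_seqs <- lapply(genomes, function(g) {
  x <- extract_gene_sequences(g)
  names(x) <- capstax:::normalize_gene_name(names(x)); x })
names(gene_seqs) <- names(lineages)

alns <- lapply(setdiff(shared_genes(genomes), "nad1"), function(g)
  build_msa(vapply(gene_seqs, `[[`, "", g), lineages = lineages, gene_name = g))

q    <- taxon_query("Fagus", lineages)
snps <- find_taxon_specific_snps(alns, q)
summary(snps)
markers <- design_caps_markers(snps[snps$conserved, ], alns, default_enzymes())
```

This prints (a warning notes that *Fagus* has a single sequenced member, so
genus-level specificity is extrapolated from one genome):

```
  target_taxon n_snps n_genes
1        Fagus     21       8
<caps_marker> Fagus_ccmfc: T vs C at column 700, BsmBI, 80 bp amplicon
  fragments 40+40 (target) / 80 (others)
<caps_marker> Fagus_matr: G vs A,C,T at column 900, BstXI, 80 bp amplicon
  fragments 40+40 (target) / 80 (others)
```

21 columns across 8 genes are diagnostic for *Fagus* and pass the
conserved-flank filter; two of them sit in a restriction site that the
*Fagus* allele completes and every alternative allele breaks.  For the
`ccmFc` marker, a BsmBI digest of the 80 bp amplicon gives two 40 bp
fragments in *Fagus* and leaves the 80 bp amplicon uncut in all other
genera — the gel pattern that assigns a sample to the genus.  The designed
primers (`markers[[1]]$fwd_primer` etc.) amplify a single product from the
full genome in `insilico_pcr`.

A command-line surface wraps the same operations (`snptax`, `caps`,
`digest`, `pcr`, `repeats`, `cpregions`, `synteny`, `orfscan`, `simulate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "capstax.R", package = "capstax"))')" \
    simulate --seed=42 --out=sim
```

## Documentation

The methods vignette (`vignettes/capstax-methods.Rmd`) describes the model
and its assumptions, all tunable parameters with defaults and units, what
the simulator does and does not emulate, and the package's numerical
choices and limitations.
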