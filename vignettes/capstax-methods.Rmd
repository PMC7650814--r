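---
title: "Methods: taxon-diagnostic SNPs and CAPS markers from organelle genomes"
author: "capstax authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxon-diagnostic SNPs and CAPS markers from organelle genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model behind
each step, the tunable parameters with their defaults and why, what the
synthetic-data generator emulates (and does not), and the numerical and
design choices made where the problem left them open.

# The marker model

Plant mitochondrial genomes evolve slowly in sequence but rapidly in
structure.  Whole-genome alignment across genera is therefore meaningless,
but the *genic* fraction is alignable across families and orders.  The
package's premise is:

1. extract the genes annotated in *all* input genomes (the shared gene set),
2. align each gene across genomes,
3. find columns where every member of a queried taxon carries one base `X`
   and no non-member carries `X` (a *taxon-diagnostic SNP*),
4. keep SNPs in conserved neighbourhoods (so one primer pair works in every
   taxon), and
5. turn SNPs into CAPS markers: a restriction enzyme whose recognition site
   is completed by the target allele and broken by every alternative allele,
   inside an amplicon short enough to survive degraded template DNA.

A marker is read out as band sizes on a gel: the target taxon shows the
digestion fragments, every other taxon the uncut amplicon.

# Gene extraction (`genbank_io`)

Internal coordinates are 0-based half-open; the GenBank boundary converts
to/from the format's 1-based inclusive convention.  This keeps all interval
arithmetic closed under concatenation and mirroring, and confines the
off-by-one surface to the parser/writer pair (checked by round-trip tests).

Decisions taken where annotation practice is ambiguous:

* **Trans-splicing detection.**  A feature is trans-spliced if it carries a
  `/trans_splicing` qualifier *or* its gene name occurs in more than one
  disjoint feature of the same kind.  Such genes (typically *nad1*, *nad2*,
  *nad5*) have no contiguous genomic sequence and are excluded from
  alignment input by default.
* **Cis-spliced genes.**  `extract_gene_sequences()` defaults to the genomic
  span *including introns* (`mode = "span"`).  Introns of slowly evolving
  mitochondrial genes are themselves informative — one of the classical
  validated markers of this assay family sits in intron 2 of *nad7* — and a
  span extraction keeps such sites reachable.  `mode = "exons"` provides the
  exon-joined alternative.
* **Name normalization.**  Shared-gene computation is case-insensitive and
  alias-driven (`default_gene_aliases()`, user-extensible).  Without it,
  spelling variants (`ccmFc`/`ccmFC`) silently shrink the shared set.
* **N handling.**  Genomes may contain N, but any extracted gene containing
  N is flagged (`has_n` attribute) and skipped by the pipeline: a diagnostic
  allele must be unambiguous in every genome.

The ORF scanner reports every ATG-initiated frame of at least `min_codons`
codons (default 100, the conventional annotation threshold), stop codon
included in both the interval and the codon count, on both strands, with
fully nested calls removed — matching how organelle ORF annotation is
usually run.

# Alignment (`alignment`)

The built-in aligner is a classical progressive MSA: pairwise k-mer
distances (k = 6), a UPGMA guide tree (`hclust`, average linkage; ties
broken by lexicographic id, making the output deterministic), and
affine-gap profile–profile alignment with match +2, mismatch −3, gap open
−6, gap extension −1.  The DP kernel is compiled (Rcpp) — the one inner
loop in the package where R would be too slow.  These scores are ordinary
DNA-alignment defaults; for the near-identical genic sequences this package
targets, gap-free alignments are optimal and the guide tree is almost
irrelevant.  Externally computed alignments (PRANK, MAFFT, ...) enter
through `import_alignment()`, which enforces equal record lengths and
checks that ungapping reproduces the extracted gene sequences.

Conventions worth stating because nothing downstream works without them:

* alignment **columns are 0-based**, ungapped **gene positions 1-based**;
  `map_position()` converts between them and is inverse off gaps;
* **identity** = matches / alignment columns × 100, reported to 0.1%.

`local_align()` is the shared engine for repeat comparison and
plastid-insertion detection: exact shared words (default 12) seed ungapped
extension, scored +1/−2 with an X-drop of 20, ending each hit at its score
maximum.  If an extension drags identity below the threshold the hit falls
back to the pure exact run, so 100%-identity repeats are never lost to
greedy extension.  Alignments are ungapped by construction; an insertion
splits a hit in two, which is the desired behaviour for both repeat and
MTPT reporting.

# SNP calling (`snptax`)

Eligibility is strict: a column with a gap or ambiguity code in *any* row is
ineligible, rather than down-weighted.  The assay requires the diagnostic
base to be present and unambiguous in every genome, and degraded input DNA
leaves no room for soft calls.

The conserved-region filter is quantified as: both flanks of `flank_width`
columns (default 20) must lie fully inside the alignment, be gap-free in
every row, and be at least `min_monomorphic`% monomorphic (default 90%),
assessed per flank.  A flank truncated by the alignment end *fails* — a SNP
that close to a gene end cannot carry primers anyway.  The defaults are a
judgment call (the underlying notion of "conserved region" has no standard
quantification); both knobs are exposed, and the test suite checks
monotonicity: tightening either never increases the conserved SNP count.

A taxon with a single sequenced member is allowed — genus-level queries
routinely have exactly one genome — but triggers a warning that specificity
is extrapolated from one sequence.  That caveat is real: markers selected
this way must be validated on more members of the taxon before use.

# CAPS design (`caps`)

Enzymes are modeled as an IUPAC recognition string plus top/bottom-strand
cut offsets, parsed from REBASE-style notation (`G^AATTC`, or
`CGTCTC(1/5)` for Type IIS enzymes cutting past an asymmetric site).
Digestion is modeled by **top-strand cut coordinates only**: sticky-end
overhangs are a few bases and invisible on an agarose gel, which is the
assay's readout.  A cut coordinate outside `[1, L−1]` does not cut — the
physically correct treatment of a Type IIS site near an amplicon end.

The design search, per SNP × enzyme:

1. every placement of the recognition window over the SNP is tested on the
   member consensus: accepted only if the site matches with the target
   allele (either strand) and fails, on both strands, for every alternative
   allele;
2. primer windows (18–25 bp) must be gap-free alignment blocks whose
   consensus matches target-clade rows exactly and all other rows with at
   most 2 mismatches — the "not close to a gene end" criterion falls out of
   this, since both windows must fit inside the gene;
3. the amplicon (≤ 200 bp, the degraded-DNA budget) is grown outward from
   the site until the target-allele digest yields fragments of at least 40
   bp (smaller bands are unreliable on gel) while every alternative-allele
   amplicon stays *uncut*.  The uncut requirement doubles as the guard
   against constitutive second sites of the same enzyme inside the
   amplicon, which would cut all taxa and blur the diagnostic pattern.

The search is deterministic (nearest-to-site amplicons first) and returns
one marker per SNP × enzyme that survives all three stages.  `insilico_pcr`
models amplification with exact 3′-terminal bases and a per-primer mismatch
budget, and signals distinct conditions for zero and for multiple products.

# Repeats and genome comparison (`repeats`, `organelle_compare`)

Interspersed repeats are found by comparing the genome against itself and
its reverse complement: exact seeds of length `min_len` (default 50 bp, the
conventional lower bound for recombinogenic organelle repeats; also the
reason `min_len < 20` is rejected — shorter seeds stop being reliable
anchors), X-drop extension, trivial self-diagonal discarded, mirrored pairs
reported once with copy A left of copy B, contained pairs collapsed into
their maximal extension, and a repeat occurring more than twice yielding
one entry per unordered copy pair.  This counting rule is the package's
own, stated here because published repeat counts from other tools depend on
their (undocumented) merging rules; equivalence is instead guaranteed
against a quadratic longest-common-substring oracle in the test suite.

Chloroplast-like regions are `local_align` hits (≥ 90% identity, ≥ 100 bp,
both plastid strands) with overlapping mitochondrial intervals merged
before the genome fraction is computed — merging is assumed, and stated,
because a raw-hit fraction would double-count overlaps.

Gene-order clusters are maximal runs of shared genes adjacent in both
genomes in a consistent relative order/orientation.  Adjacency is judged on
the full gene orders, so an unshared gene sitting between two shared genes
breaks the run in that genome — this makes "physical separation" of a
cluster in one species visible.  tRNAs are excluded by default (the
protein-coding convention for organelle synteny) but can be switched in.
Genomes are treated as linear; a cluster spanning the origin of a circular
map is reported as two runs.

# The synthetic clade (`fixtures`)

`clade_model()` defines the study conditions for all offline testing: eight
species in five orders — the target order represented by two family-mates
and one member of a second family, the target genus by a *single* species,
mirroring the situation where a genus has exactly one sequenced
mitochondrial genome — over a 12-gene roster (~27 kb genomes) with
multi-exon genes, a trans-spliced gene split across two loci, and tRNAs.
Four CAPS-compatible SNPs are planted at genus, family and order level
using the BstXI/BsmBI/SfcI/NciI chemistry of the classical validated marker
set, plus two interspersed repeats (316 bp direct — the size of a
well-known mitochondrial direct repeat — and 120 bp inverted) and one
668 bp plastid-like insertion carrying 8 substitutions (identity
660/668 = 98.8%).

Choices that make planted truth *exact* rather than approximate:

* **Discriminative-by-construction contexts.**  Each planted site sits in a
  120 bp protected flank on either side; the context is redrawn until
  exactly the intended enzyme discriminates target from alternatives and no
  stray site of that enzyme remains in the context.  A collision between
  planted features is a construction error, not a silent overwrite.
* **CAPS-neutral branch substitutions.**  Per-branch substitutions (default
  25, giving up to ~0.8% pairwise divergence — modest, as expected for
  plant mitochondrial genes) are drawn uniformly over unprotected positions
  with an equal-rate base choice, and rejected if they would create or
  destroy a recognition site of any cataloged enzyme.  Background
  divergence therefore produces genuine diagnostic SNPs (exercising the
  scanner) but can never produce an accidental CAPS marker, so
  planted-truth recovery is exact under any seed.
* **Pinned boundaries.**  The bases flanking planted repeat copies and the
  plastid insertion are set to break match extension, so recovered lengths
  equal planted lengths instead of occasionally gaining a chance-matching
  boundary base.
* **No indels** by default, so per-gene alignments are gap-free and
  alignment columns equal gene offsets — isolating SNP-calling correctness
  from aligner behaviour.

What the generator does **not** emulate: structural rearrangement,
repeat-mediated isomerization, indel variation, rate heterogeneity among
sites and lineages, RNA editing, and annotation error.  Passing tests
therefore demonstrate correctness of the algorithms under clean conditions,
not robustness of marker discovery on real, messy annotations.

# Verification

Every algorithmic core is checked against an independent oracle rather than
frozen outputs: the ORF scanner against a six-frame brute-force enumeration,
the SNP scanner against a per-column brute-force scan (100 random fixtures),
the repeat finder against a quadratic longest-common-substring DP (sequences
up to 3 kb), pairwise alignment against exhaustive alignment enumeration on
short strings, site finding against sliding-window IUPAC matching, and
digestion against the fragment-length conservation invariant (1000 random
cases).  The end-to-end check is planted-truth recovery: the default clade
must yield exactly the four planted markers with manifest-exact enzymes,
alleles and fragment arithmetic.  These problem sizes keep the default
suite at roughly two minutes on one core while still covering every
code path; `scripts/acceptance.R` re-runs the stack from scratch for an
arbitrary seed.

# Known limitations

* Identity is computed over ungapped hits; a single indel splits a repeat
  or MTPT region in two where gapped aligners may report one longer, lower
  identity hit.  Counts are exact under the package's stated rule but not
  numerically comparable to other tools without matching their merging
  behaviour.
* The built-in MSA is not a substitute for a phylogeny-aware aligner on
  divergent or indel-rich genes; import externally computed alignments for
  those.
* Primer design is purely alignment-combinatorial: no melting temperature,
  secondary structure, or dimer checks.  Designed primers are candidates
  for, not replacements of, thermodynamic screening.
* Fragment predictions for alternative alleles are computed on the target
  consensus background; length variation elsewhere in a non-target amplicon
  (e.g. an indel between the primers in some outgroup) will shift its uncut
  band size.
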