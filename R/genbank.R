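# GenBank flat-file I/O and gene extraction for annotated organelle genomes.
#
# Internal coordinates are 0-based half-open; the GenBank boundary converts
# to/from the format's 1-based inclusive convention.

#' Gene feature of an annotated genome
#'
#' @param gene_name gene symbol (e.g. `"nad7"`)
#' @param kind one of `"protein_coding"`, `"tRNA"`, `"rRNA"`, `"ORF"`,
#'   `"pseudogene"`
#' @param segments integer matrix with columns `start`, `end`: 0-based
#'   half-open exon intervals in annotation order
#' @param strand `"+"` or `"-"`
#' @param trans_spliced logical; trans-spliced genes are never concatenated
#'   into a single extracted sequence
#' @return an object of class `gene_feature`
#' @export
gene_feature <- function(gene_name, kind, segments, strand = "+",
                         trans_spliced = FALSE) {
  kinds <- c("protein_coding", "tRNA", "rRNA", "ORF", "pseudogene")
  kind <- match.arg(kind, kinds)
  if (is.vector(segments)) segments <- matrix(segments, ncol = 2, byrow = TRUE)
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) == 0L) stop("feature '", gene_name, "': no segments")
  if (any(segments[, 2] <= segments[, 1]))
    stop("feature '", gene_name, "': empty or reversed segment")
  o <- order(segments[, 1])
  if (any(segments[o, 2][-nrow(segments)] > segments[o, 1][-1L]))
    stop("feature '", gene_name, "': overlapping segments")
  stopifnot(strand %in% c("+", "-"))
  structure(list(gene_name = gene_name, kind = kind, segments = segments,
                 strand = strand, trans_spliced = isTRUE(trans_spliced)),
            class = "gene_feature")
}

#' Annotated organelle genome
#'
#' One GenBank record: sequence, gene features, organism and its taxonomic
#' lineage (the ordered taxon path of the ORGANISM block, kingdom to genus).
#'
#' @param id accession string, unique within a dataset
#' @param organism species name
#' @param lineage character vector of taxon names, outermost first
#' @param sequence DNA character scalar over A/C/G/T/N (uppercased)
#' @param features list of [gene_feature()] objects
#' @return an object of class `annotated_genome`
#' @export
annotated_genome <- function(id, organism, lineage, sequence, features = list()) {
  sequence <- toupper(sequence)
  if (!is_dna(sequence)) stop("sequence contains non-A/C/G/T/N characters")
  len <- nchar(sequence)
  for (f in features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature objects")
    if (any(f$segments[, 1] < 0L) || any(f$segments[, 2] > len))
      stop("feature '", f$gene_name, "' outside sequence [0, ", len, ")")
  }
  structure(list(id = id, organism = organism,
                 lineage = as.character(lineage),
                 sequence = sequence, features = features, length = len),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s (%s)\n  %s bp, %d features\n  lineage: %s\n",
              x$id, x$organism, format(x$length, big.mark = ","),
              length(x$features), paste(x$lineage, collapse = "; ")))
  invisible(x)
}

#' @export
print.gene_feature <- function(x, ...) {
  loc <- paste(sprintf("%d..%d", x$segments[, 1] + 1L, x$segments[, 2]),
               collapse = ",")
  cat(sprintf("<gene_feature> %s [%s] %s%s%s\n", x$gene_name, x$kind, x$strand,
              loc, if (x$trans_spliced) " (trans-spliced)" else ""))
  invisible(x)
}

# ---- location text <-> segments/strand ------------------------------------

# Parse a GenBank location string into list(segments, strand).  Handles
# `123..456`, `123`, `join(...)`, `complement(...)` and their nesting; the
# overall strand is "-" iff wrapped in an odd number of complement()s.
parse_location <- function(text) {
  text <- gsub("[<>[:space:]]", "", text)
  parse_node <- function(s, comp) {
    if (grepl("^complement\\(", s)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      return(parse_node(inner, !comp))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      parts <- split_toplevel(inner)
      res <- lapply(parts, parse_node, comp = comp)
      segs <- do.call(rbind, lapply(res, `[[`, "segments"))
      strands <- unique(vapply(res, `[[`, "", "strand"))
      if (length(strands) > 1L)
        stop("mixed-strand join() locations are not supported: ", text)
      return(list(segments = segs, strand = strands))
    }
    if (grepl("^\\d+\\.\\.\\d+$", s)) {
      ab <- as.integer(strsplit(s, "..", fixed = TRUE)[[1L]])
    } else if (grepl("^\\d+$", s)) {
      ab <- c(as.integer(s), as.integer(s))
    } else {
      stop("cannot parse location element: '", s, "'")
    }
    list(segments = matrix(c(ab[1] - 1L, ab[2]), ncol = 2),
         strand = if (comp) "-" else "+")
  }
  parse_node(text, FALSE)
}

# split "a,b(c,d),e" on top-level commas only
split_toplevel <- function(s) {
  depth <- 0L; cuts <- integer(0)
  cs <- chars(s)
  for (i in seq_along(cs)) {
    if (cs[i] == "(") depth <- depth + 1L
    else if (cs[i] == ")") depth <- depth - 1L
    else if (cs[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, nchar(s))
  vapply(seq_along(starts), function(j) substr(s, starts[j], ends[j]), "")
}

format_location <- function(segments, strand) {
  parts <- sprintf("%d..%d", segments[, 1] + 1L, segments[, 2])
  body <- if (length(parts) > 1L)
    sprintf("join(%s)", paste(parts, collapse = ",")) else parts
  if (strand == "-") sprintf("complement(%s)", body) else body
}

# ---- reader ----------------------------------------------------------------

#' Read a GenBank flat file
#'
#' Parses one or more records into [annotated_genome()] objects.  Feature keys
#' `CDS`, `tRNA` and `rRNA` with a `/gene` (or `/locus_tag`) qualifier become
#' gene features; `CDS` features named `ORF*` are classed `ORF` and features
#' with a `/pseudo` qualifier `pseudogene`.  Features carrying a
#' `/trans_splicing` qualifier, or whose gene name occurs in more than one
#' disjoint feature of the same kind, are flagged trans-spliced.
#'
#' @param path file path
#' @return list of `annotated_genome`
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  # split into records at '//'
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0L) stop("not a GenBank flat file (no '//' terminator): ", path)
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1L)], starts, ends)
  recs <- Filter(function(r) any(nzchar(r)), recs)
  lapply(recs, parse_genbank_record)
}

parse_genbank_record <- function(lines) {
  lines <- lines[cumsum(nzchar(lines)) > 0L]  # drop leading blank lines
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L)
    stop("malformed record: expected exactly one LOCUS line, line 1 is '",
         lines[1L], "'")
  locus <- strsplit(trimws(sub("^LOCUS\\s+", "", lines[locus_i])), "\\s+")[[1L]]
  if (length(locus) < 1L) stop("malformed LOCUS line: '", lines[locus_i], "'")
  id <- locus[1L]
  declared_len <- if (length(locus) >= 2L && grepl("^\\d+$", locus[2L]))
    as.integer(locus[2L]) else NA_integer_

  acc_i <- grep("^ACCESSION\\s+\\S", lines)
  if (length(acc_i)) id <- strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1L]])),
                                    "\\s+")[[1L]][1L]

  organism <- ""
  lineage <- character(0)
  org_i <- grep("^\\s{1,5}ORGANISM", lines)
  if (length(org_i)) {
    organism <- trimws(sub("^\\s+ORGANISM\\s*", "", lines[org_i[1L]]))
    j <- org_i[1L] + 1L
    lin_text <- character(0)
    while (j <= length(lines) && grepl("^\\s{6,}", lines[j]) &&
           !grepl("^FEATURES", lines[j])) {
      lin_text <- c(lin_text, trimws(lines[j])); j <- j + 1L
    }
    lin_text <- paste(lin_text, collapse = " ")
    lin_text <- sub("\\.\\s*$", "", lin_text)
    if (nzchar(lin_text))
      lineage <- trimws(strsplit(lin_text, ";", fixed = TRUE)[[1L]])
  }

  # FEATURES table
  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  features <- list()
  if (length(feat_i) && length(origin_i)) {
    ft <- lines[(feat_i[1L] + 1L):(origin_i[1L] - 1L)]
    features <- parse_feature_table(ft)
  }

  # ORIGIN sequence
  sequence <- ""
  if (length(origin_i)) {
    seq_lines <- lines[(origin_i[1L] + 1L):length(lines)]
    sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  }
  if (!is_dna(sequence))
    stop("record ", id, ": sequence contains non-A/C/G/T/N characters")
  if (!is.na(declared_len) && nchar(sequence) != declared_len)
    stop("record ", id, ": LOCUS declares ", declared_len, " bp but ORIGIN has ",
         nchar(sequence))
  for (f in features) {
    if (any(f$segments[, 2] > nchar(sequence)))
      stop("record ", id, ": feature '", f$gene_name, "' beyond sequence end")
  }
  flag_trans_spliced(annotated_genome(id, organism, lineage, sequence, features))
}

parse_feature_table <- function(ft) {
  # feature starts: key at column 6 (5 spaces + key); qualifiers deeper
  key_i <- grep("^\\s{3,8}\\S", ft)
  key_i <- key_i[!grepl("^\\s{9,}", ft[key_i])]
  feats <- list()
  for (n in seq_along(key_i)) {
    i <- key_i[n]
    j_end <- if (n < length(key_i)) key_i[n + 1L] - 1L else length(ft)
    block <- ft[i:j_end]
    m <- regmatches(block[1L], regexec("^\\s+(\\S+)\\s+(\\S.*)$", block[1L]))[[1L]]
    if (length(m) < 3L) next
    key <- m[2L]; loc_text <- m[3L]
    k <- 2L
    while (k <= length(block) && !grepl("^\\s+/", block[k])) {
      loc_text <- paste0(loc_text, trimws(block[k])); k <- k + 1L
    }
    quals <- block[seq_len(length(block)) >= k]
    if (!key %in% c("CDS", "tRNA", "rRNA", "gene")) next
    if (key == "gene") next  # gene envelopes duplicate CDS/tRNA/rRNA entries
    gene <- qualifier_value(quals, "gene") %||%
            qualifier_value(quals, "locus_tag")
    if (is.null(gene)) next
    loc <- tryCatch(parse_location(loc_text),
                    error = function(e) stop("feature '", gene, "': ",
                                             conditionMessage(e)))
    kind <- if (key == "tRNA") "tRNA"
            else if (key == "rRNA") "rRNA"
            else if (any(grepl("^\\s*/pseudo\\s*$", quals))) "pseudogene"
            else if (grepl("^orf", gene, ignore.case = TRUE)) "ORF"
            else "protein_coding"
    ts <- any(grepl("/trans_splicing", quals))
    feats[[length(feats) + 1L]] <-
      gene_feature(gene, kind, loc$segments, loc$strand, trans_spliced = ts)
  }
  feats
}

qualifier_value <- function(quals, name) {
  pat <- sprintf("^\\s*/%s=\"?([^\"]*)\"?\\s*$", name)
  hit <- grep(pat, quals, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(pat, "\\1", hit[1L])
}

# a gene name in >1 disjoint feature of the same kind implies trans-splicing
flag_trans_spliced <- function(genome) {
  key <- vapply(genome$features,
                function(f) paste(tolower(f$gene_name), f$kind), "")
  dup <- names(which(table(key) > 1L))
  genome$features <- lapply(genome$features, function(f) {
    if (paste(tolower(f$gene_name), f$kind) %in% dup) f$trans_spliced <- TRUE
    f
  })
  genome
}

# ---- writer ----------------------------------------------------------------

#' Write an annotated genome as a GenBank flat file
#'
#' Multi-exon minus-strand genes are serialized as `complement(join(...))`
#' with 1-based inclusive coordinates.
#'
#' @param genome an [annotated_genome()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "annotated_genome"))
  for (f in genome$features)
    if (any(f$segments[, 1] < 0L) || any(f$segments[, 2] > genome$length))
      stop("refusing to write: feature '", f$gene_name, "' outside sequence")
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %s%17d bp    DNA     circular PLN 01-JAN-2026",
    genome$id, genome$length)
  w("DEFINITION  %s mitochondrion.", genome$organism)
  w("ACCESSION   %s", genome$id)
  w("SOURCE      %s", genome$organism)
  w("  ORGANISM  %s", genome$organism)
  lin <- paste0(paste(genome$lineage, collapse = "; "), ".")
  for (l in strwrap(lin, width = 68)) w("            %s", l)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", genome$length)
  w("                     /organism=\"%s\"", genome$organism)
  for (f in genome$features) {
    key <- switch(f$kind, tRNA = "tRNA", rRNA = "rRNA", "CDS")
    w("     %-16s%s", key, format_location(f$segments, f$strand))
    w("                     /gene=\"%s\"", f$gene_name)
    if (f$trans_spliced) w("                     /trans_splicing")
    if (f$kind == "pseudogene") w("                     /pseudo")
  }
  w("ORIGIN")
  seq <- tolower(genome$sequence)
  pos <- seq(1L, nchar(seq), by = 60L)
  for (p in pos) {
    blocks <- wrap_text(substr(seq, p, min(p + 59L, nchar(seq))), 10)
    w("%9d %s", p, paste(blocks, collapse = " "))
  }
  writeLines("//", con)
  invisible(path)
}

# ---- gene extraction -------------------------------------------------------

#' Extract gene sequences from an annotated genome
#'
#' For each gene, segments are taken in annotation order and the result
#' reverse-complemented for minus-strand features.  Cis-spliced
#' (intron-containing) genes are extracted by default as the genomic span
#' including introns (`mode = "span"`); `mode = "exons"` joins exons instead.
#' Trans-spliced genes have no single contiguous genomic sequence and are
#' omitted when `exclude_trans_spliced` is `TRUE` (the default); otherwise
#' each part is returned separately with a `.1`, `.2`, ... suffix.
#'
#' @param genome an [annotated_genome()]
#' @param exclude_trans_spliced drop trans-spliced genes entirely
#' @param mode `"span"` (genomic span, introns retained) or `"exons"`
#' @param kinds feature kinds to extract
#' @return named character vector, gene name -> DNA string; genes whose
#'   sequence contains N carry attribute `has_n`
#' @export
extract_gene_sequences <- function(genome, exclude_trans_spliced = TRUE,
                                   mode = c("span", "exons"),
                                   kinds = c("protein_coding", "tRNA", "rRNA",
                                             "ORF")) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "annotated_genome"))
  out <- character(0)
  has_n <- character(0)
  seen <- list()
  for (f in genome$features) {
    if (!f$kind %in% kinds) next
    if (f$trans_spliced) {
      if (exclude_trans_spliced) next
      n_prev <- seen[[f$gene_name]] %||% 0L
      seen[[f$gene_name]] <- n_prev + 1L
      nm <- sprintf("%s.%d", f$gene_name, n_prev + 1L)
    } else nm <- f$gene_name
    segs <- f$segments
    if (mode == "span" && nrow(segs) > 1L)
      segs <- matrix(c(min(segs[, 1]), max(segs[, 2])), ncol = 2)
    s <- paste(vapply(seq_len(nrow(segs)), function(i)
      substr0(genome$sequence, segs[i, 1], segs[i, 2]), ""), collapse = "")
    if (f$strand == "-") s <- revcomp(s)
    out[nm] <- s
    if (grepl("N", s, fixed = TRUE)) has_n <- c(has_n, nm)
  }
  attr(out, "has_n") <- has_n
  out
}

# ---- shared genes ----------------------------------------------------------

#' Default gene-name alias table
#'
#' Maps alternate spellings (case differences and common synonyms in organelle
#' annotations) onto a canonical lower-case symbol.  Extend by passing your
#' own named vector (`alias = canonical`) to [shared_genes()].
#' @return named character vector
#' @export
default_gene_aliases <- function() {
  c(ccmfc = "ccmfc", ccmfC = "ccmfc", "ccmf-c" = "ccmfc",
    ccmfn = "ccmfn", "ccmf-n" = "ccmfn",
    "coxi" = "cox1", "coxii" = "cox2", "coxiii" = "cox3",
    "atpa" = "atp1", "cob" = "cob", "mttb" = "mttb", "tatc" = "mttb")
}

#' Genes annotated in every genome of a set
#'
#' Intersection of per-genome gene-name sets of one feature kind, after
#' case-insensitive normalization through an alias table.
#'
#' @param genomes list of [annotated_genome()]
#' @param kind feature kind (default protein-coding)
#' @param aliases named character vector mapping lower-cased alternate names
#'   to canonical names
#' @return sorted character vector of canonical gene names
#' @export
shared_genes <- function(genomes, kind = "protein_coding",
                         aliases = default_gene_aliases()) {
  if (length(genomes) == 0L) stop("need at least one genome")
  sets <- lapply(genomes, function(g) {
    nm <- vapply(Filter(function(f) f$kind == kind, g$features),
                 `[[`, "", "gene_name")
    unique(normalize_gene_name(nm, aliases))
  })
  sort(Reduce(intersect, sets))
}

normalize_gene_name <- function(x, aliases = default_gene_aliases()) {
  lx <- tolower(x)
  hit <- match(lx, tolower(names(aliases)))
  ifelse(is.na(hit), lx, unname(aliases[hit]))
}

# ---- ORF scan --------------------------------------------------------------

.stop_codons <- c("TAA", "TAG", "TGA")

#' Scan a sequence for open reading frames
#'
#' Reports every ATG-initiated reading frame of at least `min_codons` codons
#' ending at a stop codon (stop included in the interval and the codon count),
#' standard genetic code, on both strands when requested.  With
#' `exclude_nested`, calls fully contained inside another reported ORF on the
#' same strand are dropped (so of several ATGs sharing one stop only the
#' longest is kept).
#'
#' @param sequence DNA character scalar over A/C/G/T/N
#' @param min_codons minimum ORF length in codons, stop included (default 100)
#' @param both_strands scan the reverse complement too (default TRUE)
#' @param exclude_nested drop fully nested calls (default TRUE)
#' @return data frame with columns `start`, `end` (0-based half-open, on the
#'   forward sequence), `strand`, `length_codons`, sorted by `start`
#' @export
orf_scan <- function(sequence, min_codons = 100L, both_strands = TRUE,
                     exclude_nested = TRUE) {
  if (min_codons < 1L) stop("min_codons must be >= 1")
  sequence <- toupper(sequence)
  stopifnot(is_dna(sequence))
  L <- nchar(sequence)
  scan1 <- function(s) {
    # per strand: data.frame(start, end) 0-based half-open on strand s
    res <- list()
    cs <- chars(s)
    n <- length(cs)
    for (frame in 0:2) {
      starts_pending <- integer(0)
      i <- frame
      while (i + 3L <= n) {
        codon <- paste(cs[(i + 1L):(i + 3L)], collapse = "")
        if (codon == "ATG") starts_pending <- c(starts_pending, i)
        if (codon %in% .stop_codons && length(starts_pending)) {
          for (st in starts_pending) {
            ncod <- (i + 3L - st) / 3L
            if (ncod >= min_codons)
              res[[length(res) + 1L]] <- c(st, i + 3L, ncod)
          }
          starts_pending <- integer(0)
        }
        i <- i + 3L
      }
    }
    if (!length(res)) return(NULL)
    m <- do.call(rbind, res)
    data.frame(start = m[, 1], end = m[, 2], length_codons = m[, 3])
  }
  fwd <- scan1(sequence)
  if (!is.null(fwd)) fwd$strand <- "+"
  out <- fwd
  if (both_strands) {
    rc <- scan1(revcomp(sequence))
    if (!is.null(rc)) {
      rc2 <- data.frame(start = L - rc$end, end = L - rc$start,
                        length_codons = rc$length_codons, strand = "-")
      out <- rbind(out, rc2)
    }
  }
  if (is.null(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length_codons = integer(0)))
  out <- out[, c("start", "end", "strand", "length_codons")]
  if (exclude_nested && nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      nested <- out$strand == out$strand[i] &
        out$start <= out$start[i] & out$end >= out$end[i] &
        (out$start < out$start[i] | out$end > out$end[i])
      if (any(nested & keep)) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export extracted gene sequences as one FASTA file per gene
#'
#' Records are named `accession|organism`.
#'
#' @param genomes list of [annotated_genome()]
#' @param genes gene names (canonical); default: all shared protein-coding
#' @param dir output directory
#' @param ... passed to [extract_gene_sequences()]
#' @return invisible character vector of written paths
#' @export
export_gene_fastas <- function(genomes, genes = NULL, dir = ".", ...) {
  if (is.null(genes)) genes <- shared_genes(genomes)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in genes) {
    recs <- character(0)
    for (gn in genomes) {
      seqs <- extract_gene_sequences(gn, ...)
      names(seqs) <- normalize_gene_name(names(seqs))
      if (g %in% names(seqs))
        recs[sprintf("%s|%s", gn$id, gn$organism)] <- seqs[[g]]
    }
    if (!length(recs)) next
    p <- file.path(dir, paste0(g, ".fasta"))
    write_fasta(recs, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(wrap_text(seqs[[nm]], width), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("not a FASTA file: ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    body <- lines[(hdr[i] + 1L):ends[i]]
    toupper(gsub("\\s", "", paste(body[!grepl("^>", body)], collapse = "")))
  }, "")
  names(seqs) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  seqs
}
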