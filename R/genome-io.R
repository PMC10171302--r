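#' Genome input/output
#'
#' Genomes are represented as plain tibbles with one row per protein and the
#' columns `genome_id`, `label`, `taxon_group`, `protein_id`, `product`,
#' `sequence`, plus optional coordinates `contig`, `start`, `end`, `strand`
#' (1-based inclusive, GenBank/GFF3 convention). A multi-genome collection is
#' just the row-bind of per-genome tibbles, so the whole pipeline chains with
#' dplyr verbs.
#'
#' @name genome_io
NULL

genome_tbl <- function(genome_id, label, taxon_group, protein_id, product,
                       sequence, contig = NA_character_, start = NA_integer_,
                       end = NA_integer_, strand = NA_character_) {
  tibble::tibble(
    genome_id = genome_id, label = label, taxon_group = taxon_group,
    protein_id = protein_id, product = product, sequence = sequence,
    contig = contig, start = as.integer(start), end = as.integer(end),
    strand = strand)
}

check_protein_sequences <- function(seqs, ids, path) {
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seqs[i])
    if (bad > 0L) {
      rlang::abort(sprintf(
        "illegal residue '%s' at position %d of record '%s' in %s",
        substr(seqs[i], bad, bad), bad, ids[i], path))
    }
  }
  invisible(TRUE)
}

#' Read a protein FASTA file into a genome tibble
#'
#' FASTA headers are split at the first whitespace: the first token is the
#' protein id, the remainder (possibly empty) the product description.
#' Sequences are upper-cased, trailing stop characters (`*`) stripped, and
#' validated against the 20 standard residues plus `X`.
#'
#' @param path protein FASTA file.
#' @param genome_id genome identifier; defaults to the file stem.
#' @param taxon_group taxon group label (e.g. `"Lactobacillaceae"`).
#' @param label display name; defaults to `genome_id`.
#' @return a genome tibble (see [genome_io]).
#' @export
read_protein_fasta <- function(path, genome_id = NULL,
                               taxon_group = NA_character_, label = NULL) {
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(label)) label <- genome_id
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) rlang::abort(sprintf("no FASTA records in %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  products <- ifelse(grepl("\\s", headers),
                     trimws(sub("^\\S+\\s+", "", headers)), "")
  if (anyDuplicated(ids)) {
    rlang::abort(sprintf("duplicate protein id '%s' in %s",
                         ids[duplicated(ids)][1], path))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    rlang::abort(sprintf("empty sequence for record '%s' in %s",
                         ids[!nzchar(seqs)][1], path))
  }
  check_protein_sequences(seqs, ids, path)
  genome_tbl(genome_id, label, taxon_group, ids, products, unname(seqs))
}

#' Write a genome tibble as protein FASTA
#'
#' Headers are `protein_id product` (id only when the product is empty), so
#' [read_protein_fasta()] round-trips the internal model.
#'
#' @param genome a genome tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(genome, path) {
  hdr <- ifelse(nzchar(genome$product),
                paste(genome$protein_id, genome$product), genome$protein_id)
  writeLines(paste0(">", hdr, "\n", genome$sequence), path)
  invisible(path)
}

# --- GenBank flat files ------------------------------------------------------
# Minimal parser for annotated GenBank records: no installed R package reads
# local flat files, and only CDS locations + a few qualifiers are needed.

parse_gb_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (!length(nums)) rlang::abort(sprintf("unparseable CDS location: %s", loc))
  list(start = min(nums), end = max(nums), strand = strand)
}

parse_gb_features <- function(lines) {
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) rlang::abort("no FEATURES section in GenBank file")
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) - 1L else length(lines)
  flines <- lines[(fstart[1] + 1L):fend]
  # a feature starts at column 6; continuation/qualifier lines at column 22
  starts <- grep("^ {5}\\S", flines)
  feats <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(flines)
    block <- flines[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    body <- trimws(c(sub("^ {5}\\S+\\s*", "", block[1]), block[-1]))
    qstart <- grep("^/", body)
    loc <- paste(body[seq_len(if (length(qstart)) qstart[1] - 1L else length(body))],
                 collapse = "")
    quals <- list()
    for (j in seq_along(qstart)) {
      qfrom <- qstart[j]
      qto <- if (j < length(qstart)) qstart[j + 1L] - 1L else length(body)
      # translations wrap without separators; other qualifiers wrap on spaces
      qtext <- paste(body[qfrom:qto], collapse = "\n")
      qname <- sub("^/([^=]+)=?.*$", "\\1", body[qfrom])
      qval <- if (grepl("=", body[qfrom])) sub("^/[^=]+=", "", qtext) else TRUE
      if (is.character(qval)) {
        qval <- gsub("\"", "", qval)
        qval <- if (qname == "translation") gsub("\n", "", qval) else gsub("\n", " ", qval)
      }
      quals[[qname]] <- qval
    }
    feats[[length(feats) + 1L]] <- list(key = key, location = loc, qualifiers = quals)
  }
  feats
}

#' Read an annotated GenBank flat file into a genome tibble
#'
#' One protein row per CDS feature carrying a `/translation`. Protein ids are
#' taken from the `/protein_id` qualifier, falling back to `/locus_tag`; a CDS
#' with neither is an error. Coordinates are the feature span on the record's
#' contig (1-based inclusive), strand `-` for `complement(...)` locations.
#'
#' @param path GenBank flat file (single record).
#' @param taxon_group taxon group label.
#' @param genome_id genome identifier; defaults to the LOCUS name.
#' @return a genome tibble.
#' @export
read_genbank <- function(path, taxon_group = NA_character_, genome_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  contig <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else NA_character_
  if (is.null(genome_id)) {
    genome_id <- if (!is.na(contig)) contig else sub("\\.[^.]*$", "", basename(path))
  }
  defn <- grep("^DEFINITION", lines, value = TRUE)
  label <- if (length(defn)) trimws(sub("^DEFINITION\\s*", "", defn[1])) else genome_id
  feats <- parse_gb_features(lines)
  cds <- feats[vapply(feats, function(f) f$key == "CDS", logical(1))]
  if (!length(cds)) rlang::abort(sprintf("no CDS features in %s", path))
  rows <- list()
  for (f in cds) {
    tr <- f$qualifiers$translation
    if (is.null(tr)) next
    pid <- f$qualifiers$protein_id %||% f$qualifiers$locus_tag
    if (is.null(pid)) {
      rlang::abort(sprintf("CDS at %s lacks both protein_id and locus_tag in %s",
                           f$location, path))
    }
    loc <- parse_gb_location(f$location)
    seq <- sub("\\*+$", "", toupper(tr))
    check_protein_sequences(seq, pid, path)
    rows[[length(rows) + 1L]] <- genome_tbl(
      genome_id, label, taxon_group, pid,
      f$qualifiers$product %||% "", seq,
      contig = contig, start = loc$start, end = loc$end, strand = loc$strand)
  }
  if (!length(rows)) rlang::abort(sprintf("no CDS with a translation in %s", path))
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$protein_id)) {
    rlang::abort(sprintf("duplicate protein id '%s' in %s",
                         out$protein_id[duplicated(out$protein_id)][1], path))
  }
  out
}

# --- GFF3 + genomic FASTA ----------------------------------------------------

#' Read a GFF3 annotation plus genomic FASTA into a genome tibble
#'
#' CDS spans are extracted from the genomic sequence (GFF3 coordinates are
#' 1-based inclusive), reverse-complemented on the `-` strand, and translated
#' with the standard bacterial genetic code (table 11). Multi-segment CDS
#' sharing one `ID` are concatenated in coordinate order, 5' to 3' on the
#' coding strand. Ambiguous codons translate to `X`; a concatenated CDS whose
#' length is not a multiple of 3 triggers a warning and trailing-base
#' truncation.
#'
#' @param gff_path GFF3 file with CDS features carrying `ID` (and optionally
#'   `product`) attributes.
#' @param fasta_path companion genomic FASTA.
#' @param taxon_group taxon group label.
#' @param genome_id genome identifier; defaults to the GFF3 file stem.
#' @return a genome tibble.
#' @export
read_gff3_with_fasta <- function(gff_path, fasta_path,
                                 taxon_group = NA_character_, genome_id = NULL) {
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(gff_path))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0L) rlang::abort(sprintf("no CDS features in %s", gff_path))
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ids <- as.character(cds$ID)
  if (anyNA(ids)) rlang::abort(sprintf("CDS without ID attribute in %s", gff_path))
  rows <- list()
  for (id in unique(ids)) {
    seg <- cds[ids == id]
    seg <- seg[order(GenomicRanges::start(seg))]
    contig <- as.character(GenomicRanges::seqnames(seg))[1]
    if (!contig %in% names(genome)) {
      rlang::abort(sprintf("contig '%s' referenced by %s missing from %s",
                           contig, id, fasta_path))
    }
    strand <- as.character(GenomicRanges::strand(seg))[1]
    pieces <- lapply(seq_along(seg), function(i) {
      Biostrings::subseq(genome[[contig]],
                         GenomicRanges::start(seg)[i], GenomicRanges::end(seg)[i])
    })
    nt <- do.call(Biostrings::xscat, pieces)
    if (strand == "-") nt <- Biostrings::reverseComplement(nt)
    if (length(nt) %% 3L != 0L) {
      rlang::warn(sprintf(
        "CDS %s length %d not divisible by 3; truncating trailing bases",
        id, length(nt)))
      nt <- Biostrings::subseq(nt, 1L, 3L * (length(nt) %/% 3L))
    }
    aa <- Biostrings::translate(nt, genetic.code = Biostrings::getGeneticCode("11"),
                                if.fuzzy.codon = "X")
    seq <- sub("\\*+$", "", as.character(aa))
    product <- if (!is.null(seg$product)) as.character(seg$product)[1] else ""
    if (is.na(product)) product <- ""
    rows[[length(rows) + 1L]] <- genome_tbl(
      genome_id, genome_id, taxon_group, id, product, seq,
      contig = contig, start = min(GenomicRanges::start(seg)),
      end = max(GenomicRanges::end(seg)), strand = strand)
  }
  dplyr::bind_rows(rows)
}

# --- matrix and tree output --------------------------------------------------

matrix_sibling_path <- function(path) {
  paste0(sub("\\.[^.]*$", "", path), "_features.tsv")
}

#' Write a presence/absence matrix as TSV
#'
#' Writes the binary matrix with a `genome_id` column plus one column per
#' feature, and a sibling file `<stem>_features.tsv` mapping `feature_id` to
#' `category_id` (its first line is a `# mode:` comment recording enzyme- vs
#' cluster-mode). [read_matrix_tsv()] reverses both.
#'
#' @param matrix a [presence_matrix].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "presence_matrix"))
  tab <- tibble::as_tibble(matrix$cells, rownames = "genome_id")
  readr::write_tsv(tab, path)
  sib <- matrix_sibling_path(path)
  con <- file(sib, "w")
  writeLines(sprintf("# mode: %s", matrix$mode), con)
  close(con)
  readr::write_tsv(matrix$feature_category, sib, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read back a presence/absence matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path previously written by [write_matrix_tsv()].
#' @return a [presence_matrix].
#' @export
read_matrix_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  cells <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(cells) <- "integer"
  rownames(cells) <- tab$genome_id
  sib <- matrix_sibling_path(path)
  mode <- sub("^# mode: ", "", readLines(sib, n = 1L))
  fc <- readr::read_tsv(sib, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  presence_matrix(cells, fc, mode)
}

newick_quote <- function(label) {
  ifelse(grepl("[\\s()\\[\\]:;,']", label, perl = TRUE),
         paste0("'", gsub("'", "''", label), "'"), label)
}

newick_node <- function(node, parent_height) {
  bl <- parent_height - tree_height(node)
  if (is_leaf(node)) {
    sprintf("%s:%g", newick_quote(node$label), bl)
  } else {
    kids <- vapply(node$children, newick_node, character(1),
                   parent_height = tree_height(node))
    sprintf("(%s):%g", paste(kids, collapse = ","), bl)
  }
}

#' Serialise a cluster tree to Newick
#'
#' Branch lengths are height differences between parent and child, so leaf-to-
#' root path lengths reproduce the ultrametric UPGMA heights. Labels holding
#' Newick-reserved characters are single-quoted.
#'
#' @param tree an `anf_tree` from [upgma()].
#' @param path optional output file; when `NULL` the Newick string is
#'   returned instead.
#' @return the Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "anf_tree"))
  root <- tree$root
  str <- if (is_leaf(root)) {
    paste0(newick_quote(root$label), ";")
  } else {
    kids <- vapply(root$children, newick_node, character(1),
                   parent_height = tree_height(root))
    sprintf("(%s);", paste(kids, collapse = ","))
  }
  if (is.null(path)) return(str)
  writeLines(str, path)
  invisible(str)
}
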