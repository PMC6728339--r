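# Reading and writing annotated genomes.
#
# Supported formats: GenBank flat files and GFF3 + FASTA. GFF3 and FASTA go
# through rtracklayer/Biostrings; the GenBank feature table is parsed by a
# minimal reader below (LOCUS/FEATURES/ORIGIN, simple and complement()
# locations). Coordinates are converted to the package's internal 0-based
# half-open convention here and nowhere else.

#' Read an annotated genome
#'
#' Parses a GenBank flat file, or a GFF3 file plus its FASTA sequence, into a
#' [Genome]. CDS and 16S rRNA features are captured; 16S rRNAs are recognized
#' as features of type rRNA whose product (or Name) contains "16S". Features
#' spanning the origin of circular contigs (GenBank `join(...)` locations)
#' are excluded with a warning. A genome without any CDS is returned valid,
#' with a warning.
#'
#' @param path path to the GenBank or GFF3 file.
#' @param format `"genbank"` or `"gff3"`.
#' @param fasta path to the FASTA sequence (required for `format = "gff3"`).
#' @param topology contig topology for GFF3 input (GenBank records carry
#'   their own topology in the LOCUS line).
#' @return a [Genome].
#' @export
read_genome <- function(path, format = c("genbank", "gff3"), fasta = NULL,
                        topology = c("linear", "circular")) {
  format <- match.arg(format)
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "genbank") read_genbank(path) else read_gff3(path, fasta, topology)
}

read_genbank <- function(path) {
  lines <- readLines(path)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L)
    stop("parse error in ", path, ", line 1: no LOCUS line")
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "\\s+")[[1]]
  id <- locus[1]
  topology <- if ("circular" %in% locus) "circular" else "linear"

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  end_i <- grep("^//", lines)
  if (length(orig_i) == 0L)
    stop("parse error in ", path, ": no ORIGIN section")
  stop_line <- if (length(end_i)) end_i[1] else length(lines) + 1L

  seq_lines <- lines[(orig_i[1] + 1L):(stop_line - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  genes <- data.frame(gene_id = character(), kind = character(),
                      start = integer(), end = integer(),
                      strand = character(), product = character(),
                      stringsAsFactors = FALSE)
  if (length(feat_i)) {
    flines <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    fline_no <- (feat_i[1] + 1L):(orig_i[1] - 1L)
    # A feature starts in column 6; continuations/qualifiers are indented
    # further.
    is_feat <- grepl("^     \\S", flines)
    starts <- which(is_feat)
    n_auto <- 0L
    for (k in seq_along(starts)) {
      from <- starts[k]
      to <- if (k < length(starts)) starts[k + 1L] - 1L else length(flines)
      block <- flines[from:to]
      key <- sub("^\\s+", "", substr(block[1], 1, 21))
      key <- strsplit(key, "\\s+")[[1]][1]
      rest <- trimws(substring(block[1], 22))
      body <- trimws(block[-1])
      # location may continue over lines until the first qualifier
      qual_at <- which(startsWith(body, "/"))
      loc_extra <- if (length(qual_at)) body[seq_len(min(qual_at) - 1L)] else body
      location <- gsub("\\s+", "", paste(c(rest, loc_extra), collapse = ""))
      quals <- if (length(qual_at)) body[min(qual_at):length(body)] else character()

      if (!key %in% c("CDS", "rRNA")) next
      loc <- parse_gb_location(location)
      if (is.null(loc)) {
        warning("skipping feature '", key, "' at ", path, " line ",
                fline_no[from], ": unsupported location '", location, "'",
                " (origin-spanning or multi-segment)")
        next
      }
      qv <- parse_gb_qualifiers(quals)
      product <- if (!is.na(qv["product"])) unname(qv["product"]) else NA_character_
      kind <- if (key == "CDS") "CDS"
              else if (!is.na(product) && grepl("16S", product)) "rRNA_16S"
              else next
      if (!is.na(qv["locus_tag"])) {
        gid <- unname(qv["locus_tag"])
      } else if (!is.na(qv["gene"])) {
        gid <- unname(qv["gene"])
      } else {
        n_auto <- n_auto + 1L
        gid <- sprintf("feature_%04d", n_auto)
      }
      genes <- rbind(genes, data.frame(
        gene_id = gid, kind = kind,
        start = loc$start1 - 1L, end = loc$end1,
        strand = loc$strand, product = product, stringsAsFactors = FALSE))
    }
  }
  Genome(id, sequence, topology, genes)
}

# "123..456", "complement(123..456)", partial markers < > tolerated;
# join()/order() (origin-spanning or segmented) -> NULL.
parse_gb_location <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(.*\\)$", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|complement", loc)) return(NULL)
  loc <- gsub("[<>]", "", loc)
  if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc)) return(NULL)
  parts <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  if (parts[1] > parts[2]) return(NULL)
  list(start1 = parts[1], end1 = parts[2], strand = strand)
}

parse_gb_qualifiers <- function(quals) {
  out <- c(locus_tag = NA_character_, gene = NA_character_,
           product = NA_character_)
  # glue continuation lines onto their qualifier
  if (length(quals)) {
    joined <- character()
    for (q in quals) {
      if (startsWith(q, "/")) joined <- c(joined, q)
      else if (length(joined)) joined[length(joined)] <-
          paste(joined[length(joined)], q)
    }
    for (q in joined) {
      m <- regmatches(q, regexec('^/([A-Za-z_]+)="?([^"]*)"?$', q))[[1]]
      if (length(m) == 3 && m[2] %in% names(out)) out[m[2]] <- m[3]
    }
  }
  out
}

#' Write a genome as a GenBank flat file
#'
#' Emits a minimal deterministic GenBank record (LOCUS, FEATURES with CDS and
#' rRNA entries, ORIGIN) that [read_genome()] round-trips exactly.
#'
#' @param genome a [Genome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$sequence)
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s BCT 01-JAN-2026",
                   genome$id, n, genome$topology),
           sprintf("DEFINITION  %s.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  feats <- rbind(genome$genes, genome$rrnas)
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    loc <- sprintf("%d..%d", f$start + 1L, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    key <- if (f$kind == "CDS") "CDS" else "rRNA"
    out <- c(out,
             sprintf("     %-15s %s", key, loc),
             sprintf('                     /locus_tag="%s"', f$gene_id))
    if (!is.na(f$product))
      out <- c(out, sprintf('                     /product="%s"', f$product))
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", off, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

read_gff3 <- function(path, fasta, topology) {
  if (is.null(fasta)) stop("format 'gff3' requires a FASTA file")
  if (!file.exists(fasta)) stop("no such file: ", fasta)
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L)
    stop("expected a single-contig FASTA, got ", length(seqs), " sequences")
  seq_id <- strsplit(names(seqs)[1], "\\s+")[[1]][1]
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == seq_id]
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  product <- if ("product" %in% names(md)) as.character(md$product) else
    rep(NA_character_, length(gr))
  name <- if ("Name" %in% names(md)) as.character(md$Name) else
    rep(NA_character_, length(gr))
  is16s <- type == "rRNA" &
    (grepl("16S", ifelse(is.na(product), "", product)) |
     grepl("16S", ifelse(is.na(name), "", name)))
  keep <- type == "CDS" | is16s
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  ids <- if ("locus_tag" %in% names(md)) as.character(md$locus_tag) else
    rep(NA_character_, length(gr))
  if ("ID" %in% names(md)) ids[is.na(ids)] <- as.character(md$ID)[is.na(ids)]
  ids[is.na(ids)] <- sprintf("feature_%04d", which(is.na(ids)))
  genes <- data.frame(
    gene_id = ids,
    kind = ifelse(as.character(md$type) == "CDS", "CDS", "rRNA_16S"),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = if ("product" %in% names(md)) as.character(md$product) else NA_character_,
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  Genome(seq_id, as.character(seqs[[1]]), topology, genes)
}

#' Write a genome as GFF3 (+ optional FASTA)
#'
#' @param genome a [Genome].
#' @param path output GFF3 path.
#' @param fasta optional path; when given, the sequence is written there as
#'   FASTA.
#' @param original_start optional named integer vector (names = gene ids) of
#'   pre-re-annotation start coordinates (0-based forward coordinate of the
#'   first base of the original start codon), recorded as an
#'   `original_start` attribute.
#' @return `path`, invisibly.
#' @export
write_genome_gff3 <- function(genome, path, fasta = NULL,
                              original_start = NULL) {
  feats <- rbind(genome$genes, genome$rrnas)
  feats <- feats[order(feats$start, feats$end), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$type <- ifelse(feats$kind == "CDS", "CDS", "rRNA")
  S4Vectors::mcols(gr)$phase <- ifelse(feats$kind == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$ID <- feats$gene_id
  S4Vectors::mcols(gr)$locus_tag <- feats$gene_id
  S4Vectors::mcols(gr)$product <- feats$product
  if (!is.null(original_start)) {
    os <- rep(NA_character_, nrow(feats))
    hit <- match(names(original_start), feats$gene_id)
    os[hit[!is.na(hit)]] <- as.character(original_start[!is.na(hit)])
    S4Vectors::mcols(gr)$original_start <- os
  }
  rtracklayer::export(gr, path, format = "gff3")
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(genome$sequence)
    names(ss) <- genome$id
    Biostrings::writeXStringSet(ss, fasta)
  }
  invisible(path)
}

#' Apply start re-annotations to a genome
#'
#' `new_start` is the 0-based forward-strand coordinate of the first
#' nucleotide of the new start codon: for plus-strand genes the gene's
#' `start` field becomes `new_start`; for minus-strand genes the gene's `end`
#' field becomes `new_start + 1` (the biological start sits at the right end
#' of the forward-strand interval).
#'
#' @param genome a [Genome].
#' @param changes data frame with columns `gene_id`, `new_start`.
#' @param start_codons permitted start codons (gene-orientation DNA).
#' @return the modified [Genome].
#' @export
apply_reannotation <- function(genome, changes,
                               start_codons = DEFAULT_START_CODONS) {
  for (i in seq_len(nrow(changes))) {
    gid <- changes$gene_id[i]
    ns <- as.integer(changes$new_start[i])
    j <- match(gid, genome$genes$gene_id)
    if (is.na(j)) stop("no such gene: ", gid)
    g <- genome$genes[j, ]
    if (g$strand == "+") {
      if (ns < 0L || ns >= g$end)
        stop("new start for ", gid, " out of bounds")
      if ((g$end - ns) %% 3L != 0L)
        stop("new start for ", gid, " breaks the reading frame")
      genome$genes$start[j] <- ns
    } else {
      ne <- ns + 1L
      if (ne > nchar(genome$sequence) || ne <= g$start)
        stop("new start for ", gid, " out of bounds")
      if ((ne - g$start) %% 3L != 0L)
        stop("new start for ", gid, " breaks the reading frame")
      genome$genes$end[j] <- ne
    }
    first <- substr(gene_sequence(genome, genome$genes[j, ]), 1, 3)
    if (!first %in% start_codons)
      stop("new start for ", gid, " does not begin with a start codon (",
           first, ")")
  }
  genome$genes <- genome$genes[order(genome$genes$start, genome$genes$end), ,
                               drop = FALSE]
  rownames(genome$genes) <- NULL
  genome
}

#' Write a re-annotated genome to GFF3
#'
#' Applies the start changes (validated: in-frame, in-bounds, beginning with
#' a permitted start codon) and writes GFF3 in which every changed gene
#' carries an `original_start` provenance attribute.
#'
#' @inheritParams apply_reannotation
#' @param path output GFF3 path.
#' @return the re-annotated [Genome], invisibly.
#' @export
write_reannotated <- function(genome, changes, path,
                              start_codons = DEFAULT_START_CODONS) {
  orig <- NULL
  if (nrow(changes)) {
    old <- vapply(changes$gene_id, function(gid) {
      g <- get_gene(genome, gid)
      if (g$strand == "+") g$start else g$end - 1L
    }, integer(1))
    orig <- setNames(old, changes$gene_id)
  }
  genome2 <- apply_reannotation(genome, changes, start_codons)
  write_genome_gff3(genome2, path, original_start = orig)
  invisible(genome2)
}

#' Read a protein multiple alignment (aligned FASTA)
#'
#' @param path aligned FASTA with >= 2 rows of equal length.
#' @param query_id id of the query row; defaults to the first row.
#' @return an `MsaFamily`: list with `query_id`, `rows` (named character
#'   vector of aligned sequences) and `start_column` (named integer, 0-based
#'   column of each row's first non-gap character).
#' @export
read_msa <- function(path, query_id = NULL) {
  aln <- Biostrings::readAAStringSet(path)
  msa_family(setNames(as.character(aln),
                      vapply(strsplit(names(aln), "\\s+"), `[`, "", 1)),
             query_id)
}

#' @rdname read_msa
#' @param rows named character vector of aligned rows.
#' @export
msa_family <- function(rows, query_id = NULL) {
  if (length(rows) < 2L) stop("alignment needs at least 2 rows")
  if (anyDuplicated(names(rows)))
    stop("duplicate sequence ids in alignment: ",
         paste(unique(names(rows)[duplicated(names(rows))]), collapse = ", "))
  w <- nchar(rows)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(w), collapse = ", "))
  if (is.null(query_id)) query_id <- names(rows)[1]
  if (!query_id %in% names(rows)) stop("query row '", query_id, "' not found")
  start_col <- vapply(rows, function(r) {
    p <- regexpr("[^-]", r)
    if (p < 0) stop("alignment row consists only of gaps")
    as.integer(p) - 1L
  }, integer(1))
  structure(list(query_id = query_id, rows = rows, start_column = start_col),
            class = "MsaFamily")
}

#' Write an MsaFamily as aligned FASTA
#'
#' @param family an `MsaFamily`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(family, path) {
  ss <- Biostrings::AAStringSet(family$rows)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
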