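# Homolog-set construction and translation-start re-annotation.
#
# Two-tier greedy identity clustering (tight 90%, loose 50%) builds homolog
# sets; the MSA of a query with its 10 homologs is scanned with a 3-column
# sliding window for a consensus start (>= 5 homolog starts), which is then
# remapped to the nucleotide sequence, choosing the in-frame start codon
# closest to the original annotation.

#' Global-alignment identity of two protein sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap opening 10,
#' extension 0.5); identity = identical positions / alignment columns,
#' end gaps included, so gaps count against identity.
#'
#' @param a,b protein sequences (character scalars).
#' @return identity fraction in `[0, 1]`.
#' @export
alignment_identity <- function(a, b) {
  if (a == b) return(1)
  alphabet <- unique(c(strsplit(paste0(a, b), "")[[1]],
                       Biostrings::AA_STANDARD))
  mat <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

greedy_cluster <- function(proteins, identity, tier) {
  stopifnot(all(nchar(proteins) > 0L))
  ord <- order(-nchar(proteins), names(proteins))
  reps <- character()
  members <- list()
  for (id in names(proteins)[ord]) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (alignment_identity(proteins[[id]], proteins[[reps[ci]]]) >= identity) {
        members[[ci]] <- c(members[[ci]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  lapply(seq_along(reps), function(ci) {
    structure(list(cluster_id = sprintf("%s_%03d", tier, ci), tier = tier,
                   members = members[[ci]], representative = reps[ci]),
              class = "ProteinCluster")
  })
}

#' Tight (90% identity) protein clustering
#'
#' Greedy incremental clustering: sequences are sorted by length
#' (descending; ties by id) and each joins the first cluster whose founding
#' representative it matches at >= `identity` global-alignment identity, or
#' founds a new cluster. Deterministic for fixed input.
#'
#' @param proteins named character vector of protein sequences.
#' @param identity identity threshold (fraction).
#' @return list of `ProteinCluster` (fields `cluster_id`, `tier`, `members`,
#'   `representative`).
#' @export
cluster_tight <- function(proteins, identity = 0.90) {
  greedy_cluster(proteins, identity, "tight")
}

#' Representatives of tight clusters
#'
#' For each tight cluster, emits all members belonging to the reference
#' genome set (`rep720_ids`); when a cluster has none, the single longest
#' member (ties broken lexicographically by id).
#'
#' @param clusters list of `ProteinCluster` from [cluster_tight()].
#' @param rep720_ids ids of proteins from the reference genome set.
#' @param proteins named character vector (for length lookups).
#' @return character vector of selected protein ids.
#' @export
select_representatives <- function(clusters, rep720_ids, proteins) {
  unlist(lapply(clusters, function(cl) {
    hit <- intersect(cl$members, rep720_ids)
    if (length(hit)) return(hit)
    lens <- nchar(proteins[cl$members])
    cand <- cl$members[lens == max(lens)]
    sort(cand)[1]
  }), use.names = FALSE)
}

#' Loose (50% identity) clustering of representatives
#'
#' Same greedy procedure as [cluster_tight()] at the loose threshold;
#' clusters without any member from the reference genome set are discarded.
#'
#' @param representatives named character vector of representative protein
#'   sequences.
#' @param identity identity threshold (fraction).
#' @param rep720_ids ids of proteins from the reference genome set.
#' @return list of `ProteinCluster` with `tier = "loose"`.
#' @export
cluster_loose <- function(representatives, identity = 0.50,
                          rep720_ids = names(representatives)) {
  cl <- greedy_cluster(representatives, identity, "loose")
  Filter(function(x) length(intersect(x$members, rep720_ids)) > 0L, cl)
}

#' Select the homolog set for a query protein
#'
#' Candidates are the other cluster members, deduplicated by sequence and
#' excluding sequences identical to the query, ranked by global-alignment
#' identity to the query and filtered at `min_identity` (the internal-mode
#' stand-in for an e-value cutoff). The query is kept only if *more than*
#' `n` candidates qualify; the best `n` are returned, otherwise the query is
#' rejected (`NULL`).
#'
#' @param query_id id of the query (must be a cluster member).
#' @param cluster a `ProteinCluster`.
#' @param proteins named character vector covering the cluster members.
#' @param n homolog-set size (default 10).
#' @param min_identity minimum identity to the query for a hit to qualify.
#' @return a `HomologSet` (list with `query_id`, `homologs`, `identity`) or
#'   `NULL` when rejected.
#' @export
select_homolog_set <- function(query_id, cluster, proteins, n = 10L,
                               min_identity = 0.30) {
  cand <- setdiff(cluster$members, query_id)
  if (!length(cand)) return(NULL)
  qseq <- proteins[[query_id]]
  seqs <- proteins[cand]
  cand <- cand[!duplicated(seqs)]
  cand <- cand[proteins[cand] != qseq]
  if (!length(cand)) return(NULL)
  idn <- vapply(cand, function(h) alignment_identity(qseq, proteins[[h]]),
                numeric(1))
  keep <- idn >= min_identity
  cand <- cand[keep]; idn <- idn[keep]
  if (length(cand) <= n) return(NULL)   # strictly more than n required
  ord <- order(-idn, cand)[seq_len(n)]
  structure(list(query_id = query_id, homologs = cand[ord],
                 identity = unname(idn[ord])), class = "HomologSet")
}

#' Scan an alignment for a consensus start position
#'
#' Slides a `window`-column window over the alignment and counts homolog
#' rows (the query row is excluded) whose first residue falls inside.
#' Among windows with support >= `min_support`, the one closest to the
#' query's annotated start column is selected; the consensus column is the
#' column within that window holding the most homolog starts (ties broken
#' toward the query start column).
#'
#' @param family an `MsaFamily` (see [read_msa()]).
#' @param min_support minimum number of homolog starts in a window.
#' @param window window width in alignment columns.
#' @return a `ConsensusStart` (list with `window_columns`, `support`,
#'   `consensus_column`, `query_start_column`, `offset_codons`) or `NULL`
#'   when no window qualifies. `offset_codons` is the signed distance from
#'   the query's annotated start to the consensus, in codons: negative =
#'   consensus upstream of the annotated start.
#' @export
scan_consensus_start <- function(family, min_support = 5L, window = 3L) {
  ncol_aln <- nchar(family$rows[[1]])
  hom <- setdiff(names(family$rows), family$query_id)
  hstart <- family$start_column[hom]
  qcol <- family$start_column[[family$query_id]]
  wins <- 0:(ncol_aln - window)          # 0-based first column of window
  support <- vapply(wins, function(w)
    sum(hstart >= w & hstart <= w + window - 1L), integer(1))
  qual <- wins[support >= min_support]
  if (!length(qual)) return(NULL)
  # distance from the query start column to the window (0 if inside)
  dist_to_q <- pmax(0L, pmax(qual - qcol, qcol - (qual + window - 1L)))
  best_w <- qual[order(dist_to_q, -support[match(qual, wins)], qual)][1]
  cols <- best_w:(best_w + window - 1L)
  counts <- vapply(cols, function(cc) sum(hstart == cc), integer(1))
  cand <- cols[counts == max(counts)]
  consensus <- cand[order(abs(cand - qcol), cand)][1]
  structure(list(
    window_columns = cols,
    support = support[match(best_w, wins)],
    consensus_column = consensus,
    query_start_column = qcol,
    offset_codons = column_codon_offset(family, consensus)),
    class = "ConsensusStart")
}

# Signed codon offset from the query's annotated start to an alignment
# column. Downstream of the query start, residues are counted skipping
# query-row gaps; upstream (where the query row is all gaps) columns are
# counted directly.
column_codon_offset <- function(family, column) {
  qrow <- strsplit(family$rows[[family$query_id]], "")[[1]]
  qcol <- family$start_column[[family$query_id]]
  if (column == qcol) return(0L)
  if (column > qcol) {
    # residues of the query row in columns (qcol, column], gaps skipped
    as.integer(sum(qrow[(qcol + 2L):(column + 1L)] != "-"))
  } else {
    # upstream of the query start the row is all gaps; count columns
    as.integer(column - qcol)
  }
}

#' Remap a consensus start to a nucleotide coordinate
#'
#' When the consensus lies upstream of the annotated start, the in-frame
#' start codons between consensus and annotation are searched and the one
#' closest to the annotation is chosen (minimal extension); downstream,
#' likewise the closest (minimal loss of residues). With no start codon in
#' the searched range the annotation is left unchanged.
#'
#' @param genome a [Genome].
#' @param gene one-row CDS record.
#' @param consensus a `ConsensusStart` from [scan_consensus_start()].
#' @param start_codons permitted start codons (gene-orientation DNA).
#' @return list with `changed` (logical), `new_start` (0-based forward
#'   coordinate of the first base of the new start codon, as consumed by
#'   [apply_reannotation()]), `offset_codons` actually applied (0 when
#'   unchanged).
#' @export
remap_start <- function(genome, gene, consensus,
                        start_codons = DEFAULT_START_CODONS) {
  off <- consensus$offset_codons
  if (off == 0L)
    return(list(changed = FALSE, new_start = NA_integer_, offset_codons = 0L))
  rng <- if (off < 0L) seq(-1L, off, by = -1L) else seq(1L, off, by = 1L)
  for (r in rng) {
    cod <- gene_codon_at(genome, gene, r)
    if (is.na(cod)) return(list(changed = FALSE, new_start = NA_integer_,
                                offset_codons = 0L))
    if (cod %in% start_codons) {
      ns <- if (gene$strand == "+") gene$start + 3L * r
            else gene$end - 1L - 3L * r
      return(list(changed = TRUE, new_start = ns, offset_codons = r))
    }
  }
  list(changed = FALSE, new_start = NA_integer_, offset_codons = 0L)
}

# Codon r codons away from the annotated start in gene orientation
# (r < 0 = upstream). NA when outside the contig.
gene_codon_at <- function(genome, gene, r) {
  if (gene$strand == "+") {
    from <- gene$start + 3L * r
    s <- slice_seq(genome$sequence, from, from + 3L, genome$topology)
    if (is.na(s)) return(NA_character_)
    s
  } else {
    to <- gene$end - 3L * r
    s <- slice_seq(genome$sequence, to - 3L, to, genome$topology)
    if (is.na(s)) return(NA_character_)
    revcomp_dna(s)
  }
}

#' Re-annotate translation starts of a genome from homolog alignments
#'
#' For each MSA family whose query id matches a CDS, scans for a consensus
#' start and remaps it; collects the changes.
#'
#' @param genome a [Genome].
#' @param families list of `MsaFamily`.
#' @param min_support,window see [scan_consensus_start()].
#' @param start_codons permitted start codons.
#' @return data frame: `gene_id`, `old_start`, `new_start` (0-based forward
#'   coordinate of the start codon's first base), `support`, `direction`
#'   (`"extended"`/`"truncated"`).
#' @export
reannotate_genome <- function(genome, families, min_support = 5L,
                              window = 3L,
                              start_codons = DEFAULT_START_CODONS) {
  out <- data.frame(gene_id = character(), old_start = integer(),
                    new_start = integer(), support = integer(),
                    direction = character(), stringsAsFactors = FALSE)
  for (fam in families) {
    if (!fam$query_id %in% genome$genes$gene_id) next
    gene <- get_gene(genome, fam$query_id)
    cons <- scan_consensus_start(fam, min_support, window)
    if (is.null(cons)) next
    res <- remap_start(genome, gene, cons, start_codons)
    if (!res$changed) next
    old <- if (gene$strand == "+") gene$start else gene$end - 1L
    out <- rbind(out, data.frame(
      gene_id = fam$query_id, old_start = old, new_start = res$new_start,
      support = cons$support,
      direction = if (res$offset_codons < 0L) "extended" else "truncated",
      stringsAsFactors = FALSE))
  }
  out
}
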