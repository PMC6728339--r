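random_protein <- function(len) {
  paste(sample(Biostrings::AA_STANDARD, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, n_subs) {
  x <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(x), n_subs)
  for (p in pos) x[p] <- sample(setdiff(Biostrings::AA_STANDARD, x[p]), 1)
  paste(x, collapse = "")
}

test_that("global-alignment identity matches hand-constructed divergences", {
  set.seed(1)
  base <- random_protein(100)
  expect_equal(alignment_identity(base, base), 1)
  # equal-length substitution-only pairs align gap-free, so identity is
  # exactly matches/100
  expect_equal(alignment_identity(base, mutate_protein(base, 5)), 0.95)
  expect_equal(alignment_identity(base, mutate_protein(base, 20)), 0.80)
})

test_that("tight clustering groups by the 90% threshold", {
  set.seed(2)
  a <- random_protein(100)
  prots <- c(p1 = a, p2 = a, p3 = mutate_protein(a, 5),
             p4 = mutate_protein(a, 20), p5 = random_protein(80))
  cl <- cluster_tight(prots)
  memb <- lapply(cl, `[[`, "members")
  find_cluster <- function(id) which(vapply(memb, function(m) id %in% m,
                                            logical(1)))
  expect_equal(find_cluster("p1"), find_cluster("p2"))  # identical pair
  expect_equal(find_cluster("p1"), find_cluster("p3"))  # 95% identity
  expect_false(find_cluster("p4") == find_cluster("p1"))  # 80% identity
  expect_false(find_cluster("p5") == find_cluster("p1"))
  for (c1 in cl)
    for (m in c1$members)
      expect_gte(alignment_identity(prots[[m]], prots[[c1$representative]]),
                 0.90)
})

test_that("representative selection prefers reference-set members, else longest", {
  cl3 <- structure(list(cluster_id = "t1", tier = "tight",
                        members = c("r1", "r2", "r3", "x1"),
                        representative = "r1"), class = "ProteinCluster")
  prots <- c(r1 = strrep("A", 50), r2 = strrep("A", 60),
             r3 = strrep("A", 55), x1 = strrep("A", 70),
             y1 = strrep("C", 120), y2 = strrep("C", 140))
  rep720 <- c("r1", "r2", "r3")
  expect_setequal(select_representatives(list(cl3), rep720, prots),
                  c("r1", "r2", "r3"))
  # no rep720 member: single longest wins
  clx <- structure(list(cluster_id = "t2", tier = "tight",
                        members = c("y1", "y2"), representative = "y1"),
                   class = "ProteinCluster")
  expect_equal(select_representatives(list(clx), rep720, prots), "y2")
  # singleton
  cls <- structure(list(cluster_id = "t3", tier = "tight",
                        members = "x1", representative = "x1"),
                   class = "ProteinCluster")
  expect_equal(select_representatives(list(cls), rep720, prots), "x1")
})

test_that("loose clustering merges at 50% and discards non-reference clusters", {
  set.seed(3)
  a <- random_protein(100)
  b <- mutate_protein(a, 40)            # 60% identity to a
  c_ <- random_protein(100)             # unrelated
  reps <- c(q1 = a, q2 = b, z1 = c_)
  cl <- cluster_loose(reps, rep720_ids = c("q1", "q2"))
  # q1/q2 together; the z1 cluster (no rep720 member) is discarded
  expect_equal(length(cl), 1L)
  expect_setequal(cl[[1]]$members, c("q1", "q2"))
  # determinism
  cl2 <- cluster_loose(reps, rep720_ids = c("q1", "q2"))
  expect_identical(lapply(cl, `[[`, "members"), lapply(cl2, `[[`, "members"))
})

test_that("homolog sets require strictly more than 10 qualifying hits", {
  set.seed(4)
  q <- random_protein(120)
  mk <- function(n, subs) setNames(lapply(seq_len(n),
                                          function(i) mutate_protein(q, subs)),
                                   sprintf("h%02d", seq_len(n)))
  cluster_of <- function(hom) structure(
    list(cluster_id = "c", tier = "loose",
         members = c("q", names(hom)), representative = "q"),
    class = "ProteinCluster")
  hom12 <- mk(12, 10)
  hs <- select_homolog_set("q", cluster_of(hom12),
                           c(q = q, unlist(hom12)))
  expect_s3_class(hs, "HomologSet")
  expect_length(hs$homologs, 10L)
  expect_true(all(diff(hs$identity) <= 0))

  hom10 <- mk(10, 10)
  expect_null(select_homolog_set("q", cluster_of(hom10),
                                 c(q = q, unlist(hom10))))
  # singleton cluster
  single <- structure(list(cluster_id = "c", tier = "loose", members = "q",
                           representative = "q"), class = "ProteinCluster")
  expect_null(select_homolog_set("q", single, c(q = q)))
  # hits identical to the query never qualify
  hom_ident <- c(mk(11, 8), list(same = q))
  hs2 <- select_homolog_set("q", cluster_of(hom_ident),
                            c(q = q, unlist(hom_ident)))
  expect_false("same" %in% hs2$homologs)
})

make_family <- function(hom_starts, query_start, ncol_aln = 40) {
  blank <- function(from0) paste0(strrep("-", from0),
                                  strrep("K", ncol_aln - from0))
  rows <- c(query = blank(query_start))
  for (i in seq_along(hom_starts))
    rows[sprintf("h%02d", i)] <- blank(hom_starts[i])
  msa_family(rows, query_id = "query")
}

test_that("consensus scan selects supported windows near the query start", {
  # 7 of 10 homologs start within columns 12-14; query start at column 13
  fam <- make_family(c(12, 12, 13, 13, 13, 14, 14, 0, 25, 32), 13)
  cons <- scan_consensus_start(fam)
  expect_equal(cons$window_columns, 12:14)
  expect_equal(cons$support, 7L)
  expect_equal(cons$consensus_column, 13L)
  expect_equal(cons$query_start_column, 13L)

  # max support 4 in any window: no consensus
  fam4 <- make_family(c(13, 13, 13, 13, 0, 7, 21, 28, 35, 38), 13)
  expect_null(scan_consensus_start(fam4))

  # two qualifying windows; proximity to the query start decides
  fam2 <- make_family(c(4, 4, 4, 4, 4, 30, 30, 31, 31, 32), 31)
  cons2 <- scan_consensus_start(fam2)
  expect_equal(cons2$window_columns, 30:32)
})

test_that("the query row is excluded from the support count", {
  # 4 homologs + the query share a start: support must stay 4
  fam <- make_family(c(13, 13, 13, 13, 0, 7, 21, 28, 35, 38), 13)
  expect_null(scan_consensus_start(fam))
  expect_equal(length(fam$rows), 11L)
})

test_that("start remapping picks the in-frame start codon closest to the annotation", {
  # plus-strand gene at [48, 148); start codons planted 3 and 6 codons
  # upstream, and 2 and 5 codons downstream
  sq <- strrep("C", 300)
  substr(sq, 49, 51) <- "ATG"
  g <- toy_genome(data.frame(gene_id = "q", start = 48L, end = 148L,
                             strand = "+"), sequence = sq)
  substr(g$sequence, 31, 33) <- "ATG"   # -6 codons
  substr(g$sequence, 40, 42) <- "GTG"   # -3 codons
  cons_up <- structure(list(offset_codons = -6L), class = "ConsensusStart")
  res <- remap_start(g, get_gene(g, "q"), cons_up)
  expect_true(res$changed)
  expect_equal(res$new_start, 48L - 9L)   # the GTG at -3, minimal extension
  expect_equal(res$offset_codons, -3L)

  g2 <- g
  substr(g2$sequence, 55, 57) <- "ATG"  # +2 codons
  substr(g2$sequence, 64, 66) <- "ATG"  # +5 codons
  cons_dn <- structure(list(offset_codons = 5L), class = "ConsensusStart")
  res2 <- remap_start(g2, get_gene(g2, "q"), cons_dn)
  expect_equal(res2$new_start, 48L + 6L)  # +2 codons, minimal loss
  expect_equal(res2$offset_codons, 2L)

  # consensus at the annotated start: unchanged
  cons0 <- structure(list(offset_codons = 0L), class = "ConsensusStart")
  expect_false(remap_start(g, get_gene(g, "q"), cons0)$changed)

  # no start codon in the searched range: unchanged
  g3 <- toy_genome(data.frame(gene_id = "q", start = 48L, end = 148L,
                              strand = "+"), sequence = strrep("C", 300))
  expect_false(remap_start(g3, get_gene(g3, "q"), cons_up)$changed)
})

test_that("family generator truth is recovered by scan + remap", {
  for (pert in c(-9L, -6L, -3L, 3L, 6L, 9L)) {
    fg <- generate_homolog_family(concordant = 8, perturbation_nt = pert,
                                  seed = 100 + pert)
    cons <- scan_consensus_start(fg$family)
    expect_equal(cons$support, 8L)
    gene <- get_gene(fg$genome, "query")
    res <- remap_start(fg$genome, gene, cons)
    expect_true(res$changed)
    expect_equal(res$new_start, fg$truth$true_start_nt,
                 info = paste("perturbation", pert))
  }
  # concordant = 10, no perturbation: support 10, nothing to change
  fg0 <- generate_homolog_family(concordant = 10, perturbation_nt = 0,
                                 seed = 55)
  cons0 <- scan_consensus_start(fg0$family)
  expect_equal(cons0$support, 10L)
  res0 <- remap_start(fg0$genome, get_gene(fg0$genome, "query"), cons0)
  expect_false(res0$changed)
})

test_that("re-annotation is idempotent and preserves stop codon and frame", {
  fg <- generate_homolog_family(concordant = 9, perturbation_nt = 6,
                                seed = 77)
  changes <- reannotate_genome(fg$genome, list(fg$family))
  expect_equal(nrow(changes), 1L)
  expect_equal(changes$direction, "extended")
  g2 <- apply_reannotation(fg$genome, changes)
  gene2 <- get_gene(g2, "query")
  gene1 <- get_gene(fg$genome, "query")
  expect_equal(gene2$end, gene1$end)              # stop untouched
  expect_equal((gene2$end - gene2$start) %% 3L, 0L)
  s <- gene_sequence(g2, gene2)
  expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
  # second pass: the alignment-derived start now matches the annotation
  fam2 <- fg$family
  # the query row gains the residues of the extension: rebuild start column
  qcol_new <- fam2$start_column[["query"]] - 2L   # 6 nt = 2 codons upstream
  fam2$rows[["query"]] <- paste0(
    strrep("-", qcol_new),
    strrep("K", nchar(fam2$rows[["query"]]) - qcol_new))
  fam2 <- msa_family(fam2$rows, "query")
  changes2 <- reannotate_genome(g2, list(fam2))
  expect_equal(nrow(changes2), 0L)
})
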