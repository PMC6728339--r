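make_genbank_text <- function() {
  c("LOCUS       testrec              200 bp    DNA     linear BCT 01-JAN-2026",
    "DEFINITION  test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..200",
    "     CDS             11..19",
    '                     /locus_tag="gene1"',
    '                     /product="demo protein"',
    "     CDS             complement(71..100)",
    '                     /locus_tag="gene2"',
    "     rRNA            110..150",
    '                     /locus_tag="rrs"',
    '                     /product="16S ribosomal RNA"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("      121 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("      181 ", paste(rep("acgtacgtac", 2), collapse = " ")),
    "//")
}

test_that("GenBank 1-based inclusive coordinates convert to 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_genbank_text(), path)
  g <- read_genome(path, format = "genbank")
  expect_equal(g$id, "testrec")
  expect_equal(nchar(g$sequence), 200L)
  g1 <- get_gene(g, "gene1")
  expect_equal(g1$start, 10L)
  expect_equal(g1$end, 19L)
  expect_equal(g1$strand, "+")
  # minus-strand CDS occupying nt 71..100 (1-based)
  g2 <- get_gene(g, "gene2")
  expect_equal(g2$start, 70L)
  expect_equal(g2$end, 100L)
  expect_equal(g2$strand, "-")
  # 16S recognized by product
  expect_equal(nrow(g$rrnas), 1L)
  expect_equal(g$rrnas$gene_id, "rrs")
})

test_that("GenBank parse errors name the problem; joins are skipped with warning", {
  bad <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("DEFINITION  no locus."), bad)
  expect_error(read_genome(bad, format = "genbank"), "LOCUS")

  txt <- make_genbank_text()
  txt <- append(txt, c("     CDS             join(190..200,1..30)",
                       '                     /locus_tag="wrapper"'),
                after = 12)
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(txt, path)
  expect_warning(g <- read_genome(path, format = "genbank"),
                 "origin-spanning|unsupported location")
  expect_false("wrapper" %in% g$genes$gene_id)
})

test_that("a genome with zero CDS warns but is returned valid", {
  txt <- make_genbank_text()
  txt <- txt[!grepl("CDS|gene1|gene2|demo", txt)]
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(txt, path)
  expect_warning(g <- read_genome(path, format = "genbank"), "no CDS")
  expect_s3_class(g, "Genome")
  expect_equal(nrow(g$genes), 0L)
})

test_that("the same locus reads identically from GenBank and GFF3+FASTA", {
  gen <- generate_genome(n_genes = 12, seed = 101)
  gb <- withr::local_tempfile(fileext = ".gb")
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genbank(gen$genome, gb)
  write_genome_gff3(gen$genome, gff, fasta = fa)
  from_gb <- read_genome(gb, format = "genbank")
  from_gff <- read_genome(gff, format = "gff3", fasta = fa,
                          topology = "circular")
  cols <- c("gene_id", "kind", "start", "end", "strand")
  expect_equal(from_gb$genes[cols], from_gff$genes[cols])
  expect_equal(from_gb$rrnas[cols], from_gff$rrnas[cols])
  expect_equal(from_gb$sequence, from_gff$sequence)
})

test_that("read -> write -> read is a fixed point for both formats", {
  gen <- generate_genome(n_genes = 15, seed = 7)
  gb1 <- withr::local_tempfile(fileext = ".gb")
  gb2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gen$genome, gb1)
  g1 <- read_genome(gb1, format = "genbank")
  write_genbank(g1, gb2)
  expect_identical(readLines(gb1), readLines(gb2))
  cols <- c("gene_id", "kind", "start", "end", "strand")
  expect_equal(g1$genes[cols], gen$genome$genes[cols])

  gff1 <- withr::local_tempfile(fileext = ".gff3")
  fa1 <- withr::local_tempfile(fileext = ".fa")
  write_genome_gff3(g1, gff1, fasta = fa1)
  g2 <- read_genome(gff1, format = "gff3", fasta = fa1)
  expect_equal(g2$genes[cols], g1$genes[cols])
})

test_that("generated CDS begin with a start codon and end with a stop codon", {
  gen <- generate_genome(n_genes = 25, seed = 13)
  g <- gen$genome
  for (i in seq_len(nrow(g$genes))) {
    s <- gene_sequence(g, g$genes[i, ])
    expect_equal(nchar(s) %% 3, 0)
    expect_true(substr(s, 1, 3) %in% c("ATG", "GTG", "TTG"))
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
  }
})

test_that("aligned FASTA reading computes per-row start columns", {
  path <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">r1", "M-KT", ">r2", "MAKT"), path)
  fam <- read_msa(path)
  expect_equal(unname(fam$start_column), c(0L, 0L))
  expect_equal(fam$query_id, "r1")

  writeLines(c(">r1", "---MKT", ">r2", "MMMMKT"), path)
  expect_equal(read_msa(path)$start_column[["r1"]], 3L)

  writeLines(c(">r1", "MKT", ">r2", "MKTA"), path)
  expect_error(read_msa(path), "ragged")
  writeLines(c(">r1", "MKT", ">r1", "MKT"), path)
  expect_error(read_msa(path), "duplicate")
})

test_that("a generated homolog family round-trips through aligned FASTA", {
  fam <- generate_homolog_family(n_homologs = 10, concordant = 8,
                                 perturbation_nt = 6, seed = 9)$family
  path <- withr::local_tempfile(fileext = ".afa")
  write_msa(fam, path)
  back <- read_msa(path, query_id = "query")
  expect_equal(length(back$rows), 11L)
  expect_true("query" %in% names(back$rows))
  expect_equal(back$start_column, fam$start_column)
})

test_that("re-annotation writing validates, records provenance and round-trips", {
  gen <- generate_genome(n_genes = 10, seed = 31)
  g <- gen$genome
  path <- withr::local_tempfile(fileext = ".gff3")

  # empty change set: identical annotation
  out0 <- write_reannotated(g, data.frame(gene_id = character(),
                                          new_start = integer()), path)
  cols <- c("gene_id", "start", "end", "strand")
  expect_equal(out0$genes[cols], g$genes[cols])

  # move a plus-strand start 6 nt downstream onto an in-frame codon; force
  # a start codon there so validation passes
  gid <- g$genes$gene_id[1]
  old <- get_gene(g, gid)
  substr(g$sequence, old$start + 7L, old$start + 9L) <- "ATG"
  out <- write_reannotated(g, data.frame(gene_id = gid,
                                         new_start = old$start + 6L), path)
  expect_equal(get_gene(out, gid)$start, old$start + 6L)
  reread <- read_genome(path, format = "gff3",
                        fasta = { fa <- withr::local_tempfile(fileext = ".fa")
                                  write_genome_gff3(out, tempfile(), fasta = fa)
                                  fa })
  expect_equal(get_gene(reread, gid)$start, old$start + 6L)

  # frame-breaking and out-of-frame starts are rejected
  expect_error(write_reannotated(g, data.frame(gene_id = gid,
                                               new_start = old$start + 5L),
                                 path), "frame")
})

test_that("minus-strand re-annotation decreases the right edge by the shift", {
  # minus-strand gene: moving the start 6 nt downstream in gene orientation
  # decreases the GFF end field by 6
  sq <- strrep("A", 400)
  # gene on minus strand [100, 220); biological start at 219
  substr(sq, 101, 220) <- paste(rev(strsplit(paste(
    c("ATG", rep("GCA", 38), "TGA"), collapse = ""), "")[[1]]), collapse = "")
  g <- toy_genome(data.frame(gene_id = "m", start = 100L, end = 220L,
                             strand = "-"), sequence = revcomp_dna(
                               revcomp_dna(sq)))
  # plant an in-frame ATG 6 nt downstream (gene orientation)
  piece <- revcomp_dna("ATG")
  substr(g$sequence, 212, 214) <- piece
  path <- withr::local_tempfile(fileext = ".gff3")
  out <- write_reannotated(g, data.frame(gene_id = "m", new_start = 213L),
                           path)
  expect_equal(get_gene(out, "m")$end, 214L)   # 220 - 6
  txt <- readLines(path)
  cds <- grep("\tCDS\t", txt, value = TRUE)
  expect_equal(as.integer(strsplit(cds, "\t")[[1]][5]), 214L)
  expect_match(cds, "original_start=219")
})
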