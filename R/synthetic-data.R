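# Synthetic genomes, SD windows and homolog families with planted ground
# truth, so every pipeline stage can be exercised and validated without
# external downloads.
#
# Genes are laid out on a single (plus) strand as a chain of ORFs whose
# junctions are either a 4-nt stop/start overlap (ATGA), a 1-nt overlap
# (TGATG), or a gap drawn from a geometric distribution with a point mass
# at >= 200 nt to plant leading genes. ORF bodies are random non-stop
# codons; junction constraints are imposed codon-aware so frames stay
# valid and the planted overlap histogram is exact. Every gene's 12-nt
# upstream window is rejection-sampled to a target SD energy class with a
# configurable safety margin from the class thresholds.

revcomp_rna <- function(x) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", toupper(x)), "")[[1]]),
        collapse = "")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a 12-nt window with a target SD energy class
#'
#' Rejection-samples windows until the hybridization energy against
#' `anti_sd` falls in the target class with at least `margin` kcal/mol to
#' spare from both class thresholds (so that downstream classification
#' recovery is exact). For `sd`/`strong_sd` targets a reverse-complement
#' core of the anti-SD (4-6 nt and 6-8 nt respectively) is seeded at a
#' random feasible position before the remaining positions are filled
#' randomly.
#'
#' @param target_class `"none"`, `"sd"` or `"strong_sd"`.
#' @param anti_sd anti-SD RNA string.
#' @param model an [energy_model()].
#' @param seed optional integer; when given, sampling is a pure function of
#'   it (the caller's RNG state is untouched). When `NULL` the current RNG
#'   stream is used.
#' @param width window width (nt).
#' @param fixed optional character vector of length `width` with `NA` at
#'   free positions; non-NA entries (DNA) are immutable, e.g. stop-codon
#'   bases shared with an overlapping upstream gene.
#' @param valid optional predicate on the candidate DNA window (e.g. a
#'   reading-frame check for windows inside an upstream ORF).
#' @param margin required distance (kcal/mol) from the class thresholds.
#' @param max_tries rejection budget before declaring the target infeasible.
#' @return DNA character scalar of length `width`, with the achieved energy
#'   in attribute `delta_g`.
#' @export
sample_sd_window <- function(target_class = c("none", "sd", "strong_sd"),
                             anti_sd, model = energy_model(), seed = NULL,
                             width = 12L, fixed = NULL, valid = NULL,
                             margin = 0.5, max_tries = 10000L) {
  target_class <- match.arg(target_class)
  anti_sd <- dna_to_rna(anti_sd)
  if (is.null(fixed)) fixed <- rep(NA_character_, width)
  stopifnot(length(fixed) == width)
  free <- which(is.na(fixed))
  # maximal runs of consecutive free positions, for core placement
  runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      win <- fixed
      win[free] <- sample(c("A", "C", "G", "T"), length(free), replace = TRUE)
      if (target_class != "none") {
        max_run <- max(c(0L, lengths(runs)))
        lens <- if (target_class == "strong_sd") 6:8 else 4:6
        lens <- lens[lens <= min(max_run, nchar(anti_sd))]
        if (!length(lens))
          stop("no free run long enough to place a '", target_class,
               "' core in the window (infeasible target)")
        core_len <- lens[sample.int(length(lens), 1)]
        from <- sample.int(nchar(anti_sd) - core_len + 1L, 1)
        core <- rna_to_dna(revcomp_rna(substr(anti_sd, from,
                                              from + core_len - 1L)))
        slots <- Filter(function(r) length(r) >= core_len, runs)
        run <- slots[[sample.int(length(slots), 1)]]
        at <- run[sample.int(length(run) - core_len + 1L, 1)]
        win[at:(at + core_len - 1L)] <- strsplit(core, "")[[1]]
      }
      wstr <- paste(win, collapse = "")
      dg <- duplex_delta_g(dna_to_rna(wstr), anti_sd, model)
      hit <- switch(target_class,
        none = dg > SD_THRESHOLD + margin,
        sd = dg < SD_THRESHOLD - margin & dg > STRONG_SD_THRESHOLD + margin,
        strong_sd = dg < STRONG_SD_THRESHOLD - margin)
      if (hit && (is.null(valid) || valid(wstr)))
        return(structure(wstr, delta_g = dg))
    }
    stop("could not sample a '", target_class, "' window in ", max_tries,
         " tries (infeasible target)")
  })
}

# random codon ending in A that is not a stop (for the penultimate codon
# ahead of an ATGA junction)
random_codon_end_a <- function() {
  pool <- paste0(do.call(paste0, expand.grid(c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T"),
                                             stringsAsFactors = FALSE)), "")
  pool <- paste0(pool, "A")
  pool <- setdiff(pool, STOP_CODONS)
  sample(pool, 1)
}

#' Generate a synthetic annotated genome with planted ground truth
#'
#' @param n_genes number of CDS (>= 2), all on the plus strand in one
#'   translation chain.
#' @param f_overlap4 fraction of junctions planted as 4-nt ATGA overlaps.
#' @param f_overlap1 fraction planted as 1-nt TGATG overlaps.
#' @param gap_mean mean of the geometric gap-length distribution (nt).
#' @param lead_mass probability that a gap junction instead draws
#'   `lead_gap + Geom(gap_mean)`, planting a leading gene.
#' @param lead_gap minimum gap (nt) of the planted leading-gene point mass.
#' @param sd_mix named probabilities for the planted SD class of each
#'   gene's upstream window (`none`, `sd`, `strong_sd`).
#' @param sd_margin safety margin (kcal/mol) from the SD class thresholds
#'   enforced by the window sampler.
#' @param gene_codons range of gene lengths in codons (including the stop).
#' @param seed integer seed; generation is a pure function of the
#'   parameters and the seed.
#' @return list with `genome` (a [Genome], circular, one 16S rRNA whose 3'
#'   tail carries an exact anti-SD) and `truth` (a manifest: planted
#'   junction table with types/gaps/distances, per-gene SD classes and
#'   energies, the seed and all parameters).
#' @export
generate_genome <- function(n_genes = 2000L, f_overlap4 = 0.15,
                            f_overlap1 = 0.05, gap_mean = 40,
                            lead_mass = 0.5, lead_gap = 200L,
                            sd_mix = c(none = 0.3, sd = 0.4, strong_sd = 0.3),
                            sd_margin = 0.5, gene_codons = c(30L, 80L),
                            seed = 1L) {
  if (f_overlap4 + f_overlap1 > 1) stop("overlap fractions exceed 1")
  if (n_genes < 2L) stop("need at least 2 genes")
  model <- energy_model()
  with_seed(seed, {
    n_j <- n_genes - 1L
    jtype <- sample(c("overlap4", "overlap1", "gap"), n_j, replace = TRUE,
                    prob = c(f_overlap4, f_overlap1, 1 - f_overlap4 - f_overlap1))
    gap <- integer(n_j)
    is_gap <- jtype == "gap"
    base <- rgeom(n_j, 1 / (gap_mean + 1))
    lead_draw <- runif(n_j) < lead_mass
    gap[is_gap] <- ifelse(lead_draw[is_gap],
                          lead_gap + base[is_gap], base[is_gap])
    gap[jtype == "overlap4"] <- -4L
    gap[jtype == "overlap1"] <- -1L

    len <- 3L * sample(gene_codons[1]:gene_codons[2], n_genes, replace = TRUE)
    starts <- integer(n_genes); ends <- integer(n_genes)
    starts[1] <- 300L
    ends[1] <- starts[1] + len[1]
    for (i in seq_len(n_j)) {
      starts[i + 1L] <- ends[i] + gap[i]
      ends[i + 1L] <- starts[i + 1L] + len[i + 1L]
    }
    rrna_start <- ends[n_genes] + 100L
    rrna_len <- 120L
    total <- rrna_start + rrna_len + 100L
    seqv <- sample(c("A", "C", "G", "T"), total, replace = TRUE)

    # --- write ORFs left to right, junction-aware -------------------------
    for (i in seq_len(n_genes)) {
      s <- starts[i]; e <- ends[i]
      shared <- if (i > 1L && jtype[i - 1L] == "overlap4") 4L
                else if (i > 1L && jtype[i - 1L] == "overlap1") 1L else 0L
      K <- len[i] %/% 3L
      for (k in seq_len(K)) {
        p0 <- s + 3L * (k - 1L)          # 0-based codon start
        if (p0 + 3L <= s + shared) next  # codon fully inside shared prefix
        codon <- if (k == 1L) "ATG"
          else if (k == K) "TGA"
          else if (k == K - 1L && i <= n_j && jtype[i] == "overlap4")
            random_codon_end_a()
          else random_codons(1)
        cchars <- strsplit(codon, "")[[1]]
        n_fixed <- max(0L, s + shared - p0)
        if (n_fixed > 0L) {
          # partially shared codon: keep the shared prefix, write the rest;
          # for the start codon the shared bases already spell the prefix
          # of ATG by junction construction
          have <- seqv[(p0 + 1L):(p0 + n_fixed)]
          if (k == 1L && !identical(have, cchars[seq_len(n_fixed)]))
            stop("internal error: junction bases do not spell a start codon")
          if (k > 1L) {
            cchars[seq_len(n_fixed)] <- have
            while (paste(cchars, collapse = "") %in% STOP_CODONS)
              cchars[(n_fixed + 1L):3L] <-
                sample(c("A", "C", "G", "T"), 3L - n_fixed, replace = TRUE)
          }
        }
        seqv[(p0 + 1L):(p0 + 3L)] <- cchars
      }
    }

    # --- 16S rRNA with an exact anti-SD tail ------------------------------
    tail13 <- strsplit("GATCACCTCCTTA", "")[[1]]
    seqv[(rrna_start + rrna_len - 12L):(rrna_start + rrna_len)] <- tail13
    anti <- find_anti_sd(dna_to_rna(paste(tail13, collapse = "")))$sequence

    # --- plant SD windows -------------------------------------------------
    sd_mix <- sd_mix / sum(sd_mix)
    sd_class <- sample(names(sd_mix), n_genes, replace = TRUE, prob = sd_mix)
    sd_dg <- numeric(n_genes)
    for (i in seq_len(n_genes)) {
      w_lo <- starts[i] - 12L            # 0-based half-open [w_lo, w_hi)
      w_hi <- starts[i]
      fixed <- rep(NA_character_, 12L)
      frame_check <- NULL
      if (i > 1L) {
        up_s <- starts[i - 1L]; up_e <- ends[i - 1L]
        # bases that may never change: the upstream stop codon and, for an
        # ATGA junction, the A completing the penultimate codon
        protect <- (up_e - 3L):(up_e - 1L)
        if (jtype[i - 1L] == "overlap4") protect <- c(up_e - 4L, protect)
        inside <- protect[protect >= w_lo & protect < w_hi]
        fixed[inside - w_lo + 1L] <- seqv[inside + 1L]
        # window positions inside the upstream ORF body: rewritable, but
        # the touched codons must stay stop-free
        if (w_lo < up_e - 3L && w_hi > up_s) {
          frame_check <- local({
            up_s0 <- up_s; up_e0 <- up_e; w_lo0 <- w_lo; w_hi0 <- w_hi
            sq <- seqv
            function(win) {
              sq[(w_lo0 + 1L):w_hi0] <- strsplit(win, "")[[1]]
              touched_lo <- max(w_lo0, up_s0)
              touched_hi <- min(w_hi0, up_e0 - 3L)
              k_first <- (touched_lo - up_s0) %/% 3L
              k_last <- (touched_hi - 1L - up_s0) %/% 3L
              for (kk in k_first:k_last) {
                cod <- paste(sq[(up_s0 + 3L * kk + 1L):(up_s0 + 3L * kk + 3L)],
                             collapse = "")
                if (cod %in% STOP_CODONS) return(FALSE)
              }
              TRUE
            }
          })
        }
      }
      # Feasibility of the target class given the junction-fixed bases:
      # a strong SD needs a >= 7-nt complementary core (6 WC stacks reach
      # only ~ -8.8 kcal/mol before the margin), an SD needs >= 4 free
      # contiguous positions. Short gaps (4-6 nt), whose windows straddle
      # the immovable upstream stop codon, are downgraded accordingly and
      # the class actually planted is what the truth manifest records.
      free_runs <- rle(is.na(fixed))
      max_run <- max(c(0L, free_runs$lengths[free_runs$values]))
      if (sd_class[i] == "strong_sd" && max_run < 7L) sd_class[i] <- "sd"
      if (sd_class[i] == "sd" && max_run < 4L) sd_class[i] <- "none"
      win <- sample_sd_window(sd_class[i], anti, model, seed = NULL,
                              fixed = fixed, valid = frame_check,
                              margin = sd_margin)
      seqv[(w_lo + 1L):w_hi] <- strsplit(win, "")[[1]]
      sd_dg[i] <- attr(win, "delta_g")
    }

    ids <- sprintf("g%04d", seq_len(n_genes))
    genes <- data.frame(
      gene_id = c(ids, "rrna16S_1"),
      kind = c(rep("CDS", n_genes), "rRNA_16S"),
      start = c(starts, rrna_start),
      end = c(ends, rrna_start + rrna_len),
      strand = "+",
      product = c(rep("hypothetical protein", n_genes), "16S ribosomal RNA"),
      stringsAsFactors = FALSE)
    genome <- Genome("synthetic_genome", paste(seqv, collapse = ""),
                     "circular", genes)
    truth <- list(
      seed = seed,
      params = list(n_genes = n_genes, f_overlap4 = f_overlap4,
                    f_overlap1 = f_overlap1, gap_mean = gap_mean,
                    lead_mass = lead_mass, lead_gap = lead_gap,
                    sd_mix = sd_mix, sd_margin = sd_margin,
                    gene_codons = gene_codons),
      junctions = data.frame(upstream = ids[-n_genes], downstream = ids[-1],
                             type = jtype, distance = gap,
                             stringsAsFactors = FALSE),
      sd = data.frame(gene_id = ids, sd_class = sd_class, delta_g = sd_dg,
                      stringsAsFactors = FALSE),
      anti_sd = anti)
    list(genome = genome, truth = truth)
  })
}

#' Generate a homolog family with a planted true start
#'
#' Builds an `MsaFamily` of a query plus `n_homologs` homolog rows in which
#' `concordant` homologs start exactly at the true start column and the
#' rest scatter elsewhere (too dispersed to form a competing consensus),
#' together with a small linear genome holding the query CDS whose
#' annotated start is displaced from the true one by `perturbation_nt`.
#' The true position carries an in-frame ATG and the span between true and
#' annotated start contains no other in-frame start codon, so the planted
#' start is exactly recoverable.
#'
#' @param n_homologs number of homolog rows (default 10).
#' @param concordant how many homologs start at the true start column.
#' @param perturbation_nt signed displacement of the annotated start from
#'   the true start, in nt (divisible by 3; positive = annotated start
#'   downstream of the true start).
#' @param true_start_column 0-based alignment column of the true start.
#' @param protein_len core protein length (residues from the true start).
#' @param seed optional integer seed.
#' @return list with `family` (an `MsaFamily`, query row id `"query"`),
#'   `genome` (a linear [Genome] with the query CDS) and `truth`
#'   (`true_start_nt`, `annotated_start_nt`, `perturbation_nt`,
#'   `concordant`).
#' @export
generate_homolog_family <- function(n_homologs = 10L, concordant = 8L,
                                    perturbation_nt = 6L,
                                    true_start_column = 6L,
                                    protein_len = 60L, seed = NULL) {
  if (concordant > n_homologs) stop("concordant exceeds n_homologs")
  if (perturbation_nt %% 3L != 0L)
    stop("perturbation_nt must be divisible by 3")
  k <- perturbation_nt %/% 3L
  c_t <- true_start_column
  if (c_t + k < 0L) stop("true_start_column too small for this perturbation")
  with_seed(seed, {
    aas <- setdiff(Biostrings::AA_STANDARD, c("M", "W"))
    n_col <- c_t + protein_len
    master <- sample(aas, n_col, replace = TRUE)   # residue per column
    master[c_t + 1L] <- "M"                        # true start
    q_c <- c_t + k

    blank <- function(from0) paste0(strrep("-", from0),
                                    paste(master[(from0 + 1L):n_col],
                                          collapse = ""))
    rows <- c(query = blank(q_c))
    conc_ids <- sprintf("hom_%02d", seq_len(concordant))
    for (id in conc_ids) rows[id] <- blank(c_t)
    n_disc <- n_homologs - concordant
    if (n_disc > 0L) {
      cand <- setdiff(seq(0L, n_col - 15L, by = 7L),
                      (c_t - 6L):(c_t + 6L))
      disc_cols <- sample(cand, n_disc)
      for (j in seq_len(n_disc))
        rows[sprintf("hom_%02d", concordant + j)] <- blank(disc_cols[j])
    }
    family <- msa_family(rows, query_id = "query")

    # nucleotide context: reverse-translate the annotated-or-true span with
    # start-codon control
    code <- Biostrings::GENETIC_CODE
    codons_for <- function(aa, exclude_starts = FALSE) {
      cods <- names(code)[code == aa]
      if (exclude_starts) cods <- setdiff(cods, DEFAULT_START_CODONS)
      cods
    }
    lo_col <- min(q_c, c_t)              # leftmost residue in the genome
    res_cols <- (lo_col + 1L):n_col      # 1-based indices into master
    codons <- vapply(seq_along(res_cols), function(j) {
      col0 <- res_cols[j] - 1L
      aa <- master[res_cols[j]]
      if (col0 == c_t) return("ATG")
      # between annotated and true start no in-frame start codon may occur
      contested <- (col0 > min(q_c, c_t) - 1L) && (col0 < max(q_c, c_t))
      pool <- codons_for(aa, exclude_starts = contested)
      sample(pool, 1)
    }, character(1))
    flank <- paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE),
                   collapse = "")
    orf <- paste(c(codons, "TGA"), collapse = "")
    sequence <- paste0(flank, orf, flank)
    true_start_nt <- 30L + 3L * (c_t - lo_col)
    annotated_start_nt <- 30L + 3L * (q_c - lo_col)
    gene_end <- 30L + nchar(orf)
    genes <- data.frame(gene_id = "query", kind = "CDS",
                        start = annotated_start_nt, end = gene_end,
                        strand = "+", product = "query protein",
                        stringsAsFactors = FALSE)
    genome <- Genome(paste0("family_ctx_", seed %||% "x"), sequence,
                     "linear", genes)
    list(family = family, genome = genome,
         truth = list(true_start_nt = true_start_nt,
                      annotated_start_nt = annotated_start_nt,
                      perturbation_nt = perturbation_nt,
                      concordant = concordant))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
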