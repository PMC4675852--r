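## Seeded synthetic-data generators. Each generator plants a known ground
## truth (recorded in a truth table) and builds inputs that exercise the
## consuming modules: proteomes with canonical tetraspanins among decoy
## classes that each violate exactly one identification rule, gene models
## with known intron phases, promoters with planted cis-elements on a
## motif-free background, position/anchor tables realizing planned
## tandem/segmental outcomes, and Cq tables with known log2 fold changes.

## residue alphabets chosen for the hydropathy and motif constraints:
## TM core strongly hydrophobic; loop/tail backbones hydrophilic with
## negative Kyte-Doolittle values (so predicted TM boundaries are sharp);
## extracellular backbones exclude C and G (no accidental cysteines or
## GCC signatures) and K/R (so the positive-inside heuristic is decided
## by the cytoplasmic segments).
TM_ALPHABET <- c("I", "L", "V", "F", "A", "M")
CYTO_ALPHABET <- c("D", "E", "N", "Q", "S", "T", "P", "H", "K", "R")
EXTRA_ALPHABET <- c("D", "E", "N", "Q", "S", "T", "P", "H")

#' Generator specification
#'
#' Bundles the seed and the plans shared by the synthetic generators. The
#' defaults describe the study conditions the pipeline is meant to
#' reproduce: a family of 15 tetraspanins hidden among 500 decoys (125
#' per decoy class), qPCR with 3 biological x 2 technical replicates and
#' Gaussian Cq noise of 0.1 cycles, and gene-architecture plans spanning
#' intron lengths 95-4200 bp.
#'
#' @param seed Integer seed; one deterministic stream per artifact is
#'   derived from it by fixed offsets.
#' @param n_tetraspanin Number of planted tetraspanins.
#' @param n_decoys Named integer vector of decoy counts per class
#'   (`wrong_tm`, `missing_motif`, `small_ec2`, `long_tails`).
#' @param cq_genes,cq_conditions,cq_sd,n_bio,n_tech qPCR plan; `cq_truth`
#'   may supply a genes x conditions log2 fold-change matrix (first
#'   condition is the control and must be zero), otherwise one is drawn
#'   uniformly from \[-4, 4\].
#' @return List of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, n_tetraspanin = 15L,
                           n_decoys = c(wrong_tm = 125L,
                                        missing_motif = 125L,
                                        small_ec2 = 125L,
                                        long_tails = 125L),
                           cq_genes = sprintf("TET%02d", 1:14),
                           cq_conditions = c("control", "heat", "salt",
                                             "cold", "drought",
                                             "oxidative"),
                           cq_truth = NULL, cq_sd = 0.1,
                           n_bio = 3L, n_tech = 2L) {
  structure(list(seed = as.integer(seed), n_tetraspanin = n_tetraspanin,
                 n_decoys = n_decoys, cq_genes = cq_genes,
                 cq_conditions = cq_conditions, cq_truth = cq_truth,
                 cq_sd = cq_sd, n_bio = n_bio, n_tech = n_tech),
            class = "generator_spec")
}

rand_residues <- function(n, alphabet) {
  if (n <= 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## place K/R content into a cytoplasmic segment (>= 2 basic residues)
cyto_segment <- function(n) {
  s <- strsplit(rand_residues(n, EXTRA_ALPHABET), "")[[1]]
  if (n >= 2L) {
    pos <- sample(n, min(n, max(2L, round(n / 5))))
    s[pos] <- sample(c("K", "R"), length(pos), replace = TRUE)
  }
  paste(s, collapse = "")
}

## EC2 with a given length, n_cys planted cysteines and optionally the
## signature motif; cysteines are kept >= 3 residues from the segment
## edges and mutually non-adjacent so that no GCC/CC context arises and
## TM boundary extension is unaffected
make_ec2 <- function(len, n_cys = 9L, with_motif = TRUE,
                     variant = c("K", "R")) {
  variant <- sample(variant, 1L)
  motif <- if (with_motif) paste0("SGCC", variant, "PP") else ""
  n_extra <- n_cys - if (with_motif) 2L else 0L
  backbone_len <- len - nchar(motif)
  s <- strsplit(rand_residues(backbone_len, EXTRA_ALPHABET), "")[[1]]
  # keep cysteines off the segment edges and non-adjacent when room
  # allows (they are hydrophobic, and CC runs are avoided elsewhere)
  margin <- if (backbone_len - 6L >= 2L * n_extra) 3L else 1L
  avail <- seq(1L + margin, backbone_len - margin)
  spacing <- if (length(avail) >= 2L * n_extra) 2L else 1L
  pos <- integer(0)
  guard <- 0L
  while (length(pos) < n_extra) {
    guard <- guard + 1L
    if (guard > 5000L) stop("cannot place EC2 cysteines")
    p <- sample(avail, 1L)
    if (all(abs(p - pos) >= spacing)) pos <- c(pos, p)
  }
  s[pos] <- "C"
  if (with_motif) {
    at <- sample(seq(4L, backbone_len - 3L), 1L)
    paste0(paste(s[seq_len(at - 1L)], collapse = ""), motif,
           paste(s[seq(at, backbone_len)], collapse = ""))
  } else paste(s, collapse = "")
}

## EC1: one planted cysteine, no K/R
make_ec1 <- function(len) {
  s <- strsplit(rand_residues(len, EXTRA_ALPHABET), "")[[1]]
  s[sample(seq(2L, len - 1L), 1L)] <- "C"
  paste(s, collapse = "")
}

build_protein <- function(id, class) {
  ntail <- sample(8:25, 1L)
  ec1 <- sample(13:18, 1L)
  icl <- sample(8:15, 1L)
  ec2 <- sample(85:95, 1L)
  ctail <- sample(10:40, 1L)
  tm_len <- 22L
  n_tm <- 4L
  with_motif <- TRUE
  if (class == "long_tails") ntail <- sample(70:90, 1L)
  if (class == "missing_motif") with_motif <- FALSE
  if (class == "small_ec2") { ec1 <- sample(24:28, 1L); ec2 <- 18L }
  if (class == "wrong_tm") n_tm <- sample(c(3L, 5L), 1L)
  tms <- replicate(n_tm, rand_residues(tm_len, TM_ALPHABET))
  loops <- character(n_tm - 1L)
  if (n_tm == 4L) {
    loops[1L] <- make_ec1(ec1)
    loops[2L] <- cyto_segment(icl)
    loops[3L] <- make_ec2(ec2, 9L, with_motif)
  } else {
    # alternating: odd loops extracellular, even cytoplasmic
    for (k in seq_len(n_tm - 1L)) {
      loops[k] <- if (k %% 2L == 1L) make_ec1(sample(13:18, 1L))
        else cyto_segment(sample(8:15, 1L))
    }
  }
  parts <- character(0)
  parts <- c(parts, cyto_segment(ntail))
  for (k in seq_len(n_tm)) {
    parts <- c(parts, tms[k])
    if (k < n_tm) parts <- c(parts, loops[k])
  }
  parts <- c(parts, cyto_segment(ctail))
  seq_txt <- paste(parts, collapse = "")
  # TM coordinates from the construction
  lens <- nchar(parts)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  tm_idx <- seq(2L, by = 2L, length.out = n_tm)
  segs <- cbind(start = starts[tm_idx],
                end = starts[tm_idx] + lens[tm_idx] - 1L)
  list(seq = seq_txt, segs = segs)
}

#' Generate a synthetic proteome with planted tetraspanins
#'
#' Tetraspanins are built to satisfy every identification rule: four
#' strongly hydrophobic 22-residue TM helices, a small EC1 with one
#' cysteine, a large EC2 (~90 aa) with nine cysteines and an embedded
#' `SGCC(K/R)PP` signature, basic (K/R-rich) cytoplasmic tails and loop,
#' N-terminus inside. Each decoy class violates exactly one rule:
#' `wrong_tm` (3 or 5 helices), `missing_motif` (no GCC core in EC2),
#' `small_ec2` (EC2 shorter than EC1, signature and cysteines intact),
#' `long_tails` (N-tail beyond the tail limit).
#'
#' @param spec A [generator_spec()].
#' @return List with `proteins` (a [read_fasta()]-shaped table),
#'   `topology` (named list of [topology_record()]s) and `truth`
#'   (data.frame: `protein_id`, `class`, `is_tetraspanin`,
#'   `expected_failed_rule`).
#' @export
make_proteome <- function(spec = generator_spec()) {
  set.seed(spec$seed + 1L)
  classes <- c(rep("tetraspanin", spec$n_tetraspanin),
               rep(names(spec$n_decoys), spec$n_decoys))
  ids <- c(sprintf("TET%03d", seq_len(spec$n_tetraspanin)),
           unlist(lapply(names(spec$n_decoys), function(cl)
             sprintf("DEC_%s_%03d", toupper(substr(cl, 1L, 2L)),
                     seq_len(spec$n_decoys[[cl]])))))
  rule_of <- c(tetraspanin = NA_character_, wrong_tm = "four_tm",
               missing_motif = "signature", small_ec2 = "ec2_gt_ec1",
               long_tails = "short_tails")
  seqs <- character(length(ids))
  topo <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- build_protein(ids[i], classes[i])
    seqs[i] <- p$seq
    topo[[i]] <- topology_record(ids[i], nchar(p$seq), p$segs, "inside")
  }
  names(topo) <- ids
  list(proteins = data.frame(id = ids, description = classes,
                             residues = seqs, stringsAsFactors = FALSE),
       topology = topo,
       truth = data.frame(protein_id = ids, class = classes,
                          is_tetraspanin = classes == "tetraspanin",
                          expected_failed_rule = unname(rule_of[classes]),
                          stringsAsFactors = FALSE))
}

## ---- annotation / genome -------------------------------------------------

## count overlapping occurrences of an IUPAC pattern on both strands with
## plain regexes -- the generator's own checker, independent of the
## Biostrings-based scanner it feeds
iupac_regex <- function(pattern) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
               B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
               N = "[ACGT]")
  paste(classes[strsplit(pattern, "")[[1]]], collapse = "")
}

count_motif_regex <- function(seq_txt, pattern) {
  n_of <- function(s, p) {
    m <- gregexpr(paste0("(?=", iupac_regex(p), ")"), s, perl = TRUE)[[1]]
    if (m[1L] == -1L) 0L else length(m)
  }
  n_of(seq_txt, pattern) + n_of(seq_txt, revcomp(pattern))
}

## pyrimidine background free of every dictionary motif on both strands
## (no A/G kills the forward patterns; forbidding TTT runs kills the
## only pyrimidine-only reverse complement)
motif_free_background <- function(n) {
  s <- character(n)
  tt <- 0L
  for (i in seq_len(n)) {
    ch <- if (tt >= 2L) "C" else sample(c("C", "T"), 1L)
    if (ch == "T") tt <- tt + 1L else tt <- 0L
    s[i] <- ch
  }
  paste(s, collapse = "")
}

## instantiate a pattern's ambiguity codes into a concrete sequence
instantiate_iupac <- function(pattern) {
  expand <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                 Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                 K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                 D = c("A", "G", "T"), H = c("A", "C", "T"),
                 V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(pattern, "")[[1]], function(ch)
    sample(expand[[ch]], 1L), character(1)), collapse = "")
}

## build a promoter window with planted motif occurrences at recorded
## offsets on a background free of every dictionary motif. Because some
## consensus strings are dyad-symmetric (HSE matches both strands of its
## own instances) or mutual reverse complements (the MeJA pair), the
## both-strand ground-truth counts are recomputed on the finished window
## with the generator's regex counter; plus-strand planted offsets are
## recorded separately.
planted_promoter <- function(len, plan, motifs, max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    bg <- motif_free_background(len)
    if (any(vapply(motifs$pattern, function(p)
      count_motif_regex(bg, p) > 0L, logical(1)))) next
    s <- strsplit(bg, "")[[1]]
    offsets <- list()
    used <- integer(0)
    ok <- TRUE
    for (mid in names(plan)) {
      pat <- motifs$pattern[motifs$motif_id == mid]
      w <- nchar(pat)
      offs <- integer(0)
      guard <- 0L
      while (length(offs) < plan[[mid]]) {
        guard <- guard + 1L
        if (guard > 500L) { ok <- FALSE; break }
        o <- sample.int(len - w + 1L, 1L)
        span <- seq(o - 2L, o + w + 1L)  # 2-bp margin between plants
        span <- span[span >= 1L & span <= len]
        if (any(span %in% used)) next
        inst <- instantiate_iupac(pat)
        s[seq(o, o + w - 1L)] <- strsplit(inst, "")[[1]]
        used <- c(used, span)
        offs <- c(offs, o)
      }
      if (!ok) break
      offsets[[mid]] <- sort(offs)
    }
    if (!ok) next
    txt <- paste(s, collapse = "")
    counts <- vapply(seq_len(nrow(motifs)), function(i)
      count_motif_regex(txt, motifs$pattern[i]), integer(1))
    names(counts) <- motifs$motif_id
    return(list(sequence = txt, offsets = offsets, counts = counts))
  }
  stop("could not realize promoter plan without collisions")
}

default_gene_plans <- function() {
  ## exon-length plans (bp, transcript order; all exons coding, totals
  ## divisible by 3) mirroring a small plant gene family: mostly
  ## two-exon genes, two intronless genes, one four-intron gene with
  ## phase multiset {0,0,1,2}, one ten-intron gene
  plans <- list(
    SYN01 = list(exons = c(402, 465), strand = "+"),
    SYN02 = list(exons = c(300, 513), strand = "-"),
    SYN03 = list(exons = c(99, 99, 100, 100, 745), strand = "+"),
    SYN04 = list(exons = c(825), strand = "+"),
    SYN05 = list(exons = c(444, 450), strand = "+"),
    SYN06 = list(exons = c(411, 447), strand = "-"),
    SYN07 = list(exons = c(501, 384), strand = "+"),
    SYN08 = list(exons = c(360, 507), strand = "+"),
    SYN09 = list(exons = c(390, 429), strand = "-"),
    SYN10 = list(exons = c(333, 477), strand = "+"),
    SYN11 = list(exons = c(486, 336), strand = "+"),
    SYN12 = list(exons = c(834), strand = "-"),
    SYN13 = list(exons = c(405, 426), strand = "+"),
    SYN14 = list(exons = c(81, 75, 72, 90, 66, 84, 78, 63, 69, 87, 148),
                 strand = "+"),
    SYN15 = list(exons = c(465, 468), strand = "-"))
  for (nm in names(plans)) {
    ex <- plans[[nm]]$exons
    n_int <- length(ex) - 1L
    plans[[nm]]$truth_phases <- if (n_int)
      cumsum(ex)[seq_len(n_int)] %% 3L else integer(0)
  }
  plans
}

default_motif_plans <- function() {
  list(SYN01 = list(ROOT = 10L),
       SYN02 = list(ABRE = 3L, HSE = 1L),
       SYN03 = list(ABRE = 1L, LTR = 2L),
       SYN04 = list(POLLEN1LELAT52 = 2L),
       SYN05 = list(MeJA_CGTCA = 1L, MeJA_TGACG = 1L),
       SYN06 = list(HSE = 2L),
       SYN07 = list(ABRE = 4L, ROOT = 1L),
       SYN08 = list(),
       SYN09 = list(LTR = 1L),
       SYN10 = list(ROOT = 3L, POLLEN1LELAT52 = 1L),
       SYN11 = list(ABRE = 3L),
       SYN12 = list(HSE = 1L, LTR = 1L),
       SYN13 = list(MeJA_CGTCA = 2L),
       SYN14 = list(ROOT = 2L),
       SYN15 = list(ABRE = 1L))
}

#' Generate a synthetic annotated genome
#'
#' Realizes exon-length plans as gene models on a synthetic chromosome
#' (both strands), plants cis-element motifs at recorded offsets in each
#' gene's 1-kb promoter on a motif-free background, and builds gene
#' position and colinearity-anchor tables realizing planned tandem and
#' segmental outcomes (including one pair separated by 7530 bp, one at
#' the 10-intervening-gene tandem boundary, one just beyond it, one
#' 5-anchor colinear block and one chain broken by a 600-kb gap).
#'
#' @param spec A [generator_spec()].
#' @param intron_range Intron length range in bp; the observed extremes
#'   (95 and 4200) are planted deterministically.
#' @return List with `genome` (named character), `models` (named list of
#'   [gene_model()]s), `positions`, `anchors` and `truth` (list:
#'   `phases`, `motif_offsets`, `tandem_pairs`, `not_tandem_pairs`,
#'   `segmental_genes`).
#' @export
make_annotation <- function(spec = generator_spec(),
                            intron_range = c(95L, 4200L)) {
  set.seed(spec$seed + 2L)
  plans <- default_gene_plans()
  motif_plans <- default_motif_plans()
  motifs <- default_motifs()
  promoter_len <- 1000L
  gap_between <- 1500L
  pos <- promoter_len + 200L
  chrom <- "chrA"
  pieces <- list()  # chromosome assembled left to right
  cursor <- 1L
  models <- list()
  truth_phases <- list()
  truth_offsets <- list()
  truth_counts <- list()
  emit <- function(txt) {
    pieces[[length(pieces) + 1L]] <<- txt
    cursor <<- cursor + nchar(txt)
  }
  first_short <- TRUE; first_long <- TRUE
  for (nm in names(plans)) {
    pl <- plans[[nm]]
    n_int <- length(pl$exons) - 1L
    introns <- integer(0)
    if (n_int > 0L) {
      introns <- sample(seq(intron_range[1L], intron_range[2L]), n_int,
                        replace = TRUE)
      if (first_short) { introns[1L] <- intron_range[1L]
        first_short <- FALSE }
      else if (first_long && n_int >= 1L) { introns[n_int] <- intron_range[2L]
        first_long <- FALSE }
    }
    # intergenic spacer up to the promoter
    spacer <- gap_between
    emit(rand_residues(spacer, c("A", "C", "G", "T")))
    prom <- planted_promoter(promoter_len, motif_plans[[nm]], motifs)
    truth_offsets[[nm]] <- prom$offsets
    truth_counts[[nm]] <- prom$counts
    gene_len <- sum(pl$exons) + sum(introns)
    if (pl$strand == "+") {
      emit(prom$sequence)
      gstart <- cursor
      emit(rand_residues(gene_len, c("A", "C", "G", "T")))
    } else {
      gstart <- cursor
      emit(rand_residues(gene_len, c("A", "C", "G", "T")))
      emit(revcomp(prom$sequence))
    }
    # exon coordinates in transcript order -> genomic
    ex_tx <- pl$exons
    if (pl$strand == "+") {
      starts <- gstart + cumsum(c(0L, head(ex_tx, -1L) + introns))
      exm <- cbind(start = starts, end = starts + ex_tx - 1L)
    } else {
      gend <- gstart + gene_len - 1L
      ends <- gend - cumsum(c(0L, head(ex_tx, -1L) + introns))
      exm <- cbind(start = ends - ex_tx + 1L, end = ends)
    }
    models[[paste0(nm, ".1")]] <- gene_model(nm, paste0(nm, ".1"), chrom,
                                             pl$strand, exm)
    truth_phases[[paste0(nm, ".1")]] <- pl$truth_phases
  }
  emit(rand_residues(500L, c("A", "C", "G", "T")))
  genome <- setNames(paste(unlist(pieces), collapse = ""), chrom)

  ## gene position table: planned tandem outcomes on bookkeeping
  ## chromosomes (coordinates only; no sequence needed)
  mk_gene_run <- function(chrom, ids, family, start = 10000L,
                          width = 2000L, gap = 3000L) {
    n <- length(ids)
    starts <- start + (seq_len(n) - 1L) * (width + gap)
    data.frame(gene_id = ids, chromosome = chrom, start = starts,
               end = starts + width - 1L, family_member = family,
               stringsAsFactors = FALSE)
  }
  t1 <- mk_gene_run("chrT1", c("FAM_A", "FAM_B"), c(TRUE, TRUE))
  # realize the 7530 bp intergenic gap between the adjacent pair
  t1$start[2L] <- t1$end[1L] + 7530L + 1L
  t1$end[2L] <- t1$start[2L] + 1999L
  t2 <- mk_gene_run("chrT2", c("FAM_C", sprintf("FIL_%02d", 1:10), "FAM_D"),
                    c(TRUE, rep(FALSE, 10L), TRUE))
  t3 <- mk_gene_run("chrT3", c("FAM_E", sprintf("FIL_%02d", 11:21), "FAM_F"),
                    c(TRUE, rep(FALSE, 11L), TRUE))
  positions <- rbind(t1, t2, t3)

  ## anchor table: a 5-anchor colinear block (spans < 500 kb) embedding
  ## the family pair FAM_G/FAM_H, and a 3-anchor chain broken by a
  ## 600-kb gap whose short side is discarded
  block <- data.frame(
    gene_a = c("A1", "A2", "FAM_G", "A4", "A5"),
    chr_a = "chrS1",
    pos_a = c(100000, 180000, 260000, 340000, 420000),
    gene_b = c("B1", "B2", "FAM_H", "B4", "B5"),
    chr_b = "chrS2",
    pos_b = c(500000, 580000, 660000, 740000, 820000),
    family = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  broken <- data.frame(
    gene_a = c("C1", "C2", "FAM_I"),
    chr_a = "chrS3",
    pos_a = c(100000, 200000, 800000),  # 600-kb gap before the pair
    gene_b = c("D1", "D2", "FAM_J"),
    chr_b = "chrS4",
    pos_b = c(100000, 200000, 800000),
    family = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  anchors <- rbind(block, broken)

  list(genome = genome, models = models, positions = positions,
       anchors = anchors,
       truth = list(phases = truth_phases, motif_offsets = truth_offsets,
                    motif_counts = truth_counts,
                    tandem_pairs = list(c("FAM_A", "FAM_B"),
                                        c("FAM_C", "FAM_D")),
                    not_tandem_pairs = list(c("FAM_E", "FAM_F")),
                    intergenic = list(FAM_A_FAM_B = 7530L),
                    segmental_genes = c("FAM_G", "FAM_H"),
                    not_segmental_genes = c("FAM_I", "FAM_J")))
}

## ---- qPCR ----------------------------------------------------------------

#' Generate a synthetic qPCR Cq table with known fold changes
#'
#' `Cq = baseline_gene + condition/replicate loading shift - true log2fc
#' + Normal(0, sd)`. The loading shift is shared by the reference gene,
#' so the delta-delta-Ct normalization removes it. The first condition of
#' the plan is the control (true log2fc 0).
#'
#' @param spec A [generator_spec()].
#' @return List with `cq` (a Cq data.frame: `gene_id`, `condition`,
#'   `bio_rep`, `tech_rep`, `cq`), `truth` (genes x conditions log2
#'   fold-change matrix), `reference_gene` and `pairing` (each condition
#'   mapped to the control).
#' @export
make_cq <- function(spec = generator_spec()) {
  set.seed(spec$seed + 3L)
  genes <- spec$cq_genes
  conds <- spec$cq_conditions
  ctrl <- conds[1L]
  truth <- spec$cq_truth
  if (is.null(truth)) {
    truth <- matrix(round(runif(length(genes) * length(conds), -4, 4), 2),
                    length(genes), length(conds),
                    dimnames = list(genes, conds))
    truth[, ctrl] <- 0
  } else {
    stopifnot(identical(rownames(truth), genes),
              identical(colnames(truth), conds),
              all(truth[, ctrl] == 0))
  }
  ref <- "eEF1a"
  baseline <- setNames(runif(length(genes), 22, 30), genes)
  base_ref <- 18
  shift <- matrix(rnorm(length(conds) * spec$n_bio, 0, 0.5),
                  length(conds), spec$n_bio,
                  dimnames = list(conds, NULL))
  rows <- list()
  for (cond in conds) for (b in seq_len(spec$n_bio))
    for (te in seq_len(spec$n_tech)) {
      cqs <- baseline[genes] + shift[cond, b] - truth[genes, cond] +
        rnorm(length(genes), 0, spec$cq_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = c(genes, ref), condition = cond, bio_rep = b,
        tech_rep = te,
        cq = c(cqs, base_ref + shift[cond, b] + rnorm(1, 0, spec$cq_sd)),
        stringsAsFactors = FALSE)
    }
  cq <- do.call(rbind, rows)
  rownames(cq) <- NULL
  list(cq = cq, truth = truth, reference_gene = ref,
       pairing = setNames(rep(ctrl, length(conds)), conds))
}

## ---- phylogeny fixtures --------------------------------------------------

#' Random additive distance matrix with its generating tree
#'
#' Draws a random binary topology over `n` taxa with branch lengths
#' uniform in `len_range` and returns the exact path-length (additive)
#' matrix together with the tree, for testing distance-based
#' reconstruction.
#'
#' @param n Number of taxa (>= 3).
#' @param len_range Branch-length range.
#' @return List with `tree` (`phylo`) and `d` (additive matrix).
#' @export
random_additive_matrix <- function(n, len_range = c(0.05, 1)) {
  tree <- ape::rtree(n, rooted = FALSE)
  tree$edge.length <- runif(nrow(tree$edge), len_range[1L], len_range[2L])
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  list(tree = tree, d = d[ord, ord])
}

#' Four-taxon alignment with a planted bipartition
#'
#' Builds an amino-acid alignment of `n_informative` columns supporting
#' the split AB|CD (A,B share one residue, C,D another) plus uniform
#' noise columns; `noise` is the per-column probability of randomizing
#' one of the four residues.
#'
#' @param n_informative Number of split-supporting columns.
#' @param noise Per-column disruption probability.
#' @param ids Taxon labels.
#' @return An [alignment()].
#' @export
planted_split_alignment <- function(n_informative = 200L, noise = 0.05,
                                    ids = c("A", "B", "C", "D")) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  cols <- matrix("", 4L, n_informative)
  for (j in seq_len(n_informative)) {
    pair <- sample(aa, 2L)
    col <- c(pair[1L], pair[1L], pair[2L], pair[2L])
    if (runif(1) < noise) {
      k <- sample(4L, 1L)
      col[k] <- sample(aa, 1L)
    }
    cols[, j] <- col
  }
  alignment(ids, apply(cols, 1L, paste, collapse = ""))
}
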