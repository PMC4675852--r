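## Intron statistics, intron phases, intron-to-domain mapping, and
## tandem/segmental duplication classification.

#' Introns of a gene model
#'
#' Introns are the gaps between consecutive exons, reported in 5'->3'
#' transcript order (strand-aware). The phase of a CDS-interrupting intron
#' is the cumulative CDS length 5' of the intron modulo 3; introns located
#' entirely in untranslated regions get `NA` phase. `protein_position` is
#' the codon index of the interrupted/adjacent codon
#' (`floor(cumulative/3) + 1`).
#'
#' @param model A [gene_model()].
#' @return data.frame with one row per intron: `gene_id`, `transcript_id`,
#'   `index`, `start`, `end`, `length`, `phase`, `protein_position`.
#' @export
introns_of <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  empty <- data.frame(gene_id = character(0), transcript_id = character(0),
                      index = integer(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      phase = integer(0), protein_position = integer(0))
  if (n < 2L) return(empty)
  istart <- ex[-n, "end"] + 1L
  iend <- ex[-1L, "start"] - 1L
  if (any(iend < istart))
    stop("adjacent/overlapping exons in ", model$transcript_id)
  # genomic order -> transcript order
  ord <- if (model$strand == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
  istart <- istart[ord]; iend <- iend[ord]
  total_cds <- model$cds_length
  cum <- vapply(seq_len(n - 1L), function(k) {
    cds_bases_5prime(model, istart[k], iend[k])
  }, integer(1))
  phase <- ifelse(cum > 0L & cum < total_cds, cum %% 3L, NA_integer_)
  ppos <- ifelse(is.na(phase), NA_integer_, cum %/% 3L + 1L)
  data.frame(gene_id = model$gene_id, transcript_id = model$transcript_id,
             index = seq_len(n - 1L), start = istart, end = iend,
             length = iend - istart + 1L, phase = as.integer(phase),
             protein_position = as.integer(ppos), stringsAsFactors = FALSE)
}

## CDS bases 5' (transcript sense) of the intron [istart, iend]
cds_bases_5prime <- function(model, istart, iend) {
  cds <- model$cds
  if (!nrow(cds)) return(0L)
  if (model$strand == "+") {
    sum(pmax(0L, pmin(cds[, "end"], istart - 1L) - cds[, "start"] + 1L))
  } else {
    sum(pmax(0L, cds[, "end"] - pmax(cds[, "start"], iend + 1L) + 1L))
  }
}

#' Census of intron phases across gene models
#'
#' @param models List of [gene_model()]s.
#' @return List with `totals` (named counts for phases 0/1/2 and
#'   `undefined`) and `per_gene` (data.frame of per-transcript counts).
#' @export
phase_census <- function(models) {
  totals <- c(`0` = 0L, `1` = 0L, `2` = 0L, undefined = 0L)
  rows <- list()
  for (m in models) {
    ir <- introns_of(m)
    ph <- ir$phase
    cnt <- c(`0` = sum(ph %in% 0L), `1` = sum(ph %in% 1L),
             `2` = sum(ph %in% 2L), undefined = sum(is.na(ph)))
    totals <- totals + cnt
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = m$gene_id, transcript_id = m$transcript_id,
      n_introns = nrow(ir), phase0 = cnt[["0"]], phase1 = cnt[["1"]],
      phase2 = cnt[["2"]], undefined = cnt[["undefined"]],
      stringsAsFactors = FALSE)
  }
  per_gene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), transcript_id = character(0),
               n_introns = integer(0), phase0 = integer(0),
               phase1 = integer(0), phase2 = integer(0),
               undefined = integer(0))
  list(totals = totals, per_gene = per_gene)
}

#' Map an intron to the protein domain it interrupts
#'
#' @param intron One row of an [introns_of()] result (needs
#'   `protein_position`).
#' @param region_model A [derive_regions()] result for the encoded
#'   protein.
#' @return The canonical region label containing the interrupted codon
#'   (falls back to the index-based segment name when canonical labels are
#'   withheld).
#' @export
map_intron_to_domain <- function(intron, region_model) {
  p <- intron$protein_position
  if (is.na(p)) return(NA_character_)
  if (p > region_model$length)
    stop("protein position ", p, " beyond protein length ",
         region_model$length)
  for (nm in names(region_model$regions)) {
    iv <- region_model$regions[[nm]]
    if (iv["end"] >= iv["start"] && p >= iv["start"] && p <= iv["end"])
      return(nm)
  }
  seg <- region_model$segments
  hit <- seg[seg$length > 0L & seg$start <= p & seg$end >= p, , drop = FALSE]
  if (nrow(hit)) paste0(hit$type[1L], hit$index[1L]) else NA_character_
}

#' Call tandem duplications from a gene position table
#'
#' Two family genes are tandem duplicates if they are on the same
#' chromosome and separated by at most `max_intervening` non-family genes
#' (boundary inclusive).
#'
#' @param table data.frame with `gene_id`, `chromosome`, `start`, `end`,
#'   `family_member` (logical).
#' @param max_intervening Maximum number of intervening unrelated genes
#'   (default 10).
#' @return data.frame of calls: `gene_a`, `gene_b`, `type = "tandem"`,
#'   `intervening`.
#' @export
call_tandem <- function(table, max_intervening = 10L) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end",
                  "family_member") %in% names(table)))
  out <- list()
  for (chrom in unique(table$chromosome)) {
    sub <- table[table$chromosome == chrom, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    fam <- which(sub$family_member)
    if (length(fam) < 2L) next
    for (a in seq_along(fam)[-length(fam)]) for (b in seq(a + 1L, length(fam))) {
      between <- seq(fam[a] + 1L, length.out = max(0L, fam[b] - fam[a] - 1L))
      interv <- sum(!sub$family_member[between])
      if (interv <= max_intervening)
        out[[length(out) + 1L]] <- data.frame(
          gene_a = sub$gene_id[fam[a]], gene_b = sub$gene_id[fam[b]],
          type = "tandem", intervening = interv, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      type = character(0), intervening = integer(0)))
  do.call(rbind, out)
}

#' Call segmental duplications from colinearity anchors
#'
#' Anchors are homologous gene pairs with positions on two chromosomal
#' regions. Chains of anchors with consistent relative order (both
#' orientations considered) and consecutive anchors at most `max_span`
#' apart on both chromosomes, of length at least `min_anchors`, define
#' colinear blocks; every family pair inside a block is called segmental.
#'
#' @param anchors data.frame with `gene_a`, `chr_a`, `pos_a`, `gene_b`,
#'   `chr_b`, `pos_b`, `family` (logical: is this anchor the family pair
#'   of interest).
#' @param max_span Maximum distance between colinear gene pairs (bp,
#'   default 500 kb), applied on both chromosomes.
#' @param min_anchors Minimum chain length (default 3).
#' @return data.frame of calls: `gene_a`, `gene_b`, `type = "segmental"`,
#'   `chain_length`, `span_a`, `span_b`.
#' @export
call_segmental <- function(anchors, max_span = 500000L, min_anchors = 3L) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      type = character(0), chain_length = integer(0),
                      span_a = numeric(0), span_b = numeric(0))
  if (!nrow(anchors)) return(empty)
  stopifnot(all(c("gene_a", "chr_a", "pos_a", "gene_b", "chr_b", "pos_b",
                  "family") %in% names(anchors)))
  out <- list()
  grp <- paste(anchors$chr_a, anchors$chr_b, sep = "\r")
  for (g in unique(grp)) {
    sub <- anchors[grp == g, , drop = FALSE]
    sub <- sub[order(sub$pos_a, sub$pos_b), , drop = FALSE]
    m <- nrow(sub)
    best <- rep(0L, m)
    for (orient in c(1, -1)) {
      link <- function(i, j)  # can j follow i in the chain?
        sub$pos_a[j] > sub$pos_a[i] &&
        sub$pos_a[j] - sub$pos_a[i] <= max_span &&
        orient * (sub$pos_b[j] - sub$pos_b[i]) > 0 &&
        abs(sub$pos_b[j] - sub$pos_b[i]) <= max_span
      f <- rep(1L, m)  # longest chain ending at i
      for (j in seq_len(m)) for (i in seq_len(j - 1L))
        if (link(i, j)) f[j] <- max(f[j], f[i] + 1L)
      gmax <- rep(1L, m)  # longest chain starting at i
      for (i in rev(seq_len(m))) for (j in seq(i + 1L, length.out = m - i))
        if (link(i, j)) gmax[i] <- max(gmax[i], gmax[j] + 1L)
      best <- pmax(best, f + gmax - 1L)
    }
    in_block <- best >= min_anchors
    fam <- which(in_block & sub$family)
    for (i in fam)
      out[[length(out) + 1L]] <- data.frame(
        gene_a = sub$gene_a[i], gene_b = sub$gene_b[i], type = "segmental",
        chain_length = best[i],
        span_a = diff(range(sub$pos_a[in_block])),
        span_b = diff(range(sub$pos_b[in_block])),
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Intergenic distance between two genes
#'
#' The number of bases strictly between the gene extents (1-based
#' inclusive convention); 0 if the genes overlap or abut.
#'
#' @param table Gene position table (as in [call_tandem()]).
#' @param a,b Gene ids.
#' @return Distance in bp.
#' @export
intergenic_distance <- function(table, a, b) {
  ra <- table[table$gene_id == a, , drop = FALSE]
  rb <- table[table$gene_id == b, , drop = FALSE]
  if (nrow(ra) != 1L || nrow(rb) != 1L) stop("gene ids not found uniquely")
  if (ra$chromosome != rb$chromosome)
    stop(a, " and ", b, " are on different chromosomes")
  gap <- max(ra$start, rb$start) - min(ra$end, rb$end) - 1L
  max(0L, gap)
}
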