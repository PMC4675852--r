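## Promoter window extraction and IUPAC cis-element scanning.

#' Extract the upstream promoter window of a gene
#'
#' Takes the region immediately 5' of the translation start site (the
#' first CDS base): on the plus strand `[coding_start - length,
#' coding_start - 1]`, on the minus strand `[coding_start + 1,
#' coding_start + length]` reverse-complemented, so the returned sequence
#' reads 5'->3' relative to the gene. Windows running off the contig are
#' truncated and flagged; a window entirely off the contig is an error.
#'
#' @param genome Named character vector or [read_fasta()] table of
#'   chromosome sequences (or a `Biostrings::DNAStringSet`).
#' @param model A [gene_model()] with a coding start.
#' @param length Window length in bp (default 1000).
#' @return A list of class `promoter_window`: `gene_id`, `chromosome`,
#'   `strand`, `start`, `end` (genomic), `sequence`, `truncated`.
#' @export
extract_promoter <- function(genome, model, length = 1000L) {
  seqs <- genome_as_character(genome)
  if (!model$chromosome %in% names(seqs))
    stop("chromosome ", model$chromosome, " not in genome")
  chrom_seq <- seqs[[model$chromosome]]
  clen <- nchar(chrom_seq)
  cs <- model$coding_start
  if (is.na(cs)) stop("gene model ", model$transcript_id,
                      " has no coding start")
  if (model$strand == "+") {
    gstart <- cs - length; gend <- cs - 1L
  } else {
    gstart <- cs + 1L; gend <- cs + length
  }
  truncated <- FALSE
  if (gend < 1L || gstart > clen)
    stop("promoter window for ", model$transcript_id,
         " lies entirely off the contig")
  if (gstart < 1L) { gstart <- 1L; truncated <- TRUE }
  if (gend > clen) { gend <- clen; truncated <- TRUE }
  s <- substr(chrom_seq, gstart, gend)
  if (model$strand == "-")
    s <- revcomp(s)
  structure(list(gene_id = model$gene_id, chromosome = model$chromosome,
                 strand = model$strand, start = unname(gstart),
                 end = unname(gend),
                 sequence = toupper(s), truncated = truncated),
            class = "promoter_window")
}

genome_as_character <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.data.frame(genome)) {
    setNames(genome$residues, genome$id)
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome must be named")
    genome
  } else stop("unsupported genome object")
}

#' Reverse complement of a DNA string
#' @param x DNA string (IUPAC codes allowed).
#' @return Reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan a promoter window for cis-element motifs
#'
#' Reports every occurrence of every IUPAC pattern, overlaps allowed, on
#' the requested strand(s). A minus-strand hit is an occurrence of the
#' reverse complement of the pattern in the window; its offset is still
#' reported on the window's own 5'->3' axis. Hits are ordered by offset,
#' then motif id, then strand.
#'
#' @param window A [extract_promoter()] result (or a plain string).
#' @param motifs A motif dictionary ([read_motifs()] / [default_motifs()]).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param overlap If `FALSE`, overlapping occurrences of the same motif
#'   are collapsed leftmost-greedily.
#' @return data.frame of hits: `gene_id`, `motif_id`, `offset` (1-based),
#'   `strand`, `matched`.
#' @export
scan_motifs <- function(window, motifs, strands = c("both", "+", "-"),
                        overlap = TRUE) {
  strands <- match.arg(strands)
  if (!nrow(motifs)) stop("motif dictionary is empty")
  seq_txt <- if (is.character(window)) window else window$sequence
  gene_id <- if (is.character(window)) NA_character_ else window$gene_id
  subj <- Biostrings::DNAString(seq_txt)
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    pat_txt <- motifs$pattern[i]
    bad <- setdiff(strsplit(pat_txt, "")[[1]], IUPAC_DNA)
    if (length(bad))
      stop("invalid IUPAC code '", bad[1L], "' in motif ",
           motifs$motif_id[i])
    want <- list()
    if (strands %in% c("both", "+")) want[["+"]] <- pat_txt
    if (strands %in% c("both", "-")) want[["-"]] <- revcomp(pat_txt)
    for (st in names(want)) {
      m <- Biostrings::matchPattern(Biostrings::DNAString(want[[st]]),
                                    subj, fixed = FALSE)
      if (!length(m)) next
      offs <- Biostrings::start(m)
      if (!overlap && length(offs) > 1L) {
        keep <- offs[1L]
        for (o in offs[-1L])
          if (o > keep[length(keep)] + nchar(pat_txt) - 1L)
            keep <- c(keep, o)
        m <- m[offs %in% keep]
        offs <- keep
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gene_id, motif_id = motifs$motif_id[i], offset = offs,
        strand = st, matched = as.character(m), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      matched = character(0)))
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$offset, hits$motif_id, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Gene-by-motif occurrence count matrix
#'
#' @param windows List of [extract_promoter()] windows.
#' @param motifs A motif dictionary.
#' @param ... Passed to [scan_motifs()].
#' @return Integer matrix, genes in rows, motifs in columns; row sums
#'   equal the per-gene hit counts.
#' @export
element_matrix <- function(windows, motifs, ...) {
  genes <- unname(vapply(windows, `[[`, character(1), "gene_id"))
  m <- matrix(0L, length(windows), nrow(motifs),
              dimnames = list(genes, motifs$motif_id))
  for (i in seq_along(windows)) {
    hits <- scan_motifs(windows[[i]], motifs, ...)
    if (nrow(hits)) {
      tb <- table(hits$motif_id)
      m[i, names(tb)] <- as.integer(tb)
    }
  }
  m
}

#' Genes with at least k copies of a motif
#'
#' @param mat An [element_matrix()].
#' @param motif_id Motif column.
#' @param k Minimum count.
#' @return Character vector of gene ids.
#' @export
genes_with_motif <- function(mat, motif_id, k = 1L) {
  if (!motif_id %in% colnames(mat)) stop("unknown motif ", motif_id)
  unname(sort(rownames(mat)[mat[, motif_id] >= k]))
}
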