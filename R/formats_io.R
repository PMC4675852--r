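## Readers and writers for the external formats the pipeline touches.
## Every other module consumes only the in-memory types produced here.
## Coordinates are 1-based inclusive everywhere (GFF3 convention).

#' Read a FASTA file into a sequence table
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @param type `"AA"` or `"DNA"`; controls alphabet validation only.
#' @return A data.frame with columns `id`, `description`, `residues`
#'   (uppercase, whitespace-free). One row per record.
#' @details Headers are `>id description`; the id is the first whitespace
#'   token. Duplicate ids and malformed headers are errors (the offending
#'   line number is reported).
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA format error: empty file: ", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA format error at line ", first, ": expected '>' header")
  hdr <- which(startsWith(trimws(lines), ">"))
  ids <- character(length(hdr))
  desc <- character(length(hdr))
  for (k in seq_along(hdr)) {
    h <- sub("^>", "", trimws(lines[hdr[k]]))
    if (!nzchar(h))
      stop("FASTA format error at line ", hdr[k], ": empty header")
    ids[k] <- sub("\\s.*$", "", h)
    desc[k] <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  bounds <- c(hdr, length(lines) + 1L)
  residues <- vapply(seq_along(hdr), function(k) {
    body <- lines[seq(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    if (bounds[k + 1L] - 1L < hdr[k] + 1L) body <- character(0)
    toupper(gsub("\\s", "", paste(body, collapse = "")))
  }, character(1))
  empty <- which(!nzchar(residues))
  if (length(empty))
    stop("empty sequence for id(s): ", paste(ids[empty], collapse = ", "))
  data.frame(id = ids, description = desc, residues = residues,
             stringsAsFactors = FALSE)
}

#' Write a sequence table as FASTA
#'
#' @param seqs data.frame with `id`, `residues` and optional `description`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    d <- if ("description" %in% names(seqs) && nzchar(seqs$description[i]))
      paste0(" ", seqs$description[i]) else ""
    writeLines(paste0(">", seqs$id[i], d), con)
    s <- seqs$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## ---- topology -------------------------------------------------------------

#' Construct a transmembrane topology record
#'
#' @param protein_id Protein identifier.
#' @param length Protein length in residues.
#' @param tm_segments Integer matrix with columns `start`, `end` (1-based
#'   inclusive), one row per TM helix, sorted 5'->3'.
#' @param n_terminus_side `"inside"`, `"outside"`, or `NA` if unknown.
#' @return An object of class `topology_record`.
#' @export
topology_record <- function(protein_id, length, tm_segments,
                            n_terminus_side = NA_character_) {
  tm_segments <- matrix(as.integer(tm_segments), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))
  if (nrow(tm_segments)) {
    o <- order(tm_segments[, "start"])
    tm_segments <- tm_segments[o, , drop = FALSE]
    if (any(tm_segments[, "start"] < 1L) || any(tm_segments[, "end"] > length))
      stop("topology coordinate error for ", protein_id,
           ": TM segment outside [1, ", length, "]")
    if (any(tm_segments[, "end"] < tm_segments[, "start"]))
      stop("topology invariant error for ", protein_id,
           ": segment end before start")
    if (nrow(tm_segments) > 1L &&
        any(tm_segments[-1L, "start"] <= tm_segments[-nrow(tm_segments), "end"]))
      stop("topology invariant error for ", protein_id,
           ": overlapping TM segments")
  }
  if (!is.na(n_terminus_side) &&
      !n_terminus_side %in% c("inside", "outside"))
    stop("n_terminus_side must be 'inside', 'outside' or NA")
  structure(list(protein_id = protein_id, length = as.integer(length),
                 tm_segments = tm_segments,
                 n_terminus_side = n_terminus_side),
            class = "topology_record")
}

#' Read transmembrane topology predictions
#'
#' @param path Path to a topology file.
#' @param dialect `"tsv"` (the canonical exchange format: columns
#'   `protein_id`, `length`, `tm_segments` as `start-end;start-end;...`,
#'   `n_terminus_side`) or `"tmhmm_long"` (best-effort import of the
#'   long-format text emitted by the TMHMM predictor, with per-region
#'   `inside` / `TMhelix` / `outside` rows; the N-terminus side is the label
#'   of the first region).
#' @return A named list of [topology_record()] objects.
#' @export
read_topology <- function(path, dialect = c("tsv", "tmhmm_long")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("protein_id", "length", "tm_segments", "n_terminus_side")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("topology tsv missing column(s): ", paste(miss, collapse = ", "))
    recs <- lapply(seq_len(nrow(tab)), function(i) {
      segs <- parse_segments(tab$tm_segments[i])
      topology_record(tab$protein_id[i], tab$length[i], segs,
                      tab$n_terminus_side[i])
    })
  } else {
    recs <- parse_tmhmm_long(path)
  }
  names(recs) <- vapply(recs, `[[`, character(1), "protein_id")
  if (anyDuplicated(names(recs)))
    stop("duplicate protein id(s) in topology file")
  recs
}

parse_segments <- function(txt) {
  txt <- trimws(txt)
  if (!nzchar(txt) || txt == "-")
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  m <- t(vapply(parts, function(p) {
    se <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
    if (length(se) != 2L || anyNA(se))
      stop("cannot parse TM segment '", p, "'")
    se
  }, integer(2)))
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

parse_tmhmm_long <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty TMHMM file: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  ok <- vapply(fields, length, integer(1)) >= 4L
  if (!all(ok)) stop("malformed TMHMM line: ", lines[which(!ok)[1]])
  prot <- vapply(fields, `[[`, character(1), 1L)
  lab <- vapply(fields, function(f) f[[length(f) - 2L]], character(1))
  from <- as.integer(vapply(fields, function(f) f[[length(f) - 1L]],
                            character(1)))
  to <- as.integer(vapply(fields, function(f) f[[length(f)]], character(1)))
  lapply(split(seq_along(prot), factor(prot, levels = unique(prot))),
         function(idx) {
           lab_i <- lab[idx]; from_i <- from[idx]; to_i <- to[idx]
           o <- order(from_i)
           lab_i <- lab_i[o]; from_i <- from_i[o]; to_i <- to_i[o]
           tm <- lab_i == "TMhelix"
           side <- if (lab_i[1L] %in% c("inside", "outside"))
             lab_i[1L] else NA_character_
           topology_record(prot[idx[1L]], max(to_i),
                           cbind(start = from_i[tm], end = to_i[tm]), side)
         })
}

#' Write topology records in the canonical tsv dialect
#'
#' @param topos Named list of [topology_record()]s.
#' @param path Output path.
#' @export
write_topology <- function(topos, path) {
  rows <- vapply(topos, function(tp) {
    segs <- if (nrow(tp$tm_segments))
      paste(tp$tm_segments[, "start"], tp$tm_segments[, "end"],
            sep = "-", collapse = ";") else "-"
    paste(tp$protein_id, tp$length, segs, tp$n_terminus_side, sep = "\t")
  }, character(1))
  writeLines(c("protein_id\tlength\ttm_segments\tn_terminus_side", rows), path)
  invisible(path)
}

## ---- GFF3 gene models -----------------------------------------------------

#' Construct a gene model
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chromosome Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Integer matrices with columns `start`, `end`, 1-based
#'   inclusive genomic coordinates, non-overlapping. Sorted internally by
#'   genomic position.
#' @return An object of class `gene_model`. `coding_start` is the genomic
#'   coordinate of the first CDS base (strand-aware); `cds_complete` flags
#'   whether total CDS length is divisible by 3.
#' @export
gene_model <- function(gene_id, transcript_id, chromosome, strand,
                       exons, cds = exons) {
  if (!strand %in% c("+", "-")) stop("unknown strand '", strand,
                                     "' for ", transcript_id)
  fix <- function(m, what) {
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    m <- m[order(m[, "start"]), , drop = FALSE]
    if (any(m[, "start"] < 1L) || any(m[, "end"] < m[, "start"]))
      stop("invalid ", what, " interval in ", transcript_id)
    if (nrow(m) > 1L && any(m[-1L, "start"] <= m[-nrow(m), "end"]))
      stop("overlapping ", what, " intervals in ", transcript_id)
    m
  }
  exons <- fix(exons, "exon")
  cds <- if (is.null(cds) || !length(cds))
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  else fix(cds, "CDS")
  cds_len <- sum(cds[, "end"] - cds[, "start"] + 1L)
  coding_start <- if (!nrow(cds)) NA_integer_
    else if (strand == "+") unname(cds[1L, "start"])
    else unname(cds[nrow(cds), "end"])
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chromosome = chromosome, strand = strand,
                 exons = exons, cds = cds, coding_start = coding_start,
                 cds_length = cds_len, cds_complete = cds_len %% 3L == 0L),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Expects the standard gene -> mRNA -> exon/CDS hierarchy. Each transcript
#' yields its own gene model, so genes with several splice forms contribute
#' one model per form.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of [gene_model()] objects (names are transcript ids).
#' @export
read_gff3 <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$type <- as.character(g$type)
  g$strand <- as.character(g$strand)
  tx <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (!nrow(tx)) stop("no mRNA/transcript features in ", path)
  parent_of <- function(row) {
    p <- unlist(row$Parent)
    if (!length(p)) NA_character_ else p[[1L]]
  }
  children <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]
  tx_ids <- as.character(tx$ID)
  child_parents <- vapply(seq_len(nrow(children)), function(i)
    parent_of(children[i, ]), character(1))
  orphan <- which(!child_parents %in% tx_ids)
  if (length(orphan))
    stop("orphan ", children$type[orphan[1L]], " feature at ",
         children$seqid[orphan[1L]], ":", children$start[orphan[1L]],
         " (parent '", child_parents[orphan[1L]], "' not found)")
  models <- lapply(seq_len(nrow(tx)), function(i) {
    tid <- tx_ids[i]
    gid <- parent_of(tx[i, ])
    if (is.na(gid)) gid <- tid
    kid <- children[child_parents == tid, , drop = FALSE]
    ex <- kid[kid$type == "exon", c("start", "end"), drop = FALSE]
    cd <- kid[kid$type == "CDS", c("start", "end"), drop = FALSE]
    if (!nrow(ex)) stop("transcript ", tid, " has no exons")
    strand <- as.character(tx$strand[i])
    if (!strand %in% c("+", "-"))
      stop("unknown strand '", strand, "' for ", tid)
    gene_model(gid, tid, as.character(tx$seqid[i]), strand,
               as.matrix(ex), if (nrow(cd)) as.matrix(cd) else NULL)
  })
  names(models) <- tx_ids
  models
}

#' Write gene models as GFF3
#'
#' @param models List of [gene_model()]s.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  by_gene <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  for (gid in names(by_gene)) {
    ms <- by_gene[[gid]]
    chrom <- ms[[1L]]$chromosome
    strand <- ms[[1L]]$strand
    span <- range(unlist(lapply(ms, function(m) m$exons)))
    writeLines(sprintf("%s\ttetmine\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       chrom, span[1L], span[2L], strand, gid), con)
    for (m in ms) {
      writeLines(sprintf(
        "%s\ttetmine\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        chrom, min(m$exons[, "start"]), max(m$exons[, "end"]),
        strand, m$transcript_id, gid), con)
      for (i in seq_len(nrow(m$exons)))
        writeLines(sprintf("%s\ttetmine\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                           chrom, m$exons[i, "start"], m$exons[i, "end"],
                           strand, m$transcript_id), con)
      ph <- cds_phase_column(m)
      for (i in seq_len(nrow(m$cds)))
        writeLines(sprintf("%s\ttetmine\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                           chrom, m$cds[i, "start"], m$cds[i, "end"],
                           strand, ph[i], m$transcript_id), con)
    }
  }
  invisible(path)
}

## GFF3 phase column for CDS rows (genomic order), strand-aware.
cds_phase_column <- function(m) {
  n <- nrow(m$cds)
  if (!n) return(integer(0))
  lens <- m$cds[, "end"] - m$cds[, "start"] + 1L
  tx_order <- if (m$strand == "+") seq_len(n) else rev(seq_len(n))
  cum <- c(0L, cumsum(lens[tx_order]))[seq_len(n)]
  phase_tx <- (3L - (cum %% 3L)) %% 3L
  out <- integer(n)
  out[tx_order] <- phase_tx
  out
}

## ---- Newick ---------------------------------------------------------------

#' Serialize a phylogenetic tree to a Newick string
#'
#' @param tree An `ape::phylo` object (internal node labels, when present,
#'   are written as support values).
#' @return A single Newick string, terminated by `;`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Parse a Newick string or file
#'
#' @param text A Newick string, or `NULL` if `path` is given.
#' @param path Optional path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) && is.null(path)) stop("supply text or path")
  if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
}

## ---- qPCR Cq tables -------------------------------------------------------

#' Read a qPCR Cq table
#'
#' @param path CSV with header columns `gene_id`, `condition`, `bio_rep`,
#'   `tech_rep`, `cq` (an optional `timepoint` column is preserved; fold
#'   timepoints into the condition label before [ddct()] if they are to be
#'   treated as separate conditions).
#' @return A data.frame (class `cq_table`).
#' @export
read_cq <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "condition", "bio_rep", "tech_rep", "cq")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("Cq table missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(tab$cq)) {
    bad <- suppressWarnings(is.na(as.numeric(tab$cq))) & !is.na(tab$cq)
    if (any(bad))
      stop("non-numeric cq value(s), e.g. '", tab$cq[which(bad)[1L]], "'")
    tab$cq <- as.numeric(tab$cq)
  }
  if (any(!is.finite(tab$cq))) stop("non-finite cq value(s)")
  class(tab) <- c("cq_table", "data.frame")
  tab
}

#' Write a Cq table as CSV
#' @param cq A Cq data.frame.
#' @param path Output path.
#' @export
write_cq <- function(cq, path) {
  write.csv(as.data.frame(cq), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- motif dictionaries ---------------------------------------------------

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Read a cis-element motif dictionary
#'
#' @param path TSV with header columns `motif_id`, `pattern` (IUPAC
#'   nucleotide codes), `category` (e.g. hormone / stress / tissue).
#' @return A data.frame (class `motif_dictionary`).
#' @export
read_motifs <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("motif_id", "pattern", "category")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("motif dictionary missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$motif_id))
    stop("duplicate motif id(s): ",
         paste(unique(tab$motif_id[duplicated(tab$motif_id)]), collapse = ", "))
  tab$pattern <- toupper(tab$pattern)
  for (i in seq_len(nrow(tab))) {
    bad <- setdiff(strsplit(tab$pattern[i], "")[[1]], IUPAC_DNA)
    if (length(bad))
      stop("invalid IUPAC code '", bad[1L], "' in motif ", tab$motif_id[i])
  }
  class(tab) <- c("motif_dictionary", "data.frame")
  tab
}

#' Write a motif dictionary as TSV
#' @param motifs A motif dictionary data.frame.
#' @param path Output path.
#' @export
write_motifs <- function(motifs, path) {
  write.table(as.data.frame(motifs), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Bundled default cis-element dictionary
#'
#' Canonical PLACE-style consensus strings for the six element classes most
#' relevant to abiotic-stress and tissue-specific regulation: ABRE, HSE, the
#' LTR low-temperature core, the MeJA-responsive pair CGTCA/TGACG, the root
#' motif and POLLEN1LELAT52. Shipped as an editable TSV under `extdata`.
#'
#' @return A motif dictionary data.frame.
#' @export
default_motifs <- function() {
  read_motifs(system.file("extdata", "motifs_place.tsv",
                          package = "tetmine", mustWork = TRUE))
}
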