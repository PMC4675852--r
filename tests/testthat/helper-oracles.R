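# Independent oracles and small fixture builders used across the suite.

aa_seq_row <- function(id, residues)
  data.frame(id = id, description = "", residues = residues,
             stringsAsFactors = FALSE)

# brute-force residue-by-residue sidedness labeler: walk the protein,
# flipping sides at every TM segment boundary
walk_labeler <- function(len, segs, n_side) {
  lab <- character(len)
  side <- n_side
  i <- 1L
  while (i <= len) {
    k <- which(segs[, "start"] <= i & i <= segs[, "end"])
    if (length(k)) {
      lab[i] <- "membrane"
      if (i == segs[k, "end"])
        side <- if (side == "inside") "outside" else "inside"
      i <- i + 1L
    } else {
      lab[i] <- side
      i <- i + 1L
    }
  }
  lab
}

# exhaustive global alignment score under affine gaps (tiny inputs only)
brute_force_align_score <- function(a, b, mat, gap_open, gap_extend) {
  ax <- strsplit(a, "")[[1]]
  bx <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ax) && j > length(bx)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ax) && j <= length(bx))
      rec(i + 1L, j + 1L, score + mat[ax[i], bx[j]], "m")
    if (i <= length(ax))
      rec(i + 1L, j, score - if (state == "x") gap_extend
          else gap_open + gap_extend, "x")
    if (j <= length(bx))
      rec(i, j + 1L, score - if (state == "y") gap_extend
          else gap_open + gap_extend, "y")
  }
  rec(1L, 1L, 0, "m")
  best
}

# per-base spliced-CDS walk: cumulative CDS length at each exon junction
phase_oracle <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) return(integer(0))
  ord <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  cds <- model$cds
  in_cds <- function(p) nrow(cds) > 0 &&
    any(cds[, "start"] <= p & p <= cds[, "end"])
  count <- 0L
  cums <- integer(0)
  for (k in seq_along(ord)) {
    e <- ex[ord[k], ]
    positions <- if (model$strand == "+") e[["start"]]:e[["end"]]
      else e[["end"]]:e[["start"]]
    for (p in positions) if (in_cds(p)) count <- count + 1L
    if (k < n) cums <- c(cums, count)
  }
  total <- count
  ifelse(cums > 0L & cums < total, cums %% 3L, NA_integer_)
}

# random fully-coding gene model for property tests
random_gene_model <- function(id = "g") {
  n_ex <- sample(1:6, 1L)
  lens <- sample(30:300, n_ex, replace = TRUE)
  lens[n_ex] <- lens[n_ex] + (3L - sum(lens) %% 3L) %% 3L
  introns <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE)
    else integer(0)
  strand <- sample(c("+", "-"), 1L)
  gstart <- sample(1000:5000, 1L)
  # genomic coordinates, exon order given in transcript order then sorted
  tx_lens <- lens
  if (strand == "+") {
    starts <- gstart + cumsum(c(0L, head(tx_lens, -1L) + introns))
    ex <- cbind(start = starts, end = starts + tx_lens - 1L)
  } else {
    ends <- gstart + sum(tx_lens) + sum(introns) - 1L -
      cumsum(c(0L, head(tx_lens, -1L) + introns))
    ex <- cbind(start = ends - tx_lens + 1L, end = ends)
  }
  gene_model(id, paste0(id, ".1"), "chr1", strand, ex)
}

# mirror a gene model onto the opposite strand of a reverse-complemented
# chromosome of length L
mirror_model <- function(model, L) {
  mir <- function(m) {
    out <- cbind(start = L + 1L - m[, "end"], end = L + 1L - m[, "start"])
    out[order(out[, "start"]), , drop = FALSE]
  }
  gene_model(model$gene_id, model$transcript_id, model$chromosome,
             if (model$strand == "+") "-" else "+",
             mir(model$exons), mir(model$cds))
}

# brute-force colinear chain membership: is each anchor contained in some
# order-consistent chain of length >= min_anchors (both orientations,
# consecutive anchors within max_span on both chromosomes)?
brute_force_in_block <- function(anchors, max_span, min_anchors) {
  m <- nrow(anchors)
  sub <- anchors[order(anchors$pos_a, anchors$pos_b), , drop = FALSE]
  ok_chain <- function(idx, orient) {
    if (length(idx) < 2L) return(TRUE)
    for (k in seq_along(idx)[-1L]) {
      i <- idx[k - 1L]; j <- idx[k]
      if (!(sub$pos_a[j] > sub$pos_a[i] &&
            sub$pos_a[j] - sub$pos_a[i] <= max_span &&
            orient * (sub$pos_b[j] - sub$pos_b[i]) > 0 &&
            abs(sub$pos_b[j] - sub$pos_b[i]) <= max_span))
        return(FALSE)
    }
    TRUE
  }
  in_block <- rep(FALSE, m)
  for (mask in seq_len(2^m - 1L)) {
    idx <- which(as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L))))
    if (length(idx) < min_anchors) next
    if (ok_chain(idx, 1) || ok_chain(idx, -1)) in_block[idx] <- TRUE
  }
  stats::setNames(in_block, sub$gene_a)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# relabel a topology record (for duplicating a protein under a new id)
within_id <- function(tp, id) {
  tp$protein_id <- id
  tp
}
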