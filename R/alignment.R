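## Pairwise and progressive protein alignment, identity/similarity
## percentages and per-domain conservation.
##
## Pairwise optimal global alignment (affine gaps) is delegated to
## Biostrings; the progressive multiple aligner merges profiles along a
## neighbor-joining guide tree with sum-of-pairs scoring.

#' Construct an alignment object
#'
#' @param ids Sequence identifiers (unique).
#' @param rows Aligned rows, equal length, gap character `-`.
#' @return Object of class `alignment`.
#' @export
alignment <- function(ids, rows) {
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  if (length(unique(nchar(rows))) > 1L)
    stop("aligned rows have unequal lengths")
  if (anyDuplicated(ids)) stop("duplicate ids in alignment")
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 ncol = if (length(rows)) nchar(rows[1L]) else 0L),
            class = "alignment")
}

#' Remove gaps from an aligned row
#' @param x Character vector of aligned rows.
#' @return Ungapped sequences.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)

## BLOSUM62 extended with zero scores for any residue letters absent from
## the matrix (unknown residues are neutral, with a warning at use site).
substitution_matrix <- function(name = "BLOSUM62", extra_letters = NULL) {
  mat <- get(data(list = name, package = "Biostrings",
                  envir = environment()), envir = environment())
  extra <- setdiff(extra_letters, rownames(mat))
  if (length(extra)) {
    n <- nrow(mat)
    big <- matrix(0, n + length(extra), n + length(extra),
                  dimnames = list(c(rownames(mat), extra),
                                  c(colnames(mat), extra)))
    big[seq_len(n), seq_len(n)] <- mat
    mat <- big
  }
  mat
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, delegated
#' to [Biostrings::pairwiseAlignment()].
#'
#' @param a,b Protein sequences (plain strings or single rows of a
#'   [read_fasta()] table).
#' @param matrix_name Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param ids Optional length-2 identifier vector.
#' @return An [alignment()] with two rows and a `score` attribute.
#' @export
align_pair <- function(a, b, matrix_name = "BLOSUM62", gap_open = 10,
                       gap_extend = 0.5, ids = NULL) {
  pick <- function(x, default_id) {
    if (is.list(x) || is.data.frame(x)) list(id = x$id, seq = x$residues)
    else list(id = default_id, seq = as.character(x))
  }
  A <- pick(a, "seq1"); B <- pick(b, "seq2")
  if (!is.null(ids)) { A$id <- ids[1L]; B$id <- ids[2L] }
  if (!nzchar(A$seq) || !nzchar(B$seq))
    stop("align_pair requires non-empty sequences")
  letters_seen <- unique(strsplit(paste0(A$seq, B$seq), "")[[1]])
  mat <- substitution_matrix(matrix_name)
  unknown <- setdiff(letters_seen, rownames(mat))
  if (length(unknown)) {
    warning("unknown residue(s) ", paste(unknown, collapse = ", "),
            " scored as neutral (0)")
    mat <- substitution_matrix(matrix_name, letters_seen)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(A$seq), Biostrings::AAString(B$seq),
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  aln <- alignment(c(A$id, B$id),
                   c(as.character(Biostrings::alignedPattern(pa)),
                     as.character(Biostrings::alignedSubject(pa))))
  attr(aln, "score") <- Biostrings::score(pa)
  aln
}

#' Percent identity and similarity of a pairwise alignment
#'
#' Identity counts columns with identical non-gap residues; similarity
#' additionally counts columns whose residue pair has a positive
#' substitution score. Columns containing a gap are never identical or
#' similar.
#'
#' @param aln A two-row [alignment()].
#' @param denominator `"alignment_length"` (default), `"shorter_seq"` or
#'   `"mean_length"`.
#' @param matrix_name Substitution matrix used for the similarity call.
#' @return Named numeric vector `c(identity =, similarity =)` in percent.
#' @export
percent_identity_similarity <- function(aln,
                                        denominator = c("alignment_length",
                                                        "shorter_seq",
                                                        "mean_length"),
                                        matrix_name = "BLOSUM62") {
  denominator <- match.arg(denominator)
  if (length(aln$rows) != 2L)
    stop("percent_identity_similarity requires a 2-row alignment")
  x <- strsplit(aln$rows[1L], "")[[1]]
  y <- strsplit(aln$rows[2L], "")[[1]]
  both <- x != "-" & y != "-"
  ident <- sum(both & x == y)
  mat <- substitution_matrix(matrix_name, unique(c(x, y)))
  pos <- both & mat[cbind(match(x, rownames(mat)),
                          match(y, rownames(mat)))] > 0
  simil <- sum(pos)
  lens <- nchar(ungap(aln$rows))
  den <- switch(denominator,
                alignment_length = aln$ncol,
                shorter_seq = min(lens),
                mean_length = mean(lens))
  c(identity = 100 * ident / den, similarity = 100 * simil / den)
}

#' All-pairs identity and similarity matrices
#'
#' @param seqs A [read_fasta()] table.
#' @param denominator Passed to [percent_identity_similarity()].
#' @param ... Passed to [align_pair()].
#' @return List with symmetric `identity` and `similarity` percentage
#'   matrices (diagonal 100) and `mean_identity` / `mean_similarity`, the
#'   off-diagonal averages.
#' @export
similarity_matrix <- function(seqs, denominator = "alignment_length", ...) {
  n <- nrow(seqs)
  ids <- seqs$id
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  sim <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      aln <- align_pair(seqs[i, ], seqs[j, ], ...)
      v <- percent_identity_similarity(aln, denominator)
      idm[i, j] <- idm[j, i] <- v[["identity"]]
      sim[i, j] <- sim[j, i] <- v[["similarity"]]
    }
  }
  off <- upper.tri(idm)
  list(ids = ids, identity = idm, similarity = sim,
       mean_identity = if (any(off)) mean(idm[off]) else NA_real_,
       mean_similarity = if (any(off)) mean(sim[off]) else NA_real_)
}

## ---- progressive multiple alignment --------------------------------------

## residue frequency count matrix of a profile (rows = letters incl '-')
profile_counts <- function(rows, letters) {
  L <- nchar(rows[1L])
  m <- matrix(0L, length(letters), L, dimnames = list(letters, NULL))
  for (r in rows) {
    ch <- strsplit(r, "")[[1]]
    idx <- match(ch, letters)
    m[cbind(idx, seq_len(L))] <- m[cbind(idx, seq_len(L))] + 1L
  }
  m
}

## sum-of-pairs profile-profile affine alignment; deterministic tie-break
## diagonal > up (gap in B) > left (gap in A)
profile_align <- function(A, B, mat, gap_open, gap_extend) {
  letters <- rownames(mat)
  fa <- profile_counts(A$rows, c(letters, "-"))[letters, , drop = FALSE]
  fb <- profile_counts(B$rows, c(letters, "-"))[letters, , drop = FALSE]
  na <- length(A$rows); nb <- length(B$rows)
  S <- t(fa) %*% mat %*% fb / (na * nb)
  L1 <- ncol(fa); L2 <- ncol(fb)
  NEG <- -1e18
  M <- matrix(NEG, L1 + 1L, L2 + 1L)
  X <- matrix(NEG, L1 + 1L, L2 + 1L)  # ends with column from A only
  Y <- matrix(NEG, L1 + 1L, L2 + 1L)  # ends with column from B only
  M[1L, 1L] <- 0
  if (L1 >= 1L) X[-1L, 1L] <- -gap_open - gap_extend * (seq_len(L1) - 1L)
  if (L2 >= 1L) Y[1L, -1L] <- -gap_open - gap_extend * (seq_len(L2) - 1L)
  tbM <- matrix(0L, L1 + 1L, L2 + 1L)
  tbX <- matrix(0L, L1 + 1L, L2 + 1L)
  tbY <- matrix(0L, L1 + 1L, L2 + 1L)
  for (i in seq_len(L1) + 1L) {
    for (j in seq_len(L2) + 1L) {
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      k <- which.max(prev)
      M[i, j] <- prev[k] + S[i - 1L, j - 1L]
      tbM[i, j] <- k
      xv <- c(M[i - 1L, j] - gap_open, X[i - 1L, j] - gap_extend)
      k <- which.max(xv)
      X[i, j] <- xv[k]; tbX[i, j] <- k
      yv <- c(M[i, j - 1L] - gap_open, Y[i, j - 1L] - gap_extend)
      k <- which.max(yv)
      Y[i, j] <- yv[k]; tbY[i, j] <- k
    }
  }
  tbX[, 1L] <- 2L
  tbY[1L, ] <- 2L
  i <- L1 + 1L; j <- L2 + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  takeA <- integer(0); takeB <- integer(0)  # 1 = consume column, 0 = gap
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      takeA <- c(1L, takeA); takeB <- c(1L, takeB)
      state <- tbM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      takeA <- c(1L, takeA); takeB <- c(0L, takeB)
      state <- c(1L, 2L)[tbX[i, j]]  # came from M or X
      i <- i - 1L
    } else {
      takeA <- c(0L, takeA); takeB <- c(1L, takeB)
      state <- c(1L, 3L)[tbY[i, j]]  # came from M or Y
      j <- j - 1L
    }
  }
  merge_rows <- function(rows, take) {
    chs <- lapply(rows, function(r) strsplit(r, "")[[1]])
    vapply(chs, function(ch) {
      out <- character(length(take))
      out[take == 0L] <- "-"
      out[take == 1L] <- ch
      paste(out, collapse = "")
    }, character(1))
  }
  alignment(c(A$ids, B$ids),
            c(merge_rows(A$rows, takeA), merge_rows(B$rows, takeB)))
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences by profile-profile merges with sum-of-pairs scoring
#' along a guide tree (neighbor-joining on pairwise p-distances unless one
#' is supplied). Column order is deterministic given the inputs.
#'
#' @param seqs A [read_fasta()] table.
#' @param guide Optional `ape::phylo` guide tree with tip labels matching
#'   `seqs$id`.
#' @param matrix_name,gap_open,gap_extend Scoring parameters.
#' @return An [alignment()] with rows in input order.
#' @export
align_progressive <- function(seqs, guide = NULL, matrix_name = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5) {
  n <- nrow(seqs)
  if (n < 1L) stop("no sequences")
  if (n == 1L) return(alignment(seqs$id, seqs$residues))
  letters_seen <- unique(unlist(strsplit(seqs$residues, "")))
  mat <- substitution_matrix(matrix_name, letters_seen)
  leaf <- function(i) alignment(seqs$id[i], seqs$residues[i])
  if (n == 2L) {
    out <- align_pair(seqs[1L, ], seqs[2L, ], matrix_name, gap_open,
                      gap_extend)
  } else {
    if (is.null(guide)) {
      sm <- similarity_matrix(seqs, matrix_name = matrix_name,
                              gap_open = gap_open, gap_extend = gap_extend)
      d <- 1 - sm$identity / 100
      guide <- nj_tree(d)
    }
    out <- align_by_tree(guide, seqs, mat, gap_open, gap_extend)
  }
  ord <- match(seqs$id, out$ids)
  alignment(out$ids[ord], out$rows[ord])
}

align_by_tree <- function(tree, seqs, mat, gap_open, gap_extend) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  rec <- function(node) {
    if (node <= ntip) {
      i <- match(tree$tip.label[node], seqs$id)
      return(alignment(seqs$id[i], seqs$residues[i]))
    }
    kids <- edge[edge[, 1L] == node, 2L]
    subs <- lapply(kids, rec)
    # deterministic merge order: by smallest contained id
    subs <- subs[order(vapply(subs, function(a) min(a$ids), character(1)))]
    Reduce(function(A, B) profile_align(A, B, mat, gap_open, gap_extend),
           subs)
  }
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  rec(root)
}

## ---- per-domain conservation ---------------------------------------------

#' Mean pairwise identity per canonical region
#'
#' Maps each sequence's region intervals through the alignment to columns,
#' takes the union of columns per region, and scores mean pairwise percent
#' identity over those columns (pairs lacking the region are skipped and
#' counted).
#'
#' @param aln An [alignment()].
#' @param region_models Named list of [derive_regions()] results covering
#'   the aligned ids.
#' @return data.frame with `region`, `mean_identity`, `n_pairs`,
#'   `n_columns`.
#' @export
domain_identity <- function(aln, region_models) {
  n <- length(aln$ids)
  chs <- lapply(aln$rows, function(r) strsplit(r, "")[[1]])
  # residue index -> column map per sequence
  col_of <- lapply(chs, function(ch) which(ch != "-"))
  out <- list()
  for (reg in REGION_NAMES) {
    cols <- integer(0)
    has <- logical(n)
    for (i in seq_len(n)) {
      rmod <- region_models[[aln$ids[i]]]
      if (is.null(rmod)) stop("no region model for ", aln$ids[i])
      iv <- rmod$regions[[reg]]
      if (is.null(iv) || iv["end"] < iv["start"]) next
      has[i] <- TRUE
      cols <- union(cols, col_of[[i]][iv["start"]:iv["end"]])
    }
    cols <- sort(cols)
    pid <- c(); npairs <- 0L
    if (length(cols) && sum(has) >= 2L) {
      idx <- which(has)
      for (a in seq_along(idx)[-length(idx)])
        for (b in seq(a + 1L, length(idx))) {
          x <- chs[[idx[a]]][cols]; y <- chs[[idx[b]]][cols]
          ident <- sum(x != "-" & y != "-" & x == y)
          pid <- c(pid, 100 * ident / length(cols))
          npairs <- npairs + 1L
        }
    }
    out[[reg]] <- data.frame(region = reg,
                             mean_identity = if (npairs) mean(pid) else NA_real_,
                             n_pairs = npairs, n_columns = length(cols),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
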