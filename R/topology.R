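## Region model derivation and the tetraspanin identification rule cascade.
##
## The canonical tetraspanin architecture: cytoplasmic N-tail, TM1, EC1
## (small extracellular loop), TM2, ICL (small intracellular loop), TM3,
## EC2 (large, cysteine-rich extracellular loop with the GCCK/RP
## signature), TM4, cytoplasmic C-tail.

REGION_NAMES <- c("Ntail", "TM1", "EC1", "TM2", "ICL", "TM3", "EC2",
                  "TM4", "Ctail")

#' Derive the region model of a membrane protein
#'
#' Splits the protein into tails, TM helices and inter-TM loops, assigning
#' membrane sidedness by alternation starting from the N-terminus side.
#' For 4-TM proteins the extracellular loops receive the canonical `EC1`
#' and `EC2` labels and the intracellular loop `ICL`; under the canonical
#' tetraspanin orientation (N-terminus inside) EC1 is the TM1-TM2 loop and
#' EC2 the TM3-TM4 loop, and `orientation_ok` is `TRUE`. With the
#' N-terminus outside only one loop is extracellular, the canonical
#' labelling is impossible and `orientation_ok` is `FALSE`. For proteins
#' with a TM count other than 4, EC/ICL labels are withheld and only the
#' index-based segmentation is reported.
#'
#' @param seq One row of a [read_fasta()] table (or a list with `id` and
#'   `residues`).
#' @param topo A [topology_record()] for the same protein.
#' @return An object of class `region_model` with elements `protein_id`,
#'   `length`, `n_tm`, `n_terminus_side`, `orientation_ok`, `segments`
#'   (a data.frame tiling `[1, length]`: type, index, start, end, length,
#'   side) and `regions` (named list of `c(start, end)` for canonical
#'   labels; zero-length segments have `end < start` and are flagged in
#'   `zero_length`).
#' @export
derive_regions <- function(seq, topo) {
  if (!identical(seq$id, topo$protein_id))
    stop("sequence id '", seq$id, "' does not match topology id '",
         topo$protein_id, "'")
  len <- nchar(seq$residues)
  if (len != topo$length)
    stop("sequence length (", len, ") differs from topology length (",
         topo$length, ") for ", seq$id)
  tm <- topo$tm_segments
  n_tm <- nrow(tm)
  side0 <- topo$n_terminus_side
  segs <- list()
  add <- function(type, index, start, end, side) {
    segs[[length(segs) + 1L]] <<- data.frame(
      type = type, index = index, start = start, end = end,
      length = max(0L, end - start + 1L), side = side,
      stringsAsFactors = FALSE)
  }
  if (n_tm == 0L) {
    add("tail", 1L, 1L, len, if (is.na(side0)) NA_character_ else side0)
  } else {
    flip <- function(s) if (is.na(s)) NA_character_
      else if (s == "inside") "outside" else "inside"
    side <- side0
    add("tail", 1L, 1L, tm[1L, "start"] - 1L, side)
    for (k in seq_len(n_tm)) {
      add("tm", k, tm[k, "start"], tm[k, "end"], "membrane")
      side <- flip(side)
      if (k < n_tm) add("loop", k, tm[k, "end"] + 1L,
                        tm[k + 1L, "start"] - 1L, side)
    }
    add("tail", 2L, tm[n_tm, "end"] + 1L, len, side)
  }
  segments <- do.call(rbind, segs)
  regions <- list()
  orientation_ok <- FALSE
  if (n_tm == 4L && !is.na(side0)) {
    iv <- function(type, index) {
      r <- segments[segments$type == type & segments$index == index, ]
      c(start = r$start, end = r$end)
    }
    regions[["Ntail"]] <- iv("tail", 1L)
    regions[["Ctail"]] <- iv("tail", 2L)
    for (k in 1:4) regions[[paste0("TM", k)]] <- iv("tm", k)
    loops <- segments[segments$type == "loop", , drop = FALSE]
    ec <- which(loops$side == "outside")
    ic <- which(loops$side == "inside")
    if (side0 == "inside") {
      regions[["EC1"]] <- iv("loop", 1L)
      regions[["ICL"]] <- iv("loop", 2L)
      regions[["EC2"]] <- iv("loop", 3L)
      orientation_ok <- TRUE
    } else {
      # one extracellular loop only: EC1 gets it, EC2 is undefined
      if (length(ec)) regions[["EC1"]] <- iv("loop", loops$index[ec[1L]])
      if (length(ic)) regions[["ICL"]] <- iv("loop", loops$index[ic[1L]])
    }
  }
  zero_length <- segments$length == 0L
  structure(list(protein_id = seq$id, length = len, n_tm = n_tm,
                 n_terminus_side = side0, orientation_ok = orientation_ok,
                 segments = segments, regions = regions,
                 zero_length = any(zero_length)),
            class = "region_model")
}

region_seq <- function(residues, interval) {
  if (is.null(interval) || interval["end"] < interval["start"]) return("")
  substr(residues, interval["start"], interval["end"])
}

region_len <- function(interval) {
  if (is.null(interval)) return(NA_integer_)
  max(0L, interval["end"] - interval["start"] + 1L)
}

#' Score tetraspanin-diagnostic features of a protein
#'
#' Computes region lengths, cysteine counts in EC1/EC2, the EC2 signature
#' (the long form `SGCC[KR]PP` when present, otherwise the `GCC[KR]P` core),
#' N-glycosylation sequons (`N-{P}-[S/T]`) within EC2, and cysteines within
#' `w` residues of a TM boundary on the cytoplasmic side (candidate
#' palmitoylation sites; a sequence heuristic, not a trained predictor).
#'
#' @param rm A [derive_regions()] result.
#' @param seq The matching sequence row.
#' @param w Juxtamembrane window in residues (default 5).
#' @return An object of class `feature_report`.
#' @export
score_features <- function(rm, seq, w = 5L) {
  if (!identical(rm$protein_id, seq$id))
    stop("region model and sequence ids differ")
  res <- seq$residues
  r <- rm$regions
  ec2 <- region_seq(res, r[["EC2"]])
  ec1 <- region_seq(res, r[["EC1"]])
  count_c <- function(s) if (!nzchar(s)) 0L
    else sum(strsplit(s, "")[[1]] == "C")
  sig <- list(type = "absent", position = NA_integer_)
  if (nzchar(ec2)) {
    m_long <- regexpr("SGCC[KR]PP", ec2)
    m_core <- regexpr("GCC[KR]P", ec2)
    ec2_start <- unname(r[["EC2"]]["start"])
    if (m_long > 0) {
      sig <- list(type = "SGCC[KR]PP",
                  position = ec2_start + as.integer(m_long) - 1L)
    } else if (m_core > 0) {
      sig <- list(type = "GCC[KR]P",
                  position = ec2_start + as.integer(m_core) - 1L)
    }
  }
  sequons <- integer(0)
  if (nzchar(ec2)) {
    m <- gregexpr("N(?=[^P][ST])", ec2, perl = TRUE)[[1]]
    if (m[1L] > 0)
      sequons <- unname(r[["EC2"]]["start"]) + as.integer(m) - 1L
  }
  jux <- integer(0)
  if (rm$n_tm > 0L) {
    cyto <- rm$segments[!is.na(rm$segments$side) &
                          rm$segments$side == "inside" &
                          rm$segments$length > 0L, , drop = FALSE]
    tmrows <- rm$segments[rm$segments$type == "tm", , drop = FALSE]
    bounds <- c(tmrows$start, tmrows$end)
    cpos <- which(strsplit(res, "")[[1]] == "C")
    for (i in seq_len(nrow(cyto))) {
      inseg <- cpos[cpos >= cyto$start[i] & cpos <= cyto$end[i]]
      near <- inseg[vapply(inseg, function(p)
        any(abs(p - bounds) <= w), logical(1))]
      jux <- c(jux, near)
    }
    jux <- sort(unique(jux))
  }
  structure(list(
    protein_id = rm$protein_id,
    n_tm = rm$n_tm,
    ntail_len = region_len(r[["Ntail"]]),
    ctail_len = region_len(r[["Ctail"]]),
    ec1_len = region_len(r[["EC1"]]),
    icl_len = region_len(r[["ICL"]]),
    ec2_len = region_len(r[["EC2"]]),
    ec1_cys = if (is.null(r[["EC1"]])) NA_integer_ else count_c(ec1),
    ec2_cys = if (is.null(r[["EC2"]])) NA_integer_ else count_c(ec2),
    signature = sig,
    sequons = sequons,
    juxtamembrane_cys = jux,
    orientation_ok = rm$orientation_ok,
    side_known = !is.na(rm$n_terminus_side)
  ), class = "feature_report")
}

#' Rule configuration for the identification cascade
#'
#' @param cys_min Minimum cysteines in EC2 (default 9; the canonical count).
#' @param tail_max Maximum N-/C-terminal tail length in residues
#'   (default 60).
#' @param signature_mode `"core"` accepts the `GCC[KR]P` core (default);
#'   `"strict"` requires the long `SGCC[KR]PP` form.
#' @param strict_cys If `TRUE`, require exactly `cys_min` EC2 cysteines
#'   instead of at least.
#' @param enabled Character vector of enabled rule names, a subset of
#'   `c("four_tm", "ec2_gt_ec1", "ec2_cys", "signature", "short_tails",
#'   "orientation")`. Each rule is independently switchable.
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(cys_min = 9L, tail_max = 60L,
                        signature_mode = c("core", "strict"),
                        strict_cys = FALSE,
                        enabled = c("four_tm", "ec2_gt_ec1", "ec2_cys",
                                    "signature", "short_tails",
                                    "orientation")) {
  signature_mode <- match.arg(signature_mode)
  all_rules <- c("four_tm", "ec2_gt_ec1", "ec2_cys", "signature",
                 "short_tails", "orientation")
  bad <- setdiff(enabled, all_rules)
  if (length(bad)) stop("unknown rule(s): ", paste(bad, collapse = ", "))
  structure(list(cys_min = cys_min, tail_max = tail_max,
                 signature_mode = signature_mode, strict_cys = strict_cys,
                 enabled = enabled),
            class = "rule_config")
}

#' Classify a feature report as tetraspanin or rejected
#'
#' Applies the rule cascade: (1) exactly four TM helices; (2) EC2 longer
#' than EC1; (3) at least `cys_min` cysteines in EC2; (4) the EC2 signature
#' present; (5) both tails at most `tail_max` residues; (6) canonical
#' membrane orientation (loops between TM1-TM2 and TM3-TM4 extracellular).
#' A rule whose inputs are undefined for the protein (e.g. EC2 length when
#' the TM count is not 4) is recorded as not evaluable rather than failed,
#' but a protein with any non-evaluable enabled rule cannot be accepted.
#'
#' @param report A [score_features()] result.
#' @param rules A [rule_config()].
#' @return List with `verdict` (`"tetraspanin"` or `"rejected"`),
#'   `failed` (ordered character vector of failed rule names) and
#'   `not_evaluable`.
#' @export
classify <- function(report, rules = rule_config()) {
  checks <- list(
    four_tm = function(r) r$n_tm == 4L,
    ec2_gt_ec1 = function(r)
      if (is.na(r$ec2_len) || is.na(r$ec1_len)) NA else r$ec2_len > r$ec1_len,
    ec2_cys = function(r)
      if (is.na(r$ec2_cys)) NA
      else if (rules$strict_cys) r$ec2_cys == rules$cys_min
      else r$ec2_cys >= rules$cys_min,
    signature = function(r) {
      if (is.na(r$ec2_len)) return(NA)  # EC2 undefined
      if (rules$signature_mode == "strict")
        r$signature$type == "SGCC[KR]PP"
      else r$signature$type != "absent"
    },
    short_tails = function(r)
      if (is.na(r$ntail_len) || is.na(r$ctail_len)) NA
      else r$ntail_len <= rules$tail_max && r$ctail_len <= rules$tail_max,
    orientation = function(r)
      if (r$n_tm != 4L) NA else isTRUE(r$orientation_ok)
  )
  failed <- character(0)
  not_eval <- character(0)
  for (nm in rules$enabled) {
    ok <- checks[[nm]](report)
    if (is.na(ok)) not_eval <- c(not_eval, nm)
    else if (!ok) failed <- c(failed, nm)
  }
  verdict <- if (length(failed) == 0L && length(not_eval) == 0L)
    "tetraspanin" else "rejected"
  list(verdict = verdict, failed = failed, not_evaluable = not_eval)
}

#' Mine a proteome for tetraspanin candidates
#'
#' Runs [derive_regions()], [score_features()] and [classify()] over every
#' protein with a topology prediction and reports the identification
#' funnel: total proteins, proteins with at least one TM helix, proteins
#' with exactly four, and proteins passing the full cascade. Proteins with
#' unknown N-terminus sidedness are scored under both orientations and the
#' better verdict kept (flagged in the report). An optional
#' annotation-keyword track intersects the topology-based candidates with
#' proteins whose annotation text matches a keyword.
#'
#' @param seqs A [read_fasta()] table.
#' @param topos Named list of [topology_record()]s (missing proteins are
#'   counted as excluded at the first stage).
#' @param rules A [rule_config()].
#' @param keywords Optional character vector of annotation keywords.
#' @param annotations Optional named character vector (protein id ->
#'   annotation text) used with `keywords`.
#' @return List with `candidates` (character vector of accepted ids, sorted),
#'   `reports` (per-protein data.frame with verdicts and failed rules) and
#'   `funnel` (named integer vector).
#' @export
mine_proteome <- function(seqs, topos, rules = rule_config(),
                          keywords = NULL, annotations = NULL) {
  n <- nrow(seqs)
  funnel <- c(total = n, with_topology = 0L, with_tm = 0L, four_tm = 0L,
              passed = 0L)
  if (n == 0L)
    return(list(candidates = character(0),
                reports = data.frame(protein_id = character(0),
                                     n_tm = integer(0),
                                     verdict = character(0),
                                     failed = character(0),
                                     side_assumed = logical(0)),
                funnel = funnel))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- seqs$id[i]
    tp <- topos[[id]]
    if (is.null(tp)) {
      rows[[i]] <- data.frame(protein_id = id, n_tm = NA_integer_,
                              verdict = "rejected", failed = "no_topology",
                              side_assumed = FALSE, stringsAsFactors = FALSE)
      next
    }
    funnel["with_topology"] <- funnel["with_topology"] + 1L
    n_tm <- nrow(tp$tm_segments)
    if (n_tm >= 1L) funnel["with_tm"] <- funnel["with_tm"] + 1L
    if (n_tm == 4L) funnel["four_tm"] <- funnel["four_tm"] + 1L
    side_assumed <- is.na(tp$n_terminus_side)
    cands <- if (side_assumed) {
      lapply(c("inside", "outside"), function(s) {
        tp2 <- tp; tp2$n_terminus_side <- s
        rep <- score_features(derive_regions(seqs[i, ], tp2), seqs[i, ])
        classify(rep, rules)
      })
    } else {
      list(classify(score_features(derive_regions(seqs[i, ], tp),
                                   seqs[i, ]), rules))
    }
    best <- cands[[which.min(vapply(cands, function(v)
      if (v$verdict == "tetraspanin") 0L
      else length(v$failed) + length(v$not_evaluable), integer(1)))]]
    rows[[i]] <- data.frame(
      protein_id = id, n_tm = n_tm, verdict = best$verdict,
      failed = paste(best$failed, collapse = ";"),
      side_assumed = side_assumed, stringsAsFactors = FALSE)
  }
  reports <- do.call(rbind, rows)
  reports <- reports[order(reports$protein_id), , drop = FALSE]
  rownames(reports) <- NULL
  candidates <- sort(reports$protein_id[reports$verdict == "tetraspanin"])
  if (!is.null(keywords) && !is.null(annotations)) {
    pat <- paste(keywords, collapse = "|")
    kw_ids <- names(annotations)[grepl(pat, annotations, ignore.case = TRUE)]
    candidates <- intersect(candidates, kw_ids)
  }
  funnel["passed"] <- length(candidates)
  list(candidates = candidates, reports = reports, funnel = funnel)
}

## ---- hydropathy-based TM prediction --------------------------------------

## Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Predict transmembrane topology by hydropathy
#'
#' A self-contained sliding-window predictor: residues whose centered
#' Kyte-Doolittle window average exceeds `threshold` seed candidate
#' segments, segment boundaries are extended outward over contiguous
#' hydrophobic residues (per-residue score > 0), and segments closer than
#' `merge_gap` residues are merged. The N-terminus side is set by the
#' positive-inside heuristic: of the two possible orientations, the one
#' placing more lysines/arginines in cytoplasmic segments is chosen (ties
#' resolve to inside).
#'
#' @param seq One row of a [read_fasta()] table.
#' @param window Window length in residues (default 19).
#' @param threshold Window-average hydropathy cutoff (default 1.6).
#' @param merge_gap Merge segments separated by at most this many residues.
#' @param min_len Discard segments shorter than this many residues.
#' @return A [topology_record()]; proteins shorter than `window` get an
#'   empty segment list.
#' @export
predict_tm_hydropathy <- function(seq, window = 19L, threshold = 1.6,
                                  merge_gap = 3L, min_len = 8L) {
  res <- strsplit(seq$residues, "")[[1]]
  len <- length(res)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (len < window)
    return(topology_record(seq$id, len, empty, NA_character_))
  kd <- unname(KD_SCALE[res])
  kd[is.na(kd)] <- 0
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(kd))
  lo <- pmax(1L, seq_len(len) - half)
  hi <- pmin(len, seq_len(len) + half)
  score <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  above <- score > threshold
  if (!any(above))
    return(topology_record(seq$id, len, empty,
                           positive_inside_side(res, empty)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(start = starts[r$values], end = ends[r$values])
  # extend over contiguous hydrophobic residues at each boundary
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, "start"]; e <- segs[i, "end"]
    while (s > 1L && kd[s - 1L] > 0) s <- s - 1L
    while (e < len && kd[e + 1L] > 0) e <- e + 1L
    segs[i, ] <- c(s, e)
  }
  segs <- segs[order(segs[, "start"]), , drop = FALSE]
  merged <- segs[1L, , drop = FALSE]
  for (i in seq_len(nrow(segs))[-1L]) {
    if (segs[i, "start"] - merged[nrow(merged), "end"] - 1L <= merge_gap)
      merged[nrow(merged), "end"] <- max(merged[nrow(merged), "end"],
                                         segs[i, "end"])
    else merged <- rbind(merged, segs[i, , drop = FALSE])
  }
  merged <- merged[merged[, "end"] - merged[, "start"] + 1L >= min_len, ,
                   drop = FALSE]
  topology_record(seq$id, len, merged, positive_inside_side(res, merged))
}

## Positive-inside heuristic: choose the orientation that maximizes K/R
## content of cytoplasmic (non-TM) segments.
positive_inside_side <- function(res, segs) {
  len <- length(res)
  if (!nrow(segs)) return(NA_character_)
  basic <- res %in% c("K", "R")
  in_tm <- logical(len)
  for (i in seq_len(nrow(segs)))
    in_tm[segs[i, "start"]:segs[i, "end"]] <- TRUE
  # a non-TM residue is on the N-terminal side iff an even number of TM
  # segments lie fully before it
  tm_before <- vapply(seq_len(len), function(p)
    sum(segs[, "end"] < p), integer(1))
  same_side_as_n <- tm_before %% 2L == 0L
  n_side_basic <- sum(basic & !in_tm & same_side_as_n)
  other_basic <- sum(basic & !in_tm & !same_side_as_n)
  if (n_side_basic >= other_basic) "inside" else "outside"
}
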