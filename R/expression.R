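## Relative expression from qPCR Cq tables by the delta-delta-Ct (Livak)
## method, regulation flags, Venn overlaps and hierarchical clustering.

#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged to one Cq per (gene, condition,
#' biological replicate). Per biological replicate,
#' `dCq = Cq_gene - Cq_reference`; `ddCq` compares each condition's dCq
#' with the mean control dCq for the same gene, and
#' `log2 fold change = -ddCq` (amplification efficiency fixed at 2). Cells
#' report the mean and standard error over biological replicates.
#'
#' @param cq A Cq table ([read_cq()] or equivalent data.frame).
#' @param reference_gene Internal control gene id (e.g. a housekeeping
#'   gene such as eEF1a); must be measured in every (condition, biological
#'   replicate).
#' @param pairing Named character vector mapping each condition to its
#'   control condition (a control may map to itself; conditions absent
#'   from `pairing` are skipped).
#' @return A list of class `fold_change_matrix`: `log2fc`, `se` (standard
#'   error over biological replicates -- the error bar to plot), and
#'   `recovery_se` (standard error of the estimate itself, additionally
#'   carrying the uncertainty of the shared control mean; the right
#'   yardstick when comparing estimates against a known truth), `n_bio`
#'   (genes x conditions matrices; cells for gene/condition combinations
#'   that were never measured are `NA`) and `genes`, `conditions`.
#' @export
ddct <- function(cq, reference_gene, pairing) {
  cq <- as.data.frame(cq)
  if (!reference_gene %in% cq$gene_id)
    stop("reference gene ", reference_gene, " absent from the table")
  conds <- names(pairing)
  genes <- sort(setdiff(unique(cq$gene_id), reference_gene))
  # average technical replicates
  tech <- aggregate(cq ~ gene_id + condition + bio_rep, data = cq,
                    FUN = mean)
  ref <- tech[tech$gene_id == reference_gene, , drop = FALSE]
  refkey <- paste(ref$condition, ref$bio_rep, sep = "\r")
  # dCq = Cq_gene - Cq_ref, matched by condition and bio replicate
  tg <- tech[tech$gene_id != reference_gene, , drop = FALSE]
  idx <- match(paste(tg$condition, tg$bio_rep, sep = "\r"), refkey)
  for (cond in conds) {
    have <- unique(tech$bio_rep[tech$condition == cond])
    miss <- setdiff(have, ref$bio_rep[ref$condition == cond])
    if (cond %in% tech$condition && length(miss))
      stop("reference gene not measured in condition '", cond,
           "' biological replicate(s) ", paste(miss, collapse = ", "))
  }
  if (anyNA(idx)) {
    bad <- unique(tg$condition[is.na(idx)])
    stop("reference gene not measured in condition '", bad[1L], "'")
  }
  tg$dcq <- tg$cq - ref$cq[idx]
  log2fc <- se <- rse <- nb <- matrix(NA_real_, length(genes), length(conds),
                                      dimnames = list(genes, conds))
  for (g in genes) {
    dg <- tg[tg$gene_id == g, , drop = FALSE]
    for (cond in conds) {
      ctrl <- pairing[[cond]]
      dc <- dg$dcq[dg$condition == cond]
      dctrl <- dg$dcq[dg$condition == ctrl]
      if (!length(dc) || !length(dctrl)) next  # absent cell
      fc_b <- -(dc - mean(dctrl))
      log2fc[g, cond] <- mean(fc_b)
      se[g, cond] <- if (length(fc_b) > 1L)
        sd(fc_b) / sqrt(length(fc_b)) else 0
      # SE of the estimate itself: the control-mean term is shared by
      # every replicate of a treated condition, so it contributes its
      # own uncertainty on top of the per-condition spread
      v_c <- if (length(dc) > 1L) stats::var(dc) / length(dc) else 0
      v_k <- if (cond != ctrl && length(dctrl) > 1L)
        stats::var(dctrl) / length(dctrl) else 0
      rse[g, cond] <- sqrt(v_c + v_k)
      nb[g, cond] <- length(fc_b)
    }
  }
  structure(list(log2fc = log2fc, se = se, recovery_se = rse, n_bio = nb,
                 genes = genes, conditions = conds,
                 reference_gene = reference_gene),
            class = "fold_change_matrix")
}

#' Flag significantly regulated genes per condition
#'
#' A gene is up-regulated in a condition if its log2 fold change is at
#' least `tau`, down-regulated if at most `-tau` (boundary inclusive).
#'
#' @param fcm A [ddct()] result.
#' @param tau Log2 fold-change threshold (default 2, i.e. 4-fold linear).
#' @return Named list of regulation sets, one per condition:
#'   `list(condition, up, down, tau)`; `up` and `down` are disjoint.
#' @export
flag_regulated <- function(fcm, tau = 2.0) {
  lapply(setNames(fcm$conditions, fcm$conditions), function(cond) {
    fc <- fcm$log2fc[, cond]
    list(condition = cond,
         up = sort(names(fc)[!is.na(fc) & fc >= tau]),
         down = sort(names(fc)[!is.na(fc) & fc <= -tau]),
         tau = tau)
  })
}

#' Venn overlap of regulated gene sets across condition groups
#'
#' A gene belongs to a group if it is regulated in the given direction in
#' at least one of the group's conditions. All `2^k - 1` Venn regions are
#' reported.
#'
#' @param regsets A [flag_regulated()] result.
#' @param groups Named list of condition vectors (>= 2 groups).
#' @param direction `"up"` or `"down"`.
#' @return List with `membership` (named list group -> gene set) and
#'   `regions` (data.frame: `region` label, `count`, `genes`); region
#'   counts sum to the size of the union.
#' @export
overlap_sets <- function(regsets, groups, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(groups) < 2L) stop("need at least 2 groups")
  membership <- lapply(groups, function(conds) {
    sort(unique(unlist(lapply(conds, function(cond) {
      if (!cond %in% names(regsets)) stop("unknown condition ", cond)
      regsets[[cond]][[direction]]
    }))))
  })
  k <- length(groups)
  gnames <- names(groups)
  univ <- sort(unique(unlist(membership)))
  in_g <- vapply(membership, function(s) univ %in% s,
                 logical(length(univ)))
  if (length(univ) == 1L) in_g <- matrix(in_g, nrow = 1L)
  rows <- list()
  for (mask in seq_len(2^k - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    if (length(univ)) {
      inside <- apply(in_g, 1L, function(z) all(z == sel))
      genes <- univ[inside]
    } else genes <- character(0)
    rows[[mask]] <- data.frame(
      region = paste(gnames[sel], collapse = "&"),
      count = length(genes),
      genes = paste(genes, collapse = ";"), stringsAsFactors = FALSE)
  }
  list(membership = membership, regions = do.call(rbind, rows))
}

#' Hierarchical clustering of a fold-change matrix
#'
#' Rows (genes) are clustered agglomeratively; missing cells are imputed
#' as 0 for clustering and reported in a mask. Rows are pre-sorted by
#' gene id so that leaf ordering is deterministic under ties.
#'
#' @param fcm A [ddct()] result or a plain numeric matrix.
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param linkage `"average"` or `"complete"`.
#' @return List with `hclust`, `order` (gene ids, leaf order), `matrix`
#'   (rows reordered), `mask` (logical matrix of imputed cells).
#' @export
cluster_heatmap <- function(fcm, metric = c("euclidean", "correlation"),
                            linkage = c("average", "complete")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  x <- if (inherits(fcm, "fold_change_matrix")) fcm$log2fc else fcm
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  x <- x[order(rownames(x)), , drop = FALSE]
  if (nrow(x) < 2L) stop("need at least 2 genes to cluster")
  if (any(rowSums(!is.na(x)) == 0L))
    stop("all-absent row(s): ",
         paste(rownames(x)[rowSums(!is.na(x)) == 0L], collapse = ", "))
  mask <- is.na(x)
  x[mask] <- 0
  d <- switch(metric,
              euclidean = dist(x),
              correlation = as.dist(1 - cor(t(x))))
  hc <- hclust(d, method = linkage)
  ord <- order.dendrogram(as.dendrogram(hc))
  list(hclust = hc, order = rownames(x)[ord],
       matrix = x[ord, , drop = FALSE],
       mask = mask[ord, , drop = FALSE])
}

#' Draw a clustered heatmap (optional rendering)
#'
#' Thin wrapper around `pheatmap` when it is installed; the clustered
#' matrix itself comes from [cluster_heatmap()].
#'
#' @param ch A [cluster_heatmap()] result.
#' @param ... Passed to `pheatmap::pheatmap()`.
#' @return The pheatmap object, invisibly.
#' @export
draw_heatmap <- function(ch, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap is not installed")
  invisible(pheatmap::pheatmap(ch$matrix, cluster_rows = FALSE,
                               cluster_cols = FALSE, ...))
}
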