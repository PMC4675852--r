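hand_cq <- function() {
  # gene: control 25, treated 23; reference 20 in both ->
  # ddCq = -2, fold change 4, log2fc = 2
  rows <- expand.grid(bio_rep = 1:3, tech_rep = 1:2,
                      condition = c("control", "treated"),
                      stringsAsFactors = FALSE)
  rbind(
    data.frame(gene_id = "g1", rows,
               cq = ifelse(rows$condition == "control", 25, 23)),
    data.frame(gene_id = "eEF1a", rows, cq = 20))
}

test_that("delta-delta-Ct reproduces hand-computed fold changes", {
  pairing <- c(control = "control", treated = "control")
  fc <- ddct(hand_cq(), "eEF1a", pairing)
  expect_equal(fc$log2fc["g1", "treated"], 2)
  expect_equal(fc$log2fc["g1", "control"], 0)
  expect_equal(fc$se["g1", "treated"], 0)
  expect_equal(fc$n_bio["g1", "treated"], 3)

  # all Cq equal across conditions -> zero fold change everywhere
  cq <- hand_cq()
  cq$cq[cq$gene_id == "g1"] <- 24
  fc0 <- ddct(cq, "eEF1a", pairing)
  expect_true(all(fc0$log2fc == 0))
})

test_that("missing reference or missing gene cells are handled", {
  cq <- hand_cq()
  expect_error(ddct(cq[cq$gene_id != "eEF1a", ], "eEF1a",
                    c(treated = "control")), "eEF1a")
  cq2 <- cq[!(cq$gene_id == "eEF1a" & cq$condition == "treated"), ]
  expect_error(ddct(cq2, "eEF1a", c(control = "control",
                                    treated = "control")), "treated")
  # a gene absent from one condition yields an NA cell, not an error
  cq3 <- cq[!(cq$gene_id == "g1" & cq$condition == "treated"), ]
  fc <- ddct(cq3, "eEF1a", c(control = "control", treated = "control"))
  expect_true(is.na(fc$log2fc["g1", "treated"]))
  expect_false(is.na(fc$log2fc["g1", "control"]))
})

test_that("a per-replicate Cq offset shared with the reference cancels", {
  mc <- make_cq(generator_spec(seed = 51, cq_sd = 0))
  fc1 <- ddct(mc$cq, mc$reference_gene, mc$pairing)
  shifted <- mc$cq
  pick <- shifted$condition == "heat" & shifted$bio_rep == 2
  shifted$cq[pick] <- shifted$cq[pick] + 3.7
  fc2 <- ddct(shifted, mc$reference_gene, mc$pairing)
  expect_equal(fc2$log2fc, fc1$log2fc, tolerance = 1e-12)
})

test_that("regulation flags use an inclusive threshold, monotone in tau", {
  genes <- c("g1", "g2", "g3", "g4")
  truth <- matrix(0, 4, 2, dimnames = list(genes, c("control", "str")))
  truth[, "str"] <- c(2.0, -1.9, -2.5, 3.1)
  mc <- make_cq(generator_spec(seed = 52, cq_genes = genes,
                               cq_conditions = c("control", "str"),
                               cq_truth = truth, cq_sd = 0))
  fc <- ddct(mc$cq, mc$reference_gene, mc$pairing)
  rs <- flag_regulated(fc, tau = 2)
  expect_equal(rs$str$up, c("g1", "g4"))    # 2.0 is in (inclusive)
  expect_equal(rs$str$down, "g3")           # -1.9 is out
  expect_length(intersect(rs$str$up, rs$str$down), 0L)
  rs3 <- flag_regulated(fc, tau = 3)
  expect_true(all(rs3$str$up %in% rs$str$up))
  expect_true(all(rs3$str$down %in% rs$str$down))
})

test_that("Venn regions match an inclusion-exclusion enumeration", {
  genes <- sprintf("g%02d", 1:10)
  conds <- c("control", "c1", "c2", "c3")
  truth <- matrix(0, 10, 4, dimnames = list(genes, conds))
  set.seed(53)
  truth[, -1] <- sample(c(0, 3), 30, replace = TRUE)
  mc <- make_cq(generator_spec(seed = 53, cq_genes = genes,
                               cq_conditions = conds, cq_truth = truth,
                               cq_sd = 0))
  fc <- ddct(mc$cq, mc$reference_gene, mc$pairing)
  rs <- flag_regulated(fc)
  ov <- overlap_sets(rs, list(A = "c1", B = "c2", C = "c3"))
  # direct membership enumeration
  inA <- genes[truth[, "c1"] >= 2]
  inB <- genes[truth[, "c2"] >= 2]
  inC <- genes[truth[, "c3"] >= 2]
  for (i in seq_len(nrow(ov$regions))) {
    sel <- strsplit(ov$regions$region[i], "&", fixed = TRUE)[[1]]
    want <- Reduce(intersect, list(A = inA, B = inB, C = inC)[sel])
    for (other in setdiff(c("A", "B", "C"), sel))
      want <- setdiff(want, list(A = inA, B = inB, C = inC)[[other]])
    expect_equal(ov$regions$count[i], length(want))
  }
  expect_equal(sum(ov$regions$count), length(union(inA, union(inB, inC))))

  # disjoint and identical sets
  rs2 <- list(x = list(condition = "x", up = c("a", "b"), down = character(0)),
              y = list(condition = "y", up = c("c"), down = character(0)))
  ov2 <- overlap_sets(rs2, list(X = "x", Y = "y"))
  expect_equal(ov2$regions$count[ov2$regions$region == "X&Y"], 0L)
  rs3 <- list(x = rs2$x, y = list(condition = "y", up = c("a", "b"),
                                  down = character(0)))
  ov3 <- overlap_sets(rs3, list(X = "x", Y = "y"))
  expect_equal(ov3$regions$count[ov3$regions$region == "X&Y"], 2L)
  expect_equal(sum(ov3$regions$count), 2L)
})

test_that("hierarchical clustering: identical rows merge first, blocks hold", {
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9),
             d = c(9.1, 9, 9))
  ch <- cluster_heatmap(x)
  expect_equal(ch$hclust$height[1], 0)  # identical pair at height 0
  ord <- ch$order
  expect_equal(abs(which(ord == "a") - which(ord == "b")), 1L)

  # two planted blocks, zero noise: first merges stay within blocks
  y <- rbind(a = c(0, 0, 0, 5), b = c(0, 0, 0.2, 5), c = c(8, 8, 8, 0),
             d = c(8, 8.2, 8, 0))
  ch2 <- cluster_heatmap(y)
  first_pairs <- ch2$hclust$merge[1:2, ]
  expect_true(all(first_pairs < 0))  # both first merges join singletons
  merged <- sort(rownames(y)[-as.vector(first_pairs)])
  expect_equal(merged, c("a", "b", "c", "d"))
  expect_true(identical(sort(ch2$order[1:2]), c("a", "b")) ||
                identical(sort(ch2$order[1:2]), c("c", "d")))

  # scaling rows doubles euclidean heights, keeps topology
  ch3 <- cluster_heatmap(2 * y)
  expect_equal(ch3$hclust$height, 2 * ch2$hclust$height)
  expect_equal(ch3$order, ch2$order)
})
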