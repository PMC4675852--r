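canon_topo <- function(side = "inside")
  topology_record("p1", 220, rbind(c(11, 32), c(41, 62), c(81, 102),
                                   c(171, 192)), side)

canon_seq <- function(residues = paste(rep("A", 220), collapse = ""))
  aa_seq_row("p1", residues)

test_that("region derivation follows sidedness alternation", {
  rm <- derive_regions(canon_seq(), canon_topo())
  expect_equal(unname(rm$regions$EC1), c(33, 40))
  expect_equal(unname(rm$regions$ICL), c(63, 80))
  expect_equal(unname(rm$regions$EC2), c(103, 170))
  expect_equal(unname(rm$regions$Ctail), c(193, 220))
  expect_true(rm$orientation_ok)
  expect_equal(rm$regions$EC1["end"] - rm$regions$EC1["start"] + 1,
               c(end = 8))

  # N outside: the 33-40 loop becomes intracellular, the only
  # extracellular loop (63-80) carries the EC label, orientation fails
  rm2 <- derive_regions(canon_seq(), canon_topo("outside"))
  expect_false(rm2$orientation_ok)
  expect_equal(unname(rm2$regions$EC1), c(63, 80))
  expect_equal(unname(rm2$regions$ICL), c(33, 40))
  expect_null(rm2$regions$EC2)

  # 3-TM protein: canonical labels withheld
  tp3 <- topology_record("p1", 220, rbind(c(11, 32), c(41, 62), c(81, 102)),
                         "inside")
  rm3 <- derive_regions(canon_seq(), tp3)
  expect_equal(rm3$n_tm, 3L)
  expect_length(rm3$regions, 0L)
})

test_that("region segments tile the protein exactly", {
  set.seed(5)
  for (rep in 1:30) {
    len <- sample(220:400, 1)
    n_tm <- sample(1:5, 1)
    # non-overlapping TM segments with gaps
    starts <- sort(sample(seq(5, len - 25), n_tm))
    while (any(diff(starts) < 30)) starts <- sort(sample(seq(5, len - 25),
                                                         n_tm))
    segs <- cbind(starts, starts + sample(15:22, n_tm, replace = TRUE))
    tp <- topology_record("p1", len, segs, sample(c("inside", "outside"), 1))
    rm <- derive_regions(aa_seq_row("p1", paste(rep("L", len),
                                                collapse = "")), tp)
    seg <- rm$segments[rm$segments$length > 0, ]
    seg <- seg[order(seg$start), ]
    expect_equal(seg$start[1], 1L)
    expect_equal(seg$end[nrow(seg)], len)
    if (nrow(seg) > 1)
      expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1L))
  }
})

test_that("derive_regions agrees with a residue-walking labeler", {
  set.seed(11)
  for (rep in 1:40) {
    len <- sample(20:60, 1)
    n_tm <- sample(0:2, 1)
    segs <- matrix(integer(0), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
    if (n_tm > 0) {
      s1 <- sample(2:8, 1)
      e1 <- s1 + sample(3:6, 1)
      segs <- cbind(start = s1, end = e1)
      if (n_tm == 2 && e1 + 3 < len - 4) {
        s2 <- e1 + 2
        e2 <- min(len - 1, s2 + sample(3:6, 1))
        segs <- rbind(segs, c(s2, e2))
      }
    }
    side <- sample(c("inside", "outside"), 1)
    tp <- topology_record("p1", len, segs, side)
    rm <- derive_regions(aa_seq_row("p1", paste(rep("G", len),
                                                collapse = "")), tp)
    oracle <- walk_labeler(len, tp$tm_segments, side)
    mine <- character(len)
    for (i in seq_len(nrow(rm$segments))) {
      r <- rm$segments[i, ]
      if (r$length > 0)
        mine[r$start:r$end] <- if (r$type == "tm") "membrane" else r$side
    }
    expect_equal(mine, oracle)
  }
})

test_that("feature scoring finds signature, sequons, cysteines", {
  # EC2 = 103..170; plant SGCCKPP at 110 and sequons
  res <- rep("A", 220)
  res[110:116] <- strsplit("SGCCKPP", "")[[1]]
  res[150:152] <- c("N", "P", "T")   # excluded by the {P} rule
  res[155:157] <- c("N", "A", "S")   # valid sequon
  res[104] <- "C"
  seqs <- aa_seq_row("p1", paste(res, collapse = ""))
  fr <- score_features(derive_regions(seqs, canon_topo()), seqs)
  expect_equal(fr$signature$type, "SGCC[KR]PP")
  expect_equal(fr$signature$position, 110L)
  expect_equal(fr$sequons, 155L)
  expect_equal(fr$ec2_cys, 3L)  # two motif cysteines + the planted one
  expect_equal(fr$ec2_len, 68L)
  expect_equal(fr$ec1_len, 8L)

  # GCCRP core without the long form
  res2 <- rep("A", 220)
  res2[120:124] <- strsplit("GCCRP", "")[[1]]
  seqs2 <- aa_seq_row("p1", paste(res2, collapse = ""))
  fr2 <- score_features(derive_regions(seqs2, canon_topo()), seqs2)
  expect_equal(fr2$signature$type, "GCC[KR]P")
  expect_equal(fr2$signature$position, 120L)

  # hand regex cross-check: core motif is a substring of the long motif
  expect_true(grepl("GCC[KR]P", "SGCCKPP"))
  expect_false(grepl("SGCC[KR]PP", "XGCCRPX"))
})

test_that("overlapping sequons are all reported", {
  res <- rep("A", 220)
  res[130:133] <- c("N", "N", "S", "S")  # sequons at 130 and 131
  seqs <- aa_seq_row("p1", paste(res, collapse = ""))
  fr <- score_features(derive_regions(seqs, canon_topo()), seqs)
  expect_equal(fr$sequons, c(130L, 131L))
})

test_that("juxtamembrane cysteines are counted on the cytoplasmic side", {
  res <- rep("A", 220)
  res[9] <- "C"    # N-tail, 2 residues from TM1 start (11)
  res[64] <- "C"   # ICL, 2 from TM2 end (62)
  res[105] <- "C"  # EC2 (extracellular): must not count
  res[2] <- "C"    # N-tail but 9 residues from the boundary: outside w=5
  seqs <- aa_seq_row("p1", paste(res, collapse = ""))
  fr <- score_features(derive_regions(seqs, canon_topo()), seqs)
  expect_equal(fr$juxtamembrane_cys, c(9L, 64L))
})

test_that("classification failures name the violated rule", {
  pr <- make_proteome(generator_spec(seed = 21, n_tetraspanin = 3,
                                     n_decoys = c(wrong_tm = 3,
                                                  missing_motif = 3,
                                                  small_ec2 = 3,
                                                  long_tails = 3)))
  for (i in seq_len(nrow(pr$proteins))) {
    row <- pr$proteins[i, ]
    v <- classify(score_features(
      derive_regions(row, pr$topology[[row$id]]), row))
    want <- pr$truth$expected_failed_rule[i]
    if (is.na(want)) {
      expect_equal(v$verdict, "tetraspanin")
      expect_length(v$failed, 0L)
    } else {
      expect_equal(v$verdict, "rejected")
      expect_equal(v$failed, want)
    }
  }
})

test_that("relaxing any single rule threshold never shrinks the set", {
  pr <- make_proteome(generator_spec(seed = 8, n_tetraspanin = 8,
                                     n_decoys = c(wrong_tm = 10,
                                                  missing_motif = 10,
                                                  small_ec2 = 10,
                                                  long_tails = 10)))
  base <- mine_proteome(pr$proteins, pr$topology)$candidates
  relaxed <- list(
    rule_config(cys_min = 5L),
    rule_config(tail_max = 120L),
    rule_config(enabled = setdiff(c("four_tm", "ec2_gt_ec1", "ec2_cys",
                                    "signature", "short_tails",
                                    "orientation"), "signature")))
  for (rc in relaxed) {
    cand <- mine_proteome(pr$proteins, pr$topology, rc)$candidates
    expect_true(all(base %in% cand))
  }
  # strict mode is at least as restrictive
  strict <- mine_proteome(pr$proteins, pr$topology,
                          rule_config(signature_mode = "strict",
                                      strict_cys = TRUE))$candidates
  expect_true(all(strict %in% base))
})

test_that("mining funnel counts stages and tolerates empty input", {
  empty <- mine_proteome(data.frame(id = character(0),
                                    description = character(0),
                                    residues = character(0)), list())
  expect_equal(unname(empty$funnel["total"]), 0L)
  expect_length(empty$candidates, 0L)

  pr <- make_proteome(generator_spec(seed = 2, n_tetraspanin = 4,
                                     n_decoys = c(wrong_tm = 6,
                                                  missing_motif = 2,
                                                  small_ec2 = 2,
                                                  long_tails = 2)))
  res <- mine_proteome(pr$proteins, pr$topology)
  expect_equal(unname(res$funnel["total"]), 16L)
  expect_equal(unname(res$funnel["four_tm"]), 10L)  # all but wrong_tm
  expect_equal(res$candidates, pr$truth$protein_id[pr$truth$is_tetraspanin])
})

test_that("unknown sidedness is scored under both orientations", {
  pr <- make_proteome(generator_spec(seed = 5, n_tetraspanin = 2,
                                     n_decoys = c(wrong_tm = 0,
                                                  missing_motif = 0,
                                                  small_ec2 = 0,
                                                  long_tails = 0)))
  topo_na <- lapply(pr$topology, function(tp) {
    tp$n_terminus_side <- NA_character_
    tp
  })
  res <- mine_proteome(pr$proteins, topo_na)
  expect_equal(res$candidates, pr$proteins$id)
  expect_true(all(res$reports$side_assumed))
})

test_that("hydropathy prediction recovers planted and hand-built TMs", {
  # poly-L 25-mer flanked by poly-D: one TM covering the whole L run
  s <- aa_seq_row("h1", paste0(strrep("D", 30), strrep("L", 25),
                               strrep("D", 30)))
  tp <- predict_tm_hydropathy(s)
  expect_equal(nrow(tp$tm_segments), 1L)
  expect_equal(unname(tp$tm_segments[1, ]), c(31L, 55L))

  # all-hydrophilic: no TM; short sequence: empty segment list
  expect_equal(nrow(predict_tm_hydropathy(
    aa_seq_row("h2", strrep("D", 100)))$tm_segments), 0L)
  expect_equal(nrow(predict_tm_hydropathy(
    aa_seq_row("h3", "DDDDD"))$tm_segments), 0L)

  # planted synthetic tetraspanins: 4 TMs within +/- 2 residues
  pr <- make_proteome(generator_spec(seed = 13, n_tetraspanin = 5,
                                     n_decoys = c(wrong_tm = 0,
                                                  missing_motif = 0,
                                                  small_ec2 = 0,
                                                  long_tails = 0)))
  for (id in pr$proteins$id) {
    pred <- predict_tm_hydropathy(pr$proteins[pr$proteins$id == id, ])
    truth <- pr$topology[[id]]$tm_segments
    expect_equal(nrow(pred$tm_segments), 4L)
    expect_true(all(abs(pred$tm_segments - truth) <= 2L))
    expect_equal(pred$n_terminus_side, "inside")
  }
})
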