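test_that("FASTA reading handles folding, case and headers", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "MKT"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, "a")
  expect_equal(recs$residues, "MKT")

  writeLines(c(">a desc text", "mk", "tt", ">b", "ACD"), f)
  recs <- read_fasta(f)
  expect_equal(nrow(recs), 2L)
  expect_equal(recs$residues[1L], "MKTT")
  expect_equal(recs$description[1L], "desc text")

  writeLines(c(">a", "MK", ">a", "TT"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty file")
  writeLines(c("MKT", ">a", "MK"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("FASTA writing round-trips randomized records", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(1:6, 1)
    recs <- data.frame(
      id = paste0("s", seq_len(n)),
      description = replicate(n, paste(sample(letters, 3), collapse = "")),
      residues = replicate(n, paste(sample(c("A", "C", "D", "E", "F"),
                                           sample(5:200, 1), replace = TRUE),
                                    collapse = "")),
      stringsAsFactors = FALSE)
    f <- withr::local_tempfile(fileext = ".fa")
    write_fasta(recs, f, width = 17)
    expect_equal(read_fasta(f), recs)
  }
})

test_that("topology tsv and tmhmm_long dialects parse consistently", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tlength\ttm_segments\tn_terminus_side",
               "p1\t300\t11-32;41-62;81-102;171-192\tinside"), f)
  tp <- read_topology(f, "tsv")[["p1"]]
  expect_equal(nrow(tp$tm_segments), 4L)
  expect_equal(tp$tm_segments[1L, ], c(start = 11L, end = 32L))
  expect_equal(tp$n_terminus_side, "inside")

  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# p1 Length: 120",
               "p1\tTMHMM2.0\tinside\t1\t10",
               "p1\tTMHMM2.0\tTMhelix\t11\t32",
               "p1\tTMHMM2.0\toutside\t33\t120"), g)
  tp2 <- read_topology(g, "tmhmm_long")[["p1"]]
  expect_equal(tp2$n_terminus_side, "inside")
  expect_equal(unname(tp2$tm_segments[1L, ]), c(11L, 32L))
  expect_equal(tp2$length, 120L)

  writeLines(c("protein_id\tlength\ttm_segments\tn_terminus_side",
               "p1\t300\t0-5\tinside"), f)
  expect_error(read_topology(f, "tsv"), "coordinate")
  writeLines(c("protein_id\tlength\ttm_segments\tn_terminus_side",
               "p1\t300\t10-40;30-60\tinside"), f)
  expect_error(read_topology(f, "tsv"), "overlap")
})

test_that("topology tsv round-trips", {
  tp <- list(topology_record("pA", 250,
                             rbind(c(10, 30), c(50, 70)), "outside"),
             topology_record("pB", 90, matrix(integer(0), ncol = 2), NA))
  names(tp) <- c("pA", "pB")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_topology(tp, f)
  back <- read_topology(f, "tsv")
  expect_equal(back[["pA"]]$tm_segments, tp[["pA"]]$tm_segments)
  expect_equal(back[["pB"]]$length, 90L)
  expect_equal(nrow(back[["pB"]]$tm_segments), 0L)
})

test_that("GFF3 gene models: hierarchy, strand convention, intron count", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t100\t500\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t100\t500\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tx\texon\t100\t220\t.\t+\t.\tParent=t1",
               "chr1\tx\texon\t350\t500\t.\t+\t.\tParent=t1",
               "chr1\tx\tCDS\t100\t220\t.\t+\t0\tParent=t1",
               "chr1\tx\tCDS\t350\t500\t.\t+\t2\tParent=t1"), f)
  m <- read_gff3(f)[["t1"]]
  expect_equal(nrow(m$exons), 2L)
  expect_equal(nrow(introns_of(m)), 1L)
  expect_equal(m$coding_start, 100L)

  # same gene mirrored onto the minus strand of a 1000-bp contig
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t501\t901\t.\t-\t.\tID=g1",
               "chr1\tx\tmRNA\t501\t901\t.\t-\t.\tID=t1;Parent=g1",
               "chr1\tx\texon\t501\t651\t.\t-\t.\tParent=t1",
               "chr1\tx\texon\t781\t901\t.\t-\t.\tParent=t1",
               "chr1\tx\tCDS\t501\t651\t.\t-\t2\tParent=t1",
               "chr1\tx\tCDS\t781\t901\t.\t-\t0\tParent=t1"), g)
  mm <- read_gff3(g)[["t1"]]
  expect_equal(mm$coding_start, 901L)  # 5' end on the minus strand
  expect_equal(introns_of(mm)$length, introns_of(m)$length)

  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t100\t500\t.\t+\t.\tID=g1",
               "chr1\tx\tmRNA\t100\t500\t.\t+\t.\tID=t1;Parent=g1",
               "chr1\tx\tCDS\t100\t220\t.\t+\t0\tParent=missing"), f)
  expect_error(read_gff3(f), "orphan")
})

test_that("GFF3 writer round-trips models and introns = exons - 1", {
  set.seed(7)
  models <- lapply(1:10, function(i) random_gene_model(paste0("g", i)))
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(models, f)
  back <- read_gff3(f)
  for (nm in names(models)) {
    expect_equal(back[[nm]]$exons, models[[nm]]$exons)
    expect_equal(back[[nm]]$cds, models[[nm]]$cds)
    expect_equal(back[[nm]]$strand, models[[nm]]$strand)
    expect_equal(nrow(introns_of(back[[nm]])),
                 nrow(back[[nm]]$exons) - 1L)
  }
})

test_that("Newick round-trips a 3-leaf tree", {
  tr <- read_newick("(A:1.0,B:2.0,C:3.0);")
  txt <- write_newick(tr)
  tr2 <- read_newick(txt)
  expect_equal(sort(tr2$tip.label), c("A", "B", "C"))
  expect_equal(sort(tr2$edge.length), c(1, 2, 3))
})

test_that("Cq table CSV round-trips and rejects bad values", {
  cq <- data.frame(gene_id = rep(c("g1", "g2"), each = 4),
                   condition = rep(c("ctrl", "heat"), 4),
                   bio_rep = rep(1:2, 4), tech_rep = rep(1:2, each = 2),
                   cq = round(runif(8, 20, 30), 3),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cq(cq, f)
  back <- read_cq(f)
  expect_equal(as.data.frame(back), cq)

  writeLines(c("gene_id,condition,bio_rep,tech_rep,cq",
               "g1,ctrl,1,1,notanumber"), f)
  expect_error(read_cq(f), "non-numeric")
})

test_that("motif dictionaries validate IUPAC codes and round-trip", {
  m <- default_motifs()
  expect_true(all(c("ABRE", "HSE", "ROOT") %in% m$motif_id))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_motifs(m, f)
  expect_equal(as.data.frame(read_motifs(f)), as.data.frame(m))

  writeLines(c("motif_id\tpattern\tcategory", "bad\tACGTX\tstress"), f)
  expect_error(read_motifs(f), "invalid IUPAC.*bad")
  writeLines(c("motif_id\tpattern\tcategory",
               "m1\tACGT\tstress", "m1\tACGG\tstress"), f)
  expect_error(read_motifs(f), "duplicate")
})
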