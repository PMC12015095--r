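write_ann <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("annotation reader filters by category and validates columns", {
  df <- data.frame(gene_id = c("g1", "g2", "g3"), contig = "c1", strand = "+",
                   tss = c(100L, 200L, 300L),
                   category = c("Intact", "Lost", "ParalogousProjection"))
  path <- write_ann(df)
  ann <- read_annotations(path, quiet = TRUE)
  expect_equal(ann$gene_id, c("g1", "g3"))
  expect_message(read_annotations(path), "dropped 1 of 3")
  all6 <- read_annotations(path, keep_categories = hrescan:::TOGA_CATEGORIES,
                           quiet = TRUE)
  expect_equal(nrow(all6), 3L)

  expect_error(read_annotations(write_ann(df[, -5]), quiet = TRUE),
               "missing column")
  dfu <- df; dfu$category[2] <- "Garbled"
  expect_error(read_annotations(write_ann(dfu), quiet = TRUE), "unknown")
  dft <- df; dft$tss <- dft$tss + 0.5
  expect_error(read_annotations(write_ann(dft), quiet = TRUE), "integer")
})

test_that("GFF3 adapter maps strand-aware 5' ends to TSSs", {
  skip_if_not_installed("rtracklayer")
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttoga\tgene\t101\t500\t.\t+\t.\tID=gA;toga_status=Intact",
    "c1\ttoga\tgene\t701\t900\t.\t-\t.\tID=gB;toga_status=Lost",
    "c1\ttoga\tgene\t1001\t1200\t.\t-\t.\tID=gC;toga_status=ParalogousProjection"
  ), path)
  ann <- read_annotations_gff3(path, quiet = TRUE)
  expect_equal(ann$gene_id, c("gA", "gC"))
  expect_equal(ann$tss, c(100L, 1199L))  # 0-based, 5' end respects strand
})

test_that("TSS windows are symmetric, include the TSS base and clamp", {
  expect_equal(unname(tss_window(60000, 50000, 1e6)), c(10000, 110001))
  expect_equal(unname(tss_window(3000, 50000, 1e6)), c(0, 53001))
  expect_equal(unname(tss_window(999999, 10000, 1e6)), c(989999, 1e6))
})

test_that("interval merging joins overlapping and touching windows", {
  w <- data.frame(contig = "c1", start = c(0, 50), end = c(100, 150))
  ws <- merge_windows(w)
  expect_equal(ws$intervals$start, 0)
  expect_equal(ws$intervals$end, 150)
  expect_equal(ws$interrogated_bp, 150)

  w2 <- data.frame(contig = "c1", start = c(0, 200), end = c(100, 300))
  ws2 <- merge_windows(w2)
  expect_equal(nrow(ws2$intervals), 2L)
  expect_equal(ws2$interrogated_bp, 200)

  # touching intervals [a,b) + [b,c) merge
  w3 <- data.frame(contig = "c1", start = c(0, 100), end = c(100, 250))
  expect_equal(nrow(merge_windows(w3)$intervals), 1L)
})

test_that("merged union equals a per-base boolean-mask oracle", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 1000
    starts <- sample.int(50000, n) - 1L
    ends <- starts + sample.int(400, n, replace = TRUE)
    ws <- merge_windows(data.frame(contig = "c1", start = starts, end = ends))
    expect_equal(ws$interrogated_bp, mask_union_bp(starts, ends, 51000))
    # intervals disjoint and sorted
    iv <- ws$intervals
    expect_true(all(diff(iv$start) > 0))
    expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
  }
})

test_that("a hit near two genes is counted once in dedup mode, twice per-gene", {
  genes <- data.frame(gene_id = c("gA", "gB"), contig = "c1", strand = "+",
                      tss = c(40000L, 100000L), category = "Intact")
  hit <- data.frame(contig = "c1", start = 70000L, strand = "+",
                    motif_name = "ARE_canonical", hre_class = "ARE", width = 15L)
  clen <- c(c1 = 1e6)
  ws <- merge_windows(build_gene_windows(genes, 50000, clen), 50000)
  ded <- count_hits_dedup(hit, ws)
  expect_equal(unname(ded$by_class["ARE"]), 1L)
  pg <- count_hits_per_gene(hit, genes, 50000, clen)
  expect_equal(pg$ARE, c(1L, 1L))
  expect_equal(sum(pg$ARE), 2L)

  # hit outside all windows counts zero
  far <- hit; far$start <- 200000L
  expect_equal(unname(count_hits_dedup(far, ws)$by_class["ARE"]), 0L)
  # zero hits -> all zero
  none <- hit[0, ]
  expect_equal(unname(count_hits_dedup(none, ws)$by_class), c(0L, 0L))
})

test_that("hits on contigs without windows are counted as outside, with a message", {
  genes <- data.frame(gene_id = "gA", contig = "c1", strand = "+",
                      tss = 500L, category = "Intact")
  hit <- data.frame(contig = "cX", start = 500L, strand = "+",
                    motif_name = "ARE_canonical", hre_class = "ARE", width = 15L)
  ws <- merge_windows(build_gene_windows(genes, 1000, c(c1 = 10000)), 1000)
  expect_message(res <- count_hits_dedup(hit, ws), "no windows")
  expect_equal(unname(res$by_class["ARE"]), 0L)
})

test_that("per-gene counts match a nested-loop oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:5) {
    fx <- random_hits_fixture()
    flank <- 3000
    pg <- count_hits_per_gene(fx$hits, fx$genes, flank, fx$contig_lengths)
    for (i in seq_len(nrow(fx$genes))) {
      w <- tss_window(fx$genes$tss[i], flank, fx$contig_lengths[["c1"]])
      for (cls in c("ARE", "ERE")) {
        expected <- sum(fx$hits$hre_class == cls &
                        fx$hits$start >= w["start"] & fx$hits$start < w["end"])
        expect_equal(pg[[cls]][i], expected)
      }
    }
  }
})

test_that("dedup is bounded by the per-gene sum and monotone in flank", {
  set.seed(23)
  for (rep in 1:5) {
    fx <- random_hits_fixture()
    prev_dedup <- c(ARE = -1L, ERE = -1L)
    prev_bp <- -1
    for (flank in c(1000, 4000, 16000)) {
      ws <- merge_windows(build_gene_windows(fx$genes, flank, fx$contig_lengths), flank)
      ded <- count_hits_dedup(fx$hits, ws)$by_class
      pg <- count_hits_per_gene(fx$hits, fx$genes, flank, fx$contig_lengths)
      expect_lte(ded[["ARE"]], sum(pg$ARE))
      expect_lte(ded[["ERE"]], sum(pg$ERE))
      expect_true(all(ded >= prev_dedup))
      expect_gte(ws$interrogated_bp, prev_bp)
      expect_lte(ws$interrogated_bp, fx$contig_lengths[["c1"]])
      prev_dedup <- ded
      prev_bp <- ws$interrogated_bp
    }
  }
})

test_that("merged windows export as BED3", {
  w <- merge_windows(data.frame(contig = "c1", start = c(0, 200), end = c(100, 300)))
  path <- tempfile(fileext = ".bed")
  write_windows_bed(w, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, c(0, 200))
  expect_equal(bed$V3, c(100, 300))
})
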